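# Univariable and multivariable logistic regression of event occurrence
# on demographic and indication covariates, reported as odds ratios.
#
# Coding scheme (reference level first): sex F/M; age <18 / 18-65 / >=65;
# weight <50 / 50-80 / >=80 kg; indication autoimmune / transplant /
# other.  Complete cases per model: each univariable model uses its own
# covariate's complete cases, the multivariable model the joint complete
# cases -- which is why the two columns of the output can rest on
# different denominators.

default_risk_covariates <- c("sex", "age_bin", "weight_bin", "indication_group")

covariate_frame <- function(cohort, drug, covariates) {
  exp_flag <- exposed_flag(cohort, drug)
  data <- cohort[exp_flag, c("event", covariates), drop = FALSE]
  data$event <- as.integer(data$event)
  for (cv in covariates) {
    if (cv == "sex") {
      data[[cv]] <- factor(data[[cv]], levels = c("F", "M"))
    } else {
      data[[cv]] <- droplevels(as.factor(data[[cv]]))
    }
  }
  data
}

check_separation <- function(fit) {
  bad <- !is.na(coef(fit)) & abs(coef(fit)) > 15
  probs <- fit$fitted.values
  if (any(bad) && (any(probs < 1e-8) || any(probs > 1 - 1e-8))) {
    stop("Perfect separation detected for term(s): ",
         paste(names(coef(fit))[bad], collapse = ", "), call. = FALSE)
  }
  invisible(fit)
}

#' Fit the event logistic model
#'
#' Maximum-likelihood logistic regression of the binary event flag on
#' categorical covariates, by iteratively reweighted least squares
#' (tight convergence tolerance, at most 50 iterations).  Perfect
#' separation raises an error naming the offending term; non-convergence
#' raises an error with the iteration count.
#'
#' @param data Data frame with an integer `event` column (0/1) and
#'   factor covariates; rows with missing values are dropped (count
#'   reported in the result).
#' @param covariates Character vector of covariate column names.
#' @return A `glm` object with extra attributes `n_used` and
#'   `n_dropped`.
#' @export
fit_event_logistic <- function(data, covariates) {
  n_all <- nrow(data)
  data <- data[stats::complete.cases(data[, c("event", covariates)]), ,
               drop = FALSE]
  if (length(unique(data$event)) < 2) {
    stop("The outcome needs both classes among complete cases.", call. = FALSE)
  }
  if (nrow(data) <= length(covariates) + 1) {
    stop("Too few complete cases for the requested model.", call. = FALSE)
  }
  fml <- as.formula(paste("event ~", paste(covariates, collapse = " + ")))
  fit <- glm(fml, family = binomial(), data = data,
             control = list(epsilon = 1e-12, maxit = 50))
  if (!fit$converged) {
    stop("Logistic regression did not converge within ", fit$iter,
         " IRLS iterations.", call. = FALSE)
  }
  check_separation(fit)
  attr(fit, "n_used") <- nrow(data)
  attr(fit, "n_dropped") <- n_all - nrow(data)
  fit
}

or_rows <- function(fit, data, covariates, model_label) {
  est <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  z <- est / se
  p <- 2 * stats::pnorm(-abs(z))
  rows <- list()
  for (cv in covariates) {
    levs <- levels(data[[cv]])
    for (li in seq_along(levs)) {
      lev <- levs[li]
      sub <- data[[cv]] == lev
      nm <- paste0(cv, lev)
      ref <- li == 1
      rows[[length(rows) + 1]] <- tibble::tibble(
        covariate = cv,
        level = lev,
        assignment = li - 1L,
        reference = ref,
        n_no_event = sum(sub & data$event == 0, na.rm = TRUE),
        n_event = sum(sub & data$event == 1, na.rm = TRUE),
        or = if (ref) NA_real_ else unname(exp(est[nm])),
        conf.low = if (ref) NA_real_ else unname(exp(est[nm] - 1.96 * se[nm])),
        conf.high = if (ref) NA_real_ else unname(exp(est[nm] + 1.96 * se[nm])),
        p.value = if (ref) NA_real_ else unname(p[nm]),
        model = model_label,
        n_used = attr(fit, "n_used")
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Univariable odds-ratio table
#'
#' One single-covariate logistic model per covariate, each on its own
#' complete cases, for reports exposed to the drug; the outcome is the
#' SMQ event flag.  Covariates with fewer than two observed levels are
#' skipped with a warning (this is what happens to the indication term
#' for a single-indication drug).
#'
#' @param cohort A `faers_cohort`.
#' @param drug Study-drug key.
#' @param covariates Covariate columns (default sex, age bin, weight
#'   bin, indication group).
#' @return Tibble with reference and contrast rows per covariate: counts
#'   by outcome, `or`, Wald `conf.low`/`conf.high`, `p.value`.
#' @export
univariable_or <- function(cohort, drug, covariates = default_risk_covariates) {
  all_rows <- list()
  for (cv in covariates) {
    data <- covariate_frame(cohort, drug, cv)
    data <- data[!is.na(data[[cv]]), , drop = FALSE]
    data[[cv]] <- droplevels(data[[cv]])
    if (nlevels(data[[cv]]) < 2) {
      warning("Covariate '", cv, "' has fewer than two observed levels for '",
              drug, "'; skipped.", call. = FALSE)
      next
    }
    fit <- fit_event_logistic(data, cv)
    all_rows[[cv]] <- or_rows(fit, data, cv, "univariable")
  }
  out <- dplyr::bind_rows(all_rows)
  if (nrow(out) > 0) out$drug <- drug
  out
}

#' Multivariable odds-ratio table
#'
#' One joint logistic model with all covariates on the joint complete
#' cases; adjusted odds ratios per term.  Single-level covariates are
#' dropped with a warning before fitting.
#'
#' @inheritParams univariable_or
#' @return Tibble in the same shape as [univariable_or()], with
#'   `model = "multivariable"`.
#' @export
multivariable_or <- function(cohort, drug,
                             covariates = default_risk_covariates) {
  data <- covariate_frame(cohort, drug, covariates)
  data <- data[stats::complete.cases(data), , drop = FALSE]
  keep <- character()
  for (cv in covariates) {
    data[[cv]] <- droplevels(data[[cv]])
    if (nlevels(data[[cv]]) >= 2) {
      keep <- c(keep, cv)
    } else {
      warning("Covariate '", cv, "' has fewer than two observed levels for '",
              drug, "'; dropped from the joint model.", call. = FALSE)
    }
  }
  if (length(keep) == 0) {
    stop("No usable covariates for the multivariable model.", call. = FALSE)
  }
  fit <- fit_event_logistic(data, keep)
  out <- or_rows(fit, data, keep, "multivariable")
  out$drug <- drug
  out
}

#' Combined risk-factor table for a drug
#'
#' Joins the univariable and multivariable odds-ratio tables into one
#' display table.
#'
#' @inheritParams univariable_or
#' @return Tibble with one row per covariate level and columns for both
#'   models.
#' @export
risk_factor_table <- function(cohort, drug,
                              covariates = default_risk_covariates) {
  uni <- univariable_or(cohort, drug, covariates)
  multi <- multivariable_or(cohort, drug, covariates)
  if (nrow(uni) == 0) return(uni)
  uni <- dplyr::rename(uni, or_uni = "or", lo_uni = "conf.low",
                       hi_uni = "conf.high", p_uni = "p.value")
  multi <- dplyr::select(multi, "covariate", "level", or_multi = "or",
                         lo_multi = "conf.low", hi_multi = "conf.high",
                         p_multi = "p.value")
  out <- dplyr::left_join(uni, multi, by = c("covariate", "level"))
  dplyr::select(out, -"model")
}
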