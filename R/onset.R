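# Time-to-onset distributions and Weibull failure-type classification.
#
# Onset is the number of days from the earliest therapy start of the
# matched drug to the event date.  The Weibull shape parameter beta
# separates decreasing (beta < 1, "early failure"), constant (beta = 1,
# "random failure") and increasing (beta > 1, "wear-out failure") hazard
# profiles.

#' Median and interquartile range
#'
#' Quartiles by linear interpolation between order statistics at rank
#' `1 + (n - 1) p` (the type-7 convention).
#'
#' @param times Non-empty numeric vector.
#' @return List: `median`, `q1`, `q3`.
#' @export
median_iqr <- function(times) {
  times <- times[!is.na(times)]
  if (length(times) == 0) {
    stop("median_iqr() needs at least one observation.", call. = FALSE)
  }
  q <- unname(quantile(times, probs = c(0.25, 0.5, 0.75), type = 7))
  list(median = q[2], q1 = q[1], q3 = q[3])
}

#' Extract a drug's onset sample from a cohort
#'
#' Onset days of the drug's SMQ-matched reports.  Same-day events (onset
#' zero) are mapped to half a day because the Weibull support excludes
#' zero; missing onsets are dropped (complete-case analysis).
#'
#' @param cohort A `faers_cohort`.
#' @param drug Study-drug key.
#' @return Numeric vector of positive onset days.
#' @export
onset_sample <- function(cohort, drug) {
  x <- cohort[[paste0("onset_", drug)]][exposed_flag(cohort, drug) & cohort$event]
  x <- x[!is.na(x)]
  x[x == 0] <- 0.5
  x
}

weibull_loglik <- function(times, censored, alpha, beta) {
  u <- (times / alpha)^beta
  sum(ifelse(censored, 0,
             log(beta) - beta * log(alpha) + (beta - 1) * log(times))) - sum(u)
}

#' Fit a Weibull time-to-onset model
#'
#' Maximum likelihood for the Weibull density
#' `(beta/alpha) (t/alpha)^(beta-1) exp(-(t/alpha)^beta)`; right-censored
#' entries contribute survival terms.  The scale is profiled out,
#' `alpha(beta) = (sum(t_i^beta) / n_uncensored)^(1/beta)`, and the
#' profile score is solved for `beta` by bracketed root-finding
#' (tolerance 1e-10).  Confidence intervals are Wald intervals on the
#' untransformed parameters from the observed information matrix; the
#' failure type follows from the position of the shape interval relative
#' to 1 (upper bound < 1: early; lower bound > 1: wear-out; otherwise
#' random).
#'
#' @param times Positive onset days.
#' @param censored Optional logical vector (`TRUE` = right-censored);
#'   default all observed.
#' @param conf Confidence level for the Wald intervals.
#' @param min_n Minimum number of uncensored observations.
#' @return A `weibull_fit` object: `alpha`, `alpha_ci`, `beta`,
#'   `beta_ci`, `n`, `n_censored`, `loglik`, `vcov`, `failure_type`.
#' @export
fit_weibull_onset <- function(times, censored = NULL, conf = 0.95, min_n = 10) {
  if (is.null(censored)) censored <- rep(FALSE, length(times))
  stopifnot(length(censored) == length(times))
  keep <- !is.na(times)
  times <- times[keep]
  censored <- censored[keep]
  if (any(times <= 0)) {
    stop("Onset times must be positive (map same-day events to 0.5 days).",
         call. = FALSE)
  }
  n_unc <- sum(!censored)
  if (n_unc < min_n) {
    stop("Weibull fit needs at least ", min_n, " uncensored onset times (got ",
         n_unc, ").", call. = FALSE)
  }
  tu <- times[!censored]
  if (diff(range(tu)) == 0) {
    stop("Degenerate onset sample: all uncensored times are equal, the ",
         "shape parameter is unbounded.", call. = FALSE)
  }
  # profile score in beta; log-scaled times for numerical stability
  score <- function(beta) {
    tb <- times^beta
    n_unc / beta + sum(log(tu)) - n_unc * sum(tb * log(times)) / sum(tb)
  }
  lo <- 1e-3
  hi <- 10
  while (score(hi) > 0 && hi < 1e4) hi <- hi * 2
  while (score(lo) < 0 && lo > 1e-8) lo <- lo / 2
  beta <- uniroot(score, lower = lo, upper = hi, tol = 1e-10)$root
  alpha <- (sum(times^beta) / n_unc)^(1 / beta)

  # observed information from the analytic Hessian of the full loglik
  u <- (times / alpha)^beta
  lt <- log(times / alpha)
  h_aa <- -(beta / alpha^2) * (sum(u) - n_unc) - (beta^2 / alpha^2) * sum(u)
  h_bb <- -n_unc / beta^2 - sum(u * lt^2)
  h_ab <- (1 / alpha) * (sum(u) - n_unc) + (beta / alpha) * sum(u * lt)
  info <- -matrix(c(h_aa, h_ab, h_ab, h_bb), 2, 2)
  vc <- solve(info)
  z <- -stats::qnorm((1 - conf) / 2)
  alpha_ci <- alpha + c(-1, 1) * z * sqrt(vc[1, 1])
  beta_ci <- beta + c(-1, 1) * z * sqrt(vc[2, 2])

  fit <- structure(list(
    alpha = alpha, alpha_ci = alpha_ci,
    beta = beta, beta_ci = beta_ci,
    n = length(times), n_censored = sum(censored),
    conf = conf,
    loglik = weibull_loglik(times, censored, alpha, beta),
    vcov = vc,
    failure_type = NA_character_
  ), class = "weibull_fit")
  fit$failure_type <- classify_failure(fit)
  fit
}

#' Classify the hazard profile from a Weibull fit
#'
#' `early` when the shape interval lies entirely below 1 (decreasing
#' hazard), `wearout` when entirely above 1, `random` when the interval
#' straddles 1.  The interval -- not the point estimate -- drives the
#' call.
#'
#' @param fit A `weibull_fit`.
#' @return `"early"`, `"random"` or `"wearout"`.
#' @export
classify_failure <- function(fit) {
  stopifnot(inherits(fit, "weibull_fit"))
  if (fit$beta_ci[2] < 1) "early"
  else if (fit$beta_ci[1] > 1) "wearout"
  else "random"
}

#' @export
print.weibull_fit <- function(x, ...) {
  cat("<weibull_fit> n =", x$n,
      if (x$n_censored > 0) paste0("(", x$n_censored, " censored)"), "\n")
  cat("  scale alpha =", signif(x$alpha, 6), " CI [",
      signif(x$alpha_ci[1], 6), ",", signif(x$alpha_ci[2], 6), "]\n")
  cat("  shape beta  =", signif(x$beta, 6), " CI [",
      signif(x$beta_ci[1], 6), ",", signif(x$beta_ci[2], 6), "]\n")
  cat("  failure type:", x$failure_type, "\n")
  invisible(x)
}

#' @export
tidy.weibull_fit <- function(x, ...) {
  tibble::tibble(
    term = c("alpha", "beta"),
    estimate = c(x$alpha, x$beta),
    std.error = sqrt(diag(x$vcov)),
    conf.low = c(x$alpha_ci[1], x$beta_ci[1]),
    conf.high = c(x$alpha_ci[2], x$beta_ci[2])
  )
}

#' @export
glance.weibull_fit <- function(x, ...) {
  tibble::tibble(n = x$n, n_censored = x$n_censored, logLik = x$loglik,
                 failure_type = x$failure_type)
}

#' Onset summary and Weibull fit per study drug
#'
#' @param cohort A `faers_cohort`.
#' @param drugs Study-drug keys.
#' @param min_n Minimum uncensored sample per drug; drugs with fewer
#'   onset observations are skipped with a warning.
#' @return Tibble: `drug`, `n`, `median`, `q1`, `q3`, `alpha`,
#'   `alpha_lo`, `alpha_hi`, `beta`, `beta_lo`, `beta_hi`,
#'   `failure_type`.
#' @export
weibull_onset_table <- function(cohort, drugs = cohort_drugs(cohort),
                                min_n = 10) {
  rows <- lapply(drugs, function(k) {
    x <- onset_sample(cohort, k)
    if (length(x) < min_n) {
      warning("Skipping Weibull fit for '", k, "': only ", length(x),
              " onset observations.", call. = FALSE)
      return(NULL)
    }
    fit <- fit_weibull_onset(x, min_n = min_n)
    q <- median_iqr(x)
    tibble::tibble(
      drug = k, n = length(x),
      median = q$median, q1 = q$q1, q3 = q$q3,
      alpha = fit$alpha, alpha_lo = fit$alpha_ci[1], alpha_hi = fit$alpha_ci[2],
      beta = fit$beta, beta_lo = fit$beta_ci[1], beta_hi = fit$beta_ci[2],
      failure_type = fit$failure_type
    )
  })
  dplyr::bind_rows(rows)
}

#' Binned onset distribution per drug
#'
#' Counts and shares of onset days in the conventional display bins.
#'
#' @param cohort A `faers_cohort`.
#' @param drugs Study-drug keys.
#' @param breaks Right-closed bin edges in days.
#' @return Tibble: `drug`, `bin`, `n`, `pct`.
#' @export
onset_bin_table <- function(cohort, drugs = cohort_drugs(cohort),
                            breaks = c(0, 30, 90, 180, 360, Inf)) {
  labels <- paste0(
    c(0, utils::head(breaks[-1], -1) + 1),
    ifelse(is.finite(breaks[-1]), paste0("-", breaks[-1]), "+")
  )
  labels <- sub("^361\\+$", ">360", labels)
  dplyr::bind_rows(lapply(drugs, function(k) {
    x <- onset_sample(cohort, k)
    if (length(x) == 0) return(NULL)
    bin <- cut(x, breaks = breaks, labels = labels, include.lowest = TRUE)
    tab <- table(bin)
    tibble::tibble(
      drug = k, bin = names(tab), n = as.integer(tab),
      pct = round_half_up(100 * as.integer(tab) / length(x), 1)
    )
  }))
}
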