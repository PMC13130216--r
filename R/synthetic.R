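# Synthetic FAERS-like report generator with analytic ground truth.
#
# The generator emits report batches in the same shape as the file parser
# so the whole pipeline -- dedup, cohorting, disproportionality, onset
# modelling, risk factors -- can be exercised and validated against known
# truth without access to the live database.

check_prob <- function(x, name, open_upper = FALSE) {
  ok <- is.numeric(x) && all(!is.na(x)) && all(x >= 0) &&
    all(if (open_upper) x < 1 else x <= 1)
  if (!ok) {
    stop("Synthetic configuration error: '", name, "' must be a probability",
         if (open_upper) " in [0, 1)", ".", call. = FALSE)
  }
  invisible(x)
}

#' Default study-drug exposure probabilities
#'
#' Marginal exposure probabilities for the three calcineurin inhibitors,
#' proportional to their shares of adverse-event reports in the public
#' database (scaled up so that desk-sized batches contain workable
#' exposed counts), plus reporting-ratio and Weibull onset parameters per
#' drug.
#'
#' @return Tibble with columns `drug`, `exposure_prob`, `rho`,
#'   `onset_scale` (days), `onset_shape`.
#' @export
default_study_drugs <- function() {
  tibble::tibble(
    drug = c("cyclosporine", "tacrolimus", "voclosporin"),
    exposure_prob = c(0.044, 0.057, 0.005),
    rho = c(2.6, 3.5, 3.3),
    onset_scale = c(225.04, 241.17, 216.05),
    onset_shape = c(0.47, 0.48, 0.88)
  )
}

default_renal_events <- function() {
  tibble::tibble(
    pt = c(
      "acute kidney injury", "renal impairment", "blood creatinine increased",
      "renal failure", "proteinuria", "glomerular filtration rate decreased",
      "chronic kidney disease", "thrombotic microangiopathy",
      "nephropathy toxic", "renal tubular necrosis", "oliguria", "haematuria"
    ),
    baseline_prob = c(0.018, 0.014, 0.012, 0.009, 0.007, 0.005,
                      0.004, 0.003, 0.003, 0.002, 0.002, 0.002)
  )
}

default_background_events <- function() {
  tibble::tibble(
    pt = c("nausea", "headache", "diarrhoea", "fatigue", "pyrexia", "vomiting",
           "rash", "dyspnoea", "dizziness", "drug ineffective", "anaemia",
           "pruritus", "insomnia", "cough", "arthralgia"),
    baseline_prob = c(0.05, 0.04, 0.04, 0.04, 0.03, 0.03, 0.03, 0.03,
                      0.025, 0.05, 0.02, 0.02, 0.02, 0.02, 0.02)
  )
}

default_background_drugs <- function() {
  tibble::tibble(
    drug = paste0("comedication_", letters[1:8]),
    exposure_prob = rep(0.06, 8)
  )
}

#' Configure the synthetic report generator
#'
#' Full parameterisation of the FAERS-like batch generator.  Defaults
#' emulate the published calcineurin-inhibitor renal-injury setting: three
#' study drugs with exposure shares proportional to their report volumes,
#' a renal SMQ-style event set whose drug-conditional reporting ratios
#' reproduce renal reporting proportions of roughly 21--27%, Weibull
#' onset parameters per drug, demographic marginals and missingness rates
#' matching the published descriptive table, and a 10% injected duplicate
#' rate.
#'
#' @param n_reports Number of distinct cases to generate.
#' @param drugs Tibble `drug`/`exposure_prob` and optionally `rho`
#'   (reporting ratio applied to every event PT), `onset_scale`,
#'   `onset_shape` (Weibull, days).
#' @param background_drugs Tibble `drug`/`exposure_prob` of comparator
#'   drugs filling out the reporting universe.
#' @param events Tibble `pt`/`baseline_prob`: the event set targeted by
#'   the SMQ under study.
#' @param background_events Tibble `pt`/`baseline_prob` of unrelated
#'   reactions.
#' @param effect Optional tibble `drug`/`pt`/`rho` of per-pair reporting
#'   ratios; overrides the per-drug `rho` for listed pairs.  For an
#'   exposed report the event PT is included with probability
#'   `min(1, rho * baseline_prob)`; unexposed reports use
#'   `baseline_prob`.
#' @param sex_split Probability that a non-missing sex is male.
#' @param sex_missing,age_missing,weight_missing,reporter_missing,country_missing,outcome_missing,indication_missing
#'   Missingness rates (missing completely at random).
#' @param age_mean,age_sd,weight_mean,weight_sd Normal parameters for age
#'   (years, truncated at 0) and weight (kg, truncated at 2).
#' @param reporter_probs,country_probs Named probability vectors for the
#'   reporter occupation and 2-letter country codes.
#' @param outcome_probs Named probabilities of outcome codes given an
#'   outcome is recorded; must sum to at most 1, remainder goes to `OT`.
#' @param indication_probs Named list per study drug: probabilities over
#'   `autoimmune`/`transplant`/`other` indication groups.
#' @param duplicate_rate Fraction of cases emitted as 2--3 versions with
#'   increasing FDA dates and primary ids (the latest version carries the
#'   true content).
#' @param date_range Character vector of two dates bounding therapy
#'   start dates.
#' @param seed Integer seed; every stochastic choice in
#'   [simulate_reports()] flows from it.
#' @return A validated `synthetic_config` object.
#' @export
synthetic_config <- function(n_reports = 20000,
                             drugs = default_study_drugs(),
                             background_drugs = default_background_drugs(),
                             events = default_renal_events(),
                             background_events = default_background_events(),
                             effect = NULL,
                             sex_split = 0.555,
                             sex_missing = 0.40,
                             age_mean = 50, age_sd = 17, age_missing = 0.47,
                             weight_mean = 62, weight_sd = 18, weight_missing = 0.88,
                             reporter_probs = c(physician = 0.33, pharmacist = 0.04,
                                                other_health = 0.46, consumer = 0.17),
                             reporter_missing = 0.36,
                             country_probs = c(US = 0.34, JP = 0.15, FR = 0.07,
                                               GB = 0.05, DE = 0.05, CA = 0.04,
                                               ES = 0.04, IT = 0.03, CN = 0.03,
                                               IN = 0.03, BR = 0.17),
                             country_missing = 0.36,
                             outcome_probs = c(DE = 0.164, LT = 0.052,
                                               HO = 0.366, DS = 0.004),
                             outcome_missing = 0.37,
                             indication_probs = list(
                               cyclosporine = c(autoimmune = 0.40, transplant = 0.45, other = 0.15),
                               tacrolimus = c(autoimmune = 0.25, transplant = 0.60, other = 0.15),
                               voclosporin = c(autoimmune = 1.00, transplant = 0.00, other = 0.00)
                             ),
                             indication_missing = 0.30,
                             duplicate_rate = 0.10,
                             date_range = c("2004-01-01", "2024-06-30"),
                             seed = NULL) {
  stopifnot(is.numeric(n_reports), length(n_reports) == 1, n_reports >= 1)
  drugs <- tibble::as_tibble(drugs)
  if (!all(c("drug", "exposure_prob") %in% names(drugs)) || nrow(drugs) == 0) {
    stop("Synthetic configuration error: 'drugs' needs columns drug and ",
         "exposure_prob.", call. = FALSE)
  }
  if (!"rho" %in% names(drugs)) drugs$rho <- 1
  if (!"onset_scale" %in% names(drugs)) drugs$onset_scale <- 120
  if (!"onset_shape" %in% names(drugs)) drugs$onset_shape <- 1
  check_prob(drugs$exposure_prob, "drugs$exposure_prob", open_upper = TRUE)
  if (any(drugs$exposure_prob <= 0)) {
    stop("Synthetic configuration error: exposure probabilities must be in (0, 1).",
         call. = FALSE)
  }
  if (any(!is.finite(drugs$rho)) || any(drugs$rho < 0)) {
    stop("Synthetic configuration error: reporting ratios must be finite and >= 0.",
         call. = FALSE)
  }
  if (any(drugs$onset_scale <= 0) || any(drugs$onset_shape <= 0)) {
    stop("Synthetic configuration error: Weibull onset parameters must be positive.",
         call. = FALSE)
  }
  background_drugs <- tibble::as_tibble(background_drugs)
  check_prob(background_drugs$exposure_prob, "background_drugs$exposure_prob",
             open_upper = TRUE)
  events <- tibble::as_tibble(events)
  background_events <- tibble::as_tibble(background_events)
  check_prob(events$baseline_prob, "events$baseline_prob", open_upper = TRUE)
  if (any(events$baseline_prob <= 0)) {
    stop("Synthetic configuration error: baseline event probabilities must be ",
         "in (0, 1).", call. = FALSE)
  }
  check_prob(background_events$baseline_prob, "background_events$baseline_prob",
             open_upper = TRUE)
  if (is.null(effect)) {
    effect <- tidyr::expand_grid(drug = drugs$drug, pt = events$pt)
    effect$rho <- drugs$rho[match(effect$drug, drugs$drug)]
  } else {
    effect <- tibble::as_tibble(effect)
    stopifnot(all(c("drug", "pt", "rho") %in% names(effect)))
    base <- tidyr::expand_grid(drug = drugs$drug, pt = events$pt)
    base$rho <- drugs$rho[match(base$drug, drugs$drug)]
    base <- dplyr::rows_update(base, effect[, c("drug", "pt", "rho")],
                               by = c("drug", "pt"), unmatched = "error")
    effect <- base
  }
  if (any(!is.finite(effect$rho)) || any(effect$rho < 0)) {
    stop("Synthetic configuration error: effect ratios must be finite and >= 0.",
         call. = FALSE)
  }
  check_prob(sex_split, "sex_split")
  check_prob(sex_missing, "sex_missing", open_upper = TRUE)
  check_prob(age_missing, "age_missing", open_upper = TRUE)
  check_prob(weight_missing, "weight_missing", open_upper = TRUE)
  check_prob(reporter_missing, "reporter_missing", open_upper = TRUE)
  check_prob(country_missing, "country_missing", open_upper = TRUE)
  check_prob(outcome_missing, "outcome_missing", open_upper = TRUE)
  check_prob(duplicate_rate, "duplicate_rate", open_upper = TRUE)
  check_prob(outcome_probs, "outcome_probs")
  if (sum(outcome_probs) > 1 + 1e-12) {
    stop("Synthetic configuration error: outcome probabilities must sum to ",
         "at most 1 (remainder is assigned to OT).", call. = FALSE)
  }
  cfg <- structure(list(
    n_reports = as.integer(n_reports),
    drugs = drugs, background_drugs = background_drugs,
    events = events, background_events = background_events,
    effect = effect,
    sex_split = sex_split, sex_missing = sex_missing,
    age_mean = age_mean, age_sd = age_sd, age_missing = age_missing,
    weight_mean = weight_mean, weight_sd = weight_sd,
    weight_missing = weight_missing,
    reporter_probs = reporter_probs / sum(reporter_probs),
    reporter_missing = reporter_missing,
    country_probs = country_probs / sum(country_probs),
    country_missing = country_missing,
    outcome_probs = outcome_probs, outcome_missing = outcome_missing,
    indication_probs = indication_probs,
    indication_missing = check_prob(indication_missing, "indication_missing",
                                    open_upper = TRUE),
    duplicate_rate = duplicate_rate,
    date_range = as.Date(date_range),
    seed = seed
  ), class = "synthetic_config")
  cfg
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("<synthetic_config> ", x$n_reports, " reports; ",
      nrow(x$drugs), " study + ", nrow(x$background_drugs),
      " background drugs; ", nrow(x$events), " target + ",
      nrow(x$background_events), " background event PTs; duplicate rate ",
      x$duplicate_rate, "\n", sep = "")
  invisible(x)
}

sample_cat <- function(n, probs, missing_rate) {
  out <- sample(names(probs), n, replace = TRUE, prob = probs)
  out[runif(n) < missing_rate] <- NA_character_
  out
}

#' Generate a synthetic report batch
#'
#' Draws `n_reports` cases under the configured generative model and
#' returns them in the same `faers_reports` shape as
#' [read_faers_quarter()].  Exposure flags are independent Bernoulli
#' draws; for a report exposed to drugs with reporting ratio `rho` on an
#' event PT the inclusion probability is `min(1, max(rho) *
#' baseline_prob)`, otherwise `baseline_prob`.  Onset days for a study
#' drug's event reports are Weibull draws rounded up to at least one day;
#' the event date is the therapy start plus onset, and the FDA receipt
#' date follows after a reporting delay.  A `duplicate_rate` fraction of
#' cases is emitted as 2--3 versions with increasing receipt date and
#' primary id (the last version is the truth that deduplication should
#' recover).
#'
#' @param config A `synthetic_config`.
#' @param seed Overrides `config$seed`.
#' @return A `faers_reports` tibble with attribute `truth`
#'   (list: `n_cases`, `n_versions`, `config`).
#' @export
simulate_reports <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "synthetic_config"))
  if (is.null(seed)) {
    stop("simulate_reports() needs a seed (in the config or as an argument).",
         call. = FALSE)
  }
  withr::with_seed(as.integer(seed), simulate_reports_impl(config))
}

simulate_reports_impl <- function(config) {
  n <- config$n_reports
  case_id <- seq_len(n)

  all_drugs <- dplyr::bind_rows(
    config$drugs[, c("drug", "exposure_prob")],
    config$background_drugs[, c("drug", "exposure_prob")]
  )
  K <- nrow(all_drugs)
  exposed <- matrix(runif(n * K) < rep(all_drugs$exposure_prob, each = n),
                    nrow = n)
  colnames(exposed) <- all_drugs$drug
  # every report lists at least one drug
  none <- rowSums(exposed) == 0
  if (any(none)) {
    filler <- sample.int(nrow(config$background_drugs), sum(none), replace = TRUE)
    exposed[cbind(which(none), nrow(config$drugs) + filler)] <- TRUE
  }

  all_events <- dplyr::bind_rows(config$events, config$background_events)
  J <- nrow(all_events)
  target <- all_events$pt %in% config$events$pt
  # effective reporting ratio per report x event PT: max over the exposed
  # study drugs carrying an effect on that PT; reports exposed to none of
  # them sit at the baseline (rho = 1)
  rho_eff <- matrix(-Inf, nrow = n, ncol = J)
  for (i in seq_len(nrow(config$effect))) {
    d <- config$effect$drug[i]
    j <- match(config$effect$pt[i], all_events$pt)
    rho_eff[exposed[, d], j] <- pmax(rho_eff[exposed[, d], j],
                                     config$effect$rho[i])
  }
  rho_eff[!is.finite(rho_eff)] <- 1
  p_evt <- pmin(1, sweep(rho_eff, 2, all_events$baseline_prob, "*"))
  has_evt <- matrix(runif(n * J), nrow = n) < p_evt
  colnames(has_evt) <- all_events$pt

  reactions <- apply(has_evt, 1, function(r) all_events$pt[r], simplify = FALSE)
  empty <- lengths(reactions) == 0
  if (any(empty)) {
    reactions[empty] <- as.list(sample(config$background_events$pt,
                                       sum(empty), replace = TRUE))
  }

  # demographics
  sex <- ifelse(runif(n) < config$sex_split, "M", "F")
  sex[runif(n) < config$sex_missing] <- NA_character_
  age <- pmax(0, rnorm(n, config$age_mean, config$age_sd))
  age[runif(n) < config$age_missing] <- NA_real_
  weight <- pmax(2, rnorm(n, config$weight_mean, config$weight_sd))
  weight[runif(n) < config$weight_missing] <- NA_real_
  reporter <- sample_cat(n, config$reporter_probs, config$reporter_missing)
  country <- sample_cat(n, config$country_probs, config$country_missing)

  # outcomes: drawn for reports with a recorded outcome; remainder of the
  # configured mass goes to OT
  probs <- config$outcome_probs
  probs <- c(probs, OT = max(0, 1 - sum(probs)))
  probs <- probs[probs > 0]
  outcome <- sample(names(probs), n, replace = TRUE, prob = probs)
  outcome[runif(n) < config$outcome_missing] <- NA_character_
  outcomes <- lapply(outcome, function(o) if (is.na(o)) character() else o)

  # therapy start dates and the event date
  span <- as.integer(config$date_range[2] - config$date_range[1])
  start_date <- config$date_range[1] + sample.int(span + 1L, n, replace = TRUE) - 1L
  study <- config$drugs
  target_evt <- rowSums(has_evt[, target, drop = FALSE]) > 0
  onset <- sample.int(365L, n, replace = TRUE)  # background latency
  for (i in seq_len(nrow(study))) {
    idx <- which(exposed[, study$drug[i]] & target_evt)
    if (length(idx) > 0) {
      onset[idx] <- pmax(1, ceiling(
        rweibull(length(idx), shape = study$onset_shape[i],
                 scale = study$onset_scale[i])
      ))
    }
  }
  event_date <- start_date + onset
  fda_date <- event_date + 7L + sample.int(90L, n, replace = TRUE)

  # long tables
  drug_rows <- which(exposed, arr.ind = TRUE)
  drug_rows <- drug_rows[order(drug_rows[, 1], drug_rows[, 2]), , drop = FALSE]
  seq_within <- stats::ave(drug_rows[, 1], drug_rows[, 1], FUN = seq_along)
  drug_tbl <- tibble::tibble(
    primary_id = as.numeric(drug_rows[, 1]),
    seq = as.integer(seq_within),
    name = all_drugs$drug[drug_rows[, 2]],
    role = "PS"
  )
  ther_tbl <- tibble::tibble(
    primary_id = drug_tbl$primary_id,
    drug_seq = drug_tbl$seq,
    start_date = start_date[drug_tbl$primary_id],
    end_date = as.Date(NA)
  )
  # indications attach to study-drug entries
  ind_rows <- drug_tbl[drug_tbl$name %in% study$drug, , drop = FALSE]
  if (nrow(ind_rows) > 0) {
    grp <- character(nrow(ind_rows))
    for (d in unique(ind_rows$name)) {
      p <- config$indication_probs[[d]]
      if (is.null(p)) p <- c(autoimmune = 1 / 3, transplant = 1 / 3, other = 1 / 3)
      sel <- ind_rows$name == d
      grp[sel] <- sample(names(p), sum(sel), replace = TRUE, prob = p)
    }
    ind_pt <- dplyr::case_when(
      grp == "autoimmune" ~ "systemic lupus erythematosus",
      grp == "transplant" ~ "renal transplant",
      TRUE ~ "hypertension"
    )
    indi_tbl <- tibble::tibble(primary_id = ind_rows$primary_id,
                               drug_seq = ind_rows$seq, pt = ind_pt)
    indi_tbl <- indi_tbl[runif(nrow(indi_tbl)) >= config$indication_missing, ,
                         drop = FALSE]
  } else {
    indi_tbl <- empty_indications()
    indi_tbl$primary_id <- numeric()
  }

  reac_tbl <- tibble::tibble(
    primary_id = rep(as.numeric(case_id), lengths(reactions)),
    pt = unlist(reactions, use.names = FALSE)
  )
  outc_tbl <- tibble::tibble(
    primary_id = rep(as.numeric(case_id), lengths(outcomes)),
    code = unlist(outcomes, use.names = FALSE) %||% character()
  )

  # duplicate case versions: truth gets the highest primary id and the
  # latest receipt date; earlier versions are content copies
  truth_pid <- as.numeric(case_id) + 2 * n
  dup <- runif(n) < config$duplicate_rate
  n_extra <- integer(n)
  n_extra[dup] <- sample(1:2, sum(dup), replace = TRUE)
  version_pid <- list(as.numeric(case_id), as.numeric(case_id) + n)

  demo_tbl <- tibble::tibble(
    primary_id = truth_pid,
    case_id = as.numeric(case_id),
    fda_date = fda_date,
    event_date = event_date,
    sex = dplyr::if_else(is.na(sex), "unknown", sex),
    age_years = age,
    weight_kg = weight,
    reporter = reporter,
    country = country
  )
  child <- list(drug = drug_tbl, reac = reac_tbl, outc = outc_tbl,
                ther = ther_tbl, indi = indi_tbl)
  # remap child tables from case id to truth pid, then append duplicates
  remap <- function(tbl, from, to) {
    idx <- match(tbl$primary_id, from)
    keep <- !is.na(idx)
    out <- tbl[keep, , drop = FALSE]
    out$primary_id <- to[idx[keep]]
    out
  }
  demo_all <- demo_tbl
  child_all <- lapply(child, remap, from = as.numeric(case_id), to = truth_pid)
  for (v in 1:2) {
    sel <- n_extra >= v
    if (!any(sel)) next
    demo_v <- demo_tbl[sel, , drop = FALSE]
    demo_v$primary_id <- version_pid[[v]][sel]
    demo_v$fda_date <- demo_v$fda_date - (3L - v) * 45L
    demo_all <- dplyr::bind_rows(demo_all, demo_v)
    child_all <- Map(function(acc, tbl) {
      dplyr::bind_rows(acc, remap(tbl, as.numeric(case_id)[sel],
                                  version_pid[[v]][sel]))
    }, child_all, child)
  }
  ord <- order(demo_all$primary_id)
  demo_all <- demo_all[ord, , drop = FALSE]

  reports <- assemble_reports(demo_all, child_all$drug, child_all$reac,
                              child_all$outc, child_all$ther, child_all$indi)
  attr(reports, "truth") <- list(
    n_cases = n,
    n_versions = nrow(demo_all),
    config = config
  )
  reports
}

#' Lexicon and SMQ implied by a synthetic configuration
#'
#' Convenience accessors so a simulated batch can be cohorted with the
#' exact drug keys and event set it was generated from.
#'
#' @param config A `synthetic_config`.
#' @return `synthetic_lexicon()`: named list; `synthetic_smq()`: an
#'   `smq_definition`.
#' @export
synthetic_lexicon <- function(config) {
  setNames(as.list(config$drugs$drug), config$drugs$drug)
}

#' @rdname synthetic_lexicon
#' @export
synthetic_smq <- function(config) {
  smq_definition("synthetic renal SMQ", config$events$pt, scope = "narrow")
}

#' Analytic reporting odds ratio implied by the generator
#'
#' Closed-form odds ratio of the report-level 2x2 table for one study
#' drug and one event PT under the generative model, marginalising over
#' the other study drugs' independent exposures (whose reporting ratios
#' also shift the unexposed arm's event probability).  Used as the
#' recovery target in validation studies.
#'
#' @param config A `synthetic_config`.
#' @param drug Study-drug key.
#' @param pt Event PT.
#' @return The true odds ratio (0 when `rho = 0`).
#' @export
true_ror <- function(config, drug, pt) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!drug %in% config$drugs$drug) {
    stop("Unknown study drug '", drug, "'.", call. = FALSE)
  }
  if (!pt %in% config$events$pt) {
    stop("Unknown event PT '", pt, "'.", call. = FALSE)
  }
  p0 <- config$events$baseline_prob[config$events$pt == pt]
  eff <- config$effect[config$effect$pt == pt, , drop = FALSE]
  rho_of <- function(d) {
    r <- eff$rho[eff$drug == d]
    if (length(r) == 0) 1 else r
  }
  others <- setdiff(config$drugs$drug, drug)
  # enumerate exposure patterns of the other study drugs (a single empty
  # pattern when the target is the only study drug)
  patterns <- if (length(others) == 0) {
    data.frame(row.names = "1")
  } else {
    expand.grid(rep(list(c(FALSE, TRUE)), length(others)))
  }
  p_event_given <- function(target_exposed) {
    total <- 0
    for (r in seq_len(nrow(patterns))) {
      w <- 1
      rhos <- if (target_exposed) rho_of(drug) else numeric()
      for (k in seq_along(others)) {
        q <- config$drugs$exposure_prob[config$drugs$drug == others[k]]
        if (isTRUE(patterns[r, k])) {
          w <- w * q
          rhos <- c(rhos, rho_of(others[k]))
        } else {
          w <- w * (1 - q)
        }
      }
      # mirror of the generator's rule: max rho over exposed effect drugs,
      # baseline when none are present
      p <- if (length(rhos) == 0) p0 else min(1, max(rhos) * p0)
      total <- total + w * p
    }
    total
  }
  p1 <- p_event_given(TRUE)
  p0m <- p_event_given(FALSE)
  if (p1 == 0) return(0)
  (p1 / (1 - p1)) / (p0m / (1 - p0m))
}
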