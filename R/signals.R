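# Positivity thresholds, joint classification, PT-level scans, rankings
# and descriptive summaries.

#' Positivity thresholds for the four algorithms
#'
#' The conventional criteria: ROR positive when cases >= 3 and the lower
#' 95% bound exceeds 1; PRR positive when cases >= 3, PRR >= 2 and
#' chi-square >= 4; BCPNN positive when cases >= 3 and IC025 > 0; MGPS
#' positive when the empirical Bayes geometric mean exceeds 2 (the EB05
#' lower bound can be selected instead).  The case-count gate applies to
#' all four.  A pair is a *valid* signal when at least
#' `valid_min_algorithms` criteria hold and a *strong* signal when all
#' four hold.
#'
#' @param min_cases,ror_lo_gt,prr_min,chi2_min,ic025_gt,ebgm_min Cutoffs.
#' @param ebgm_criterion Apply `ebgm_min` to `"ebgm"` or `"eb05"`.
#' @param valid_min_algorithms Number of positive algorithms required for
#'   a valid signal (1--4).
#' @return A `signal_thresholds` list.
#' @export
signal_thresholds <- function(min_cases = 3, ror_lo_gt = 1, prr_min = 2,
                              chi2_min = 4, ic025_gt = 0, ebgm_min = 2,
                              ebgm_criterion = c("ebgm", "eb05"),
                              valid_min_algorithms = 2) {
  ebgm_criterion <- match.arg(ebgm_criterion)
  vals <- c(min_cases, ror_lo_gt, prr_min, chi2_min, ic025_gt, ebgm_min)
  if (any(!is.finite(vals))) {
    stop("Signal thresholds must be finite.", call. = FALSE)
  }
  if (!valid_min_algorithms %in% 1:4) {
    stop("valid_min_algorithms must be between 1 and 4.", call. = FALSE)
  }
  structure(list(
    min_cases = min_cases, ror_lo_gt = ror_lo_gt, prr_min = prr_min,
    chi2_min = chi2_min, ic025_gt = ic025_gt, ebgm_min = ebgm_min,
    ebgm_criterion = ebgm_criterion,
    valid_min_algorithms = valid_min_algorithms
  ), class = "signal_thresholds")
}

#' Apply thresholds and the joint classification
#'
#' Adds per-algorithm positivity flags (`ror_pos`, `prr_pos`,
#' `bcpnn_pos`, `mgps_pos`), the number of positive algorithms, and the
#' joint `classification` (`none` / `valid` / `strong`).  Undefined
#' statistics (`NA`) never count as positive.
#'
#' @param stats Tibble from [signal_stats()] (needs `cases`, `ror_lo`,
#'   `prr`, `chi2`, `ic025` and -- if MGPS is to contribute -- `ebgm` /
#'   `eb05`).
#' @param thresholds A [signal_thresholds()] object.
#' @return `stats` with the verdict columns appended.
#' @export
evaluate_signals <- function(stats, thresholds = signal_thresholds()) {
  stopifnot(inherits(thresholds, "signal_thresholds"))
  stats <- tibble::as_tibble(stats)
  gate <- !is.na(stats$cases) & stats$cases >= thresholds$min_cases
  flag <- function(x, test) gate & !is.na(x) & test(x)
  stats$ror_pos <- flag(stats$ror_lo, function(x) x > thresholds$ror_lo_gt)
  stats$prr_pos <- flag(stats$prr, function(x) x >= thresholds$prr_min) &
    !is.na(stats$chi2) & stats$chi2 >= thresholds$chi2_min
  stats$bcpnn_pos <- flag(stats$ic025, function(x) x > thresholds$ic025_gt)
  eb <- if (thresholds$ebgm_criterion == "eb05") stats[["eb05"]] else stats[["ebgm"]]
  if (is.null(eb)) eb <- rep(NA_real_, nrow(stats))
  stats$mgps_pos <- flag(eb, function(x) x > thresholds$ebgm_min)
  stats$n_pos <- stats$ror_pos + stats$prr_pos + stats$bcpnn_pos + stats$mgps_pos
  stats$classification <- factor(
    dplyr::case_when(
      stats$n_pos == 4 ~ "strong",
      stats$n_pos >= thresholds$valid_min_algorithms ~ "valid",
      TRUE ~ "none"
    ),
    levels = c("none", "valid", "strong")
  )
  stats
}

#' SMQ-level signal table for every study drug
#'
#' One row per study drug (plus a pooled `"any"` row when requested):
#' report-level 2x2 counts, the four algorithms' statistics, and the
#' joint verdict.
#'
#' @param cohort A `faers_cohort`.
#' @param drugs Study-drug keys (default: all in the cohort).
#' @param prior Optional `mgps_prior`; fitted on [drug_event_grid()] of
#'   the cohort when `NULL`.
#' @param thresholds A [signal_thresholds()].
#' @param include_total Add the pooled exposure row.
#' @param z,yates Passed to [signal_stats()].
#' @return Tibble of statistics and verdicts.
#' @export
smq_signal_table <- function(cohort, drugs = cohort_drugs(cohort),
                             prior = NULL,
                             thresholds = signal_thresholds(),
                             include_total = TRUE, z = 1.96, yates = FALSE) {
  if (is.null(prior)) {
    grid <- drug_event_grid(cohort)
    prior <- fit_mgps_prior(tibble::tibble(a = grid$a, e = grid$e))
  }
  keys <- c(drugs, if (include_total) "any")
  counts <- dplyr::bind_rows(lapply(keys, function(k) contingency_table(cohort, k)))
  evaluate_signals(signal_stats(counts, prior = prior, z = z, yates = yates),
                   thresholds)
}

#' PT-level signal scan with Bonferroni correction
#'
#' For each preferred term the event is that single PT; counts,
#' statistics and verdicts are computed as at SMQ level.  The frequentist
#' p-value comes from the 1-df chi-square statistic and is
#' Bonferroni-adjusted with `m = length(pt_list)` (`adj_p = min(1, m p)`).
#' Two positivity notions are reported side by side: the thresholded
#' verdict columns, and the laxer `ror_gt1` flag (point estimate > 1)
#' used when ranking frequent PTs.
#'
#' @param cohort A `faers_cohort`.
#' @param drug Study-drug key.
#' @param pt_list Character vector of PTs to scan (default: the PTs
#'   matched by the cohort's SMQ).
#' @param thresholds A [signal_thresholds()].
#' @param prior Optional `mgps_prior` (fitted from the cohort grid when
#'   `NULL`).
#' @param z,yates Passed to [signal_stats()].
#' @return Tibble sorted by descending ROR (undefined RORs last), with
#'   `p_chi2`, `adj_p`, `ror_gt1` and verdict columns.
#' @export
pt_level_scan <- function(cohort, drug, pt_list = NULL,
                          thresholds = signal_thresholds(), prior = NULL,
                          z = 1.96, yates = FALSE) {
  if (is.null(pt_list)) {
    pt_list <- sort(unique(unlist(cohort$matched_pts, use.names = FALSE)))
  }
  pt_list <- unique(fold_term(pt_list))
  if (length(pt_list) == 0) {
    stop("pt_level_scan() needs a non-empty PT list.", call. = FALSE)
  }
  if (is.null(prior)) {
    grid <- drug_event_grid(cohort)
    prior <- fit_mgps_prior(tibble::tibble(a = grid$a, e = grid$e))
  }
  exp_flag <- exposed_flag(cohort, drug)
  n <- nrow(cohort)
  rl <- tibble::tibble(
    row = rep(seq_len(n), lengths(cohort$reactions)),
    pt = unlist(cohort$reactions, use.names = FALSE) %||% character()
  )
  rl <- dplyr::distinct(rl[rl$pt %in% pt_list, , drop = FALSE])
  n_pt <- dplyr::count(rl, .data$pt, name = "n_pt")
  a_pt <- dplyr::count(rl[exp_flag[rl$row], , drop = FALSE], .data$pt, name = "a")
  ne <- sum(exp_flag)
  counts <- tibble::tibble(drug = drug, event = pt_list)
  counts$n_pt <- n_pt$n_pt[match(counts$event, n_pt$pt)]
  counts$n_pt[is.na(counts$n_pt)] <- 0L
  counts$a <- a_pt$a[match(counts$event, a_pt$pt)]
  counts$a[is.na(counts$a)] <- 0L
  counts$b <- ne - counts$a
  counts$c <- counts$n_pt - counts$a
  counts$d <- n - ne - counts$c
  counts$n_pt <- NULL

  m <- length(pt_list)
  out <- evaluate_signals(signal_stats(counts, prior = prior, z = z,
                                       yates = yates), thresholds)
  out$p_chi2 <- pchisq(out$chi2, df = 1, lower.tail = FALSE)
  out$adj_p <- pmin(1, m * out$p_chi2)
  out$ror_gt1 <- !is.na(out$ror) & out$ror > 1
  out$undefined <- is.na(out$ror) | is.na(out$ror_lo)
  out[order(-dplyr::coalesce(out$ror, -Inf), out$event), , drop = FALSE]
}

#' Most frequently reported event PTs for a drug
#'
#' Ranks the SMQ-matched preferred terms of a drug's exposed reports by
#' report count (descending, ties broken alphabetically) and annotates
#' each with its PT-level ROR and the lax positivity flag
#' (point estimate > 1).
#'
#' @param cohort A `faers_cohort`.
#' @param drug Study-drug key.
#' @param k Number of PTs to keep (all PTs when fewer exist).
#' @return Tibble: `rank`, `pt`, `count`, `ror`, `ror_gt1`.
#' @export
top_events <- function(cohort, drug, k = 30) {
  if (k < 1) stop("k must be at least 1.", call. = FALSE)
  exp_flag <- exposed_flag(cohort, drug)
  pts <- unlist(cohort$matched_pts[exp_flag], use.names = FALSE)
  if (length(pts) == 0) {
    return(tibble::tibble(rank = integer(), pt = character(),
                          count = integer(), ror = double(),
                          ror_gt1 = logical()))
  }
  counts <- dplyr::count(tibble::tibble(pt = pts), .data$pt, name = "count")
  counts <- counts[order(-counts$count, counts$pt), , drop = FALSE]
  counts <- head(counts, k)
  scan <- dplyr::bind_rows(lapply(counts$pt, function(p) {
    contingency_table(cohort, drug, pt = p)
  }))
  rs <- ror_stats(scan$a, scan$b, scan$c, scan$d)
  tibble::tibble(
    rank = seq_len(nrow(counts)),
    pt = counts$pt,
    count = counts$count,
    ror = rs$ror,
    ror_gt1 = !is.na(rs$ror) & rs$ror > 1
  )
}

#' Event reporting proportion for a drug
#'
#' The share of a drug's reports that match the SMQ, used as an internal
#' reference for signal strength (it is not an incidence).
#'
#' @param cohort A `faers_cohort`.
#' @param drug Study-drug key.
#' @return One-row tibble: `drug`, `n_event`, `n_exposed`, `proportion`,
#'   `pct` (percent, one decimal, rounded half up).
#' @export
reporting_proportion <- function(cohort, drug) {
  exp_flag <- exposed_flag(cohort, drug)
  if (sum(exp_flag) == 0) {
    stop("No reports exposed to '", drug, "'.", call. = FALSE)
  }
  n_event <- sum(cohort$event[exp_flag])
  n_exposed <- sum(exp_flag)
  tibble::tibble(
    drug = drug, n_event = n_event, n_exposed = n_exposed,
    proportion = n_event / n_exposed,
    pct = round_half_up(100 * n_event / n_exposed, 1)
  )
}

summary_block <- function(x, characteristic, levels = NULL) {
  x <- x[!is.na(x)]
  denom <- length(x)
  if (is.null(levels)) levels <- sort(unique(as.character(x)))
  counts <- as.integer(table(factor(as.character(x), levels = levels)))
  pct <- if (denom > 0) round_half_up(100 * counts / denom, 2)
  else rep(NA_real_, length(levels))
  tibble::tibble(
    characteristic = characteristic,
    level = levels,
    n = counts,
    denom = denom,
    pct = pct
  )
}

#' Descriptive characteristics of a drug's event reports
#'
#' Per-drug (and pooled) counts and percentages over "data available"
#' denominators -- reports with the characteristic recorded -- for sex,
#' age and weight bins, reporter occupation, grouped outcomes and the ten
#' most frequent reporting countries, plus medians (age, weight) and the
#' onset median with quartiles.  Only reports that are exposed to the
#' drug *and* match the SMQ enter the summary.
#'
#' @param cohort A `faers_cohort`.
#' @param drugs Study-drug keys (default all); a pooled `"any"` block is
#'   appended.
#' @param top_countries Number of countries to list.
#' @return Tibble: `drug`, `characteristic`, `level`, `n`, `denom`,
#'   `pct`, `value` (medians/quartiles only).
#' @export
descriptive_summary <- function(cohort, drugs = cohort_drugs(cohort),
                                top_countries = 10) {
  one_drug <- function(key) {
    flag <- if (identical(key, "any")) {
      Reduce(`|`, lapply(cohort_drugs(cohort),
                         function(k) exposed_flag(cohort, k)))
    } else {
      exposed_flag(cohort, key)
    }
    sub <- cohort[flag & cohort$event, , drop = FALSE]
    onset <- if (identical(key, "any")) {
      cols <- paste0("onset_", cohort_drugs(cohort))
      suppressWarnings(do.call(pmin, c(sub[cols], na.rm = TRUE)))
    } else {
      sub[[paste0("onset_", key)]]
    }
    onset <- onset[!is.na(onset)]
    # country percentages use the full "data available" denominator even
    # though only the top countries are listed, so they need not sum to 100
    ctab <- sort(table(sub$country), decreasing = TRUE)
    top_c <- head(names(ctab), top_countries)
    country_block <- tibble::tibble(
      characteristic = "country",
      level = top_c,
      n = as.integer(ctab[top_c]),
      denom = sum(!is.na(sub$country)),
      pct = round_half_up(100 * as.integer(ctab[top_c]) /
                            max(1L, sum(!is.na(sub$country))), 2)
    )
    blocks <- dplyr::bind_rows(
      summary_block(sub$sex, "sex", c("F", "M")),
      summary_block(sub$age_bin, "age", age_bin_levels),
      summary_block(sub$weight_bin, "weight", weight_bin_levels),
      summary_block(sub$reporter, "reporter",
                    c("physician", "pharmacist", "other_health", "consumer")),
      summary_block(sub$outcome_group, "outcome", outcome_group_levels),
      country_block
    )
    med <- function(characteristic, level, value) {
      tibble::tibble(characteristic = characteristic, level = level,
                     n = NA_integer_, denom = NA_integer_, pct = NA_real_,
                     value = value)
    }
    qs <- if (length(onset) > 0) median_iqr(onset) else
      list(median = NA_real_, q1 = NA_real_, q3 = NA_real_)
    blocks$value <- NA_real_
    blocks <- dplyr::bind_rows(
      blocks,
      med("age", "median", median(sub$age_years, na.rm = TRUE)),
      med("weight", "median", median(sub$weight_kg, na.rm = TRUE)),
      med("onset", "median", qs$median),
      med("onset", "q1", qs$q1),
      med("onset", "q3", qs$q3)
    )
    blocks$drug <- key
    blocks
  }
  out <- dplyr::bind_rows(lapply(c(drugs, "any"), one_drug))
  out[, c("drug", "characteristic", "level", "n", "denom", "pct", "value")]
}

#' Annual counts of event reports
#'
#' Number of SMQ-matched reports per calendar year (FDA receipt year) and
#' study drug -- the input for reporting-trend figures.
#'
#' @param cohort A `faers_cohort`.
#' @param drugs Study-drug keys.
#' @return Tibble: `drug`, `year`, `n`.
#' @export
annual_counts <- function(cohort, drugs = cohort_drugs(cohort)) {
  dplyr::bind_rows(lapply(drugs, function(k) {
    sub <- cohort[exposed_flag(cohort, k) & cohort$event, , drop = FALSE]
    out <- dplyr::count(sub, .data$year, name = "n")
    out$drug <- k
    out[, c("drug", "year", "n")]
  }))
}
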