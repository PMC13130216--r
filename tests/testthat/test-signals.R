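stats_row <- function(cases = 100, ror_lo = 2, prr = 3, chi2 = 50,
                      ic025 = 1, ebgm = 3) {
  tibble::tibble(cases = cases, ror = ror_lo * 1.1, ror_lo = ror_lo,
                 ror_hi = ror_lo * 1.3, prr = prr, chi2 = chi2,
                 ic = ic025 + 0.3, ic025 = ic025, ebgm = ebgm,
                 eb05 = ebgm * 0.9)
}

test_that("joint classification follows the four-algorithm criteria", {
  # published SMQ-level row: all four positive -> strong
  row <- stats_row(cases = 9141, ror_lo = 2.99, prr = 2.94, chi2 = 11827.37,
                   ic025 = 1.52, ebgm = 2.92)
  v <- evaluate_signals(row)
  expect_true(all(c(v$ror_pos, v$prr_pos, v$bcpnn_pos, v$mgps_pos)))
  expect_equal(as.character(v$classification), "strong")

  # the case-count gate beats arbitrarily large statistics
  gated <- evaluate_signals(stats_row(cases = 2, ror_lo = 100, prr = 100,
                                      chi2 = 1e6, ic025 = 10, ebgm = 100))
  expect_equal(gated$n_pos, 0)
  expect_equal(as.character(gated$classification), "none")

  # exactly two algorithms positive -> valid
  two <- evaluate_signals(stats_row(ror_lo = 2, prr = 3, chi2 = 50,
                                    ic025 = -1, ebgm = 1))
  expect_equal(two$n_pos, 2)
  expect_equal(as.character(two$classification), "valid")

  # one positive -> none under the default rule, valid when the bar is 1
  one <- stats_row(ror_lo = 2, prr = 1, chi2 = 1, ic025 = -1, ebgm = 1)
  expect_equal(as.character(evaluate_signals(one)$classification), "none")
  expect_equal(
    as.character(evaluate_signals(
      one, signal_thresholds(valid_min_algorithms = 1))$classification),
    "valid"
  )

  # NA statistics never count as positive
  na_row <- stats_row()
  na_row$ror_lo <- NA_real_
  expect_equal(evaluate_signals(na_row)$n_pos, 3)
})

test_that("raising any statistic never demotes the classification", {
  set.seed(700)
  rank <- function(cl) match(cl, c("none", "valid", "strong"))
  for (i in 1:50) {
    row <- stats_row(cases = sample(0:10, 1), ror_lo = runif(1, 0, 3),
                     prr = runif(1, 0, 4), chi2 = runif(1, 0, 10),
                     ic025 = runif(1, -1, 1), ebgm = runif(1, 0, 4))
    base <- rank(as.character(evaluate_signals(row)$classification))
    col <- sample(c("cases", "ror_lo", "prr", "chi2", "ic025", "ebgm"), 1)
    bumped <- row
    bumped[[col]] <- bumped[[col]] + abs(rnorm(1, 2))
    expect_gte(rank(as.character(evaluate_signals(bumped)$classification)),
               base)
  }
})

test_that("threshold construction rejects nonsense", {
  expect_error(signal_thresholds(prr_min = Inf), "finite")
  expect_error(signal_thresholds(valid_min_algorithms = 5), "between 1 and 4")
})

test_that("the PT scan applies Bonferroni over the scanned list", {
  # adjusted p is m * p capped at 1, with m the PT list length
  expect_equal(min(1, 113 * 0.0004), 0.0452)

  cfg <- small_recovery_config(n_reports = 4000, seed = 55)
  cohort <- build_cohort(simulate_reports(cfg), synthetic_lexicon(cfg),
                         synthetic_smq(cfg))
  scan <- pt_level_scan(cohort, "drugx",
                        pt_list = c("proteinuria", "nausea", "absent pt"))
  expect_equal(nrow(scan), 3)
  expect_true(all(scan$adj_p >= scan$p_chi2 - 1e-15, na.rm = TRUE))
  expect_equal(scan$adj_p, pmin(1, 3 * scan$p_chi2))

  # a PT absent from the cohort yields a = 0 and an undefined flag
  absent <- scan[scan$event == "absent pt", ]
  expect_equal(absent$a, 0)
  expect_true(absent$undefined)

  # m = 1: adjusted equals raw
  scan1 <- pt_level_scan(cohort, "drugx", pt_list = "proteinuria")
  expect_equal(scan1$adj_p, scan1$p_chi2)

  # rows sorted by descending ROR, undefined last
  expect_false(is.unsorted(rev(dplyr::coalesce(scan$ror, -Inf))))
})

test_that("top events rank by count with alphabetical ties and lax ROR flag", {
  cohort <- make_mini_cohort(
    exposed = rep(TRUE, 6),
    event = rep(TRUE, 6),
    reactions = list(c("zeta", "alpha"), "zeta", "alpha", "beta",
                     "zeta", "beta")
  )
  # add unexposed background so RORs are defined
  bg <- make_mini_cohort(exposed = rep(FALSE, 20),
                         event = rep(c(TRUE, FALSE), 10),
                         reactions = c(rep(list("alpha"), 10),
                                       rep(list(character()), 10)))
  both <- dplyr::bind_rows(cohort, bg)
  attr(both, "drugs") <- "drugx"
  class(both) <- c("faers_cohort", class(both))

  top <- top_events(both, "drugx", k = 2)
  expect_equal(top$pt, c("zeta", "alpha"))
  expect_equal(top$count, c(3, 2))

  # ties break alphabetically and k beyond the distinct set returns all
  all_pts <- top_events(both, "drugx", k = 10)
  expect_equal(all_pts$pt, c("zeta", "alpha", "beta"))
  expect_equal(all_pts$count, c(3, 2, 2))
  expect_error(top_events(both, "drugx", k = 0), "at least 1")
})

test_that("reporting proportions divide event reports by exposed reports", {
  cohort <- make_mini_cohort(exposed = rep(TRUE, 10),
                             event = c(rep(TRUE, 3), rep(FALSE, 7)))
  rp <- reporting_proportion(cohort, "drugx")
  expect_equal(rp$proportion, 0.3)
  expect_equal(rp$pct, 30.0)

  none <- make_mini_cohort(exposed = rep(TRUE, 5), event = rep(FALSE, 5))
  expect_equal(reporting_proportion(none, "drugx")$pct, 0)

  unexposed <- make_mini_cohort(exposed = rep(FALSE, 5), event = rep(TRUE, 5))
  expect_error(reporting_proportion(unexposed, "drugx"), "No reports exposed")
})

test_that("descriptive summaries use data-available denominators", {
  n <- 20
  cohort <- make_mini_cohort(
    exposed = rep(TRUE, n),
    event = rep(TRUE, n),
    sex = c(rep("F", 8), rep("M", 4), rep(NA, 8)),
    age_bin = factor(c(rep("18-65", 10), rep(">=65", 5), rep(NA, 5)),
                     levels = c("<18", "18-65", ">=65")),
    weight_bin = factor(rep(NA_character_, n),
                        levels = c("<50", "50-80", ">=80")),
    age_years = c(rep(40, 10), rep(70, 5), rep(NA, 5)),
    weight_kg = rep(NA_real_, n),
    reporter = rep(NA_character_, n),
    country = c(rep("US", 3), rep(NA, 17)),
    outcome_group = factor(c(rep("Died", 2), rep("Hospitalized", 6),
                             rep(NA, 12)), levels = faersignal:::outcome_group_levels),
    year = rep(2020L, n)
  )
  cohort$onset_drugx <- rep(NA_real_, n)

  ds <- descriptive_summary(cohort, drugs = "drugx")
  sexes <- ds[ds$drug == "drugx" & ds$characteristic == "sex", ]
  expect_equal(sexes$denom, c(12, 12))
  expect_equal(sexes$pct[sexes$level == "F"], round(100 * 8 / 12, 2),
               tolerance = 0.005)
  expect_equal(sum(sexes$pct), 100, tolerance = 0.05)

  # all-missing weight: denominator zero, no percentages
  wt <- ds[ds$drug == "drugx" & ds$characteristic == "weight" &
             !is.na(ds$n), ]
  expect_true(all(wt$denom == 0))
  expect_true(all(is.na(wt$pct) | wt$n == 0))

  # outcome severity grouping uses recorded outcomes only
  oc <- ds[ds$drug == "drugx" & ds$characteristic == "outcome" & !is.na(ds$n), ]
  expect_equal(oc$denom[1], 8)
  expect_equal(oc$n[oc$level == "Died"], 2)
  expect_equal(sum(oc$pct, na.rm = TRUE), 100, tolerance = 0.05)
})

test_that("percentages within characteristics sum to 100 on random cohorts", {
  set.seed(808)
  for (i in 1:5) {
    n <- 200
    cohort <- make_mini_cohort(
      exposed = rep(TRUE, n),
      event = rep(TRUE, n),
      sex = sample(c("F", "M", NA), n, replace = TRUE),
      age_bin = factor(sample(c("<18", "18-65", ">=65", NA), n, replace = TRUE),
                       levels = c("<18", "18-65", ">=65")),
      weight_bin = factor(sample(c("<50", "50-80", ">=80", NA), n,
                                 replace = TRUE),
                          levels = c("<50", "50-80", ">=80")),
      age_years = runif(n, 1, 90),
      weight_kg = runif(n, 30, 120),
      reporter = sample(c("physician", "consumer", NA), n, replace = TRUE),
      country = sample(c("US", "JP", "FR", NA), n, replace = TRUE),
      outcome_group = factor(
        sample(c(faersignal:::outcome_group_levels, NA), n, replace = TRUE),
        levels = faersignal:::outcome_group_levels
      ),
      year = sample(2010:2020, n, replace = TRUE)
    )
    cohort$onset_drugx <- runif(n, 1, 400)
    ds <- descriptive_summary(cohort, drugs = "drugx")
    for (ch in c("sex", "age", "weight", "reporter", "outcome")) {
      blk <- ds[ds$drug == "drugx" & ds$characteristic == ch & !is.na(ds$n), ]
      expect_equal(sum(blk$pct), 100, tolerance = 0.1)
    }
  }
})

test_that("annual counts tally event reports per receipt year", {
  cohort <- make_mini_cohort(
    exposed = rep(TRUE, 6),
    event = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE),
    year = c(2019L, 2019L, 2019L, 2020L, 2020L, 2021L)
  )
  ac <- annual_counts(cohort, "drugx")
  expect_equal(ac$n[ac$year == 2019], 2)
  expect_equal(ac$n[ac$year == 2020], 2)
  expect_equal(ac$n[ac$year == 2021], 1)
})
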