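test_that("a parsed quarter joins all sub-tables onto DEMO rows", {
  dir <- write_tiny_quarter()
  reports <- read_faers_quarter(dir)

  expect_equal(nrow(reports), 3)
  expect_setequal(reports$primary_id, c(101, 102, 103))

  r101 <- reports[reports$primary_id == 101, ]
  expect_setequal(r101$reactions[[1]], c("Proteinuria", "Headache"))
  expect_equal(r101$age_years, 70)
  expect_equal(r101$weight_kg, 81)
  expect_equal(r101$sex, "F")
  expect_equal(r101$reporter, "physician")
  expect_equal(r101$event_date, as.Date("2023-01-11"))

  # unit conversions: 150 months -> 12.5 years, 110 lbs -> ~49.9 kg
  r102 <- reports[reports$primary_id == 102, ]
  expect_equal(r102$age_years, 12.5)
  expect_equal(r102$weight_kg, 110 * 0.45359237, tolerance = 1e-10)

  # report with no REAC rows: empty reactions, flagged in the parse log
  r103 <- reports[reports$primary_id == 103, ]
  expect_length(r103$reactions[[1]], 0)
  log <- attr(reports, "parse_log")
  expect_true(any(log$file == "REAC" & log$n == 1))
  # partial fda date (YYYYMM) is padded for ordering
  expect_equal(r103$fda_date, as.Date("2023-03-01"))
})

test_that("a missing mandatory column is a parse error naming file and column", {
  dir <- write_tiny_quarter()
  demo <- readLines(file.path(dir, "DEMO.txt"))
  writeLines(sub("^primaryid\\$caseid", "pid$caseid", demo),
             file.path(dir, "DEMO.txt"))
  expect_error(read_faers_quarter(dir), "primaryid")
  expect_error(read_faers_quarter(dir), "DEMO")
})

test_that("deduplication keeps the latest receipt date, then the highest id", {
  mk <- function(pid, cid, fda) {
    tibble::tibble(primary_id = pid, case_id = cid,
                   fda_date = as.Date(fda, format = "%Y%m%d"))
  }
  two <- dplyr::bind_rows(mk(1, 100, "20230101"), mk(2, 100, "20230301"))
  expect_equal(dedupe_reports(two)$primary_id, 2)
  tie <- dplyr::bind_rows(mk(2, 100, "20230301"), mk(3, 100, "20230301"))
  expect_equal(dedupe_reports(tie)$primary_id, 3)
  expect_equal(nrow(dedupe_reports(mk(numeric(), numeric(), character()))), 0)
})

test_that("deduplication is permutation invariant, idempotent, and matches brute force", {
  set.seed(401)
  n_cases <- 400
  versions <- sample(1:3, n_cases, replace = TRUE,
                     prob = c(0.75, 0.15, 0.10))
  base <- tibble::tibble(
    case_id = rep(seq_len(n_cases), versions),
    fda_date = as.Date("2020-01-01") +
      sample.int(1500, sum(versions), replace = TRUE)
  )
  base$primary_id <- sample.int(1e6, nrow(base))
  expect_equal(nrow(base) > n_cases, TRUE)

  # brute force: per case, maximise (fda_date, primary_id) lexicographically
  brute <- vapply(split(base, base$case_id), function(g) {
    g <- g[g$fda_date == max(g$fda_date), , drop = FALSE]
    max(g$primary_id)
  }, numeric(1))

  out1 <- dedupe_reports(base)
  expect_equal(nrow(out1), n_cases)
  expect_setequal(out1$primary_id, unname(brute))

  shuffled <- base[sample.int(nrow(base)), , drop = FALSE]
  out2 <- dedupe_reports(shuffled)
  expect_setequal(out2$primary_id, out1$primary_id)

  again <- dedupe_reports(out1)
  expect_equal(dplyr::arrange(again, case_id), dplyr::arrange(out1, case_id),
               ignore_attr = TRUE)
})

test_that("drug matching honours the lexicon, normalisation and role filter", {
  dir <- write_tiny_quarter()
  reports <- read_faers_quarter(dir)
  flags <- match_drugs(reports, tiny_lexicon())

  # brand name PROGRAF (PS) matches tacrolimus
  expect_true(flags$tacrolimus[flags$primary_id == 101])
  # " Cyclosporine " mixed case with whitespace matches after folding
  expect_true(flags$cyclosporine[flags$primary_id == 102])
  # tacrolimus with role C on report 102 must NOT count under default roles
  expect_false(flags$tacrolimus[flags$primary_id == 102])
  # widening the role set picks it up
  flags_c <- match_drugs(reports, tiny_lexicon(), roles = c("PS", "C"))
  expect_true(flags_c$tacrolimus[flags_c$primary_id == 102])

  expect_error(match_drugs(reports, list()), "lexicon")
})

test_that("SMQ matching is a case-folded set intersection", {
  smq <- tiny_smq()
  expect_equal(map_smq(c("Proteinuria", "Headache"), smq), "proteinuria")
  expect_length(map_smq(c("Nausea", "Rash"), smq), 0)
  # a PT listed twice in one report counts once
  expect_equal(map_smq(c("PROTEINURIA", "proteinuria "), smq), "proteinuria")
})

test_that("the cohort carries covariate bins, events and onset arithmetic", {
  dir <- write_tiny_quarter()
  cohort <- build_cohort(dedupe_reports(read_faers_quarter(dir)),
                         tiny_lexicon(), tiny_smq())

  expect_equal(nrow(cohort), 3)
  expect_equal(cohort$event, lengths(cohort$matched_pts) > 0)

  r101 <- cohort[cohort$primary_id == 101, ]
  expect_equal(as.character(r101$age_bin), ">=65")
  expect_equal(as.character(r101$weight_bin), ">=80")
  expect_equal(as.character(r101$indication_group), "transplant")
  # onset: event 2023-01-11 minus therapy start 2023-01-01 = 10 days
  expect_equal(r101$onset_tacrolimus, 10)

  # earliest therapy start rule: report 102 has starts 2023-03-01 and
  # 2023-01-10; the event (2023-01-20) is after the earliest start only
  r102 <- cohort[cohort$primary_id == 102, ]
  expect_equal(r102$onset_cyclosporine, 10)

  # missing weight retained with a missing bin
  r103 <- cohort[cohort$primary_id == 103, ]
  expect_true(is.na(r103$weight_bin))
  expect_false(r103$event)

  # a negative interval is an anomaly, not a negative onset
  dir2 <- write_tiny_quarter()
  ther <- readLines(file.path(dir2, "THER.txt"))
  writeLines(c(ther[1], "101$1$20230301$"), file.path(dir2, "THER.txt"))
  cohort2 <- build_cohort(dedupe_reports(read_faers_quarter(dir2)),
                          tiny_lexicon(), tiny_smq())
  expect_true(is.na(cohort2$onset_tacrolimus[cohort2$primary_id == 101]))
  expect_equal(attr(cohort2, "onset_anomalies"), 1L)
})

test_that("exposure prevalence in a generated cohort tracks the configured probability", {
  cfg <- synthetic_config(
    n_reports = 10000,
    drugs = tibble::tibble(drug = "drugx", exposure_prob = 0.05, rho = 1),
    duplicate_rate = 0, seed = 77
  )
  cohort <- build_cohort(simulate_reports(cfg), synthetic_lexicon(cfg),
                         synthetic_smq(cfg))
  phat <- mean(cohort$exposed_drugx)
  se <- sqrt(0.05 * 0.95 / 10000)
  expect_lt(abs(phat - 0.05), 4 * se)
})

test_that("a quarter round-trips: write, re-parse, identical cohort", {
  cfg <- small_recovery_config(n_reports = 300, duplicate_rate = 0.1, seed = 5)
  reports <- dedupe_reports(simulate_reports(cfg))
  cohort <- build_cohort(reports, synthetic_lexicon(cfg), synthetic_smq(cfg))

  dir <- tempfile("roundtrip")
  write_faers_quarter(reports, dir)
  reparsed <- dedupe_reports(read_faers_quarter(dir))
  cohort2 <- build_cohort(reparsed, synthetic_lexicon(cfg), synthetic_smq(cfg))

  ord1 <- order(cohort$primary_id)
  ord2 <- order(cohort2$primary_id)
  expect_equal(as.data.frame(cohort[ord1, ]), as.data.frame(cohort2[ord2, ]),
               ignore_attr = TRUE)
})
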