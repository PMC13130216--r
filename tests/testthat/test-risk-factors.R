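cohort_from_design <- function(design, drug = "drugx") {
  n <- nrow(design)
  cohort <- make_mini_cohort(exposed = rep(TRUE, n),
                             event = design$event == 1)
  for (nm in setdiff(names(design), "event")) cohort[[nm]] <- design[[nm]]
  cohort
}

test_that("a binary-covariate univariable OR equals the sample odds ratio", {
  design <- expand_two_by_two(500, 40, 300, 60)
  cohort <- cohort_from_design(design)
  cohort$sex <- as.character(design$x)
  tbl <- univariable_or(cohort, "drugx", covariates = "sex")
  sample_or <- (60 / 300) / (40 / 500)
  expect_equal(tbl$or[tbl$level == "M"], sample_or, tolerance = 1e-10)
  expect_equal(tbl$n_no_event, c(500, 300))
  expect_equal(tbl$n_event, c(40, 60))
  expect_true(tbl$reference[tbl$level == "F"])
})

test_that("a three-level covariate yields two contrasts against the reference", {
  set.seed(1000)
  n <- 600
  ab <- factor(sample(c("<18", "18-65", ">=65"), n, replace = TRUE),
               levels = c("<18", "18-65", ">=65"))
  p <- c("<18" = 0.3, "18-65" = 0.2, ">=65" = 0.1)[as.character(ab)]
  design <- tibble::tibble(event = rbinom(n, 1, p), age_bin = ab)
  cohort <- cohort_from_design(design)
  tbl <- univariable_or(cohort, "drugx", covariates = "age_bin")
  expect_equal(nrow(tbl), 3)
  expect_equal(tbl$assignment, 0:2)
  expect_equal(sum(!tbl$reference), 2)
  expect_true(all(tbl$or[!tbl$reference] < 1))
})

test_that("a covariate independent of the outcome has an OR interval containing 1", {
  set.seed(1001)
  n <- 2000
  design <- tibble::tibble(
    event = rbinom(n, 1, 0.2),
    sex = sample(c("F", "M"), n, replace = TRUE)
  )
  cohort <- cohort_from_design(design)
  tbl <- univariable_or(cohort, "drugx", covariates = "sex")
  m <- tbl[tbl$level == "M", ]
  expect_true(m$conf.low <= 1 && 1 <= m$conf.high)
})

test_that("adjustment moves a confounded estimate toward the truth", {
  set.seed(1002)
  n <- 6000
  age_bin <- factor(sample(c("18-65", ">=65"), n, replace = TRUE),
                    levels = c("18-65", ">=65"))
  old <- age_bin == ">=65"
  # male sex more common among the old; age drives the event, sex has
  # a known OR of 1.8
  sex <- ifelse(runif(n) < ifelse(old, 0.7, 0.4), "M", "F")
  lp <- -2.5 + log(1.8) * (sex == "M") + log(3) * old
  design <- tibble::tibble(event = rbinom(n, 1, stats::plogis(lp)),
                           sex = sex, age_bin = age_bin)
  cohort <- cohort_from_design(design)

  crude <- univariable_or(cohort, "drugx", covariates = "sex")
  adj <- multivariable_or(cohort, "drugx", covariates = c("sex", "age_bin"))
  or_crude <- crude$or[crude$level == "M"]
  or_adj <- adj$or[adj$level == "M" & adj$covariate == "sex"]
  expect_lt(abs(log(or_adj) - log(1.8)), abs(log(or_crude) - log(1.8)))
})

test_that("a configured unconfounded effect is recovered within its interval", {
  set.seed(1010)
  n <- 5000
  sex <- sample(c("F", "M"), n, replace = TRUE)
  lp <- -2 + log(1.8) * (sex == "M")
  design <- tibble::tibble(event = rbinom(n, 1, stats::plogis(lp)), sex = sex)
  cohort <- cohort_from_design(design)
  tbl <- univariable_or(cohort, "drugx", covariates = "sex")
  m <- tbl[tbl$level == "M", ]
  expect_true(m$conf.low <= 1.8 && 1.8 <= m$conf.high)
})

test_that("results are invariant to row permutation", {
  set.seed(1003)
  n <- 800
  design <- tibble::tibble(
    event = rbinom(n, 1, 0.15),
    sex = sample(c("F", "M"), n, replace = TRUE),
    age_bin = factor(sample(c("<18", "18-65", ">=65"), n, replace = TRUE),
                     levels = c("<18", "18-65", ">=65"))
  )
  c1 <- cohort_from_design(design)
  c2 <- cohort_from_design(design[sample.int(n), ])
  t1 <- multivariable_or(c1, "drugx", covariates = c("sex", "age_bin"))
  t2 <- multivariable_or(c2, "drugx", covariates = c("sex", "age_bin"))
  expect_equal(t1$or, t2$or, tolerance = 1e-12)
  expect_equal(t1$conf.low, t2$conf.low, tolerance = 1e-12)
})

test_that("single-level covariates are skipped or dropped with a warning", {
  set.seed(1004)
  n <- 300
  design <- tibble::tibble(
    event = rbinom(n, 1, 0.3),
    sex = sample(c("F", "M"), n, replace = TRUE),
    indication_group = factor(rep("autoimmune", n),
                              levels = c("autoimmune", "transplant", "other"))
  )
  cohort <- cohort_from_design(design)
  expect_warning(
    uni <- univariable_or(cohort, "drugx",
                          covariates = c("sex", "indication_group")),
    "fewer than two observed levels"
  )
  expect_false("indication_group" %in% uni$covariate)
  expect_warning(
    multi <- multivariable_or(cohort, "drugx",
                              covariates = c("sex", "indication_group")),
    "dropped"
  )
  expect_false("indication_group" %in% multi$covariate)
})

test_that("perfect separation and one-class outcomes raise errors", {
  design <- tibble::tibble(
    event = c(rep(0L, 50), rep(1L, 50)),
    sex = factor(c(rep("F", 50), rep("M", 50)), levels = c("F", "M"))
  )
  expect_error(suppressWarnings(fit_event_logistic(design, "sex")),
               "separation")
  none <- tibble::tibble(event = rep(0L, 50),
                         sex = factor(sample(c("F", "M"), 50, replace = TRUE)))
  expect_error(fit_event_logistic(none, "sex"), "both classes")
})

test_that("complete-case handling differs between the two model columns", {
  set.seed(1005)
  n <- 500
  design <- tibble::tibble(
    event = rbinom(n, 1, 0.3),
    sex = sample(c("F", "M"), n, replace = TRUE),
    weight_bin = factor(
      sample(c("<50", "50-80", ">=80", NA), n, replace = TRUE,
             prob = c(0.2, 0.3, 0.2, 0.3)),
      levels = c("<50", "50-80", ">=80")
    )
  )
  cohort <- cohort_from_design(design)
  tbl <- risk_factor_table(cohort, "drugx", covariates = c("sex", "weight_bin"))
  n_uni_sex <- unique(tbl$n_used[tbl$covariate == "sex"])
  expect_equal(n_uni_sex, n)  # sex is fully observed
  # the joint model drops weight-missing rows for every term
  expect_true(all(!is.na(tbl$or_multi[!tbl$reference])))
})
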