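test_that("quartiles use linear interpolation between order statistics", {
  q <- median_iqr(c(1, 2, 3, 4))
  expect_equal(q$median, 2.5)
  expect_equal(q$q1, 1.75)
  expect_equal(q$q3, 3.25)

  single <- median_iqr(7)
  expect_equal(unlist(single), c(median = 7, q1 = 7, q3 = 7))

  set.seed(900)
  x <- rweibull(101, 0.7, 100)
  expect_equal(median_iqr(x), median_iqr(sample(x)))
  expect_error(median_iqr(numeric()), "at least one")
})

test_that("exponential onset data recovers shape near 1", {
  set.seed(901)
  x <- stats::rexp(5000, rate = 1 / 80)
  fit <- fit_weibull_onset(x)
  expect_gt(fit$beta, 0.95)
  expect_lt(fit$beta, 1.05)
  expect_equal(fit$alpha, 80, tolerance = 0.05 * 80)
  expect_equal(classify_failure(fit), "random")
})

test_that("the fitted likelihood dominates a surrounding grid", {
  set.seed(902)
  x <- rweibull(2000, shape = 0.47, scale = 225)
  fit <- fit_weibull_onset(x)
  n <- length(x)
  slog <- sum(log(x))
  betas <- seq(fit$beta * 0.7, fit$beta * 1.3, length.out = 200)
  alphas <- seq(fit$alpha * 0.7, fit$alpha * 1.3, length.out = 200)
  best_grid <- -Inf
  for (b in betas) {
    stb <- sum(x^b)
    ll <- n * log(b) - n * b * log(alphas) + (b - 1) * slog - stb / alphas^b
    best_grid <- max(best_grid, max(ll))
  }
  expect_gte(fit$loglik, best_grid)
})

test_that("the profiled MLE agrees with an independent fitting routine", {
  skip_if_not_installed("fitdistrplus")
  set.seed(910)
  x <- rweibull(1500, shape = 0.6, scale = 180)
  ours <- fit_weibull_onset(x)
  ref <- suppressWarnings(fitdistrplus::fitdist(x, "weibull"))
  # agreement to the reference optimiser's own precision ...
  expect_equal(ours$beta, unname(ref$estimate["shape"]), tolerance = 1e-3)
  expect_equal(ours$alpha, unname(ref$estimate["scale"]), tolerance = 1e-3)
  # ... and the profiled root-finder never sits below the reference
  ll <- function(sh, sc) sum(stats::dweibull(x, sh, sc, log = TRUE))
  expect_gte(ours$loglik, ll(ref$estimate["shape"], ref$estimate["scale"]) - 1e-8)
})

test_that("the fit is scale equivariant", {
  set.seed(903)
  x <- rweibull(500, shape = 0.8, scale = 120)
  f1 <- fit_weibull_onset(x)
  f2 <- fit_weibull_onset(x * 3)
  expect_equal(f2$beta, f1$beta, tolerance = 1e-8)
  expect_equal(f2$alpha, 3 * f1$alpha, tolerance = 1e-8 * f1$alpha)
})

test_that("all-observed censoring flags reproduce the complete-data path", {
  set.seed(904)
  x <- rweibull(300, shape = 0.6, scale = 200)
  f1 <- fit_weibull_onset(x)
  f2 <- fit_weibull_onset(x, censored = rep(FALSE, 300))
  expect_identical(f1$alpha, f2$alpha)
  expect_identical(f1$beta, f2$beta)
  expect_identical(f1$loglik, f2$loglik)
})

test_that("right-censoring shifts the fit as survival terms", {
  set.seed(905)
  x <- rweibull(2000, shape = 1, scale = 100)
  cens_at <- 150
  censored <- x > cens_at
  xc <- pmin(x, cens_at)
  fit <- fit_weibull_onset(xc, censored = censored)
  # censoring-aware fit should stay near the truth ...
  expect_equal(fit$beta, 1, tolerance = 0.1)
  expect_equal(fit$alpha, 100, tolerance = 10)
  # ... while ignoring censoring biases the scale down
  naive <- fit_weibull_onset(xc)
  expect_lt(naive$alpha, fit$alpha)
})

test_that("degenerate and undersized samples are rejected", {
  expect_error(fit_weibull_onset(rep(5, 50)), "Degenerate")
  expect_error(fit_weibull_onset(c(1, 2, 3)), "at least 10")
  expect_error(fit_weibull_onset(c(rep(2, 20), 0)), "positive")
})

test_that("failure typing follows the confidence interval against 1", {
  mk <- function(beta, lo, hi) {
    structure(list(alpha = 200, alpha_ci = c(150, 250), beta = beta,
                   beta_ci = c(lo, hi), n = 100, n_censored = 0,
                   conf = 0.95, loglik = 0, vcov = diag(2),
                   failure_type = NA), class = "weibull_fit")
  }
  # published voclosporin-style shape interval entirely below 1
  expect_equal(classify_failure(mk(0.88, 0.79, 0.96)), "early")
  expect_equal(classify_failure(mk(1.0, 0.9, 1.1)), "random")
  expect_equal(classify_failure(mk(1.5, 1.2, 1.8)), "wearout")
})

test_that("tidy and glance expose the Weibull fit in broom shape", {
  set.seed(906)
  fit <- fit_weibull_onset(rweibull(200, 0.5, 150))
  td <- tidy(fit)
  expect_equal(td$term, c("alpha", "beta"))
  expect_true(all(td$conf.low < td$estimate & td$estimate < td$conf.high))
  gl <- glance(fit)
  expect_equal(gl$n, 200)
  expect_true(gl$failure_type %in% c("early", "random", "wearout"))
})

test_that("per-drug onset tables summarise the cohort", {
  cfg <- synthetic_config(
    n_reports = 6000,
    drugs = tibble::tibble(drug = "drugx", exposure_prob = 0.3, rho = 8,
                           onset_scale = 225, onset_shape = 0.47),
    events = tibble::tibble(pt = "proteinuria", baseline_prob = 0.1),
    background_events = tibble::tibble(pt = "nausea", baseline_prob = 0.3),
    duplicate_rate = 0, seed = 41
  )
  cohort <- build_cohort(simulate_reports(cfg), synthetic_lexicon(cfg),
                         synthetic_smq(cfg))
  tbl <- weibull_onset_table(cohort)
  expect_equal(tbl$drug, "drugx")
  expect_equal(tbl$failure_type, "early")
  expect_true(tbl$beta_lo < tbl$beta & tbl$beta < tbl$beta_hi)

  bins <- onset_bin_table(cohort)
  expect_equal(sum(bins$n), tbl$n)
  expect_equal(bins$bin,
               c("0-30", "31-90", "91-180", "181-360", ">360"))
  # zero-day onsets map to half a day rather than dropping out
  x <- onset_sample(cohort, "drugx")
  expect_true(all(x > 0))
})
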