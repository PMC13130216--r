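# Disproportionality statistics on report-level 2x2 contingency tables.
#
# Notation for a drug/event pair: a = target drug & target event,
# b = target drug & other events, c = other drugs & target event,
# d = neither; N = a+b+c+d, with margins n1. = a+b and n.1 = a+c.

#' Build a 2x2 contingency table for a drug/event pair
#'
#' Counts at report level against the comparator of all other reports in
#' the cohort universe.  In SMQ mode (default) the event is the cohort's
#' SMQ flag; in PT mode the event is a single preferred term.
#'
#' @param cohort A `faers_cohort`.
#' @param drug Study-drug key (an `exposed_<drug>` column), or `"any"`
#'   for exposure to any study drug.
#' @param pt Optional single PT (case-folded on use); when `NULL` the
#'   SMQ-level event flag is used.
#' @return One-row tibble: `drug`, `event`, `a`, `b`, `c`, `d`, `n`.
#' @export
contingency_table <- function(cohort, drug, pt = NULL) {
  if (nrow(cohort) == 0) {
    stop("Cannot build a contingency table from an empty cohort.", call. = FALSE)
  }
  exp_flag <- if (identical(drug, "any")) {
    Reduce(`|`, lapply(cohort_drugs(cohort),
                       function(k) exposed_flag(cohort, k)))
  } else {
    exposed_flag(cohort, drug)
  }
  if (is.null(pt)) {
    evt <- cohort$event
    label <- attr(cohort, "smq_name") %||% "smq"
  } else {
    ptf <- fold_term(pt)
    evt <- vapply(cohort$reactions, function(r) ptf %in% r, logical(1))
    label <- ptf
  }
  tibble::tibble(
    drug = drug, event = label,
    a = sum(exp_flag & evt), b = sum(exp_flag & !evt),
    c = sum(!exp_flag & evt), d = sum(!exp_flag & !evt),
    n = length(evt)
  )
}

#' Reporting odds ratio with Wald confidence interval
#'
#' `ROR = (a d)/(b c)`; the interval is
#' `exp(log ROR +/- z sqrt(1/a + 1/b + 1/c + 1/d))`.  No continuity
#' correction is applied: when any cell is zero the interval (and, for a
#' zero denominator, the point estimate) is returned as `NA` so that
#' undefined statistics cannot masquerade as signals.
#'
#' @param a,b,c,d Cell counts (vectorised).
#' @param z Normal quantile for the interval (1.96 for 95%).
#' @return Tibble: `ror`, `ror_lo`, `ror_hi`.
#' @export
ror_stats <- function(a, b, c, d, z = 1.96) {
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  point_ok <- b * c > 0
  ror <- ifelse(point_ok, (a * d) / (b * c), NA_real_)
  ci_ok <- a > 0 & b > 0 & c > 0 & d > 0
  se <- ifelse(ci_ok, sqrt(1 / a + 1 / b + 1 / c + 1 / d), NA_real_)
  tibble::tibble(
    ror = ror,
    ror_lo = ifelse(ci_ok, exp(log(ror) - z * se), NA_real_),
    ror_hi = ifelse(ci_ok, exp(log(ror) + z * se), NA_real_)
  )
}

#' Proportional reporting ratio and Pearson chi-square
#'
#' `PRR = [a/(a+b)] / [c/(c+d)]` and the 1-df Pearson statistic
#' `N (ad - bc)^2 / [(a+b)(c+d)(a+c)(b+d)]`.  The Yates continuity
#' correction is off by default (and recorded in pipeline metadata when
#' toggled).
#'
#' @param a,b,c,d Cell counts (vectorised).
#' @param yates Apply the Yates correction to the chi-square.
#' @return Tibble: `prr`, `chi2`.
#' @export
prr_stats <- function(a, b, c, d, yates = FALSE) {
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  ok <- (a + b) > 0 & (c + d) > 0 & c > 0
  prr <- ifelse(ok, (a / (a + b)) / (c / (c + d)), NA_real_)
  denom <- (a + b) * (c + d) * (a + c) * (b + d)
  chi_ok <- denom > 0
  dev <- abs(a * d - b * c)
  if (yates) dev <- pmax(0, dev - n / 2)
  chi2 <- ifelse(chi_ok, n * dev^2 / denom, NA_real_)
  tibble::tibble(prr = prr, chi2 = chi2)
}

#' BCPNN information component (closed form)
#'
#' The information component is a shrunken log2 observed-to-expected
#' reporting ratio under independent Beta priors on the margins
#' (`alpha1 = beta1 = 1`, totals `alpha = beta = 2`) and a joint cell
#' prior calibrated so that independence maps to IC = 0:
#' `gamma = gamma11 (N+alpha)(N+beta) / [(n1.+alpha1)(n.1+beta1)]`.
#' `ic025` is `ic - z * sqrt(V)` with the standard closed-form variance.
#'
#' @param a,b,c,d Cell counts (vectorised).
#' @param z Credible-interval multiplier (1.96 default; 2.0 available).
#' @param alpha1,beta1,alpha,beta,gamma11 Prior constants.
#' @return Tibble: `ic`, `ic025`.
#' @export
bcpnn_stats <- function(a, b, c, d, z = 1.96,
                        alpha1 = 1, beta1 = 1, alpha = 2, beta = 2,
                        gamma11 = 1) {
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  n1 <- a + b
  m1 <- a + c
  gamma <- gamma11 * (n + alpha) * (n + beta) / ((n1 + alpha1) * (m1 + beta1))
  ic <- log2((a + gamma11) * (n + alpha) * (n + beta) /
               ((n + gamma) * (n1 + alpha1) * (m1 + beta1)))
  v <- (1 / log(2)^2) * (
    (n - a + gamma - gamma11) / ((a + gamma11) * (1 + n + gamma)) +
      (n - n1 + alpha - alpha1) / ((n1 + alpha1) * (1 + n + alpha)) +
      (n - m1 + beta - beta1) / ((m1 + beta1) * (1 + n + beta))
  )
  tibble::tibble(ic = ic, ic025 = ic - z * sqrt(v))
}

#' Fit the MGPS two-gamma mixture prior
#'
#' The multi-item gamma Poisson shrinker models each cell count `a` as
#' Poisson with mean `lambda * E`, where `E = n1. n.1 / N` is the
#' expected count under independence and `lambda` follows a mixture of
#' two gamma distributions,
#' `w Gamma(alpha1, beta1) + (1-w) Gamma(alpha2, beta2)` (shape/rate).
#' Marginally each count is a two-component negative binomial mixture;
#' the prior is fitted by maximising the summed log marginal likelihood
#' over all drug-event cells with box-constrained BFGS from DuMouchel's
#' classical start (0.2, 0.1, 2, 4, 1/3).  Shrinkage only works against
#' the full ensemble, so the cells should cover the whole drug-by-event
#' grid of the cohort universe, not just the study pairs.
#'
#' @param cells Tibble with columns `a` (observed count) and `e`
#'   (expected count), one row per drug-event cell.
#' @return An `mgps_prior` object: `alpha1`, `beta1`, `alpha2`, `beta2`,
#'   `w`, `loglik`, `convergence`, `n_cells`.
#' @export
fit_mgps_prior <- function(cells) {
  cells <- tibble::as_tibble(cells)
  stopifnot(all(c("a", "e") %in% names(cells)))
  cells <- cells[is.finite(cells$a) & is.finite(cells$e) & cells$e > 0, ,
                 drop = FALSE]
  if (nrow(cells) < 2) {
    stop("MGPS prior fitting needs at least two usable cells.", call. = FALSE)
  }
  if (all(cells$a == 0)) {
    stop("MGPS prior fitting is degenerate: every cell has a zero count.",
         call. = FALSE)
  }
  a <- cells$a
  e <- cells$e
  # optimised on log (shapes/rates) and logit (w) scale for conditioning;
  # the box maps back to parameters in [1e-6, 1e6] and w in (1e-6, 1-1e-6)
  negll <- function(theta) {
    p <- exp(theta[1:4])
    w <- stats::plogis(theta[5])
    l1 <- dnbinom(a, size = p[1], prob = p[2] / (p[2] + e), log = TRUE)
    l2 <- dnbinom(a, size = p[3], prob = p[4] / (p[4] + e), log = TRUE)
    hi <- pmax(l1 + log(w), l2 + log1p(-w))
    ll <- hi + log1p(exp(pmin(l1 + log(w), l2 + log1p(-w)) - hi))
    -sum(ll)
  }
  start <- c(log(c(0.2, 0.1, 2, 4)), stats::qlogis(1 / 3))
  lower <- c(rep(log(1e-6), 4), stats::qlogis(1e-6))
  upper <- c(rep(log(1e6), 4), stats::qlogis(1 - 1e-6))
  fit <- optim(
    start, negll, method = "L-BFGS-B", lower = lower, upper = upper,
    control = list(maxit = 500, factr = 1e4)
  )
  if (fit$convergence != 0) {
    # near-degenerate mixtures (components collapsing to a spike) push the
    # optimum onto the box where the quasi-Newton line search can abort;
    # polish from the best iterate with a simplex restricted to the box
    clamped <- function(theta) negll(pmin(pmax(theta, lower), upper))
    polish <- optim(fit$par, clamped, method = "Nelder-Mead",
                    control = list(maxit = 5000, reltol = 1e-12))
    polish$par <- pmin(pmax(polish$par, lower), upper)
    if (polish$value <= fit$value) fit <- polish
  }
  if (fit$convergence != 0) {
    stop("MGPS prior optimisation did not converge (code ", fit$convergence,
         ", message: ", fit$message, "); best iterate: ",
         paste(signif(c(exp(fit$par[1:4]), stats::plogis(fit$par[5])), 4),
               collapse = ", "), call. = FALSE)
  }
  structure(list(
    alpha1 = exp(fit$par[1]), beta1 = exp(fit$par[2]),
    alpha2 = exp(fit$par[3]), beta2 = exp(fit$par[4]),
    w = stats::plogis(fit$par[5]), loglik = -fit$value,
    convergence = fit$convergence, n_cells = nrow(cells)
  ), class = "mgps_prior")
}

#' @export
print.mgps_prior <- function(x, ...) {
  cat("<mgps_prior> w =", signif(x$w, 4),
      "| Gamma(", signif(x$alpha1, 4), ",", signif(x$beta1, 4), ") /",
      "Gamma(", signif(x$alpha2, 4), ",", signif(x$beta2, 4), ") |",
      "loglik", signif(x$loglik, 6), "on", x$n_cells, "cells\n")
  invisible(x)
}

#' @export
tidy.mgps_prior <- function(x, ...) {
  tibble::tibble(
    term = c("alpha1", "beta1", "alpha2", "beta2", "w"),
    estimate = c(x$alpha1, x$beta1, x$alpha2, x$beta2, x$w)
  )
}

#' @export
glance.mgps_prior <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, n_cells = x$n_cells,
                 converged = x$convergence == 0)
}

mgps_loglik <- function(prior, cells) {
  l1 <- dnbinom(cells$a, size = prior$alpha1,
                prob = prior$beta1 / (prior$beta1 + cells$e), log = TRUE)
  l2 <- dnbinom(cells$a, size = prior$alpha2,
                prob = prior$beta2 / (prior$beta2 + cells$e), log = TRUE)
  hi <- pmax(l1 + log(prior$w), l2 + log1p(-prior$w))
  sum(hi + log1p(exp(pmin(l1 + log(prior$w), l2 + log1p(-prior$w)) - hi)))
}

#' Empirical Bayes geometric mean and EB05
#'
#' Given the fitted mixture prior, the posterior of the reporting ratio
#' `lambda` for a cell with count `a` and expectation `E` is
#' `Q Gamma(alpha1 + a, beta1 + E) + (1-Q) Gamma(alpha2 + a, beta2 + E)`
#' with posterior mixture weight `Q`.  The EBGM is the geometric mean
#' `exp(E[log lambda])`, evaluated through the digamma function; EB05 is
#' the posterior 5th percentile obtained by bracketed root-finding on the
#' mixture CDF (tolerance 1e-8).
#'
#' @param a Observed counts (vectorised).
#' @param e Expected counts under independence.
#' @param prior An `mgps_prior`.
#' @return Tibble: `ebgm`, `eb05`, `q` (posterior weight of the first
#'   component).  `NA` where `e = 0`.
#' @export
ebgm_stats <- function(a, e, prior) {
  stopifnot(inherits(prior, "mgps_prior"))
  n <- length(a)
  stopifnot(length(e) == n)
  out <- tibble::tibble(ebgm = rep(NA_real_, n), eb05 = rep(NA_real_, n),
                        q = rep(NA_real_, n))
  ok <- is.finite(a) & is.finite(e) & e > 0
  if (!any(ok)) return(out)
  a1 <- prior$alpha1; b1 <- prior$beta1
  a2 <- prior$alpha2; b2 <- prior$beta2
  l1 <- dnbinom(a[ok], size = a1, prob = b1 / (b1 + e[ok]), log = TRUE) +
    log(prior$w)
  l2 <- dnbinom(a[ok], size = a2, prob = b2 / (b2 + e[ok]), log = TRUE) +
    log1p(-prior$w)
  q <- 1 / (1 + exp(l2 - l1))
  elog <- q * (digamma(a1 + a[ok]) - log(b1 + e[ok])) +
    (1 - q) * (digamma(a2 + a[ok]) - log(b2 + e[ok]))
  out$ebgm[ok] <- exp(elog)
  out$q[ok] <- q
  idx <- which(ok)
  for (i in seq_along(idx)) {
    k <- idx[i]
    out$eb05[k] <- mixture_gamma_quantile(
      0.05, q[i], a1 + a[k], b1 + e[k], a2 + a[k], b2 + e[k]
    )
  }
  out
}

# Quantile of w Gamma(s1, r1) + (1 - w) Gamma(s2, r2) by root-finding.
mixture_gamma_quantile <- function(p, w, s1, r1, s2, r2) {
  cdf <- function(x) {
    w * pgamma(x, shape = s1, rate = r1) +
      (1 - w) * pgamma(x, shape = s2, rate = r2) - p
  }
  hi <- max(qgamma(p, shape = s1, rate = r1), qgamma(p, shape = s2, rate = r2))
  lo <- min(qgamma(p, shape = s1, rate = r1), qgamma(p, shape = s2, rate = r2))
  if (hi == lo) return(hi)
  uniroot(cdf, lower = lo, upper = hi, tol = 1e-8, extendInt = "upX")$root
}

#' Full drug-by-event cell grid of a cohort
#'
#' Observed and expected counts for every (drug name, reaction PT) pair
#' in the cohort universe -- the ensemble on which the MGPS prior is
#' fitted.  Drug names are the role-filtered, case-folded verbatim names
#' carried by the cohort; counts are at report level.
#'
#' @param cohort A `faers_cohort`.
#' @return Tibble: `drug_name`, `pt`, `a`, `e`.
#' @export
drug_event_grid <- function(cohort) {
  n <- nrow(cohort)
  dl <- tibble::tibble(
    row = rep(seq_len(n), lengths(cohort$drug_names)),
    drug_name = unlist(cohort$drug_names, use.names = FALSE) %||% character()
  )
  rl <- tibble::tibble(
    row = rep(seq_len(n), lengths(cohort$reactions)),
    pt = unlist(cohort$reactions, use.names = FALSE) %||% character()
  )
  pair <- dplyr::count(
    dplyr::distinct(
      dplyr::inner_join(dl, rl, by = "row", relationship = "many-to-many")
    ),
    .data$drug_name, .data$pt, name = "a"
  )
  nd <- dplyr::count(dplyr::distinct(dl), .data$drug_name, name = "n_drug")
  np <- dplyr::count(dplyr::distinct(rl), .data$pt, name = "n_pt")
  grid <- tidyr::expand_grid(drug_name = nd$drug_name, pt = np$pt)
  grid <- dplyr::left_join(grid, pair, by = c("drug_name", "pt"))
  grid$a[is.na(grid$a)] <- 0L
  grid$e <- nd$n_drug[match(grid$drug_name, nd$drug_name)] *
    np$n_pt[match(grid$pt, np$pt)] / n
  grid
}

#' All four disproportionality statistics for a set of tables
#'
#' @param counts Tibble with columns `a`, `b`, `c`, `d` (one row per
#'   drug-event table); extra columns are carried through.
#' @param prior Optional `mgps_prior`; when supplied, EBGM and EB05 are
#'   computed with `E = (a+b)(a+c)/N`.
#' @param z Normal/credible multiplier for the ROR and IC intervals.
#' @param yates Yates correction for the chi-square.
#' @return `counts` augmented with `cases`, `ror`, `ror_lo`, `ror_hi`,
#'   `prr`, `chi2`, `ic`, `ic025`, and (given a prior) `e`, `ebgm`,
#'   `eb05`.
#' @export
signal_stats <- function(counts, prior = NULL, z = 1.96, yates = FALSE) {
  counts <- tibble::as_tibble(counts)
  stopifnot(all(c("a", "b", "c", "d") %in% names(counts)))
  for (cl in c("a", "b", "c", "d")) counts[[cl]] <- as.numeric(counts[[cl]])
  out <- dplyr::bind_cols(
    counts,
    tibble::tibble(cases = counts$a),
    ror_stats(counts$a, counts$b, counts$c, counts$d, z = z),
    prr_stats(counts$a, counts$b, counts$c, counts$d, yates = yates),
    bcpnn_stats(counts$a, counts$b, counts$c, counts$d, z = z)
  )
  if (!is.null(prior)) {
    n <- counts$a + counts$b + counts$c + counts$d
    e <- (counts$a + counts$b) * (counts$a + counts$c) / n
    eb <- ebgm_stats(counts$a, e, prior)
    out$e <- e
    out$ebgm <- eb$ebgm
    out$eb05 <- eb$eb05
  }
  out
}
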