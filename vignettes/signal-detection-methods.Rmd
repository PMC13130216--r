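---
title: "Disproportionality signal detection for spontaneous adverse-event reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality signal detection for spontaneous adverse-event reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Spontaneous reporting systems such as the FDA Adverse Event Reporting
System (FAERS) collect unsolicited reports of suspected adverse drug
events. They have no denominator — nobody knows how many patients took a
drug without an incident being reported — so incidence cannot be
estimated. What *can* be estimated is disproportionality: whether a
drug/event pair is reported more often than the background of all other
reports would predict. `faersignal` implements the standard pipeline for
such analyses, motivated by the renal safety of the calcineurin
inhibitors (cyclosporine, tacrolimus, voclosporin), immunosuppressants
whose nephrotoxicity is a long-standing clinical concern: case
deduplication, cohorting by a drug-name lexicon and a renal-injury
SMQ-style preferred-term (PT) set, four disproportionality statistics
with a joint positivity rule, Weibull time-to-onset modelling, and
logistic risk-factor regression.

```{r setup}
library(faersignal)
```

## From raw quarters to a cohort

FAERS quarters arrive as `'$'`-delimited ASCII tables (DEMO, DRUG, REAC,
OUTC, THER, INDI) joined on `primaryid`. Cases are versioned: the same
`caseid` may be submitted repeatedly, and the FDA-recommended rule keeps,
per case, the version with the latest receipt date (`fda_dt`), breaking
ties by the highest `primaryid`. `dedupe_reports()` implements exactly
this lexicographic maximum, so the survivor set is invariant to input
order and the operation is idempotent.

Two normalisation choices matter downstream:

* **Name and term matching** is exact on case-folded,
  whitespace-collapsed strings. FAERS drug names are free text; mapping
  brand and spelling variants onto study drugs is the job of the
  user-supplied lexicon, not of fuzzy matching, which would be
  impossible to audit.
* **Dates** are `YYYYMMDD`, with partial dates (`YYYYMM`, `YYYY`)
  common. Deduplication needs a *total order*, so partial dates are
  padded with `01` components there; onset arithmetic needs *day
  precision*, so partial event or therapy dates count as missing for
  time-to-onset.

Exposure defaults to the primary-suspect (PS) role only. Reports name
many concomitant drugs; counting them all as exposure dilutes the
comparator and inflates apparent signals for heavily co-prescribed
drugs. The role set is configurable and echoed in the pipeline metadata.
A report exposed to several study drugs contributes to each drug's
cohort — the drugs are analysed separately, each against the comparator
of all other reports.

At the SMQ level one report is one counting unit regardless of how many
renal PTs it lists; PT-level scans count per term. Outcome codes are
grouped for display as Died (DE), Life threatening (LT), Hospitalized
(HO), Disabled (DS), and Other outcomes (CA, RI, OT pooled), taking the
most severe code when a report carries several; percentages are always
over "data available" denominators, i.e. reports with the characteristic
recorded.

## The four disproportionality statistics

Every statistic reduces to the 2×2 table for a drug/event pair: `a`
(drug & event), `b` (drug, other events), `c` (other drugs, event), `d`
(neither), with `N = a+b+c+d`, margins `n1. = a+b`, `n.1 = a+c`, and
expected count `E = n1. n.1 / N`.

**ROR** — reporting odds ratio `(ad)/(bc)` with the Wald interval
`exp(log ROR ± z √(1/a+1/b+1/c+1/d))`. Positive when `a ≥ 3` and the
lower 95% bound exceeds 1.

**PRR** — proportional reporting ratio `[a/(a+b)]/[c/(c+d)]` with the
1-df Pearson χ². Positive when `a ≥ 3`, `PRR ≥ 2` and `χ² ≥ 4`. The
Yates correction is off by default (and recorded in metadata when
enabled). The two frequentist measures obey the identity
`ROR/PRR = (1+a/b)/(1+c/d)`, a useful internal consistency check.

**BCPNN IC** — the information component is a shrunken
`log2` observed-to-expected ratio under the standard closed-form Bayesian
model (margin priors Beta(1,1), totals 2, joint prior constant
calibrated so independence gives IC = 0). `ic025 = ic − z√V` with the
closed-form variance. Positive when `a ≥ 3` and `ic025 > 0`. The closed
form is the ratio of posterior means; the test suite checks it against a
10⁶-draw Monte-Carlo evaluation of the same Beta posteriors.

**MGPS / EBGM** — the multi-item gamma Poisson shrinker models
`a ~ Poisson(λE)` with a two-component gamma mixture prior on λ fitted
by maximum marginal likelihood over the *entire* drug×event grid of the
cohort universe (shrinkage needs the ensemble, not just the study
pairs). The optimisation runs on log/logit-transformed parameters from
the classical start (0.2, 0.1, 2, 4, 1/3); the posterior for a cell is a
two-gamma mixture, `EBGM = exp(E[log λ])` via digamma, and EB05 is the
posterior 5th percentile by root-finding on the mixture CDF (tolerance
1e-8). Positive when `EBGM > 2` (EB05 selectable). With thin grids
(small batches, expected counts of a few) the fitted prior can
legitimately collapse towards a spike at λ = 1 and shrink everything to
the null — that is the method being honest about sparse evidence, and it
is why validation studies run at realistic batch sizes.

**Joint classification.** A pair positive on at least two algorithms is
a *valid* signal; positive on all four, a *strong* signal. The
case-count gate applies to every algorithm. The joint rule trades the
frequentist measures' sensitivity against the Bayesian measures'
shrinkage-based specificity.

Zero cells never receive continuity corrections; the affected statistics
are flagged undefined instead, so an absent comparator cannot
manufacture a signal.

### PT-level scans

`pt_level_scan()` repeats the analysis with the event defined as a
single PT, reports the χ² p-value, and applies Bonferroni correction
with `m` equal to the scanned list length (`adj_p = min(1, m·p)`). χ² is
the only frequentist p-value in the stack, which is why the correction
attaches there; raw and adjusted values are both reported. Ranked
frequency tables (`top_events()`) carry a deliberately laxer flag — ROR
point estimate above 1 — under a distinct name (`ror_gt1`), because
ranking "most reported terms" is descriptive, not confirmatory.

## Time-to-onset: Weibull shape as a failure clock

Onset is the event date minus the earliest therapy start of the matched
drug, in days. Same-day events are set to 0.5 days (the Weibull support
excludes zero); negative intervals are data errors, counted and treated
as missing; analysis is complete-case by default, with right-censoring
supported through survival terms in the likelihood for settings where
follow-up truncation matters.

The Weibull density `(β/α)(t/α)^{β−1} e^{−(t/α)^β}` is fitted by
profiling the scale, `α(β) = (Σ tᵢ^β / n)^{1/β}`, and root-finding the
1-D profile score in β to 1e-10. Wald intervals come from the analytic
observed information on the natural (not log) scale — the intervals this
field reports are symmetric around the estimates. The shape interval
then classifies the hazard: entirely below 1, *early failure*
(decreasing hazard — the risk is front-loaded after therapy start);
entirely above 1, *wear-out*; straddling 1, *random*. The interval, not
the point estimate, drives the call, so a shape of 0.98 with a tight
interval below 1 is still early failure while the same estimate with a
wide interval is not.

Quartiles of onset use linear interpolation between order statistics at
rank `1 + (n−1)p` (the default convention in R); the nearest-rank
alternative differs at these sample sizes by at most a day and the
choice is documented here rather than configurable.

## Risk factors

Logistic regression of the event flag on binned covariates — sex
(female reference), age (<18 / 18–65 / ≥65), weight (<50 / 50–80 / ≥80
kg), indication group (autoimmune / transplant / other) — is fitted by
IRLS (`stats::glm`, tolerance tightened to 1e-12, 50 iterations) among
the reports exposed to each drug. Univariable models use each
covariate's own complete cases; the multivariable model uses joint
complete cases — so the two columns of the output can rest on different
denominators, which is the standard presentation. Perfect separation is
an error naming the offending term, not a silently penalised fit;
single-level covariates (for example, indication for a drug approved in
one indication only) are dropped with a warning, which reproduces the
natural table layout for such drugs. The indication grouping is a
configurable PT→group map, since indication coding is free-form.

## The synthetic generator

`synthetic_config()` / `simulate_reports()` produce FAERS-shaped batches
with known ground truth, so that every pipeline stage is testable
without redistributing database extracts. The generative model:

* independent Bernoulli exposures per drug (three study drugs plus
  background comedications filling out the reporting universe);
* for each event PT, inclusion with probability
  `min(1, ρ·p₀)` for reports exposed to a drug carrying reporting ratio
  ρ on that PT (maximum over exposed drugs), `p₀` otherwise —
  `true_ror()` returns the exact odds ratio implied by these cell
  probabilities, marginalised over the other drugs' exposures;
* per-drug Weibull onset in days (rounded up to ≥ 1), event date =
  therapy start + onset, receipt date after a reporting delay;
* demographics with missing-completely-at-random missingness;
* a configurable fraction of cases emitted as 2–3 versions with
  increasing receipt dates and primary ids — the latest version is the
  truth deduplication must recover.

The defaults are calibrated to the published calcineurin-inhibitor
renal-injury setting: exposure shares proportional to the three drugs'
report volumes (scaled so desk-sized batches contain workable exposed
counts), reporting ratios that put the per-drug renal reporting
proportions near 21–27%, Weibull onset parameters (α ≈ 225/241/216
days, β ≈ 0.47/0.48/0.88), demographic marginals and missingness rates
from the published descriptive table, and a 10% duplicate rate. What
the generator does **not** emulate: correlated co-prescription,
informative missingness, country-specific reporting cultures, secular
reporting trends, or term-coding noise. Green tests therefore certify
the *estimators* (recovery, coverage, classification) under a clean
generative model, not robustness to every pathology of real spontaneous
data.

## Numerical and design choices

* Event-probability clipping at `min(1, ρ·p₀)` is documented; recovery
  studies use parameters far from the clip.
* MGPS optimisation: L-BFGS-B on log/logit scale, box equivalent to
  parameters in `[1e-6, 1e6]` and weight in `(1e-6, 1−1e-6)`;
  convergence failures raise an error carrying the best iterate. An
  all-zero cell grid is rejected as degenerate.
* BCPNN uses z = 1.96 to honour the "95% interval" convention; z = 2 is
  available by argument.
* All randomness in the pipeline flows from the single configured seed
  through named substreams per module, so runs are byte-reproducible.
* Report-level counting at SMQ level (a report with three matched PTs
  counts once) was chosen because the published case totals feed
  proportions of report counts; PT-level counting is available through
  the scan functions.
* The background universe for `c` and `d` is the loaded batch; with a
  full database extract that is all reports, with a filtered extract it
  is the filtered universe. The published analysis does not state its
  choice; this one is recorded in metadata.

## Validation study sizes

The shipped test suite exercises: parser/dedup round-trips on generated
quarters (300–1,000 cases); exposure and cell-frequency
goodness-of-fit at 10,000–50,000 reports; ROR interval coverage against
the analytic truth of 3 over 500 generated batches of 2,000 reports
(93–97% band); Weibull recovery at the published-scale truth
(α = 225, β = 0.47) over 200 samples of n = 2,000 with interval
coverage and early-failure typing; BCPNN closed form against 10⁶-draw
Monte-Carlo posteriors on 20 random tables (0.05-bit band); EBGM
digamma arithmetic against adaptive quadrature (1e-6); and logistic
IRLS against a refined brute-force likelihood grid (1e-3) at n = 200.
These sizes were chosen to make each check statistically meaningful
while keeping the default suite in the low minutes on one CPU.

## Known limitations

Disproportionality is relative reporting, not risk: a strong signal
means the pair is over-represented among reports, nothing more. The
package does not stratify MGPS by demographics, does not implement
multi-item itemsets or regression-adjusted shrinkage variants, does not
traverse the MedDRA hierarchy (PT lists are user-supplied inputs), and
treats weighted/algorithmic SMQs as out of scope. The Weibull model
assumes a single homogeneous onset process per drug; mixtures of acute
and chronic mechanisms will be summarised by an averaged shape.
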