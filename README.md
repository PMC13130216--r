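# faersignal

Pharmacovigilance signal detection for spontaneous adverse-event report
databases distributed as FAERS-style quarterly ASCII tables, built
around the renal safety of the calcineurin inhibitors (cyclosporine,
tacrolimus, voclosporin) but applicable to any drug/event question of
the same shape.

Spontaneous reporting systems have no denominator, so risk cannot be
estimated — but *disproportionality* can: whether a drug/event pair is
reported more often than the background of all other reports predicts.
For the 2×2 table of a pair (`a` drug & event, `b` drug & other events,
`c` other drugs & event, `d` neither; `N = a+b+c+d`,
`E = (a+b)(a+c)/N`), the package computes the four standard statistics:

* **ROR** `= ad/bc` with Wald interval
  `exp(log ROR ± z√(1/a+1/b+1/c+1/d))`; positive if `a ≥ 3` and the
  lower 95% bound `> 1`;
* **PRR** `= [a/(a+b)]/[c/(c+d)]` with the Pearson χ²; positive if
  `a ≥ 3`, `PRR ≥ 2`, `χ² ≥ 4`;
* **BCPNN IC**, the shrunken `log₂(observed/expected)` of the
  closed-form Bayesian confidence propagation neural network, with
  credible bound `IC025`; positive if `a ≥ 3` and `IC025 > 0`;
* **MGPS EBGM**, the empirical-Bayes geometric mean of the posterior
  reporting ratio under a two-gamma mixture prior fitted to the whole
  drug×event grid, with percentile `EB05`; positive if `EBGM > 2`.

Pairs positive on ≥ 2 algorithms are **valid** signals; on all four,
**strong** signals. Around this core the package provides FAERS ASCII
parsing, FDA-rule case deduplication (latest `fda_dt`, ties to highest
`primaryid`), lexicon/SMQ cohorting, Bonferroni-corrected PT-level
scans, descriptive tables over "data available" denominators, Weibull
time-to-onset fits with shape-based failure typing (shape interval
below 1 ⇒ early failure), logistic risk-factor regression, and a
synthetic FAERS-like generator with analytic ground truth
(`true_ror()`) for end-to-end validation.

## Worked example

Simulate a study-scale batch under the default configuration (three
study drugs with realistic exposure shares, a renal event set with
elevated reporting ratios, injected duplicate case versions), then run
the full analysis:

```r
library(faersignal)

cfg     <- synthetic_config(n_reports = 20000, seed = 2024)
reports <- simulate_reports(cfg)          # 23,144 versions of 20,000 cases
cohort  <- build_cohort(dedupe_reports(reports),
                        synthetic_lexicon(cfg), synthetic_smq(cfg))

dplyr::bind_rows(lapply(c("cyclosporine", "tacrolimus", "voclosporin"),
                        function(k) reporting_proportion(cohort, k)))
#>   drug         n_event n_exposed proportion   pct
#> 1 cyclosporine     194       907      0.214  21.4
#> 2 tacrolimus       292      1141      0.256  25.6
#> 3 voclosporin       24        89      0.270  27

smq_signal_table(cohort)
#>           drug cases  ror ror_lo ror_hi  prr   chi2   ic ic025 ebgm eb05 classification
#> 1 cyclosporine   194 2.83   2.40   3.35 2.44 163.11 1.18  0.95 2.83 2.82         strong
#> 2   tacrolimus   292 3.77   3.27   4.35 3.06 377.83 1.44  1.25 2.83 2.82         strong
#> 3  voclosporin    24 3.62   2.26   5.80 2.91  32.84 1.41  0.77 2.82 2.82         strong
#> 4          any   487 3.67   3.27   4.12 3.05 545.96 1.32  1.17 2.83 2.82         strong

weibull_onset_table(cohort)
#>           drug   n median    q1     q3  alpha alpha_lo alpha_hi beta beta_lo beta_hi failure_type
#> 1 cyclosporine 194     80 13.50 367.75 201.37   142.12   260.62 0.51    0.45    0.56        early
#> 2   tacrolimus 292    124 19.00 555.50 278.76   209.85   347.68 0.49    0.45    0.53        early
#> 3  voclosporin  24    115 81.25 289.50 237.34   127.81   346.87 0.92    0.63    1.20       random
```

Reading the output: each drug's reports match the renal event set in
21–27% of cases, and every drug clears all four positivity criteria, so
all are strong signals — as configured (reporting ratios 2.6–3.5). The
onset fits recover shapes near the configured 0.47/0.48/0.88: shapes
well below 1 with tight intervals classify as early failure (risk
front-loaded after therapy start), while voclosporin's 24 onset
observations leave an interval straddling 1, so its hazard trend is not
yet resolvable at this batch size.

Risk-factor tables come from `univariable_or()` / `multivariable_or()`
(odds ratios against female / youngest / lightest / autoimmune
reference levels), and `run_pipeline(config)` executes the whole flow
from a YAML config to a CSV/JSON output bundle with reproducibility
metadata (see `inst/extdata/example_config.yml`; a thin CLI wrapper
lives in `inst/cli/faersignal.R`).

Real FAERS quarters are read with
`read_faers_quarter(dir)` — files `DEMO.txt`, `DRUG.txt`, `REAC.txt`,
`OUTC.txt`, `THER.txt`, `INDI.txt`, `'$'`-delimited — together with a
drug lexicon (`read_drug_lexicon()`) and an SMQ preferred-term list
(`read_smq()`). MedDRA content is licensed, so PT lists are always
user-supplied inputs; the packaged list under `inst/extdata/` is a
synthetic stand-in for tests and examples.

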