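Package: faersignal
Title: Disproportionality Signal Detection and Onset Modelling for
    Spontaneous Adverse-Event Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A pharmacovigilance toolkit for spontaneous-report databases
    distributed as FAERS-style quarterly ASCII tables.  Parses and
    deduplicates case reports, builds drug/event analysis cohorts from a
    drug-name lexicon and an SMQ preferred-term list, and screens
    drug-event pairs with four disproportionality algorithms: the
    reporting odds ratio (ROR), the proportional reporting ratio (PRR)
    with Pearson chi-square, the Bayesian confidence propagation neural
    network information component (BCPNN IC), and the multi-item gamma
    Poisson shrinker (MGPS/EBGM).  Signals are classified jointly across
    algorithms, time-to-onset is modelled with Weibull maximum likelihood
    and shape-based failure typing, and demographic risk factors are
    assessed by logistic regression.  A fully parameterised synthetic
    report generator with analytic ground truth supports end-to-end
    validation without access to the live database.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    fitdistrplus,
    optparse,
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
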