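Package: coxbinom
Title: Cox-Binomial Mixture Change-Point Tests for Retrospectively
    Reconstructed Status Histories
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects a change at a known calendar time t0 in how members of
    a cross-sectionally sampled population acquire a permanent status
    (motivating case: consistent condom use by female sex workers).  The
    acquisition time has a point mass at population entry, modelled by
    binomial regression on a pre/post-t0 indicator, and a continuous part,
    modelled by Cox regression with a time-dependent step covariate; the two
    likelihood-ratio (or Wald) statistics add to a 2-df chi-squared test,
    with a cluster-robust version for multi-site data.  Includes the
    average-slope GEE comparator on a yearly panel, a prevalent-cohort
    simulator, and a Monte-Carlo harness for type-I error and power.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    survival,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
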