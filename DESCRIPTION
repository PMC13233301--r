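Package: mitmethyl
Title: Meet-in-the-Middle Analysis of Methylation Exposure and Disease Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for linking an exposure epigenome-wide association study
    (EWAS) run at birth with a disease EWAS run at diagnosis through shared
    differentially methylated regions (DMRs). Provides per-probe linear
    modelling on M-values with reference-free cell-composition and ancestry
    components, sample-size-weighted z-score meta-analysis across array
    platforms, spatially corrected DMR calling (autocorrelation-adjusted
    Stouffer-Liptak combination with Sidak correction), genomic-interval
    overlap of exposure and disease DMRs, and an exact binomial test of
    direction-of-effect concordance, overall and within demographic
    subgroups. A synthetic-data module simulates array-like methylation
    cohorts with planted differential regions and known concordance so the
    whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    readr,
    rlang,
    stats,
    tibble,
    yaml
Suggests: testthat (>= 3.0.0), withr, jsonlite, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
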