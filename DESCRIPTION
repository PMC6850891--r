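Package: ctstab
Title: Reference-Gene Stability Analysis for RT-qPCR
Version: 0.1.0
Authors@R:
    person("ctstab", "maintainers", email = "ctstab@example.org", role = c("aut", "cre"))
Description: Tools for selecting and validating RT-qPCR reference
    (housekeeping) genes. Implements candidate screening from two-library
    RNA-seq expression tables (RPKM and log2 expression ratio with a
    |log2Ratio| < 1 filter), standard-curve fitting over serial-dilution Ct
    series (slope, R-squared, amplification efficiency), Ct descriptive
    statistics, the geNorm (M value, stepwise exclusion, pairwise variation
    V_n/n+1), NormFinder (model-based intra/inter-group variance
    decomposition) and BestKeeper (SD/CV and index correlation) stability
    algorithms, a geometric-mean-of-ranks consensus, 2^-ddCt relative
    quantification for validating the chosen references, and a synthetic Ct
    generator with known ground-truth stability structure for testing the
    whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
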