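Package: tcbench
Title: Benchmarking Cross-Species Annotation Transfer for Membrane Transporters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for benchmarking how reliably functional annotations of
    membrane transporters (Transporter Classification families and substrate
    classes) can be transferred between organisms by sequence comparison.
    Provides affine-gap local and global protein alignment with
    Karlin-Altschul E-values, database-size normalization of E-values,
    ZOOPS expectation-maximization motif discovery with PWM scanning and
    exact score-distribution p-values, best-hit label transfer, family-size
    weighted precision/recall/F-measure over an E-value threshold sweep, and
    a synthetic two-organism family generator with known ground truth for
    end-to-end evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    withr,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
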