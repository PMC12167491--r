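Package: exocargo
Title: Differential Exosomal Cargo Analysis via iBAQ and Delta Fold Change
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Label-free quantitative proteomics pipeline for identifying
    knockdown-dependent exosomal cargo proteins in a 2x2 factorial design
    (oxidative stress x siRNA knockdown). Implements iBAQ protein
    quantification from peptide-level intensities via in-silico tryptic
    digestion, Perseus-style preprocessing (log2 transform, valid-value
    filtering, down-shifted normal imputation of left-censored missing
    values), per-contrast fold changes and two-sample t-tests, the
    delta-fold-change classification cascade that separates
    loading-factor-dependent from independent cargoes, and hypergeometric
    term enrichment. Ships a synthetic-data generator with planted effects
    and intensity-dependent missingness for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    tools,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
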