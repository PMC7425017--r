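Package: sifcall
Title: Significant Interacting Fragment Calling from Hi-C Ligation Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Calls significant interacting fragments (SIFs) from paired-end
    Hi-C ligation data at restriction-fragment resolution. Implements in-silico
    genome digestion, ligation-product quality control (self-, re- and
    valid-ligation classification), a two-component Poisson mixture model of
    fragment-pair interaction scores fitted by expectation-maximisation with
    bootstrap robustification, a power-law contact-distance background with a
    digestion-efficiency likelihood filter, local false discovery rate calling
    with an empirical null, equal-score fragment merging defining per-anchor
    resolution, promoter-distal loop classification, and loop-set evaluation by
    aggregate peak analysis and ROC/AUC. A synthetic-data generator with full
    ground truth supports simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
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
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pROC,
    yaml
Config/testthat/edition: 3
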