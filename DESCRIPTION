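Package: divselect
Title: Analysis of Divergent Selection Experiments on Inbred Lines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative-genetic analysis of divergent
    truncation-selection experiments started from inbred lines propagated by
    selfing. Covers selfing pedigrees and variance effective population sizes,
    control-plot correction of field-trial phenotypes with genotypic-value and
    heritability estimation, a drift-plus-mutation variance model with
    Monte-Carlo EM estimation of mutational and initial heritabilities, a
    forward-time locus-based simulator of the standing-variation-only null,
    single-breakpoint segmented regression with small-sample AIC weights,
    genealogy-based candidate-locus association with gene-dropping null
    distributions, neutral drift exceedance tests, and a synthetic-data
    generator that emulates the full experimental design with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    stats,
    ggplot2,
    generics,
    jsonlite,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
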