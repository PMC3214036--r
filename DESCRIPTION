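Package: essgenes
Title: Essentiality-Stratified Analysis of Human Disease Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies human disease genes by the lethality of their mouse
    ortholog knockouts (disease-lethal, disease-viable, disease-unknown),
    and characterises the resulting groups: protein-protein interaction
    network degree and component summaries, annotation enrichment by
    Fisher's exact test with Benjamini-Hochberg false-discovery-rate
    control, lexicon and naive-Bayes classification of free-text disease
    mechanism records, and mode-of-inheritance contrasts. Ships a
    synthetic-data generator with known ground truth so the whole pipeline
    can be exercised and calibrated without live database access.
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
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
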