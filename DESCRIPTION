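Package: devlethal
Title: Curation and Statistics for Candidate Developmental-Lethal Gene Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates Mendelian disease-gene curation, mouse knockout
    lethality classification, cell-line essentiality aggregation, and
    gene-level genetic-constraint categorisation into a per-gene master table,
    and derives the set of candidate developmental-lethal genes: genes
    essential for murine development or cellular viability that are not yet
    linked to a clinically relevant human phenotype. Ships the association
    statistics used to characterise these gene sets (two-sided Fisher exact
    tests, sample odds ratios with Woolf confidence intervals,
    inheritance-stratified constraint proportions, and hypergeometric GO-slim
    enrichment with Benjamini-Hochberg correction), together with a
    synthetic-source generator that emulates the seven input table dialects
    with planted ground truth for end-to-end testing.
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
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
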