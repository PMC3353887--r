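Package: orthotox
Title: Ortholog-Guided Discovery of Human DNA-Damage Toxicity Modulators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for projecting yeast DNA-damage sensitivity phenotypes onto
    the human protein-protein interaction network and for analysing RNAi
    knockdown screens of the resulting candidates. Implements ortholog-table
    merging and phenotype projection, induced-subgraph largest-connected-
    component statistics with permutation-based significance, hypergeometric
    functional enrichment, rule-based candidate selection with a per-gene
    audit trail, classification of clonogenic-survival curves into
    sensitivity/resistance tiers relative to a control-derived noise region,
    autophagy scoring from per-cell puncta counts, and a synthetic-data
    generator that emulates every input so the whole pipeline is testable
    end to end.
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
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
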