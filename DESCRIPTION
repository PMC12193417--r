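Package: echinodiv
Title: Multi-Marker Diversity Analysis for Barnyard Grass Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies phenotypic and genetic diversity of weed populations
    (Echinochloa spp.) across complementary marker systems and relates them to
    herbicide multi-resistance. Implements Shannon-Wiener trait diversity with
    ten-level binning, Ward clustering of standardized quantitative traits,
    DNA-barcode analysis (variable sites, haplotype grouping, Kimura
    two-parameter distances, neighbor-joining trees with bootstrap support,
    multi-locus concatenation), dominant-marker (SCoT/ISSR-style) 0/1 band
    analysis (polymorphism rates, polymorphism information content, simple
    matching similarity, UPGMA clustering), herbicide multi-resistance
    profiling by fresh-weight inhibition, and cross-marker concordance of
    cluster assignments. A synthetic-study generator with known ground truth
    makes every stage testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
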