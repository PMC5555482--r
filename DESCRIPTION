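Package: embryogem
Title: Genome-Wide Expression Map Search and Shared-Motif Dotplots for
    Embryo In Situ Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts in situ hybridization embryo images into standardized
    binary spatial expression profiles, aggregates profiles that share a data
    source, developmental stage range and anatomical orientation into a
    genome-wide expression map (GEM; a per-pixel inverted index from pixel to
    expressed genes), and ranks genes against pixel queries with the n/t
    coexpression score. Includes the classical Jaccard pairwise-search
    baseline and a formal comparison of the two searches, a k-mer dotplot of
    upstream intergenic regions that lists and renders maximal shared motifs
    with PhastCons-style conservation binning to SVG, and a fully seeded
    synthetic-data module (parametric embryo images with planted expression
    domains, annotation tables, motif-planted sequence pairs and conservation
    tracks) so every component is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    purrr,
    tibble,
    tidyr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    xml2,
    png,
    withr,
    stats,
    utils,
    EBImage,
    GenomicRanges,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
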