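Package: ectocage
Title: Cross-Species CAGE Screening for Ectopic Olfactory Receptor Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for screening olfactory receptor (OR)
    gene expression outside the olfactory epithelium from CAGE (Cap Analysis
    of Gene Expression) 5'-end tag data. Projects promoter windows across
    genomes through UCSC chain alignments with collision handling, quantifies
    CTSS tag counts and tags-per-million over windows and whole loci,
    classifies promoter shape (sharp versus broad) and TSS position relative
    to annotation, and applies the quartile and absolute-count candidate
    filters with artifact flagging. Companion quantifications include maximum
    parsimony homology search (Fitch scoring with random sequence addition and
    close-neighbour-interchange hill climbing), pairwise percent identity,
    delta-delta-Ct relative qPCR quantification with heat-map rescaling, and
    ratiometric fura-2 calcium response scoring. A synthetic-data generator
    produces every input with known ground truth so all stages are testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
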