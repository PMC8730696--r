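Package: bulkmapr
Title: Bulked-Segregant Mapping and Promoter-Conservation Analysis for
    Recessive Fruit Loci
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tidyverse-native toolkit for localizing a monogenic recessive
    locus from segregating populations, modelled on the mapping of the tomato
    all-flesh-fruit (locule-gel) locus. Implements chi-squared goodness-of-fit
    tests for Mendelian segregation ratios, bulked-segregant delta-SNP-index
    genome scans with a Monte-Carlo no-linkage confidence envelope,
    recombinant-panel fine-mapping with gene counting from GFF3 annotation,
    sliding-window conservation profiling of multi-species promoter
    alignments with structural-variant overlap reporting, per-gene windowed
    nucleotide diversity (pi) with percentile ranking, and small assay
    utilities (2^-ddCt relative expression, dual-luciferase ratios). A
    synthetic-data module generates every input the pipeline consumes - F2
    crosses under the Haldane map function, bulk read counts, promoter
    families with conserved blocks and a configurable deletion, and a toy
    variome - so the whole analysis is testable end to end without external
    sequencing data.
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
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    jsonlite,
    rtracklayer,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
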