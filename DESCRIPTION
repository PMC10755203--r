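Package: gbsmapr
Title: Genotyping-by-Sequencing Linkage Maps and Map-Guided Genome Finishing
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for finishing draft plant genome assemblies with an F2
    genetic map built from genotyping-by-sequencing (GBS) data. Discovers
    parent-diagnostic 51-mer markers between two inbred lines, demultiplexes
    and genotypes a barcoded single-end GBS run, bins raw calls into 14-kb
    majority-rule consensus windows, builds linkage groups and Kosambi
    genetic distances, detects and breaks chimeric contigs from
    population-wide haplotype switches, and orders and orients contigs into
    chromosome-scale pseudomolecules with AGP output. Includes a full
    synthetic-data module (inbred parents, F2 recombinant mosaics,
    ApeKI-digested barcoded reads, fragmented and chimeric assemblies) with
    ground truth so every stage can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tidyr,
    tibble,
    readr,
    rlang,
    igraph,
    ggplot2,
    generics,
    yaml,
    jsonlite,
    Biostrings,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
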