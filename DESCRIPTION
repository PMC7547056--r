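Package: phyllonet
Title: Leaf-Microbiome Co-Occurrence Networks, Hub Taxa and Host Genetic
    Association from Whole-Genome Sequencing Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for characterizing a crop leaf microbiome
    from host whole-genome sequencing data: unmapped-read extraction and
    classification-report ingestion into genus count profiles, diversity
    and accumulation statistics with SIMPER dissimilarity decomposition,
    centered log-ratio co-occurrence network inference with composite hub
    scoring and Louvain module detection, abundance-weighted community
    function profiles, kinship-corrected linear mixed model association of
    hub abundances with SNPs, and haplotype-block, candidate-gene, QTL and
    GO follow-up. A synthetic-data module with planted hubs and planted
    SNP effects makes every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    vegan,
    vcfR,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
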