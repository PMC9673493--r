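Package: magcurate
Title: Post-Assembly Curation of Long-Read Metagenome Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Post-assembly curation toolkit for HiFi (high-fidelity long
    read) metagenome assemblies: assembly-graph topology triage into
    circular, tangled and linear components; fragment-based average
    nucleotide identity (ANI) estimation and complete-linkage
    dereplication of genomes at strain (99% ANI) and species (95% ANI)
    levels with quality-aware representative selection; CheckM-style
    quality ranking and an RNA-completeness criterion based on full-length
    rRNA operons and tRNA complements; ANI and 16S identity novelty
    calling; greedy nonredundant gene-catalog construction and catalog
    comparison; and a synthetic-community generator with known ground
    truth for validating every step.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    methods,
    rtracklayer,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
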