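Package: aimpop
Title: Ancestry-Informative Marker Taxon Assignment and Population
    Genomics for Anopheles Surveillance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for whole-genome-sequencing based surveillance of the
    Anopheles gambiae species complex: ancestry-informative marker (AIM)
    species assignment, adaptive-introgression profiling along the genome,
    population structure analysis (dosage PCA, neighbour-joining trees on
    cityblock distances, Hudson's FST), genetic diversity statistics
    (nucleotide diversity, Watterson's theta, Tajima's D), and
    insecticide-resistance amino-acid substitution frequencies from coding
    variant annotation. Includes a synthetic genotype simulator with known
    ground truth (taxon labels, introgression states, planted resistance
    frequencies) so the whole pipeline can be validated end-to-end without
    access to large sequencing datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    jsonlite,
    methods,
    rtracklayer,
    S4Vectors,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
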