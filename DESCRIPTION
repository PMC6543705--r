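Package: circlemat
Title: Circular-Contig Detection, Mini-Circle Annotation and Phylogenomic
    Supermatrix Curation for Parasite Genome Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterising extrachromosomal circular DNA in
    fragmented genome assemblies and for curating phylogenomic supermatrices
    from heavily contaminated parasite data. Detects "circular" contigs by
    their terminal direct repeats, splits them into short and long pools,
    measures low-complexity content with a windowed DUST score, estimates the
    periodic spacing of the long-circle length distribution, clusters circles
    into families by pairwise similarity, scans circles with position weight
    matrices at exact p-values and tests motif enrichment, annotates
    mitochondrial mini-circles (including pseudogene stop/frameshift flags and
    a paired-read precursor test), runs a three-step host/prokaryote
    decontamination cascade, and builds concatenated supermatrices with
    chimeric-taxon merging, gap trimming, compositional (RCFV) filtering,
    Dayhoff-6 recoding and a per-position synapomorphy statistic q(i) for
    signal-based partition selection. A synthetic-data module generates
    assemblies, proteomes, read pairs and alignment partitions with known
    ground truth so that every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
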