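Package: baconscope
Title: Discovery and Evolution of Tandem BACON-Domain Repeats in Phage Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for discovering and characterising
    BACON-like protein domain tandem repeats in viral (phage) contigs:
    ORF prediction under translation table 11, profile hidden Markov model
    construction and iterative Viterbi domain search, gene-sharing contig
    clustering (Smith-Waterman homology graph, Markov clustering,
    hypergeometric shared-content tests, Ward.D2 with silhouette-based
    cluster-number selection), tandem-array architecture and genomic
    neighbourhood analysis with a permutation test for tail-gene
    association, progressive alignment, gap-column trimming, bootstrapped
    neighbor-joining domain phylogenies with position-in-array clade
    analysis and duplication-mode inference, and a k-mer Markov model for
    phage-host prediction. A fully seeded synthetic-genome generator with
    known ground truth exercises every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    ape,
    cluster,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    rtracklayer,
    BiocGenerics
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
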