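Package: magbin
Title: Semi-Supervised Metagenomic Contig Binning with a Siamese Embedding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Recovers metagenome-assembled genomes (MAGs) by clustering
    assembled contigs. Contigs are represented by canonical tetranucleotide
    frequencies and per-sample read-depth summaries; a siamese neural
    network trained jointly with a contrastive loss over must-link
    constraints (from artificially split contigs) and cannot-link
    constraints (from taxonomy disagreements and single-copy marker-gene
    seeds) plus an autoencoder reconstruction loss learns a low-dimensional
    embedding; contigs are then binned by Infomap community detection on a
    pruned similarity graph, with optional single-copy-gene guided weighted
    k-means reclustering. Includes a planted-genome synthetic community
    generator and a ground-truth evaluator so the whole pipeline is testable
    without external data or tools.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
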