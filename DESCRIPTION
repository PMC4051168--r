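Package: oralcap
Title: Off-Target Exome-Capture Metagenomics and Paralogue-Aware Locus Genotyping
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tiered fragment-recruitment metagenomics from the off-target read
    pool of exome-capture sequencing: quality filtering, a seed-and-extend local
    aligner emitting BLAST m8-style hits, identity/coverage/e-value tier
    classification with genome-length-normalized relative abundance and
    taxonomic rollup, strand-aware per-position substitution-bias profiles, and
    cross-population community statistics (partition-around-medoids silhouette
    scans, PCA loadings, Bonferroni-corrected Wilcoxon comparisons). Also
    implements paralogue-aware genotyping of polymorphic multigene loci
    (HLA/KIR-like) via positive/negative read-pair filters, depth-thresholded
    genotype calls, variable-content gene presence, and local phasing. A
    synthetic-data module generates every input with known truth so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    cluster,
    stats,
    utils,
    vegan
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
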