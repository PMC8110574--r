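Package: syntevol
Title: Synteny-Constrained Comparative Genomics and Molecular Rate Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for comparative analysis of related plant genomes:
    synteny-constrained orthology inference (hit culling, orthogroup
    clustering, collinear block chaining, density pruning, block extension
    and syntenic homolog classification), pairwise synonymous-substitution
    (Ks) estimation by Nei-Gojobori counting with Jukes-Cantor correction,
    Ks-distribution peak detection for dating divergence and whole-genome
    duplication, profile-likelihood estimation of the population mutation
    rate from read base-count quartets, gene-family expansion and tandem
    array classification with hypergeometric pathway enrichment, and a
    seeded genome-evolution simulator that plants ground truth for every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    igraph,
    jsonlite,
    Biostrings,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
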