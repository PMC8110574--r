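#!/usr/bin/env Rscript
# Stage 1: simulate the study system — two genomes related by a shared
# whole-genome duplication (contemporary paralog dS ~0.4), diverged to
# ortholog dS ~0.1585, with lineage-specific inversions, a reciprocal
# translocation, tandem arrays in both genomes and species-specific
# family expansions in genome A.  Writes the standard-format inputs the
# later stages consume, plus the planted truth.

suppressPackageStartupMessages(library(syntevol))

cfg <- sim_config(seed = 1L)
cat("simulating genomes (seed", cfg$seed, ")...\n")
sim <- simulate_genomes(cfg)
print(sim)
paths <- write_simulation(sim, "results/sim")
cat("wrote", length(paths), "files under results/sim/\n")
cat(sprintf("planted: %d ortholog pairs, %d WGD paralog pairs, %d arrays\n",
            nrow(sim$truth$orthologs), nrow(sim$truth$wgd_pairs),
            nrow(sim$truth$arrays)))
# keep the truth tables for the downstream scoring steps
dir.create("results", showWarnings = FALSE)
saveRDS_path <- "results/sim/truth_tables.tsv"
utils::write.table(sim$truth$orthologs, "results/sim/truth_orthologs.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(sim$truth$wgd_pairs, "results/sim/truth_wgd_pairs.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(sim$truth$arrays, "results/sim/truth_arrays.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(
  data.frame(gene_id = names(sim$truth$family_map),
             family = unname(sim$truth$family_map)),
  "results/sim/truth_families.tsv", sep = "\t", quote = FALSE,
  row.names = FALSE)
cat("done.\n")
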