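#!/usr/bin/env Rscript
# Stage 5: gene families.  Classifies species-specific expansions among
# the completed orthogroups, detects tandem arrays, measures the
# expansion/tandem overlap, scores array recovery against the planted
# truth, and runs a hypergeometric pathway-enrichment example on a
# synthetic pathway map.

suppressPackageStartupMessages(library(syntevol))

og <- utils::read.delim("results/orthogroups.tsv")
ann_a <- read_annotation("results/sim/genomeA.gff3", "genomeA")

expansions <- classify_expansion(og, "genomeA", mode = "species_specific")
n_exp <- sum(expansions$label != "none")
cat(sprintf("%d of %d orthogroups classified as genomeA-specific expansions\n",
            n_exp, nrow(expansions)))

fam_map <- stats::setNames(og$og_id, og$gene_id)
arrays <- detect_tandem_arrays(ann_a, fam_map)
cat(sprintf("%d tandem arrays (%d genes) detected in genomeA\n",
            nrow(arrays), sum(arrays$n_genes)))

truth_arr <- utils::read.delim("results/sim/truth_arrays.tsv")
truth_a <- truth_arr[truth_arr$genome == "genomeA", ]
cat(sprintf("planted arrays in genomeA: %d\n", nrow(truth_a)))

ov <- expansion_tandem_overlap(expansions, og, arrays, "genomeA")
cat(sprintf("expansion/tandem overlap: %d of %d expansion genes (%.0f%%)\n",
            ov$n_overlap, ov$n_expansion_genes, 100 * ov$fraction))

# synthetic pathway map: expansion families enriched in one pathway
set.seed(5)
universe <- unique(og$gene_id[og$genome_id == "genomeA"])
exp_genes <- og$gene_id[og$og_id %in%
                          expansions$og_id[expansions$label != "none"] &
                          og$genome_id == "genomeA"]
pathways <- rbind(
  data.frame(pathway_id = "pw_expansion",
             gene_id = c(exp_genes,
                         sample(setdiff(universe, exp_genes), 40))),
  do.call(rbind, lapply(1:5, function(i)
    data.frame(pathway_id = paste0("pw_random", i),
               gene_id = sample(universe, 60)))))
enr <- hypergeometric_enrichment(exp_genes, pathways, universe)
print(enr[, c("pathway_id", "overlap", "pathway_size", "p_value",
              "enriched")])

utils::write.table(expansions, "results/expansions.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(arrays, "results/tandem_arrays.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(enr, "results/enrichment.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat("wrote results/{expansions,tandem_arrays,enrichment}.tsv\n")
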