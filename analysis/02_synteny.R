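#!/usr/bin/env Rscript
# Stage 2: synteny-constrained orthology.  Reads the simulated
# annotations and the all-vs-all hit table, runs cull -> pairwise
# orthogroups -> chaining -> DBSCAN pruning -> completion -> extension ->
# classification, scores the anchors against the planted truth, and
# writes the block/orthogroup tables and the chromosome summary.

suppressPackageStartupMessages(library(syntevol))

ann_a <- read_annotation("results/sim/genomeA.gff3", "genomeA")
ann_b <- read_annotation("results/sim/genomeB.gff3", "genomeB")
hits <- read_hit_table("results/sim/hits.tsv")
cat(sprintf("loaded %d + %d genes, %d hits\n", nrow(ann_a$genes),
            nrow(ann_b$genes), nrow(hits)))

res <- synteny_run(hits, ann_a, ann_b)
cat(sprintf("%d blocks (%d inverted), %d anchors\n",
            nrow(res$blocks$blocks),
            sum(res$blocks$blocks$orientation == "inverted"),
            nrow(res$blocks$anchors)))
print(res$summary)

truth <- utils::read.delim("results/sim/truth_orthologs.tsv")
truth_pairs <- paste(truth$gene_a, truth$gene_b)
# under a WGD, anchors between a gene and its duplicate's ortholog are
# also true homologous anchors: include the cross-copy pairs
wgd <- utils::read.delim("results/sim/truth_wgd_pairs.tsv")
omap <- stats::setNames(truth$gene_b, truth$gene_a)
wa <- wgd[wgd$genome == "genomeA", ]
cross_pairs <- c(paste(wa$gene_1, omap[wa$gene_2]),
                 paste(wa$gene_2, omap[wa$gene_1]))
found <- paste(res$blocks$anchors$gene_a, res$blocks$anchors$gene_b)
precision <- mean(found %in% c(truth_pairs, cross_pairs))
recall <- mean(truth_pairs %in% found)
cat(sprintf("anchor precision %.3f (vs all true homolog pairs), ortholog recall %.3f\n",
            precision, recall))

utils::write.table(res$summary, "results/synteny_summary.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(res$blocks$blocks, "results/blocks.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(res$blocks$anchors, "results/block_anchors.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(res$orthogroups, "results/orthogroups.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(res$classes, "results/homolog_classes.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat("wrote results/{synteny_summary,blocks,block_anchors,orthogroups,",
    "homolog_classes}.tsv\n", sep = "")
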