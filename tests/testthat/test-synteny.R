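# Hit culling, orthogroup clustering, block chaining, DBSCAN pruning,
# completion, extension and classification.

test_that("culling keeps the top hits per haplotype and enforces the score floor", {
  ann_a <- make_ann("A", 10)
  ann_b <- make_ann("B", 10)
  q <- ann_a$genes$gene_id[1]
  targets <- ann_b$genes$gene_id[1:5]
  h <- make_hits(rep(q, 5), targets, c(300, 250, 200, 150, 100))
  out <- cull_hits(h, list(ann_a, ann_b))
  expect_equal(sort(out$bit_score), c(250, 300))
  # bit score boundary: strictly-less dropped
  h2 <- make_hits(c(q, q), targets[1:2], c(49.9, 50.0))
  out2 <- cull_hits(h2, list(ann_a, ann_b))
  expect_equal(out2$bit_score, 50.0)
  # self hits removed
  h3 <- make_hits(q, q, 900)
  expect_equal(nrow(cull_hits(h3, list(ann_a, ann_b))), 0L)
})

test_that("a diploid target retains up to four hits per query gene", {
  ann_a <- make_ann("A", 10)
  ann_b <- make_ann("B", 10, ploidy = 2L)
  q <- ann_a$genes$gene_id[1]
  h <- make_hits(rep(q, 10), ann_b$genes$gene_id[1:10], seq(500, 140, -40))
  out <- cull_hits(h, list(ann_a, ann_b))
  expect_equal(nrow(out), 4L)
  expect_equal(sort(out$bit_score, decreasing = TRUE),
               c(500, 460, 420, 380))
})

test_that("culling is a subset operation and idempotent", {
  set.seed(21)
  ann_a <- make_ann("A", 30)
  ann_b <- make_ann("B", 30)
  h <- make_hits(sample(ann_a$genes$gene_id, 200, TRUE),
                 sample(ann_b$genes$gene_id, 200, TRUE),
                 runif(200, 30, 600))
  once <- cull_hits(h, list(ann_a, ann_b))
  key <- function(x) paste(x$query_gene, x$target_gene, x$bit_score)
  expect_true(all(key(once) %in% key(h)))
  twice <- cull_hits(once, list(ann_a, ann_b))
  expect_equal(sort(key(twice)), sort(key(once)))
  expect_error(cull_hits(make_hits("nope", "B_c1_001", 100),
                         list(ann_a, ann_b)), "unknown gene")
})

test_that("pairwise orthogroups are components of the filtered hit graph", {
  ann_a <- make_ann("A", 5)
  ann_b <- make_ann("B", 5)
  a <- ann_a$genes$gene_id; b <- ann_b$genes$gene_id
  # two reciprocal singleton pairs -> two groups of two
  h <- make_hits(a[1:2], b[1:2], c(400, 380))
  og <- infer_pairwise_orthogroups(h, ann_a, ann_b)
  expect_equal(length(unique(og$og_id)), 2L)
  expect_equal(nrow(og), 4L)
  # a connected clique of four -> one group of four
  h2 <- make_hits(c(a[1], a[1], a[2], a[2]), c(b[1], b[2], b[1], b[2]),
                  c(400, 390, 380, 395))
  og2 <- infer_pairwise_orthogroups(h2, ann_a, ann_b)
  expect_equal(length(unique(og2$og_id)), 1L)
  expect_equal(sort(og2$gene_id), sort(c(a[1:2], b[1:2])))
  # isolated gene (no surviving hits) belongs to no group
  expect_false(a[5] %in% og2$gene_id)
  # weak edges below half the best score are dropped before clustering
  h3 <- make_hits(c(a[1], a[1]), c(b[1], b[2]), c(400, 150))
  og3 <- infer_pairwise_orthogroups(h3, ann_a, ann_b)
  expect_false(b[2] %in% og3$gene_id)
})

test_that("chaining recovers planted diagonals with orientations", {
  # 30-anchor perfect diagonal -> one collinear block
  an <- make_anchors(1:30, 1:30)
  blk <- chain_collinear_blocks(an)
  expect_equal(nrow(blk$blocks), 1L)
  expect_equal(blk$blocks$orientation, "collinear")
  expect_equal(blk$blocks$anchor_count, 30L)
  # diagonal + anti-diagonal -> two blocks, one of each orientation
  an2 <- rbind(make_anchors(1:30, 1:30),
               make_anchors(41:70, 100:71))
  blk2 <- chain_collinear_blocks(an2)
  expect_equal(nrow(blk2$blocks), 2L)
  expect_setequal(blk2$blocks$orientation, c("collinear", "inverted"))
  expect_equal(blk2$blocks$anchor_count, c(30L, 30L))
  # 9 anchors with mbs = 10 -> no block
  expect_equal(nrow(chain_collinear_blocks(make_anchors(1:9, 1:9))$blocks),
               0L)
})

test_that("the rank-gap allowance splits chains at 26 intervening ranks", {
  # gap of 26 intervening ranks (> max_gap 25) -> two blocks
  an <- rbind(make_anchors(1:30, 1:30), make_anchors(57:86, 57:86))
  blk <- chain_collinear_blocks(an)
  expect_equal(nrow(blk$blocks), 2L)
  # gap of exactly 25 intervening ranks -> one block
  an2 <- rbind(make_anchors(1:30, 1:30), make_anchors(56:85, 56:85))
  blk2 <- chain_collinear_blocks(an2)
  expect_equal(nrow(blk2$blocks), 1L)
  expect_equal(blk2$blocks$anchor_count, 60L)
})

test_that("emitted blocks are strictly monotone in both rank coordinates", {
  set.seed(33)
  for (rep in 1:5) {
    # noisy mixture of two diagonals plus scatter
    an <- rbind(make_anchors(1:40, 1:40),
                make_anchors(60:95, 130:95),
                make_anchors(sample(1:150, 25), sample(1:150, 25)))
    an <- an[!duplicated(an[, c("rank_a", "rank_b")]), ]
    blk <- suppressWarnings(chain_collinear_blocks(an))
    for (b in blk$blocks$block_id) {
      sub <- blk$anchors[blk$anchors$block_id == b, ]
      expect_true(all(diff(sub$rank_a) > 0))
      dr <- diff(sub$rank_b)
      expect_true(all(dr > 0) || all(dr < 0))
      ori <- blk$blocks$orientation[blk$blocks$block_id == b]
      expect_equal(ori, if (all(dr > 0)) "collinear" else "inverted")
    }
  }
})

test_that("duplicate rank anchors are deduplicated with a warning", {
  an <- rbind(make_anchors(1:30, 1:30), make_anchors(5, 5))
  expect_warning(blk <- chain_collinear_blocks(an), "deduplicated")
  expect_equal(blk$blocks$anchor_count, 30L)
})

test_that("density pruning matches a direct DBSCAN oracle", {
  set.seed(55)
  p <- synteny_params()
  for (rep in 1:6) {
    n <- sample(30:200, 1)
    x <- sample(1:400, n, replace = TRUE)
    y <- sample(1:400, n, replace = TRUE)
    mine <- syntevol:::dbscan_ranks(x, y, p$dbscan_eps, p$dbscan_min_pts,
                                    "chebyshev")
    ref <- oracle_dbscan(x, y, p$dbscan_eps, p$dbscan_min_pts, "chebyshev")
    expect_identical(mine, ref)
  }
})

test_that("pruning removes scattered outliers but keeps dense blocks", {
  dense <- make_anchors(1:30, 1:30)
  stray <- make_anchors(c(101, 121, 141), c(300, 350, 400))
  blk <- structure(list(
    blocks = data.frame(block_id = "B00001", chrom_a = "chr1",
                        chrom_b = "chr1", orientation = "collinear",
                        anchor_count = 33L),
    anchors = cbind(block_id = "B00001", rbind(dense, stray))),
    class = "synteny_blocks")
  out <- prune_blocks_density(blk)
  expect_equal(nrow(out$blocks), 1L)
  expect_equal(out$blocks$anchor_count, 30L)
  expect_false(any(out$anchors$rank_a > 100))
  # a block of exactly mbs anchors within eps survives unchanged
  tight <- chain_collinear_blocks(make_anchors(1:10, 1:10))
  expect_equal(prune_blocks_density(tight)$blocks$anchor_count, 10L)
  # fewer than min_pts anchors -> entire block removed
  small <- structure(list(
    blocks = data.frame(block_id = "B00001", chrom_a = "chr1",
                        chrom_b = "chr1", orientation = "collinear",
                        anchor_count = 8L),
    anchors = cbind(block_id = "B00001", make_anchors(1:8, 1:8))),
    class = "synteny_blocks")
  expect_equal(nrow(prune_blocks_density(small)$blocks), 0L)
})

test_that("orthogroup completion is a transitive closure", {
  og1 <- data.frame(og_id = "OG000001", genome_id = c("A", "B"),
                    gene_id = c("A1", "B1"))
  og2 <- data.frame(og_id = "OG000001", genome_id = c("B", "C"),
                    gene_id = c("B1", "C1"))
  merged <- complete_orthogroups(list(og1, og2))
  expect_equal(length(unique(merged$og_id)), 1L)
  expect_setequal(merged$gene_id, c("A1", "B1", "C1"))
  # disjoint groups stay disjoint
  og3 <- data.frame(og_id = "OG000001", genome_id = c("A", "B"),
                    gene_id = c("A2", "B2"))
  m2 <- complete_orthogroups(list(og1, og3))
  expect_equal(length(unique(m2$og_id)), 2L)
  # chain across five genomes collapses into one group
  chain <- lapply(1:4, function(i)
    data.frame(og_id = "OG000001",
               genome_id = c(LETTERS[i], LETTERS[i + 1]),
               gene_id = paste0(LETTERS[c(i, i + 1)], "x")))
  m3 <- complete_orthogroups(chain)
  expect_equal(length(unique(m3$og_id)), 1L)
  expect_equal(nrow(m3), 5L)
  # closure: running completion twice equals running it once
  m4 <- complete_orthogroups(merged)
  expect_equal(m4, merged)
})

test_that("extension fills orthogroup gaps and ignores distant hits", {
  ann_a <- make_ann("A", 60, prefix = "a")
  ann_b <- make_ann("B", 60, prefix = "b")
  a <- ann_a$genes$gene_id; b <- ann_b$genes$gene_id
  present <- setdiff(1:40, 20:22)   # 3-anchor hole at ranks 19:21
  anchors <- data.frame(gene_a = a[present], gene_b = b[present],
                        chrom_a = "chr1", chrom_b = "chr1",
                        rank_a = present - 1L, rank_b = present - 1L,
                        bit_score = 500)
  blk <- chain_collinear_blocks(anchors)
  expect_equal(blk$blocks$anchor_count, 37L)
  # score-passing hits exist for the hole (not orthogroup members)
  hits <- make_hits(a[20:22], b[20:22], c(80, 80, 80))
  out <- extend_blocks(blk, hits, ann_a, ann_b)
  expect_equal(out$blocks$anchor_count, 40L)
  expect_true(all(paste0("a_c1_0", 20:22) %in% out$anchors$gene_a))
  # no additional hits -> output equals input anchors
  same <- extend_blocks(blk, make_hits(character(0), character(0),
                                       numeric(0)), ann_a, ann_b)
  expect_setequal(paste(same$anchors$gene_a, same$anchors$gene_b),
                  paste(blk$anchors$gene_a, blk$anchors$gene_b))
})

test_that("hits far outside the extension radius are not pulled in", {
  ann_a <- make_ann("A", 300, prefix = "a")
  ann_b <- make_ann("B", 300, prefix = "b")
  a <- ann_a$genes$gene_id; b <- ann_b$genes$gene_id
  anchors <- data.frame(gene_a = a[1:30], gene_b = b[1:30],
                        chrom_a = "chr1", chrom_b = "chr1",
                        rank_a = 0:29, rank_b = 0:29, bit_score = 500)
  blk <- chain_collinear_blocks(anchors)
  # hits at ranks ~180, 150 ranks away from the block
  hits <- make_hits(a[181:220], b[181:220], rep(400, 40))
  out <- extend_blocks(blk, hits, ann_a, ann_b)
  expect_equal(sort(unique(out$anchors$rank_a)), 0:29)
})

test_that("syntenic homologs are labeled ortholog/paralog/unclustered", {
  ann_a <- make_ann("A", 40, prefix = "a")
  ann_b <- make_ann("B", 40, prefix = "b")
  a <- ann_a$genes$gene_id; b <- ann_b$genes$gene_id
  anchors <- data.frame(gene_a = a[1:20], gene_b = b[1:20],
                        chrom_a = "chr1", chrom_b = "chr1",
                        rank_a = 0:19, rank_b = 0:19, bit_score = 500)
  blk <- chain_collinear_blocks(anchors)
  og <- data.frame(og_id = "OG000001", genome_id = c("A", "A", "B"),
                   gene_id = c(a[1], a[2], b[1]))
  hits <- rbind(make_hits(a[1], b[1], 500),   # ortholog
                make_hits(a[1], a[2], 450),   # paralog
                make_hits(a[3], b[3], 400),   # unclustered, best for a3
                make_hits(a[1], b[4], 180))   # 36% of a1's best -> dropped
  cls <- classify_syntenic_homologs(hits, blk, og, list(ann_a, ann_b))
  lab <- setNames(cls$label, paste(cls$gene_a, cls$gene_b))
  expect_equal(unname(lab[paste(min(a[1], b[1]), max(a[1], b[1]))]),
               "ortholog")
  expect_equal(unname(lab[paste(a[1], a[2])]), "paralog")
  expect_equal(unname(lab[paste(min(a[3], b[3]), max(a[3], b[3]))]),
               "unclustered_homolog")
  expect_equal(unname(lab[paste(min(a[1], b[4]), max(a[1], b[4]))]),
               "dropped")
})

test_that("summary percentages and totals are internally consistent", {
  counts <- data.frame(chromosome = c("1", "2"),
                       total_genes = c(2436L, 1000L),
                       genes_in_blocks = c(2235L, 0L),
                       n_blocks = c(25L, 0L),
                       genes_largest_block = c(426L, 0L))
  s <- summarize_synteny_counts(counts)
  expect_equal(s$pct_in_blocks, c(91.7, 0, round(100 * 2235 / 3436, 1)))
  expect_equal(s$genes_in_blocks[3], 2235L)
  expect_equal(s$total_genes[3], 3436L)
})

test_that("block summaries count unique focal genes per chromosome", {
  ann_a <- make_ann("A", c(40, 30), prefix = "a")
  an <- rbind(
    cbind(block_id = "B00001",
          make_anchors(0:29, 0:29, chrom_a = "chr1", chrom_b = "chr1")),
    cbind(block_id = "B00002",
          make_anchors(0:25, 0:25, chrom_a = "chr2", chrom_b = "chr2")))
  an$gene_a <- ifelse(an$chrom_a == "chr1",
                      sprintf("a_c1_%03d", an$rank_a + 1),
                      sprintf("a_c2_%03d", an$rank_a + 1))
  blocks <- structure(list(
    blocks = data.frame(block_id = c("B00001", "B00002"),
                        chrom_a = c("chr1", "chr2"),
                        chrom_b = c("chr1", "chr2"),
                        orientation = "collinear",
                        anchor_count = c(30L, 26L)),
    anchors = an), class = "synteny_blocks")
  s <- summarize_synteny(blocks, ann_a, min_block_genes = 25L)
  expect_equal(s$genes_in_blocks[1:2], c(30L, 26L))
  expect_equal(s$pct_in_blocks[1:2], c(75.0, 86.7))
  expect_equal(s$genes_in_blocks[3], 56L)
  # raising the reporting threshold drops the smaller block
  s2 <- summarize_synteny(blocks, ann_a, min_block_genes = 28L)
  expect_equal(s2$genes_in_blocks[1:2], c(30L, 0L))
})
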