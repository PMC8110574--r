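# Genome-evolution simulator: determinism, planted-truth consistency,
# codon evolution round trips, hit-score monotonicity and read profiles.

small_cfg <- function(...) {
  sim_config(seed = 19, n_chromosomes = 3L, genes_per_chromosome = 50L,
             codon_length_range = c(80L, 150L), inversion_count = 1L,
             inversion_size_range = c(12L, 18L), translocation_count = 1L,
             translocation_size_range = c(6L, 10L),
             tandem_family_count = 5L, expansion_count = 2L,
             n_sites = 1e4, ...)
}

test_that("identical configs and seeds reproduce the simulation exactly", {
  s1 <- simulate_genomes(small_cfg())
  s2 <- simulate_genomes(small_cfg())
  expect_identical(s1$annotations$genomeA$genes, s2$annotations$genomeA$genes)
  expect_identical(s1$cds, s2$cds)
  expect_identical(s1$truth$orthologs, s2$truth$orthologs)
  h1 <- simulate_hit_table(s1)
  set.seed(small_cfg()$seed)
  h2 <- simulate_hit_table(s2)
  expect_equal(nrow(h1), nrow(h2))
})

test_that("the identity limit yields two identical genomes and full-chromosome blocks", {
  cfg <- sim_config(seed = 3, n_chromosomes = 2L, genes_per_chromosome = 40L,
                    codon_length_range = c(60L, 100L), wgd_ks = NA,
                    speciation_ks = 0, inversion_count = 0L,
                    translocation_count = 0L, tandem_family_count = 0L,
                    expansion_count = 0L, noise_hit_fraction = 0)
  sim <- simulate_genomes(cfg)
  a <- sim$annotations$genomeA$genes; b <- sim$annotations$genomeB$genes
  expect_identical(sub("^gA_", "", a$gene_id), sub("^gB_", "", b$gene_id))
  expect_identical(a$rank, b$rank)
  expect_identical(unname(sim$cds[a$gene_id]), unname(sim$cds[b$gene_id]))
  hits <- simulate_hit_table(sim)
  res <- synteny_run(hits, sim$annotations$genomeA, sim$annotations$genomeB)
  # one block per chromosome covering every gene
  expect_equal(nrow(res$blocks$blocks), 2L)
  expect_equal(sort(res$blocks$blocks$anchor_count), c(40L, 40L))
})

test_that("codon evolution hits its dS target in expectation", {
  set.seed(37)
  src <- random_sense_cds(500)
  expect_identical(evolve_codons(src, 0), src)
  # omega = 0 -> protein unchanged
  ev0 <- evolve_codons(src, 0.3, omega = 0)
  expect_identical(syntevol:::translate_cds(ev0),
                   syntevol:::translate_cds(src))
  # mean estimated Ks across replicates within 5% of the target
  ks <- replicate(40, {
    ev <- evolve_codons(src, 0.15)
    estimate_pairwise_ks(codon_alignment(src, ev))$ks
  })
  expect_lt(abs(mean(ks) - 0.15) / 0.15, 0.05)
  # no stop codons ever introduced
  expect_false(grepl("\\*", syntevol:::translate_cds(ev0)))
})

test_that("hit tables mirror planted truth and score monotonically", {
  sim <- simulate_genomes(small_cfg())
  h0 <- simulate_hit_table(sim, noise_hit_fraction = 0)
  expect_true(all(is.finite(h0$true_ds)))
  # noise arithmetic: |hits| = |true pairs| * (1 + fraction), rounded
  h1 <- simulate_hit_table(sim, noise_hit_fraction = 0.1)
  expect_equal(nrow(h1), nrow(h0) + round(0.1 * nrow(h0)))
  # monotone identity-to-score map: among true pairs of equal length, a
  # more diverged pair never outscores a less diverged one
  len <- pmin(nchar(sim$cds[h0$query_gene]), nchar(sim$cds[h0$target_gene]))
  for (l in unique(len)) {
    sub <- h0[len == l, ]
    if (nrow(sub) < 2) next
    o <- order(sub$true_ds)
    expect_true(all(diff(sub$bit_score[o]) <= 0))
  }
})

test_that("planted tandem arrays are recovered exactly by the detector", {
  cfg <- sim_config(seed = 23, n_chromosomes = 3L,
                    genes_per_chromosome = 60L,
                    codon_length_range = c(60L, 100L), wgd_ks = NA,
                    inversion_count = 0L, translocation_count = 0L,
                    tandem_family_count = 15L, expansion_count = 0L)
  sim <- simulate_genomes(cfg)
  annA <- sim$annotations$genomeA
  famA <- sim$truth$family_map[annA$genes$gene_id]
  arr <- detect_tandem_arrays(annA, famA)
  truthA <- sim$truth$arrays[sim$truth$arrays$genome == "genomeA", ]
  expect_equal(nrow(arr), nrow(truthA))
  expect_setequal(
    vapply(strsplit(arr$genes, ","), function(g) paste(sort(g),
                                                       collapse = ","), ""),
    vapply(strsplit(truthA$genes, ","), function(g) paste(sort(g),
                                                          collapse = ","),
           ""))
})

test_that("planted expansions overlap tandem duplicates completely", {
  # expansions are the only duplicates in their families here (no WGD),
  # so every expansion gene is a tandem-array member
  sim <- simulate_genomes(small_cfg(wgd_ks = NA))
  annA <- sim$annotations$genomeA
  fam <- sim$truth$family_map
  og <- data.frame(og_id = unname(fam), genome_id = "genomeA",
                   gene_id = names(fam))
  og <- og[og$gene_id %in% annA$genes$gene_id, ]
  exp_fams <- sim$truth$arrays[grepl("expansion",
                                     sim$truth$arrays$kind), "family"]
  cls <- data.frame(og_id = exp_fams, label = "species_specific:genomeA")
  arr <- detect_tandem_arrays(annA, fam[annA$genes$gene_id])
  ov <- expansion_tandem_overlap(cls, og, arr, "genomeA")
  expect_equal(ov$fraction, 1)
})

test_that("truth blocks are monotone runs of ortholog anchors", {
  sim <- simulate_genomes(small_cfg())
  tb <- syntevol:::truth_blocks(sim)
  for (b in unique(tb$truth_block)) {
    seg <- tb[tb$truth_block == b, ]
    if (nrow(seg) < 2) next
    expect_true(all(diff(seg$rank_a) > 0))
    dr <- diff(seg$rank_b)
    expect_true(all(dr > 0) || all(dr < 0))
  }
  # planted orthologs all appear in truth blocks of a simulator without
  # rearrangement edge effects
  expect_gt(nrow(tb) / nrow(sim$truth$orthologs), 0.97)
})

test_that("read profiles are deterministic and match their model", {
  p1 <- simulate_profiles(5e3, 0.008, 20, 0.01, seed = 5)
  p2 <- simulate_profiles(5e3, 0.008, 20, 0.01, seed = 5)
  expect_identical(p1$profiles, p2$profiles)
  # theta = 0 and error 0 -> every profile monomorphic
  p0 <- simulate_profiles(5e3, 0, 20, 0, seed = 6)
  cnt <- as.matrix(p0$profiles[, c("nA", "nC", "nG", "nT")])
  expect_true(all(rowSums(cnt > 0) <= 1))
  # binomial expectation checks against the truth labels
  set.seed(8)
  p <- simulate_profiles(5e4, 0.01, 20, 0.02)
  cnt <- as.matrix(p$profiles[, c("nA", "nC", "nG", "nT")])
  depth <- rowSums(cnt)
  expect_lt(abs(mean(depth) - 20), 3 * sqrt(20 / 5e4))
  hom <- !p$is_het & depth > 0
  # error-read fraction among true hom sites ~ error_rate
  major <- apply(cnt[hom, ], 1, max)
  err <- sum(depth[hom] - major) / sum(depth[hom])
  expect_lt(abs(err - 0.02), 0.002)
})

test_that("simulation outputs round-trip through standard formats", {
  sim <- simulate_genomes(small_cfg())
  dir <- tempfile()
  paths <- write_simulation(sim, dir)
  ann <- read_annotation(paths[["genomeA_gff3"]], "genomeA")
  expect_identical(ann$genes$gene_id, sim$annotations$genomeA$genes$gene_id)
  expect_identical(ann$genes$rank, sim$annotations$genomeA$genes$rank)
  hits <- read_hit_table(paths[["hits"]])
  expect_equal(nrow(hits), nrow(simulate_hit_table(sim)))
  cds <- Biostrings::readDNAStringSet(paths[["genomeA_cds"]])
  expect_identical(unname(as.character(cds[1])),
                   unname(sim$cds[names(cds)[1]]))
  prof <- load_profiles(paths[["profiles"]], min_depth = 0L)
  expect_gt(nrow(prof), 0L)
})
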