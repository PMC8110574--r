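# Codon back-translation, NG86 Ka/Ks, peak detection and rate arithmetic.

test_that("back-translation replaces residues by codons and gaps by ---", {
  # M K - V   vs   M K A V
  aln <- backtranslate_alignment("MK-V", "MKAV",
                                 "ATGAAAGTT", "ATGAAAGCTGTA")
  expect_equal(aln$seq_a, "ATGAAA---GTT")
  expect_equal(aln$seq_b, "ATGAAAGCTGTA")
  # terminal stop codons are stripped before validation
  aln2 <- backtranslate_alignment("MK", "MK", "ATGAAATAA", "ATGAAG")
  expect_equal(aln2$seq_a, "ATGAAA")
  # translation mismatch names the first discordant residue
  expect_error(backtranslate_alignment("MKV", "MKV",
                                       "ATGGGGGTT", "ATGAAAGTT"),
               "residue 2")
  # CDS length must be 3x the protein length
  expect_error(backtranslate_alignment("MKV", "MKV",
                                       "ATGAAA", "ATGAAAGTT"),
               "3x protein length")
})

test_that("a four-codon worked pair back-translates column by column", {
  # proteins MIRA / MI-A with hand-built codons
  aln <- backtranslate_alignment("MIRA", "MI-A",
                                 "ATGATTCGTGCC", "ATGATAGCG")
  expect_equal(aln$seq_a, "ATGATTCGTGCC")
  expect_equal(aln$seq_b, "ATGATA---GCG")
  e <- estimate_pairwise_ks(aln)
  expect_equal(e$codons, 3L)   # gap column skipped
})

test_that("identical sequences give ks = ka = 0", {
  s <- random_sense_cds(50)
  e <- estimate_pairwise_ks(codon_alignment(s, s))
  expect_equal(e$ks, 0)
  expect_equal(e$ka, 0)
  expect_false(e$saturated)
})

test_that("a single synonymous change matches the hand-derived value", {
  # TTT -> TTC over 10 GCT filler codons: S = 10 + 1/3, sd = 1
  a <- paste(c(rep("GCT", 10), "TTT"), collapse = "")
  b <- paste(c(rep("GCT", 10), "TTC"), collapse = "")
  e <- estimate_pairwise_ks(codon_alignment(a, b))
  expect_equal(e$s_sites, 10 + 1 / 3)
  expect_equal(e$ks, -0.75 * log(1 - 4 / (3 * (10 + 1 / 3))))
  expect_equal(e$ks, 0.103612753861, tolerance = 1e-10)
  expect_equal(e$ka, 0)
})

test_that("site totals decompose as s_sites + n_sites = 3 x codons", {
  set.seed(13)
  for (i in 1:10) {
    s1 <- random_sense_cds(30)
    s2 <- random_sense_cds(30)
    e <- estimate_pairwise_ks(codon_alignment(s1, s2))
    expect_equal(e$s_sites + e$n_sites, 90)
  }
})

test_that("estimates agree with the brute-force NG86 oracle", {
  set.seed(29)
  for (i in 1:40) {
    s1 <- random_sense_cds(20)
    s2 <- random_sense_cds(20)
    mine <- estimate_pairwise_ks(codon_alignment(s1, s2))
    ref <- oracle_ng86(s1, s2)
    expect_equal(mine$s_sites, ref$s_sites, tolerance = 1e-10)
    expect_equal(mine$n_sites, ref$n_sites, tolerance = 1e-10)
    expect_equal(mine$ks, ref$ks, tolerance = 1e-10)
    expect_equal(mine$ka, ref$ka, tolerance = 1e-10)
    expect_identical(mine$saturated, ref$saturated)
  }
})

test_that("ks is symmetric in its arguments", {
  set.seed(31)
  for (i in 1:10) {
    s1 <- random_sense_cds(25)
    s2 <- evolve_codons(s1, 0.3)
    e1 <- estimate_pairwise_ks(codon_alignment(s1, s2))
    e2 <- estimate_pairwise_ks(codon_alignment(s2, s1))
    expect_equal(e1$ks, e2$ks)
    expect_equal(e1$ka, e2$ka)
  }
})

test_that("proportions beyond the correction domain flag saturation", {
  # one-codon alignment GCT vs GCA: sd = 1, S = 1 -> ps = 1 > 0.74
  e <- estimate_pairwise_ks(codon_alignment("GCT", "GCA"))
  expect_true(e$saturated)
  expect_equal(e$ks, 3.0)
})

test_that("alignments without comparable codons are rejected", {
  expect_error(estimate_pairwise_ks(codon_alignment("---", "---")),
               "no comparable codon")
  expect_error(estimate_pairwise_ks(codon_alignment("TAA", "TAA")),
               "no comparable codon")
})

test_that("single-copy orthogroups require exactly one gene per genome", {
  og <- rbind(
    data.frame(og_id = "OG1", genome_id = c("A", "B", "C"),
               gene_id = c("a1", "b1", "c1")),
    data.frame(og_id = "OG2", genome_id = c("A", "A", "B", "C"),
               gene_id = c("a2", "a3", "b2", "c2")),
    data.frame(og_id = "OG3", genome_id = c("A", "B"),
               gene_id = c("a4", "b4")))
  out <- single_copy_orthologs(og, c("A", "B", "C"))
  expect_equal(unique(out$og_id), "OG1")
  out2 <- single_copy_orthologs(og, c("A", "B"))
  expect_setequal(unique(out2$og_id), c("OG1", "OG3"))
})

test_that("single-copy filtering matches the simulator truth table", {
  cfg <- sim_config(seed = 47, n_chromosomes = 2L,
                    genes_per_chromosome = 50L,
                    codon_length_range = c(60L, 100L), wgd_ks = NA,
                    inversion_count = 0L, translocation_count = 0L,
                    tandem_family_count = 0L, expansion_count = 3L)
  sim <- simulate_genomes(cfg)
  fam <- sim$truth$family_map
  gmap <- c(stats::setNames(rep("genomeA",
                                nrow(sim$annotations$genomeA$genes)),
                            sim$annotations$genomeA$genes$gene_id),
            stats::setNames(rep("genomeB",
                                nrow(sim$annotations$genomeB$genes)),
                            sim$annotations$genomeB$genes$gene_id))
  og <- data.frame(og_id = unname(fam), genome_id = unname(gmap[names(fam)]),
                   gene_id = names(fam))
  sco <- single_copy_orthologs(og, c("genomeA", "genomeB"))
  # every 1:1 family is retained; the 3 expanded families are excluded
  expect_equal(length(unique(sco$og_id)), 100L - 3L)
  expect_false(any(sim$truth$arrays$family %in% sco$og_id))
})

test_that("Ks peaks recover planted divergence across the dS range", {
  set.seed(59)
  for (ds in c(0.05, 0.4, 1.2)) {
    ks <- replicate(60, {
      anc <- random_sense_cds(300)
      ev <- evolve_codons(anc, ds)
      estimate_pairwise_ks(codon_alignment(anc, ev))$ks
    })
    mode <- {
      p <- ks_peak(ks[is.finite(ks) & ks < 3])
      p$peaks$location[which.max(p$peaks$density)]
    }
    tol <- if (ds <= 0.5) 0.10 else 0.20
    expect_lt(abs(mode - ds) / ds, tol)
  }
})

test_that("peak detection finds planted modes", {
  set.seed(17)
  # single truncated-normal mode near 0.4
  v <- abs(rnorm(1000, 0.4, 0.05))
  p <- ks_peak(v)
  main <- p$peaks$location[which.max(p$peaks$density)]
  expect_lt(abs(main - 0.4), 0.02)
  # mixture: modes near 0.4 and 1.2
  v2 <- c(rnorm(500, 0.4, 0.05), rnorm(500, 1.2, 0.15))
  p2 <- ks_peak(v2[v2 > 0])
  expect_gte(nrow(p2$peaks), 2L)
  expect_lt(abs(p2$peaks$location[1] - 0.4), 0.05)
  expect_lt(abs(p2$peaks$location[nrow(p2$peaks)] - 1.2), 0.15)
  # all values identical -> single peak at the value
  p3 <- ks_peak(rep(0.25, 30))
  expect_equal(p3$peaks$location, 0.25)
  expect_error(ks_peak(rep(0.3, 10)), "at least 20")
})

test_that("rate arithmetic is exact and validated", {
  expect_identical(rate_per_site_year(0.1585, 57.2e6),
                   0.1585 / (2 * 57.2e6))
  expect_identical(rate_per_site_year(0, 1e6), 0)
  expect_error(rate_per_site_year(0.1, 0), "positive")
  expect_error(rate_per_site_year(-0.1, 1e6), "non-negative")
})

test_that("the WGD window is endpoint-inclusive", {
  kt <- data.frame(gene_a = letters[1:4], gene_b = LETTERS[1:4],
                   ks = c(0.33, 0.38, 0.45, 0.50),
                   saturated = FALSE)
  out <- extract_wgd_paralogs(kt, c(0.33, 0.45))
  expect_equal(out$ks, c(0.33, 0.38, 0.45))
  expect_equal(nrow(extract_wgd_paralogs(kt[0, ], c(0.33, 0.45))), 0L)
  expect_error(extract_wgd_paralogs(kt, c(0.45, 0.33)), "low > high")
})
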