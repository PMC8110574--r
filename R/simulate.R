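# Seeded genome-evolution simulator with planted truth.  Two descendant
# genomes are derived from a common ancestor through an optional shared
# whole-genome duplication (with gene loss), codon-level divergence to
# target dS values, lineage-specific inversions and reciprocal
# translocations, and recent tandem duplications / gene-family
# expansions.  Every event is recorded in truth tables so each pipeline
# stage can be scored against ground truth.

#' Simulation configuration
#'
#' Defaults mirror the genome structure the pipeline is designed around:
#' 11 chromosomes, a shared paleotetraploidy whose retained paralogs sit
#' near dS 0.4, and two genomes diverged to dS 0.1585.  `wgd_ks` is the
#' target *contemporary* paralog divergence: post-WGD copies are diverged
#' to `wgd_ks - speciation_ks` before the split so that, after both
#' lineages accumulate `speciation_ks/2` each, within-genome paralog pairs
#' sit at ~`wgd_ks` and ortholog pairs at ~`speciation_ks`.
#'
#' @param seed Integer RNG seed; identical configs and seeds reproduce
#'   runs exactly.
#' @param n_chromosomes Chromosome count (default 11).
#' @param genes_per_chromosome Ancestral genes per chromosome
#'   (default 182, ~2,000 genes per genome).
#' @param codon_length_range CDS lengths in codons, sampled uniformly
#'   (default 300-1500).
#' @param wgd_ks Target contemporary paralog dS of the shared WGD
#'   (default 0.4); `NA` disables the WGD.
#' @param speciation_ks Target ortholog dS between the two genomes
#'   (default 0.1585).
#' @param loss_fraction Probability a post-WGD duplicate is lost
#'   (default 0.3).
#' @param inversion_count,inversion_size_range Lineage-specific
#'   inversions per genome and their size in genes.
#' @param translocation_count,translocation_size_range Reciprocal
#'   terminal translocations per genome and the swapped segment sizes.
#' @param tandem_family_count,tandem_sizes,tandem_ks Planted tandem
#'   arrays per genome, their total sizes, and the copy-to-source dS.
#' @param expansion_count,expansion_size Species-specific family
#'   expansions planted (as tandem duplications) in genome A, and genes
#'   per expanded family.
#' @param expansion_ks_recent,expansion_ks_old dS of expansion copies;
#'   half the families are planted as recent, half as pre-divergence.
#' @param omega Nonsynonymous/synonymous acceptance ratio of the codon
#'   evolver (default 0.2).
#' @param noise_hit_fraction Spurious random hits added to the hit table
#'   as a fraction of the true pair count (default 0.1).
#' @param heterozygosity True theta for read-profile simulation
#'   (default 0.008).
#' @param coverage Mean read depth (Poisson; default 20).
#' @param error_rate Per-base sequencing error (default 0.01).
#' @param n_sites Sites in the simulated profile table (default 1e5).
#' @param intergenic_bp Fixed intergenic spacer (default 1000 bp).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_chromosomes = 11L,
                       genes_per_chromosome = 182L,
                       codon_length_range = c(300L, 1500L),
                       wgd_ks = 0.4, speciation_ks = 0.1585,
                       loss_fraction = 0.3,
                       inversion_count = 3L,
                       inversion_size_range = c(40L, 120L),
                       translocation_count = 1L,
                       translocation_size_range = c(20L, 60L),
                       tandem_family_count = 40L, tandem_sizes = 2:4,
                       tandem_ks = 0.05,
                       expansion_count = 10L, expansion_size = 5L,
                       expansion_ks_recent = 0.08,
                       expansion_ks_old = 0.21,
                       omega = 0.2, noise_hit_fraction = 0.1,
                       heterozygosity = 0.008, coverage = 20,
                       error_rate = 0.01, n_sites = 1e5,
                       intergenic_bp = 1000L) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_chromosomes > 0, cfg$genes_per_chromosome > 0,
            cfg$loss_fraction >= 0, cfg$loss_fraction <= 1,
            cfg$noise_hit_fraction >= 0, cfg$noise_hit_fraction <= 1,
            cfg$speciation_ks >= 0, cfg$omega >= 0,
            cfg$heterozygosity >= 0, cfg$error_rate >= 0,
            cfg$error_rate < 0.5)
  if (cfg$inversion_count > 0 &&
      cfg$inversion_size_range[2L] > cfg$genes_per_chromosome)
    stop("infeasible config: inversion longer than a chromosome")
  if (cfg$translocation_count > 0 &&
      2L * cfg$translocation_size_range[2L] > cfg$genes_per_chromosome)
    stop("infeasible config: translocation segments exceed chromosome")
  class(cfg) <- "sim_config"
  cfg
}

#' Evolve a coding sequence to a target synonymous divergence
#'
#' Applies random codon-site substitutions until the expected synonymous
#' divergence (in Nei-Gojobori site units) reaches `target_ds` in
#' expectation: the number of synonymous events is Poisson with mean
#' `target_ds * S` (S = synonymous sites of the input) and the number of
#' nonsynonymous events is Poisson with mean `omega * target_ds * N`.
#' Events are drawn proportionally to each codon's synonymous (or
#' nonsynonymous) single-step change count; stop codons are never
#' introduced.
#'
#' @param cds Ungapped CDS string (no internal stops).
#' @param target_ds Target dS (>= 0; 0 returns the sequence unchanged).
#' @param omega dN/dS acceptance ratio (0 yields no nonsynonymous
#'   change).
#' @param seed Optional local seed.
#' @return The evolved CDS string.
#' @export
evolve_codons <- function(cds, target_ds, omega = 0.2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (target_ds < 0) stop("target_ds must be >= 0")
  if (target_ds == 0) return(cds)
  tab <- codon_tables()
  cods <- split_codons(cds)
  if (!all(cods %in% tab$sense)) stop("CDS contains stop/ambiguous codons")
  syn_n <- lengths(tab$syn_alt)
  non_n <- lengths(tab$nonsyn_alt)
  s_sites <- sum(tab$syn_sites[cods])
  n_sites <- 3 * length(cods) - s_sites
  m_s <- stats::rpois(1L, target_ds * s_sites)
  m_n <- stats::rpois(1L, omega * target_ds * n_sites)
  if (m_s + m_n == 0L) return(cds)
  events <- sample(c(rep("s", m_s), rep("n", m_n)))
  w_s <- syn_n[cods]
  w_n <- non_n[cods]
  for (ev in events) {
    w <- if (ev == "s") w_s else w_n
    tot <- sum(w)
    if (tot == 0) next
    i <- sample.int(length(cods), 1L, prob = w)
    alts <- if (ev == "s") tab$syn_alt[[cods[i]]] else tab$nonsyn_alt[[cods[i]]]
    cods[i] <- alts[sample.int(length(alts), 1L)]
    w_s[i] <- syn_n[[cods[i]]]
    w_n[i] <- non_n[[cods[i]]]
  }
  paste(cods, collapse = "")
}

random_cds <- function(n_codons, sense) {
  paste(sample(sense, n_codons, replace = TRUE), collapse = "")
}

# Insert new rows immediately after row `after` of a per-genome gene
# table (ordered within chromosome).
insert_after <- function(df, after, rows) {
  if (after == nrow(df)) return(rbind(df, rows))
  rbind(df[seq_len(after), , drop = FALSE], rows,
        df[(after + 1L):nrow(df), , drop = FALSE])
}

#' Simulate two related genomes with planted truth
#'
#' Pipeline: ancestral gene order with random CDS; optional shared WGD
#' (duplicated gene arm appended to each chromosome, duplicate loss,
#' paralog divergence); speciation into genomes `A` and `B` at the target
#' ortholog dS; per-genome inversions (gene-order reversal with strand
#' flip) and reciprocal terminal translocations; planted tandem arrays in
#' both genomes and species-specific expansions (as tandem duplications,
#' half recent, half pre-divergence) in genome A; coordinate and rank
#' assignment.
#'
#' @param config A [sim_config()].
#' @return List of class `genome_simulation`: `annotations` (named list
#'   of two [genome_annotation()]s), `cds` and `proteins` (named
#'   vectors), `truth` (orthologs, wgd_pairs, arrays, expansions,
#'   inversions, translocations, family_map, theta), and `config`.
#' @export
simulate_genomes <- function(config = sim_config()) {
  set.seed(config$seed)
  tab <- codon_tables()
  nc <- config$n_chromosomes
  gpc <- config$genes_per_chromosome
  wgd_on <- is.finite(config$wgd_ks)
  d0 <- if (wgd_on) max(0, config$wgd_ks - config$speciation_ks) else 0
  sp_half <- config$speciation_ks / 2

  # --- ancestral genome (post-WGD, pre-speciation gene order) ----------
  anc <- list()   # per chromosome: data.frame(base_id, family, strand, codons)
  anc_cds <- list()
  for (ci in seq_len(nc)) {
    ids <- sprintf("c%02dg%04d", ci, seq_len(gpc))
    codons <- sample(seq(config$codon_length_range[1L],
                         config$codon_length_range[2L]), gpc, replace = TRUE)
    strand <- sample(c("+", "-"), gpc, replace = TRUE)
    df <- data.frame(base_id = ids, family = ids, strand = strand,
                     codons = codons, stringsAsFactors = FALSE)
    for (j in seq_len(gpc)) anc_cds[[ids[j]]] <- random_cds(codons[j],
                                                            tab$sense)
    wgd_rows <- NULL
    if (wgd_on) {
      keep <- stats::runif(gpc) >= config$loss_fraction
      if (any(keep)) {
        wid <- paste0(ids[keep], "w")
        wgd_rows <- data.frame(base_id = wid, family = ids[keep],
                               strand = strand[keep],
                               codons = codons[keep],
                               stringsAsFactors = FALSE)
        for (j in which(keep))
          anc_cds[[paste0(ids[j], "w")]] <-
            evolve_codons(anc_cds[[ids[j]]], d0, config$omega)
      }
    }
    anc[[ci]] <- rbind(df, wgd_rows)
  }

  # --- speciation ------------------------------------------------------
  genomes <- list()
  cds <- list()
  wgd_pairs <- list()
  for (g in c("A", "B")) {
    rows <- list()
    for (ci in seq_len(nc)) {
      a <- anc[[ci]]
      gid <- paste0("g", g, "_", a$base_id)
      rows[[ci]] <- data.frame(gene_id = gid,
                               chromosome = sprintf("chr%02d", ci),
                               strand = a$strand, family = a$family,
                               codons = a$codons, stringsAsFactors = FALSE)
      for (j in seq_len(nrow(a)))
        cds[[gid[j]]] <- evolve_codons(anc_cds[[a$base_id[j]]], sp_half,
                                       config$omega)
      if (wgd_on) {
        dup <- grepl("w$", a$base_id)
        if (any(dup))
          wgd_pairs[[paste(g, ci)]] <- data.frame(
            genome = paste0("genome", g),
            gene_1 = paste0("g", g, "_", sub("w$", "", a$base_id[dup])),
            gene_2 = gid[dup], stringsAsFactors = FALSE)
      }
    }
    genomes[[g]] <- rows
  }

  # --- rearrangements --------------------------------------------------
  inversions <- list()
  translocations <- list()
  # inversions in the two lineages are planted on disjoint ancestral gene
  # sets so no planted inversion is cancelled by one in the other genome
  # (overlapping double inversions would make the planted truth undefined)
  inv_used <- character(0)
  for (g in c("A", "B")) {
    for (k in seq_len(config$inversion_count)) {
      for (try in 1:200) {
        ci <- sample.int(nc, 1L)
        df <- genomes[[g]][[ci]]
        size <- sample(seq(config$inversion_size_range[1L],
                           config$inversion_size_range[2L]), 1L)
        size <- min(size, nrow(df))
        s <- sample.int(nrow(df) - size + 1L, 1L)
        idx <- s:(s + size - 1L)
        if (!length(intersect(df$family[idx], inv_used))) break
        if (try == 200L)
          stop("infeasible config: cannot place disjoint inversions")
      }
      inv_used <- c(inv_used, df$family[idx])
      seg <- df[rev(idx), , drop = FALSE]
      seg$strand <- ifelse(seg$strand == "+", "-", "+")
      df[idx, ] <- seg
      genomes[[g]][[ci]] <- df
      inversions[[paste(g, k)]] <- data.frame(
        genome = paste0("genome", g), chromosome = df$chromosome[1L],
        n_genes = size, genes = paste(seg$gene_id, collapse = ","),
        stringsAsFactors = FALSE)
    }
    for (k in seq_len(config$translocation_count)) {
      cij <- sample.int(nc, 2L)
      d1 <- genomes[[g]][[cij[1L]]]
      d2 <- genomes[[g]][[cij[2L]]]
      sz <- sample(seq(config$translocation_size_range[1L],
                       config$translocation_size_range[2L]), 2L,
                   replace = TRUE)
      t1 <- d1[(nrow(d1) - sz[1L] + 1L):nrow(d1), , drop = FALSE]
      t2 <- d2[(nrow(d2) - sz[2L] + 1L):nrow(d2), , drop = FALSE]
      keep1 <- d1[seq_len(nrow(d1) - sz[1L]), , drop = FALSE]
      keep2 <- d2[seq_len(nrow(d2) - sz[2L]), , drop = FALSE]
      t1$chromosome <- d2$chromosome[1L]
      t2$chromosome <- d1$chromosome[1L]
      genomes[[g]][[cij[1L]]] <- rbind(keep1, t2)
      genomes[[g]][[cij[2L]]] <- rbind(keep2, t1)
      translocations[[paste(g, k)]] <- data.frame(
        genome = paste0("genome", g),
        chrom_1 = t2$chromosome[1L], chrom_2 = t1$chromosome[1L],
        genes_1 = paste(t1$gene_id, collapse = ","),
        genes_2 = paste(t2$gene_id, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }

  # --- tandem arrays and expansions ------------------------------------
  arrays <- list()
  used_sources <- character(0)
  plant_array <- function(g, n_copies, ds, kind, suffix) {
    ci <- sample.int(nc, 1L)
    df <- genomes[[g]][[ci]]
    avail <- setdiff(df$gene_id, used_sources)
    src_id <- sample(avail, 1L)
    used_sources <<- c(used_sources, src_id)
    at <- match(src_id, df$gene_id)
    src <- df[at, , drop = FALSE]
    ids <- paste0(src_id, suffix, seq_len(n_copies))
    rows <- src[rep(1L, n_copies), , drop = FALSE]
    rows$gene_id <- ids
    for (id in ids) cds[[id]] <<- evolve_codons(cds[[src_id]], ds,
                                                config$omega)
    genomes[[g]][[ci]] <<- insert_after(df, at, rows)
    arrays[[length(arrays) + 1L]] <<- data.frame(
      genome = paste0("genome", g), chromosome = src$chromosome,
      family = src$family, kind = kind,
      genes = paste(c(src_id, ids), collapse = ","),
      n_genes = n_copies + 1L, stringsAsFactors = FALSE)
  }
  for (g in c("A", "B"))
    for (k in seq_len(config$tandem_family_count))
      plant_array(g, sample(config$tandem_sizes, 1L) - 1L,
                  config$tandem_ks, "tandem", "_t")
  if (config$expansion_count > 0L) {
    n_old <- floor(config$expansion_count / 2)
    for (k in seq_len(config$expansion_count)) {
      ds <- if (k <= n_old) config$expansion_ks_old
            else config$expansion_ks_recent
      plant_array("A", config$expansion_size - 1L, ds,
                  if (k <= n_old) "expansion_old" else "expansion_recent",
                  "_x")
    }
  }
  arrays <- do.call(rbind, arrays)

  # --- coordinates, annotations, truth ---------------------------------
  annotations <- list()
  for (g in c("A", "B")) {
    all_rows <- do.call(rbind, genomes[[g]])
    pieces <- split(all_rows, all_rows$chromosome)
    lens <- c()
    out <- list()
    for (ch in names(pieces)) {
      df <- pieces[[ch]]
      glen <- 3L * df$codons
      start <- config$intergenic_bp +
        cumsum(c(0L, glen[-length(glen)] + config$intergenic_bp))
      df$start <- start
      df$end <- start + glen
      lens[ch] <- df$end[length(glen)] + config$intergenic_bp
      out[[ch]] <- df
    }
    all_rows <- do.call(rbind, out)
    annotations[[paste0("genome", g)]] <- genome_annotation(
      paste0("genome", g),
      all_rows[, c("gene_id", "chromosome", "start", "end", "strand")],
      chromosome_lengths = lens, ploidy = 1L)
  }

  base_ids <- unlist(lapply(anc, function(a) a$base_id), use.names = FALSE)
  orthologs <- data.frame(gene_a = paste0("gA_", base_ids),
                          gene_b = paste0("gB_", base_ids),
                          ds = config$speciation_ks,
                          stringsAsFactors = FALSE)
  all_genes <- c(annotations$genomeA$genes$gene_id,
                 annotations$genomeB$genes$gene_id)
  fam_lookup <- do.call(rbind, lapply(c("A", "B"), function(g)
    do.call(rbind, genomes[[g]])))
  family_map <- stats::setNames(fam_lookup$family, fam_lookup$gene_id)
  cds <- unlist(cds)
  proteins <- vapply(cds, translate_cds, character(1L))
  truth <- list(
    orthologs = orthologs,
    wgd_pairs = if (length(wgd_pairs)) do.call(rbind, wgd_pairs)
                else NULL,
    arrays = arrays,
    inversions = if (length(inversions)) do.call(rbind, inversions)
                 else NULL,
    translocations = if (length(translocations))
                       do.call(rbind, translocations) else NULL,
    family_map = family_map[all_genes],
    theta = config$heterozygosity)
  if (!is.null(truth$wgd_pairs)) rownames(truth$wgd_pairs) <- NULL
  if (!is.null(truth$inversions)) rownames(truth$inversions) <- NULL
  structure(list(annotations = annotations, cds = cds,
                 proteins = proteins, truth = truth, config = config),
            class = "genome_simulation")
}

#' @export
print.genome_simulation <- function(x, ...) {
  cat(sprintf(
    "<genome_simulation> seed %d: %d + %d genes, %d true ortholog pairs\n",
    x$config$seed, nrow(x$annotations$genomeA$genes),
    nrow(x$annotations$genomeB$genes), nrow(x$truth$orthologs)))
  invisible(x)
}

# True synteny blocks: maximal runs of ortholog anchors monotone in both
# rank coordinates with bounded rank gaps, derived from the planted
# ortholog pairs and the final gene orders.
truth_blocks <- function(sim, max_gap = 25L, min_len = 2L) {
  ga <- sim$annotations$genomeA$genes
  gb <- sim$annotations$genomeB$genes
  ca <- stats::setNames(ga$chromosome, ga$gene_id)
  ra <- stats::setNames(ga$rank, ga$gene_id)
  cb <- stats::setNames(gb$chromosome, gb$gene_id)
  rb <- stats::setNames(gb$rank, gb$gene_id)
  o <- sim$truth$orthologs
  d <- data.frame(gene_a = o$gene_a, gene_b = o$gene_b,
                  chrom_a = unname(ca[o$gene_a]),
                  rank_a = unname(ra[o$gene_a]),
                  chrom_b = unname(cb[o$gene_b]),
                  rank_b = unname(rb[o$gene_b]), stringsAsFactors = FALSE)
  d <- d[order(d$chrom_a, d$chrom_b, d$rank_a), , drop = FALSE]
  key <- paste(d$chrom_a, d$chrom_b)
  out <- list()
  for (k in unique(key)) {
    s <- d[key == k, , drop = FALSE]
    if (nrow(s) < min_len) next
    step <- diff(s$rank_b)
    dir <- sign(step)
    brk <- c(TRUE, abs(step) - 1L > max_gap)
    if (length(dir) > 1L)
      brk[which(dir[-1L] != dir[-length(dir)]) + 1L] <- TRUE
    run <- cumsum(brk)
    for (r in unique(run)) {
      seg <- s[run == r, , drop = FALSE]
      if (nrow(seg) >= min_len)
        out[[length(out) + 1L]] <- cbind(seg,
                                         truth_block = length(out) + 1L)
    }
  }
  do.call(rbind, out)
}

#' Simulate an all-vs-all homology hit table
#'
#' Emits one 12-column hit per true homolog pair (orthologs, WGD paralog
#' pairs within and across the genomes, tandem/expansion copies and their
#' cross-genome counterparts) with bit scores given by a deterministic,
#' monotone-decreasing map from the pair's planted divergence
#' (`2 * min_codons * exp(-1.1 ds)`), plus `noise_hit_fraction` random
#' low-scoring pairs (bit scores uniform in 40-80).
#'
#' @param sim A [simulate_genomes()] result.
#' @param noise_hit_fraction Overrides the config value when not `NULL`.
#' @param directions 1 (default) emits one row per unordered pair; 2
#'   emits both query/target orientations as an all-vs-all search would.
#' @param include_self Also emit maximal-score self hits (default FALSE).
#' @return Hit `data.frame` in the [read_hit_table()] layout, with an
#'   extra `true_ds` column (`NA` for noise hits).
#' @export
simulate_hit_table <- function(sim, noise_hit_fraction = NULL,
                               directions = 1L, include_self = FALSE) {
  cfg <- sim$config
  if (is.null(noise_hit_fraction)) noise_hit_fraction <- cfg$noise_hit_fraction
  nlen <- stats::setNames(nchar(sim$cds) / 3, names(sim$cds))
  pair_rows <- list()
  add_pairs <- function(a, b, ds) {
    if (!length(a)) return(invisible())
    pair_rows[[length(pair_rows) + 1L]] <<-
      data.frame(query_gene = a, target_gene = b, true_ds = ds,
                 stringsAsFactors = FALSE)
  }
  ortho <- sim$truth$orthologs
  add_pairs(ortho$gene_a, ortho$gene_b, cfg$speciation_ks)
  wp <- sim$truth$wgd_pairs
  if (!is.null(wp)) {
    add_pairs(wp$gene_1, wp$gene_2, cfg$wgd_ks)
    # cross-genome WGD pairs: gene in one genome vs duplicate's ortholog
    omap <- stats::setNames(ortho$gene_b, ortho$gene_a)
    wa <- wp[wp$genome == "genomeA", , drop = FALSE]
    add_pairs(wa$gene_1, unname(omap[wa$gene_2]), cfg$wgd_ks)
    add_pairs(wa$gene_2, unname(omap[wa$gene_1]), cfg$wgd_ks)
  }
  arr <- sim$truth$arrays
  if (!is.null(arr) && nrow(arr)) {
    omap <- stats::setNames(c(ortho$gene_b, ortho$gene_a),
                            c(ortho$gene_a, ortho$gene_b))
    for (i in seq_len(nrow(arr))) {
      genes <- strsplit(arr$genes[i], ",", fixed = TRUE)[[1L]]
      src <- genes[1L]; copies <- genes[-1L]
      ds <- switch(arr$kind[i], tandem = cfg$tandem_ks,
                   expansion_recent = cfg$expansion_ks_recent,
                   expansion_old = cfg$expansion_ks_old)
      add_pairs(rep(src, length(copies)), copies, ds)
      if (length(copies) > 1L) {
        cmb <- utils::combn(copies, 2L)
        add_pairs(cmb[1L, ], cmb[2L, ], 2 * ds)
      }
      cross <- omap[src]
      if (!is.na(cross))
        add_pairs(copies, rep(unname(cross), length(copies)),
                  ds + cfg$speciation_ks)
    }
  }
  pairs <- do.call(rbind, pair_rows)
  n_true <- nrow(pairs)
  n_noise <- round(noise_hit_fraction * n_true)
  if (n_noise > 0L) {
    all_genes <- names(sim$cds)
    q <- sample(all_genes, n_noise, replace = TRUE)
    t <- sample(all_genes, n_noise, replace = TRUE)
    while (any(bad <- q == t))       # redraw accidental self-pairs
      t[bad] <- sample(all_genes, sum(bad), replace = TRUE)
    pairs <- rbind(pairs, data.frame(query_gene = q, target_gene = t,
                                     true_ds = NA_real_,
                                     stringsAsFactors = FALSE))
  }
  len <- pmin(nlen[pairs$query_gene], nlen[pairs$target_gene])
  is_noise <- is.na(pairs$true_ds)
  bit <- round(2 * len * exp(-1.1 * pairs$true_ds), 1)
  bit[is_noise] <- round(stats::runif(sum(is_noise), 40, 80), 1)
  pid <- round(100 * exp(-0.75 * ifelse(is_noise, 1.5, pairs$true_ds)), 1)
  h <- data.frame(query_gene = pairs$query_gene,
                  target_gene = pairs$target_gene,
                  percent_identity = pid, length = unname(3 * len),
                  mismatches = 0, gapopen = 0, qstart = 1,
                  qend = unname(3 * len), tstart = 1, tend = unname(3 * len),
                  evalue = 0, bit_score = unname(bit),
                  true_ds = pairs$true_ds, stringsAsFactors = FALSE)
  if (directions >= 2L) {
    rev <- h
    rev$query_gene <- h$target_gene
    rev$target_gene <- h$query_gene
    h <- rbind(h, rev)
  }
  if (include_self) {
    sg <- names(sim$cds)
    h <- rbind(h, data.frame(query_gene = sg, target_gene = sg,
                             percent_identity = 100,
                             length = unname(3 * nlen[sg]), mismatches = 0,
                             gapopen = 0, qstart = 1,
                             qend = unname(3 * nlen[sg]), tstart = 1,
                             tend = unname(3 * nlen[sg]), evalue = 0,
                             bit_score = unname(round(2.3 * nlen[sg], 1)),
                             true_ds = 0, stringsAsFactors = FALSE))
  }
  h$self_hit <- h$query_gene == h$target_gene
  rownames(h) <- NULL
  h
}

#' Simulate diploid read-count profiles
#'
#' Each site is heterozygous with probability `theta/(1+theta)`; read
#' depth is Poisson(`coverage`); reads draw an allele uniformly (het
#' sites) and err to a uniform alternative base with probability
#' `error_rate` — exactly the generative model assumed by
#' [estimate_theta_ml()].
#'
#' @param n_sites Number of sites.
#' @param theta True population mutation rate per site.
#' @param coverage Mean depth.
#' @param error_rate Per-base error probability.
#' @param seed Optional local seed.
#' @param chromosome Chromosome label for the emitted table.
#' @return List: `profiles` (`chromosome`, `position`, `nA`, `nC`, `nG`,
#'   `nT`), `theta`, `is_het` (true site classes).
#' @export
simulate_profiles <- function(n_sites, theta = 0.008, coverage = 20,
                              error_rate = 0.01, seed = NULL,
                              chromosome = "sim1") {
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n_sites)
  het <- stats::runif(n) < theta / (1 + theta)
  depth <- stats::rpois(n, coverage)
  counts <- matrix(0L, n, 4L)
  base_idx <- sample.int(4L, n, replace = TRUE)          # true/major base
  others <- rbind(c(2L, 3L, 4L), c(1L, 3L, 4L), c(1L, 2L, 4L),
                  c(1L, 2L, 3L))
  # homozygous sites: errors spread uniformly over the three other bases
  hom <- which(!het)
  if (length(hom)) {
    e <- stats::rbinom(length(hom), depth[hom], error_rate)
    e1 <- stats::rbinom(length(hom), e, 1 / 3)
    e2 <- stats::rbinom(length(hom), e - e1, 1 / 2)
    e3 <- e - e1 - e2
    counts[cbind(hom, base_idx[hom])] <- depth[hom] - e
    counts[cbind(hom, others[base_idx[hom], 1L])] <- e1
    counts[cbind(hom, others[base_idx[hom], 2L])] <- e2
    counts[cbind(hom, others[base_idx[hom], 3L])] <- e3
  }
  # heterozygous sites: two alleles, reads split with error leakage
  hz <- which(het)
  if (length(hz)) {
    alt_pick <- sample.int(3L, length(hz), replace = TRUE)
    a1 <- base_idx[hz]
    a2 <- others[cbind(a1, alt_pick)]
    rest <- t(vapply(seq_along(hz),
                     function(i) setdiff(1:4, c(a1[i], a2[i])),
                     integer(2L)))
    pa <- (1 - error_rate) / 2 + error_rate / 6
    x1 <- stats::rbinom(length(hz), depth[hz], pa)
    x2 <- stats::rbinom(length(hz), depth[hz] - x1, pa / (1 - pa))
    rem <- depth[hz] - x1 - x2
    r1 <- stats::rbinom(length(hz), rem, 1 / 2)
    counts[cbind(hz, a1)] <- x1
    counts[cbind(hz, a2)] <- x2
    counts[cbind(hz, rest[, 1L])] <- r1
    counts[cbind(hz, rest[, 2L])] <- rem - r1
  }
  profiles <- data.frame(chromosome = chromosome, position = seq_len(n) - 1L,
                         nA = counts[, 1L], nC = counts[, 2L],
                         nG = counts[, 3L], nT = counts[, 4L],
                         stringsAsFactors = FALSE)
  list(profiles = profiles, theta = theta, is_het = het)
}

#' Write a simulation to disk in standard formats
#'
#' Emits per genome a GFF3 annotation and CDS/protein FASTA, plus the
#' 12-column hit table, a profile TSV and a JSON truth summary.
#'
#' @param sim A [simulate_genomes()] result.
#' @param dir Output directory (created if needed).
#' @param hits Optional precomputed hit table (else simulated with
#'   defaults).
#' @return Invisibly, the named vector of written paths.
#' @export
write_simulation <- function(sim, dir, hits = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  for (gid in names(sim$annotations)) {
    ann <- sim$annotations[[gid]]
    p <- file.path(dir, paste0(gid, ".gff3"))
    write_annotation(ann, p)
    paths[paste0(gid, "_gff3")] <- p
    genes <- ann$genes$gene_id
    cset <- Biostrings::DNAStringSet(sim$cds[genes])
    p <- file.path(dir, paste0(gid, "_cds.fa"))
    Biostrings::writeXStringSet(cset, p)
    paths[paste0(gid, "_cds")] <- p
    pset <- Biostrings::AAStringSet(sim$proteins[genes])
    p <- file.path(dir, paste0(gid, "_prot.fa"))
    Biostrings::writeXStringSet(pset, p)
    paths[paste0(gid, "_prot")] <- p
  }
  if (is.null(hits)) hits <- simulate_hit_table(sim)
  p <- file.path(dir, "hits.tsv")
  write_hit_table(hits, p)
  paths["hits"] <- p
  prof <- simulate_profiles(sim$config$n_sites, sim$config$heterozygosity,
                            sim$config$coverage, sim$config$error_rate)
  p <- file.path(dir, "profiles.tsv")
  utils::write.table(prof$profiles, p, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths["profiles"] <- p
  p <- file.path(dir, "truth.json")
  jsonlite::write_json(
    list(n_orthologs = nrow(sim$truth$orthologs),
         n_wgd_pairs = if (is.null(sim$truth$wgd_pairs)) 0L
                       else nrow(sim$truth$wgd_pairs),
         n_arrays = if (is.null(sim$truth$arrays)) 0L
                    else nrow(sim$truth$arrays),
         theta = sim$truth$theta, seed = sim$config$seed),
    p, auto_unbox = TRUE, pretty = TRUE)
  paths["truth"] <- p
  invisible(paths)
}
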