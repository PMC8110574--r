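# Independent oracles and tiny fixture builders shared across the suite.
# The oracles are deliberately written as plain nested loops against
# Biostrings::GENETIC_CODE, structurally independent of the package's
# lookup-table implementations.

GC_ORACLE <- Biostrings::GENETIC_CODE
SENSE_CODONS <- names(GC_ORACLE)[GC_ORACLE != "*"]

# ---- brute-force NG86 + Jukes-Cantor oracle ---------------------------

# all orderings of up to three positions, hard-coded
.perm_table <- list(
  `1` = list(1L),
  `2` = list(c(1L, 2L), c(2L, 1L)),
  `3` = list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
             c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))

oracle_codon_sites <- function(codon) {
  nt <- c("A", "C", "G", "T")
  s <- 0
  for (pos in 1:3) {
    for (b in nt) {
      if (substr(codon, pos, pos) == b) next
      mut <- codon
      substr(mut, pos, pos) <- b
      if (GC_ORACLE[[mut]] == "*") next
      if (GC_ORACLE[[mut]] == GC_ORACLE[[codon]]) s <- s + 1 / 3
    }
  }
  s
}

oracle_codon_diffs <- function(c1, c2) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (!length(pos)) return(c(0, 0))
  walk <- function(order, allow_stop) {
    cur <- c1
    sd <- 0; nd <- 0
    for (p in order) {
      mut <- cur
      substr(mut, p, p) <- substr(c2, p, p)
      if (GC_ORACLE[[mut]] == "*" && !allow_stop) return(NULL)
      if (GC_ORACLE[[mut]] == GC_ORACLE[[cur]]) sd <- sd + 1 else nd <- nd + 1
      cur <- mut
    }
    c(sd, nd)
  }
  orders <- lapply(.perm_table[[as.character(length(pos))]],
                   function(o) pos[o])
  res <- list()
  for (o in orders) {
    r <- walk(o, FALSE)
    if (!is.null(r)) res[[length(res) + 1]] <- r
  }
  if (!length(res)) for (o in orders) res[[length(res) + 1]] <- walk(o, TRUE)
  m <- do.call(rbind, res)
  colMeans(m)
}

oracle_ng86 <- function(seq_a, seq_b) {
  ca <- substring(seq_a, seq(1, nchar(seq_a), 3), seq(3, nchar(seq_a), 3))
  cb <- substring(seq_b, seq(1, nchar(seq_b), 3), seq(3, nchar(seq_b), 3))
  keep <- ca %in% SENSE_CODONS & cb %in% SENSE_CODONS
  ca <- ca[keep]; cb <- cb[keep]
  s_sites <- 0; sd <- 0; nd <- 0
  for (i in seq_along(ca)) {
    s_sites <- s_sites + (oracle_codon_sites(ca[i]) +
                            oracle_codon_sites(cb[i])) / 2
    d <- oracle_codon_diffs(ca[i], cb[i])
    sd <- sd + d[1]; nd <- nd + d[2]
  }
  n_sites <- 3 * length(ca) - s_sites
  ps <- sd / s_sites; pn <- nd / n_sites
  saturated <- FALSE
  if (ps > 0.74) { ks <- 3.0; saturated <- TRUE }
  else ks <- -0.75 * log(1 - 4 * ps / 3)
  if (pn > 0.74) { ka <- 3.0; saturated <- TRUE }
  else ka <- -0.75 * log(1 - 4 * pn / 3)
  list(ks = ks, ka = ka, s_sites = s_sites, n_sites = n_sites,
       saturated = saturated)
}

# ---- direct quadratic DBSCAN oracle -----------------------------------

oracle_dbscan <- function(x, y, eps, min_pts, metric = "chebyshev") {
  n <- length(x)
  neighbours <- function(i) {
    out <- integer(0)
    for (j in 1:n) {
      d <- if (metric == "chebyshev") max(abs(x[i] - x[j]), abs(y[i] - y[j]))
           else sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2)
      if (d <= eps) out <- c(out, j)
    }
    out
  }
  nb <- lapply(1:n, neighbours)
  is_core <- sapply(nb, length) >= min_pts
  label <- rep(0L, n)
  cluster <- 0L
  for (i in 1:n) {
    if (label[i] != 0L || !is_core[i]) next
    cluster <- cluster + 1L
    frontier <- i
    label[i] <- cluster
    while (length(frontier)) {
      nxt <- integer(0)
      for (p in frontier) {
        if (!is_core[p]) next
        for (j in nb[[p]]) {
          if (label[j] == 0L) {
            label[j] <- cluster
            nxt <- c(nxt, j)
          }
        }
      }
      frontier <- nxt
    }
  }
  label
}

# ---- exact attained size of the hypergeometric test -------------------

oracle_attained_size <- function(pathway_size, universe_size, set_size,
                                 alpha = 0.05) {
  for (k in 0:min(pathway_size, set_size)) {
    p <- stats::phyper(k - 1, pathway_size, universe_size - pathway_size,
                       set_size, lower.tail = FALSE)
    if (p < alpha) return(p)   # = P(X >= k), the attained size
  }
  0
}

# ---- fixture builders -------------------------------------------------

make_ann <- function(genome_id, chrom_sizes, ploidy = 1L, prefix = NULL) {
  if (is.null(prefix)) prefix <- genome_id
  genes <- do.call(rbind, lapply(seq_along(chrom_sizes), function(ci) {
    n <- chrom_sizes[ci]
    data.frame(gene_id = sprintf("%s_c%d_%03d", prefix, ci, seq_len(n)),
               chromosome = paste0("chr", ci),
               start = (seq_len(n) - 1) * 1000,
               end = (seq_len(n) - 1) * 1000 + 500,
               strand = "+", stringsAsFactors = FALSE)
  }))
  genome_annotation(genome_id, genes, ploidy = ploidy)
}

make_hits <- function(query, target, bit, pid = 90) {
  if (!length(query))
    return(syntevol:::empty_hits())
  data.frame(query_gene = query, target_gene = target,
             percent_identity = pid, length = 300, mismatches = 0,
             gapopen = 0, qstart = 1, qend = 300, tstart = 1, tend = 300,
             evalue = 0, bit_score = bit, self_hit = query == target,
             stringsAsFactors = FALSE)
}

make_anchors <- function(rank_a, rank_b, chrom_a = "chr1", chrom_b = "chr1",
                         bit = 500) {
  data.frame(gene_a = sprintf("a%04d", rank_a),
             gene_b = sprintf("b%04d", rank_b),
             chrom_a = chrom_a, chrom_b = chrom_b,
             rank_a = as.integer(rank_a), rank_b = as.integer(rank_b),
             bit_score = bit, stringsAsFactors = FALSE)
}

random_sense_cds <- function(n_codons) {
  paste(sample(SENSE_CODONS, n_codons, replace = TRUE), collapse = "")
}

og_table <- function(...) {
  # og_table(og1 = c(A = 3, B = 2), ...) -> orthogroup data.frame
  specs <- list(...)
  do.call(rbind, lapply(names(specs), function(og) {
    counts <- specs[[og]]
    do.call(rbind, lapply(names(counts), function(g) {
      if (counts[[g]] == 0) return(NULL)
      data.frame(og_id = og, genome_id = g,
                 gene_id = sprintf("%s_%s_%d", og, g, seq_len(counts[[g]])),
                 stringsAsFactors = FALSE)
    }))
  }))
}
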