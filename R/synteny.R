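# Synteny-constrained orthology: hit culling, pairwise orthogroup
# clustering, collinear block chaining in gene-rank space, DBSCAN density
# pruning, orthogroup completion, orthogroup-agnostic block extension,
# syntenic homolog classification and chromosome-level summaries.

#' Parameters of the synteny pipeline
#'
#' All radii and gaps are expressed in gene ranks (ordinal gene positions
#' along a chromosome), not base pairs.
#'
#' @param mbs Minimum block size: smallest number of anchor pairs a block
#'   may contain (default 10).
#' @param gap_allowance_factor The maximum rank gap between consecutive
#'   anchors in a chain is `gap_allowance_factor * 0.5 * mbs` intervening
#'   ranks (default 5, i.e. 25 at `mbs = 10`), applied independently on both
#'   chromosomes.
#' @param dbscan_radius_factor DBSCAN pruning radius is
#'   `dbscan_radius_factor * mbs` ranks (default 5).
#' @param dbscan_min_pts DBSCAN core-point threshold, counting the point
#'   itself; defaults to `mbs`.
#' @param extension_radius Rank radius around existing blocks within which
#'   orthogroup-agnostic score-passing hits are pulled back in when blocks
#'   are re-formed (default 100).
#' @param orthology_cull_radius Rank radius around blocks used to cull hits
#'   before syntenic homolog classification (default 50).
#' @param min_bit_score Hits below this bit score are dropped (default 50).
#' @param top_hits_per_haplotype Hits kept per query gene and target
#'   haplotype (default 2; a diploid target therefore retains up to 4 hits
#'   per query).
#' @param best_score_fraction Unclustered hits (and orthogroup-graph edges)
#'   below this fraction of a gene's best bit score for the same
#'   gene-by-genome combination are dropped (default 0.5).
#' @param tandem_exclusion_radius In intra-genome (paralog) mode, hits
#'   between genes closer than this many ranks are excluded before chaining
#'   so tandem arrays do not masquerade as duplicated segments (default 5).
#' @param gap_rule `"per_step"` (default): the gap allowance bounds each
#'   inter-anchor step; `"per_block"`: it bounds the total number of gapped
#'   ranks in a chain.
#' @param dbscan_metric `"chebyshev"` (default, matching the rank-gap
#'   semantics) or `"euclidean"`.
#' @return A list of class `synteny_params`.
#' @export
synteny_params <- function(mbs = 10L, gap_allowance_factor = 5,
                           dbscan_radius_factor = 5, dbscan_min_pts = NULL,
                           extension_radius = 100L,
                           orthology_cull_radius = 50L,
                           min_bit_score = 50, top_hits_per_haplotype = 2L,
                           best_score_fraction = 0.5,
                           tandem_exclusion_radius = 5L,
                           gap_rule = c("per_step", "per_block"),
                           dbscan_metric = c("chebyshev", "euclidean")) {
  gap_rule <- match.arg(gap_rule)
  dbscan_metric <- match.arg(dbscan_metric)
  if (is.null(dbscan_min_pts)) dbscan_min_pts <- mbs
  p <- list(mbs = as.integer(mbs),
            gap_allowance_factor = gap_allowance_factor,
            max_gap = gap_allowance_factor * 0.5 * mbs,
            dbscan_eps = dbscan_radius_factor * mbs,
            dbscan_min_pts = as.integer(dbscan_min_pts),
            extension_radius = as.integer(extension_radius),
            orthology_cull_radius = as.integer(orthology_cull_radius),
            min_bit_score = min_bit_score,
            top_hits_per_haplotype = as.integer(top_hits_per_haplotype),
            best_score_fraction = best_score_fraction,
            tandem_exclusion_radius = as.integer(tandem_exclusion_radius),
            gap_rule = gap_rule, dbscan_metric = dbscan_metric)
  stopifnot(p$mbs > 0, p$max_gap > 0, p$dbscan_eps > 0, p$dbscan_min_pts > 0,
            p$best_score_fraction > 0, p$best_score_fraction <= 1)
  class(p) <- "synteny_params"
  p
}

# gene_id -> genome_id / chromosome / rank lookup across a list of
# annotations (names are ignored; genome ids come from the objects).
gene_lookup <- function(annotations) {
  tabs <- lapply(annotations, function(a)
    data.frame(gene_id = a$genes$gene_id, genome_id = a$genome_id,
               chromosome = a$genes$chromosome, rank = a$genes$rank,
               ploidy = a$ploidy, stringsAsFactors = FALSE))
  do.call(rbind, tabs)
}

#' Cull homology hits per haplotype and score
#'
#' Removes self-hits, drops hits with bit score below
#' `params$min_bit_score` (strictly-less dropped), and keeps per query gene
#' and target genome only the `top_hits_per_haplotype * ploidy(target)`
#' highest-scoring hits, so a diploid-to-diploid comparison retains at most
#' four hits per query gene.
#'
#' @param hits Hit `data.frame` (see [read_hit_table()]).
#' @param annotations List of [genome_annotation()] objects covering every
#'   gene appearing in `hits`.
#' @param params A [synteny_params()] object.
#' @return The surviving subset of `hits` (culling is idempotent).
#' @export
cull_hits <- function(hits, annotations, params = synteny_params()) {
  lk <- gene_lookup(annotations)
  unknown <- setdiff(unique(c(hits$query_gene, hits$target_gene)), lk$gene_id)
  if (length(unknown))
    stop("hit references unknown gene: ", unknown[1L])
  h <- hits[!(hits$query_gene == hits$target_gene), , drop = FALSE]
  h <- h[h$bit_score >= params$min_bit_score, , drop = FALSE]
  if (!nrow(h)) return(h)
  gmap <- stats::setNames(lk$genome_id, lk$gene_id)
  pl <- stats::setNames(lk$ploidy, lk$gene_id)
  dt <- data.table::as.data.table(h)
  dt[, target_genome := gmap[target_gene]]
  dt[, cap := params$top_hits_per_haplotype * pl[target_gene]]
  data.table::setorder(dt, query_gene, target_genome, -bit_score, target_gene)
  dt[, keep := seq_len(.N) <= cap[1L], by = .(query_gene, target_genome)]
  out <- dt[keep == TRUE]
  out[, c("target_genome", "cap", "keep") := NULL]
  data.table::setDF(out)
  out
}

#' Cluster culled hits of a genome pair into orthogroups
#'
#' Edges below `best_score_fraction` of either endpoint gene's best
#' inter-genome bit score are removed, then connected components of the
#' remaining hit graph become orthogroups.  Hits whose endpoints fall in
#' different orthogroups are thereby discarded downstream.
#'
#' @param culled_hits Output of [cull_hits()] restricted to two genomes.
#' @param ann_a,ann_b The two [genome_annotation()] objects.
#' @param params A [synteny_params()].
#' @return `data.frame` with columns `og_id`, `genome_id`, `gene_id`; every
#'   gene belongs to at most one orthogroup and each group has >= 2 genes.
#' @export
infer_pairwise_orthogroups <- function(culled_hits, ann_a, ann_b,
                                       params = synteny_params()) {
  lk <- gene_lookup(list(ann_a, ann_b))
  gmap <- stats::setNames(lk$genome_id, lk$gene_id)
  h <- culled_hits
  h <- h[gmap[h$query_gene] != gmap[h$target_gene], , drop = FALSE]
  if (!nrow(h)) return(empty_orthogroups())
  # per-gene best inter-genome score over both hit directions
  best <- tapply(c(h$bit_score, h$bit_score),
                 c(h$query_gene, h$target_gene), max)
  keep <- h$bit_score >= params$best_score_fraction *
    pmax(best[h$query_gene], best[h$target_gene])
  h <- h[keep, , drop = FALSE]
  if (!nrow(h)) return(empty_orthogroups())
  components_to_orthogroups(h$query_gene, h$target_gene, gmap)
}

empty_orthogroups <- function() {
  data.frame(og_id = character(), genome_id = character(),
             gene_id = character(), stringsAsFactors = FALSE)
}

# Connected components -> orthogroup table with deterministic ids (groups
# ordered by their lexicographically smallest member).
components_to_orthogroups <- function(from, to, gmap) {
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to, stringsAsFactors = FALSE),
    directed = FALSE)
  cmp <- igraph::components(g)
  genes <- names(cmp$membership)
  key <- stats::ave(genes, cmp$membership, FUN = min)
  ord <- sort(unique(key))
  og_id <- sprintf("OG%06d", match(key, ord))
  out <- data.frame(og_id = og_id, genome_id = unname(gmap[genes]),
                    gene_id = genes, stringsAsFactors = FALSE)
  out[order(out$og_id, out$genome_id, out$gene_id), , drop = FALSE]
}

#' Merge pairwise orthogroups into multi-genome orthogroups
#'
#' Transitive closure over shared genes: orthogroups from different
#' pairwise runs that share any gene are merged.  The operation is a
#' closure (applying it twice equals applying it once) and yields a
#' partition of the clustered genes.
#'
#' @param og_list A single orthogroup `data.frame` or a list of them, one
#'   per pairwise genome comparison.
#' @return A merged orthogroup `data.frame` (`og_id`, `genome_id`,
#'   `gene_id`).
#' @export
complete_orthogroups <- function(og_list) {
  if (is.data.frame(og_list)) og_list <- list(og_list)
  og <- do.call(rbind, lapply(seq_along(og_list), function(i) {
    x <- og_list[[i]]
    x$og_id <- paste0("run", i, ":", x$og_id)
    x
  }))
  if (!nrow(og)) return(empty_orthogroups())
  gmap <- stats::setNames(og$genome_id, og$gene_id)
  components_to_orthogroups(og$gene_id, og$og_id, gmap)[
    , c("og_id", "genome_id", "gene_id")] -> merged
  # og-label vertices entered the graph as pseudo-genes; drop them
  merged <- merged[!grepl("^run[0-9]+:", merged$gene_id), , drop = FALSE]
  # re-normalise ids after dropping label vertices
  key <- stats::ave(merged$gene_id, merged$og_id, FUN = min)
  ord <- sort(unique(key))
  merged$og_id <- sprintf("OG%06d", match(key, ord))
  merged <- merged[order(merged$og_id, merged$genome_id, merged$gene_id), ,
                   drop = FALSE]
  rownames(merged) <- NULL
  merged
}

#' Build anchor pairs from orthogroup-constrained hits
#'
#' Keeps inter-genome hits whose two genes share an orthogroup, attaches
#' chromosome and rank coordinates from the two annotations, and collapses
#' the two hit directions onto one anchor per unordered gene pair (highest
#' bit score wins).
#'
#' @param hits Culled hits.
#' @param orthogroups Orthogroup table (`og_id`, `genome_id`, `gene_id`).
#' @param ann_a,ann_b Annotations of the two genomes; `ann_a` supplies the
#'   `*_a` coordinates.
#' @return Anchor `data.frame`: `gene_a`, `gene_b`, `chrom_a`, `chrom_b`,
#'   `rank_a`, `rank_b`, `bit_score`.
#' @export
anchors_from_hits <- function(hits, orthogroups, ann_a, ann_b) {
  ogm <- stats::setNames(orthogroups$og_id, orthogroups$gene_id)
  ga <- ann_a$genes; gb <- ann_b$genes
  in_a <- stats::setNames(rep(TRUE, nrow(ga)), ga$gene_id)
  h <- hits
  qa <- !is.na(in_a[h$query_gene])  # query in genome A?
  gene_a <- ifelse(qa, h$query_gene, h$target_gene)
  gene_b <- ifelse(qa, h$target_gene, h$query_gene)
  ok <- !is.na(in_a[gene_a]) & is.na(in_a[gene_b])
  same_og <- !is.na(ogm[gene_a]) & !is.na(ogm[gene_b]) &
    ogm[gene_a] == ogm[gene_b]
  keep <- ok & same_og
  an <- data.frame(gene_a = gene_a[keep], gene_b = gene_b[keep],
                   bit_score = h$bit_score[keep], stringsAsFactors = FALSE)
  if (!nrow(an)) return(empty_anchors())
  an <- an[order(an$gene_a, an$gene_b, -an$bit_score), , drop = FALSE]
  an <- an[!duplicated(an[, c("gene_a", "gene_b")]), , drop = FALSE]
  ca <- stats::setNames(ga$chromosome, ga$gene_id)
  ra <- stats::setNames(ga$rank, ga$gene_id)
  cb <- stats::setNames(gb$chromosome, gb$gene_id)
  rb <- stats::setNames(gb$rank, gb$gene_id)
  an$chrom_a <- unname(ca[an$gene_a]); an$rank_a <- unname(ra[an$gene_a])
  an$chrom_b <- unname(cb[an$gene_b]); an$rank_b <- unname(rb[an$gene_b])
  rownames(an) <- NULL
  an[, c("gene_a", "gene_b", "chrom_a", "chrom_b", "rank_a", "rank_b",
         "bit_score")]
}

empty_anchors <- function() {
  data.frame(gene_a = character(), gene_b = character(),
             chrom_a = character(), chrom_b = character(),
             rank_a = integer(), rank_b = integer(), bit_score = numeric(),
             stringsAsFactors = FALSE)
}

empty_blocks <- function() {
  structure(list(
    blocks = data.frame(block_id = character(), chrom_a = character(),
                        chrom_b = character(), orientation = character(),
                        anchor_count = integer(), stringsAsFactors = FALSE),
    anchors = cbind(data.frame(block_id = character(),
                               stringsAsFactors = FALSE), empty_anchors())),
    class = "synteny_blocks")
}

#' @export
print.synteny_blocks <- function(x, ...) {
  cat(sprintf("<synteny_blocks> %d blocks, %d anchors\n",
              nrow(x$blocks), nrow(x$anchors)))
  invisible(x)
}

# Dynamic-programming extraction of the best chain among anchors of one
# chromosome pair and one orientation (s = +1 collinear, -1 inverted).
# Chain score = anchor count; ties prefer smaller total rank gap, then
# smaller starting rank_a.  Returns indices (into ra/rb) of the best chain.
best_chain <- function(ra, rb, s, max_gap, gap_rule = "per_step") {
  n <- length(ra)
  o <- order(ra, s * rb)
  ra <- ra[o]; rbs <- s * rb[o]
  len <- rep(1L, n); gap <- rep(0, n); prev <- rep(0L, n)
  for (i in seq_len(n)) {
    lo <- ra[i] - max_gap - 1
    j <- which(ra >= lo & ra < ra[i] & rbs < rbs[i] &
                 (rbs[i] - rbs) <= max_gap + 1)
    if (!length(j)) next
    step_gap <- (ra[i] - ra[j] - 1) + (rbs[i] - rbs[j] - 1)
    cand_len <- len[j] + 1L
    cand_gap <- gap[j] + step_gap
    if (gap_rule == "per_block") {
      ok <- cand_gap <= max_gap
      if (!any(ok)) next
      j <- j[ok]; cand_len <- cand_len[ok]; cand_gap <- cand_gap[ok]
    }
    best <- order(-cand_len, cand_gap)[1L]
    len[i] <- cand_len[best]; gap[i] <- cand_gap[best]; prev[i] <- j[best]
  }
  ends <- order(-len, gap, ra)[1L]
  chain <- integer(len[ends]); k <- len[ends]; i <- ends
  while (i > 0L) { chain[k] <- i; k <- k - 1L; i <- prev[i] }
  o[chain]
}

#' Chain anchors into collinear synteny blocks
#'
#' Dynamic-programming chaining in gene-rank space.  Chains must be
#' strictly monotone in both rank coordinates (increasing/increasing for
#' collinear blocks, increasing/decreasing for inverted ones); consecutive
#' anchors may be separated by at most the gap allowance
#' (`gap_allowance_factor * 0.5 * mbs` intervening ranks) on either
#' chromosome.  Chains are extracted greedily best-first; chains shorter
#' than `mbs` anchors are discarded, and each anchor joins at most one
#' block.  Duplicate `(rank_a, rank_b)` anchors are deduplicated with a
#' warning.
#'
#' @param anchors Anchor `data.frame` (see [anchors_from_hits()]); may span
#'   several chromosome pairs.
#' @param params A [synteny_params()].
#' @return A `synteny_blocks` object: list with a `blocks` table
#'   (`block_id`, `chrom_a`, `chrom_b`, `orientation`, `anchor_count`) and
#'   an `anchors` table carrying `block_id`.
#' @export
chain_collinear_blocks <- function(anchors, params = synteny_params()) {
  if (!nrow(anchors)) return(empty_blocks())
  dup <- duplicated(anchors[, c("chrom_a", "chrom_b", "rank_a", "rank_b")])
  if (any(dup)) {
    warning(sum(dup), " duplicate (rank_a, rank_b) anchors deduplicated")
    anchors <- anchors[!dup, , drop = FALSE]
  }
  key <- paste(anchors$chrom_a, anchors$chrom_b, sep = "\r")
  pieces <- split(anchors, key)
  res_blocks <- list(); res_anchors <- list(); bi <- 0L
  for (an in pieces) {
    remaining <- an
    repeat {
      if (nrow(remaining) < params$mbs) break
      ch_f <- best_chain(remaining$rank_a, remaining$rank_b, 1,
                         params$max_gap, params$gap_rule)
      ch_r <- best_chain(remaining$rank_a, remaining$rank_b, -1,
                         params$max_gap, params$gap_rule)
      use_f <- length(ch_f) >= length(ch_r)
      ch <- if (use_f) ch_f else ch_r
      if (length(ch) < params$mbs) break
      bi <- bi + 1L
      blk <- remaining[ch, , drop = FALSE]
      blk <- blk[order(blk$rank_a), , drop = FALSE]
      blk$block_id <- sprintf("B%05d", bi)
      res_anchors[[bi]] <- blk
      res_blocks[[bi]] <- data.frame(
        block_id = sprintf("B%05d", bi), chrom_a = blk$chrom_a[1L],
        chrom_b = blk$chrom_b[1L],
        orientation = if (use_f) "collinear" else "inverted",
        anchor_count = nrow(blk), stringsAsFactors = FALSE)
      remaining <- remaining[-ch, , drop = FALSE]
    }
  }
  if (!bi) return(empty_blocks())
  out <- structure(list(blocks = do.call(rbind, res_blocks),
                        anchors = do.call(rbind, res_anchors)),
                   class = "synteny_blocks")
  rownames(out$blocks) <- rownames(out$anchors) <- NULL
  out$anchors <- out$anchors[, c("block_id", "gene_a", "gene_b", "chrom_a",
                                 "chrom_b", "rank_a", "rank_b", "bit_score")]
  out
}

# DBSCAN in 2-D rank space (quadratic neighbourhoods; block anchor sets are
# small).  Returns an integer cluster label per point, 0 = noise.
dbscan_ranks <- function(x, y, eps, min_pts, metric = "chebyshev") {
  n <- length(x)
  if (!n) return(integer(0))
  dx <- abs(outer(x, x, "-")); dy <- abs(outer(y, y, "-"))
  d <- if (metric == "chebyshev") pmax(dx, dy) else sqrt(dx^2 + dy^2)
  nb <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  core <- vapply(nb, length, 1L) >= min_pts
  lab <- integer(n); cl <- 0L
  for (i in seq_len(n)) {
    if (lab[i] != 0L || !core[i]) next
    cl <- cl + 1L
    queue <- i; lab[i] <- cl
    while (length(queue)) {
      q <- queue[1L]; queue <- queue[-1L]
      for (j in nb[[q]]) {
        if (lab[j] == 0L) {
          lab[j] <- cl
          if (core[j]) queue <- c(queue, j)
        }
      }
    }
  }
  lab
}

#' Prune blocks by anchor density (DBSCAN)
#'
#' Within each block, anchors are clustered by DBSCAN in 2-D rank space
#' with radius `dbscan_radius_factor * mbs` (Chebyshev metric by default)
#' and core threshold `dbscan_min_pts` (counting the point itself).  Noise
#' anchors are removed, clusters below `mbs` anchors are dropped, and each
#' surviving cluster is re-emitted as a block.
#'
#' @param blocks A `synteny_blocks` object.
#' @param params A [synteny_params()].
#' @return A pruned `synteny_blocks` object.
#' @export
prune_blocks_density <- function(blocks, params = synteny_params()) {
  if (!nrow(blocks$blocks)) return(blocks)
  res_blocks <- list(); res_anchors <- list(); bi <- 0L
  for (b in seq_len(nrow(blocks$blocks))) {
    info <- blocks$blocks[b, ]
    an <- blocks$anchors[blocks$anchors$block_id == info$block_id, ,
                         drop = FALSE]
    lab <- dbscan_ranks(an$rank_a, an$rank_b, params$dbscan_eps,
                        params$dbscan_min_pts, params$dbscan_metric)
    for (cl in setdiff(unique(lab), 0L)) {
      sub <- an[lab == cl, , drop = FALSE]
      if (nrow(sub) < params$mbs) next
      bi <- bi + 1L
      sub <- sub[order(sub$rank_a), , drop = FALSE]
      sub$block_id <- sprintf("B%05d", bi)
      res_anchors[[bi]] <- sub
      res_blocks[[bi]] <- data.frame(
        block_id = sprintf("B%05d", bi), chrom_a = info$chrom_a,
        chrom_b = info$chrom_b, orientation = info$orientation,
        anchor_count = nrow(sub), stringsAsFactors = FALSE)
    }
  }
  if (!bi) return(empty_blocks())
  out <- structure(list(blocks = do.call(rbind, res_blocks),
                        anchors = do.call(rbind, res_anchors)),
                   class = "synteny_blocks")
  rownames(out$blocks) <- rownames(out$anchors) <- NULL
  out
}

# Rank intervals occupied by blocks, per chromosome pair, padded by radius.
block_windows <- function(blocks, radius) {
  if (!nrow(blocks$blocks)) return(NULL)
  an <- blocks$anchors
  agg <- stats::aggregate(cbind(rank_a, rank_b) ~ block_id + chrom_a + chrom_b,
                          an, function(v) c(min(v), max(v)))
  data.frame(chrom_a = agg$chrom_a, chrom_b = agg$chrom_b,
             a_lo = agg$rank_a[, 1L] - radius, a_hi = agg$rank_a[, 2L] + radius,
             b_lo = agg$rank_b[, 1L] - radius, b_hi = agg$rank_b[, 2L] + radius,
             stringsAsFactors = FALSE)
}

# TRUE for rows of an anchor-like frame lying inside any padded block
# window of the same chromosome pair (both coordinates inside).
in_block_window <- function(chrom_a, rank_a, chrom_b, rank_b, windows) {
  if (is.null(windows)) return(rep(FALSE, length(rank_a)))
  hit <- rep(FALSE, length(rank_a))
  for (w in seq_len(nrow(windows))) {
    hit <- hit | (chrom_a == windows$chrom_a[w] &
                    chrom_b == windows$chrom_b[w] &
                    rank_a >= windows$a_lo[w] & rank_a <= windows$a_hi[w] &
                    rank_b >= windows$b_lo[w] & rank_b <= windows$b_hi[w])
  }
  hit
}

#' Extend blocks with orthogroup-agnostic hits
#'
#' Pulls all score-passing hits (>= `min_bit_score`, regardless of
#' orthogroup membership) whose both endpoints lie within
#' `extension_radius` gene ranks of an existing block on the same
#' chromosome pair, adds them to the anchor pool, and re-runs chaining and
#' density pruning.  With no additional hits the output equals the input.
#'
#' @param blocks Pruned `synteny_blocks`.
#' @param hits The full (unculled) hit table; only the bit-score threshold
#'   is applied here.
#' @param ann_a,ann_b Annotations of the two genomes.
#' @param params A [synteny_params()].
#' @return Re-formed `synteny_blocks`.
#' @export
extend_blocks <- function(blocks, hits, ann_a, ann_b,
                          params = synteny_params()) {
  if (!nrow(blocks$blocks)) return(blocks)
  windows <- block_windows(blocks, params$extension_radius)
  h <- hits[hits$bit_score >= params$min_bit_score &
              hits$query_gene != hits$target_gene, , drop = FALSE]
  # fake an all-in-one orthogroup table so anchors_from_hits keeps all hits
  all_genes <- c(ann_a$genes$gene_id, ann_b$genes$gene_id)
  og_all <- data.frame(og_id = "OGALL",
                       genome_id = c(rep(ann_a$genome_id, nrow(ann_a$genes)),
                                     rep(ann_b$genome_id, nrow(ann_b$genes))),
                       gene_id = all_genes, stringsAsFactors = FALSE)
  cand <- anchors_from_hits(h, og_all, ann_a, ann_b)
  cand <- cand[in_block_window(cand$chrom_a, cand$rank_a, cand$chrom_b,
                               cand$rank_b, windows), , drop = FALSE]
  pool <- rbind(blocks$anchors[, names(cand)], cand)
  pool <- pool[order(pool$gene_a, pool$gene_b, -pool$bit_score), ,
               drop = FALSE]
  pool <- pool[!duplicated(pool[, c("gene_a", "gene_b")]), , drop = FALSE]
  chained <- suppressWarnings(chain_collinear_blocks(pool, params))
  prune_blocks_density(chained, params)
}

#' Classify hits into syntenic homolog classes
#'
#' Hits are first culled to those whose both genes lie within
#' `orthology_cull_radius` gene ranks of a syntenic block on their own
#' chromosome.  Each surviving unordered pair is then labeled `ortholog`
#' (different genomes, same orthogroup), `paralog` (same genome, same
#' orthogroup), `unclustered_homolog` (no shared orthogroup but bit score
#' >= `min_bit_score` and >= `best_score_fraction` of the best bit score
#' for that gene-by-genome combination), or `dropped`.
#'
#' @param hits Hit table (culled or raw).
#' @param blocks Final `synteny_blocks`.
#' @param orthogroups Completed orthogroup table.
#' @param annotations List of [genome_annotation()] objects.
#' @param params A [synteny_params()].
#' @return `data.frame`: `gene_a`, `gene_b`, `bit_score`, `label`.
#' @export
classify_syntenic_homologs <- function(hits, blocks, orthogroups, annotations,
                                       params = synteny_params()) {
  lk <- gene_lookup(annotations)
  gmap <- stats::setNames(lk$genome_id, lk$gene_id)
  cmap <- stats::setNames(lk$chromosome, lk$gene_id)
  rmap <- stats::setNames(lk$rank, lk$gene_id)
  ogm <- stats::setNames(orthogroups$og_id, orthogroups$gene_id)
  h <- hits[hits$query_gene != hits$target_gene, , drop = FALSE]
  # per-gene rank windows near blocks, on each side's own chromosome axis
  an <- blocks$anchors
  near <- function(genes) {
    if (!nrow(an)) return(rep(FALSE, length(genes)))
    ch <- cmap[genes]; rk <- rmap[genes]
    ok <- rep(FALSE, length(genes))
    wins <- rbind(
      stats::aggregate(rank_a ~ block_id + chrom_a, an,
                       function(v) c(min(v), max(v)))[
        , c("chrom_a", "rank_a")] |>
        (\(d) data.frame(chrom = d$chrom_a, lo = d$rank_a[, 1L],
                         hi = d$rank_a[, 2L]))(),
      stats::aggregate(rank_b ~ block_id + chrom_b, an,
                       function(v) c(min(v), max(v)))[
        , c("chrom_b", "rank_b")] |>
        (\(d) data.frame(chrom = d$chrom_b, lo = d$rank_b[, 1L],
                         hi = d$rank_b[, 2L]))())
    r <- params$orthology_cull_radius
    for (w in seq_len(nrow(wins)))
      ok <- ok | (ch == wins$chrom[w] & rk >= wins$lo[w] - r &
                    rk <= wins$hi[w] + r)
    ok
  }
  h <- h[near(h$query_gene) & near(h$target_gene), , drop = FALSE]
  if (!nrow(h))
    return(data.frame(gene_a = character(), gene_b = character(),
                      bit_score = numeric(), label = character(),
                      stringsAsFactors = FALSE))
  # collapse to unordered pairs, best score wins
  a <- pmin(h$query_gene, h$target_gene)
  b <- pmax(h$query_gene, h$target_gene)
  p <- data.frame(gene_a = a, gene_b = b, bit_score = h$bit_score,
                  stringsAsFactors = FALSE)
  p <- p[order(p$gene_a, p$gene_b, -p$bit_score), , drop = FALSE]
  p <- p[!duplicated(p[, c("gene_a", "gene_b")]), , drop = FALSE]
  # best score per gene-by-target-genome combination (over both directions)
  dt <- data.table::data.table(
    gene = c(p$gene_a, p$gene_b),
    other_genome = gmap[c(p$gene_b, p$gene_a)],
    score = c(p$bit_score, p$bit_score))
  best <- dt[, .(best = max(score)), by = .(gene, other_genome)]
  bkey <- stats::setNames(best$best, paste(best$gene, best$other_genome))
  same_og <- !is.na(ogm[p$gene_a]) & !is.na(ogm[p$gene_b]) &
    ogm[p$gene_a] == ogm[p$gene_b]
  inter <- gmap[p$gene_a] != gmap[p$gene_b]
  best_a <- bkey[paste(p$gene_a, gmap[p$gene_b])]
  best_b <- bkey[paste(p$gene_b, gmap[p$gene_a])]
  strong <- p$bit_score >= params$min_bit_score &
    p$bit_score >= params$best_score_fraction * pmax(best_a, best_b)
  p$label <- ifelse(same_og & inter, "ortholog",
                    ifelse(same_og, "paralog",
                           ifelse(strong, "unclustered_homolog", "dropped")))
  rownames(p) <- NULL
  p
}

#' Summarize synteny per chromosome from raw counts
#'
#' Computes the percentage columns of a chromosome-by-chromosome synteny
#' summary (percent of genes in syntenic blocks, percent captured by the
#' largest block, both to 1 decimal) and appends a genome-wide totals row.
#'
#' @param counts `data.frame` with columns `chromosome`, `total_genes`,
#'   `genes_in_blocks`, `n_blocks`, `genes_largest_block`.
#' @return The input with `pct_in_blocks` and `pct_largest_block` columns
#'   plus a final `"total"` row; the total row's `genes_in_blocks` is the
#'   column sum used for the genome-wide percentage.
#' @export
summarize_synteny_counts <- function(counts) {
  counts$pct_in_blocks <- round(100 * counts$genes_in_blocks /
                                  counts$total_genes, 1)
  counts$pct_largest_block <- round(100 * counts$genes_largest_block /
                                      counts$total_genes, 1)
  tot <- data.frame(chromosome = "total",
                    total_genes = sum(counts$total_genes),
                    genes_in_blocks = sum(counts$genes_in_blocks),
                    n_blocks = sum(counts$n_blocks),
                    genes_largest_block = max(counts$genes_largest_block),
                    stringsAsFactors = FALSE)
  tot$pct_in_blocks <- round(100 * tot$genes_in_blocks / tot$total_genes, 1)
  tot$pct_largest_block <- NA_real_
  rbind(counts, tot)
}

#' Chromosome-level synteny summary table
#'
#' For each chromosome of the focal (A-side) genome: total genes, genes in
#' syntenic blocks, percent in blocks, number of blocks, genes in the
#' largest block and the percent it captures, plus genome-wide totals.
#' Blocks are re-filtered to a reporting threshold of at least
#' `min_block_genes` anchors (block construction itself uses `mbs`).
#'
#' @param blocks `synteny_blocks`.
#' @param annotation Focal [genome_annotation()] (the A side of the
#'   blocks).
#' @param min_block_genes Reporting threshold in anchors (default 25).
#' @return See [summarize_synteny_counts()].
#' @export
summarize_synteny <- function(blocks, annotation, min_block_genes = 25L) {
  keep <- blocks$blocks$block_id[blocks$blocks$anchor_count >=
                                   min_block_genes]
  an <- blocks$anchors[blocks$anchors$block_id %in% keep, , drop = FALSE]
  chroms <- names(annotation$chromosome_lengths)
  rows <- lapply(chroms, function(ch) {
    tot <- sum(annotation$genes$chromosome == ch)
    sub <- an[an$chrom_a == ch, , drop = FALSE]
    inb <- length(unique(sub$gene_a))
    nb <- length(unique(sub$block_id))
    largest <- if (nb) max(tapply(sub$gene_a, sub$block_id,
                                  function(g) length(unique(g)))) else 0L
    data.frame(chromosome = ch, total_genes = tot, genes_in_blocks = inb,
               n_blocks = nb, genes_largest_block = as.integer(largest),
               stringsAsFactors = FALSE)
  })
  summarize_synteny_counts(do.call(rbind, rows))
}

#' Run the full two-genome synteny pipeline
#'
#' Cull -> pairwise orthogroups -> orthogroup-constrained anchors ->
#' chaining -> DBSCAN pruning -> orthogroup completion -> block extension
#' with orthogroup-agnostic hits -> syntenic homolog classification.
#'
#' @param hits Raw hit table between (and within) the two genomes.
#' @param ann_a,ann_b The two [genome_annotation()] objects.
#' @param params A [synteny_params()].
#' @return List with elements `culled_hits`, `orthogroups`, `blocks`
#'   (final, extended), `initial_blocks`, `classes`, and `summary`.
#' @export
synteny_run <- function(hits, ann_a, ann_b, params = synteny_params()) {
  culled <- cull_hits(hits, list(ann_a, ann_b), params)
  og <- infer_pairwise_orthogroups(culled, ann_a, ann_b, params)
  anchors <- anchors_from_hits(culled, og, ann_a, ann_b)
  chained <- chain_collinear_blocks(anchors, params)
  pruned <- prune_blocks_density(chained, params)
  completed <- complete_orthogroups(og)
  final <- extend_blocks(pruned, hits, ann_a, ann_b, params)
  classes <- classify_syntenic_homologs(culled, final, completed,
                                        list(ann_a, ann_b), params)
  list(culled_hits = culled, orthogroups = completed, blocks = final,
       initial_blocks = pruned, classes = classes,
       summary = summarize_synteny(final, ann_a,
                                   min_block_genes = params$mbs))
}

#' Intra-genome paralog synteny blocks
#'
#' Runs chaining and pruning on within-genome hits to recover duplicated
#' segments (e.g. whole-genome duplication remnants).  Self-hits and hits
#' between genes on the same chromosome closer than
#' `tandem_exclusion_radius` ranks are excluded first, so tandem arrays do
#' not masquerade as duplicated segments.  Each unordered pair is oriented
#' with the lower-ranked gene on the A side.
#'
#' @param hits Hit table restricted to one genome (self-genome hits).
#' @param annotation The genome's [genome_annotation()].
#' @param orthogroups Orthogroup table used to constrain anchors (pairs
#'   must share a group); pass `NULL` to skip the constraint.
#' @param params A [synteny_params()].
#' @return A `synteny_blocks` object of paralog blocks.
#' @export
paralog_blocks <- function(hits, annotation, orthogroups = NULL,
                           params = synteny_params()) {
  g <- annotation$genes
  cmap <- stats::setNames(g$chromosome, g$gene_id)
  rmap <- stats::setNames(g$rank, g$gene_id)
  h <- hits[hits$query_gene != hits$target_gene &
              hits$bit_score >= params$min_bit_score, , drop = FALSE]
  h <- h[h$query_gene %in% g$gene_id & h$target_gene %in% g$gene_id, ,
         drop = FALSE]
  if (!is.null(orthogroups)) {
    ogm <- stats::setNames(orthogroups$og_id, orthogroups$gene_id)
    h <- h[!is.na(ogm[h$query_gene]) & !is.na(ogm[h$target_gene]) &
             ogm[h$query_gene] == ogm[h$target_gene], , drop = FALSE]
  }
  if (!nrow(h)) return(empty_blocks())
  # orient unordered pairs: lower (chromosome, rank) on the A side
  ka <- paste(cmap[h$query_gene], sprintf("%09d", rmap[h$query_gene]))
  kb <- paste(cmap[h$target_gene], sprintf("%09d", rmap[h$target_gene]))
  swap <- ka > kb
  gene_a <- ifelse(swap, h$target_gene, h$query_gene)
  gene_b <- ifelse(swap, h$query_gene, h$target_gene)
  an <- data.frame(gene_a = gene_a, gene_b = gene_b, bit_score = h$bit_score,
                   stringsAsFactors = FALSE)
  an$chrom_a <- unname(cmap[an$gene_a]); an$rank_a <- unname(rmap[an$gene_a])
  an$chrom_b <- unname(cmap[an$gene_b]); an$rank_b <- unname(rmap[an$gene_b])
  near_tandem <- an$chrom_a == an$chrom_b &
    abs(an$rank_a - an$rank_b) <= params$tandem_exclusion_radius
  an <- an[!near_tandem, , drop = FALSE]
  an <- an[order(an$gene_a, an$gene_b, -an$bit_score), , drop = FALSE]
  an <- an[!duplicated(an[, c("gene_a", "gene_b")]), , drop = FALSE]
  pruned <- prune_blocks_density(
    suppressWarnings(chain_collinear_blocks(an, params)), params)
  pruned
}
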