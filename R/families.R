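# Gene-family expansion classification, tandem-array detection,
# expansion/tandem overlap, relative-age Ks profiling and hypergeometric
# pathway enrichment.

#' Classify orthogroups as expanded gene families
#'
#' Two rules are supported.  Lineage-shared mode: an orthogroup is an
#' expansion when its total gene count is strictly greater than
#' `min_genes` (default 5) and the combined fraction of genes from the two
#' focal genomes is strictly greater than `min_fraction` (default 0.70),
#' with both focal genomes contributing at least one gene.
#' Species-specific mode: total count at least `min_genes` (non-strict)
#' and the single focal genome's fraction at least `min_fraction`
#' (default 0.50, non-strict).
#'
#' @param orthogroups Completed orthogroup table (`og_id`, `genome_id`,
#'   `gene_id`).
#' @param focal_genomes Character vector: two genomes in lineage mode, one
#'   in species mode.
#' @param mode `"lineage_shared"` or `"species_specific"`.
#' @param min_genes,min_fraction Rule thresholds; defaults depend on
#'   `mode` as described above.
#' @return `data.frame` with one row per orthogroup: `og_id`, `label`
#'   (`"lineage_shared"`, `"species_specific:<genome>"`, or `"none"`),
#'   `gene_count`, `focal_fraction`.
#' @export
classify_expansion <- function(orthogroups, focal_genomes,
                               mode = c("lineage_shared",
                                        "species_specific"),
                               min_genes = 5L, min_fraction = NULL) {
  mode <- match.arg(mode)
  if (is.null(min_fraction))
    min_fraction <- if (mode == "lineage_shared") 0.70 else 0.50
  if (mode == "lineage_shared" && length(focal_genomes) != 2L)
    stop("lineage_shared mode needs exactly two focal genomes")
  if (mode == "species_specific" && length(focal_genomes) != 1L)
    stop("species_specific mode needs exactly one focal genome")
  absent <- setdiff(focal_genomes, unique(orthogroups$genome_id))
  if (length(absent))
    stop("focal genome absent from clustering: ", absent[1L])
  dt <- data.table::as.data.table(orthogroups)
  per <- dt[, .(gene_count = .N,
                focal = sum(genome_id %in% focal_genomes),
                n_focal_genomes = data.table::uniqueN(
                  genome_id[genome_id %in% focal_genomes])),
            by = og_id]
  per[, focal_fraction := focal / gene_count]
  if (mode == "lineage_shared") {
    hit <- per$gene_count > min_genes &
      per$focal_fraction > min_fraction &
      per$n_focal_genomes == 2L
    label <- ifelse(hit, "lineage_shared", "none")
  } else {
    hit <- per$gene_count >= min_genes & per$focal_fraction >= min_fraction
    label <- ifelse(hit, paste0("species_specific:", focal_genomes), "none")
  }
  out <- data.frame(og_id = per$og_id, label = label,
                    gene_count = per$gene_count,
                    focal_fraction = per$focal_fraction,
                    stringsAsFactors = FALSE)
  out <- out[order(out$og_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect tandem gene arrays
#'
#' Maximal runs of same-family genes along a chromosome where consecutive
#' members differ by at most `max_rank_gap` gene ranks (default 1, i.e.
#' strictly adjacent genes — the conservative reading).  Runs of at least
#' two genes are emitted.
#'
#' @param annotation A [genome_annotation()].
#' @param family_map Named character vector: gene_id -> family (orthogroup)
#'   id.  Genes without a family are ignored.
#' @param max_rank_gap Maximum rank difference between consecutive array
#'   members (default 1).
#' @return `data.frame`: `array_id`, `chromosome`, `family`, `n_genes`,
#'   `genes` (comma-separated, ordered by rank).
#' @export
detect_tandem_arrays <- function(annotation, family_map, max_rank_gap = 1L) {
  g <- annotation$genes
  g$family <- unname(family_map[g$gene_id])
  g <- g[!is.na(g$family), , drop = FALSE]
  g <- g[order(g$chromosome, g$rank), , drop = FALSE]
  if (!nrow(g))
    return(data.frame(array_id = character(), chromosome = character(),
                      family = character(), n_genes = integer(),
                      genes = character(), stringsAsFactors = FALSE))
  new_run <- c(TRUE, g$chromosome[-1L] != g$chromosome[-nrow(g)] |
                 g$family[-1L] != g$family[-nrow(g)] |
                 diff(g$rank) > max_rank_gap)
  run <- cumsum(new_run)
  sizes <- tabulate(run)
  keep <- run %in% which(sizes >= 2L)
  g <- g[keep, , drop = FALSE]
  run <- run[keep]
  if (!nrow(g))
    return(data.frame(array_id = character(), chromosome = character(),
                      family = character(), n_genes = integer(),
                      genes = character(), stringsAsFactors = FALSE))
  ids <- match(run, unique(run))
  out <- data.frame(
    array_id = sprintf("TA%05d", unique(ids)),
    chromosome = tapply(g$chromosome, ids, `[`, 1L),
    family = tapply(g$family, ids, `[`, 1L),
    n_genes = as.integer(tabulate(ids)),
    genes = tapply(g$gene_id, ids, paste, collapse = ","),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Overlap between expansions and tandem arrays
#'
#' Counts the focal genome's genes belonging to expanded orthogroups that
#' are also members of tandem arrays, reporting the count and the fraction
#' of expansion genes (gene-level counting).
#'
#' @param expansions Output of [classify_expansion()] (only rows whose
#'   `label != "none"` count).
#' @param orthogroups Orthogroup table used for the classification.
#' @param arrays Output of [detect_tandem_arrays()].
#' @param genome Focal genome id whose genes are counted.
#' @return List: `n_expansion_genes`, `n_overlap`, `fraction`.
#' @export
expansion_tandem_overlap <- function(expansions, orthogroups, arrays,
                                     genome) {
  exp_og <- expansions$og_id[expansions$label != "none"]
  exp_genes <- orthogroups$gene_id[orthogroups$og_id %in% exp_og &
                                     orthogroups$genome_id == genome]
  array_genes <- unlist(strsplit(arrays$genes, ",", fixed = TRUE),
                        use.names = FALSE)
  ov <- intersect(exp_genes, array_genes)
  list(n_expansion_genes = length(exp_genes), n_overlap = length(ov),
       fraction = if (length(exp_genes)) length(ov) / length(exp_genes)
                  else NA_real_)
}

#' Pooled within-orthogroup Ks distributions per expansion class
#'
#' Computes pairwise Ks for every within-orthogroup gene pair of each
#' expansion class (all intra-group pairs with CDS available), pools the
#' values per class, and detects peaks.  A reference distribution from
#' 1:1 ortholog pairs supplies the divergence-peak overlay.
#'
#' @param class_map Named list: class label -> character vector of og_ids.
#' @param orthogroups Orthogroup table.
#' @param cds Named character vector of CDS keyed by gene id.
#' @param reference_pairs Optional `data.frame` (`gene_a`, `gene_b`) of
#'   1:1 ortholog pairs for the reference divergence distribution.
#' @param ... Passed to [ks_peak()].
#' @return Named list per class (plus `"reference"` when supplied):
#'   each element has `ks` (the pair table) and `distribution`
#'   (a `ks_distribution`, or `NULL` when fewer than 20 usable values).
#' @export
expansion_age_profile <- function(class_map, orthogroups, cds,
                                  reference_pairs = NULL, ...) {
  one_class <- function(og_ids) {
    pairs <- do.call(rbind, lapply(og_ids, function(og) {
      genes <- orthogroups$gene_id[orthogroups$og_id == og]
      genes <- genes[genes %in% names(cds)]
      if (length(genes) < 2L) {
        warning("orthogroup ", og, " lacks 2 sequenced members; skipped")
        return(NULL)
      }
      cmb <- utils::combn(sort(genes), 2L)
      data.frame(gene_a = cmb[1L, ], gene_b = cmb[2L, ],
                 stringsAsFactors = FALSE)
    }))
    if (is.null(pairs)) return(list(ks = NULL, distribution = NULL))
    kt <- ks_batch(pairs, cds)
    usable <- kt$ks[is.finite(kt$ks) & !kt$saturated]
    dist <- if (length(usable) >= 20L) ks_peak(usable, ...) else NULL
    list(ks = kt, distribution = dist)
  }
  out <- lapply(class_map, one_class)
  if (!is.null(reference_pairs)) {
    kt <- ks_batch(reference_pairs, cds)
    usable <- kt$ks[is.finite(kt$ks) & !kt$saturated]
    out$reference <- list(
      ks = kt,
      distribution = if (length(usable) >= 20L) ks_peak(usable, ...)
                     else NULL)
  }
  out
}

#' Hypergeometric pathway enrichment
#'
#' Upper-tail hypergeometric test per pathway: the probability of drawing
#' at least the observed overlap when `set_size` genes are sampled without
#' replacement from a universe containing `pathway_size` pathway members.
#' Pathways are intersected with the universe first; results are sorted by
#' ascending p and flagged enriched when `p < alpha`.
#'
#' @param gene_set Character vector of genes (must be a subset of
#'   `universe`).
#' @param pathway_map `data.frame` with columns `pathway_id`, `gene_id`.
#' @param universe Character vector: the gene universe.
#' @param alpha Enrichment threshold on the raw p-value (default 0.05).
#' @param adjust Also report Benjamini-Hochberg adjusted p-values
#'   (default TRUE; the `enriched` flag always uses the raw p).
#' @return `data.frame`: `pathway_id`, `overlap`, `set_size`,
#'   `pathway_size`, `universe_size`, `p_value`, (`p_adjusted`,)
#'   `enriched`.
#' @export
hypergeometric_enrichment <- function(gene_set, pathway_map, universe,
                                      alpha = 0.05, adjust = TRUE) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  gene_set <- unique(gene_set)
  if (length(setdiff(gene_set, universe)))
    stop("gene_set contains genes outside the universe")
  pm <- pathway_map[pathway_map$gene_id %in% universe, , drop = FALSE]
  pm <- pm[!duplicated(pm[, c("pathway_id", "gene_id")]), , drop = FALSE]
  paths <- split(pm$gene_id, pm$pathway_id)
  n_u <- length(universe)
  n_s <- length(gene_set)
  rows <- lapply(names(paths), function(pid) {
    pg <- paths[[pid]]
    k <- length(intersect(gene_set, pg))
    m <- length(pg)
    p <- stats::phyper(k - 1L, m, n_u - m, n_s, lower.tail = FALSE)
    data.frame(pathway_id = pid, overlap = k, set_size = n_s,
               pathway_size = m, universe_size = n_u, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(pathway_id = character(), overlap = integer(),
                      set_size = integer(), pathway_size = integer(),
                      universe_size = integer(), p_value = numeric(),
                      enriched = logical(), stringsAsFactors = FALSE))
  if (adjust) out$p_adjusted <- stats::p.adjust(out$p_value, "BH")
  out$enriched <- out$p_value < alpha
  out <- out[order(out$p_value, out$pathway_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
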