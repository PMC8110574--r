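# Codon-level divergence: protein-guided codon back-translation, pairwise
# Ka/Ks by Nei-Gojobori (1986) counting with Jukes-Cantor correction,
# Ks-distribution peak detection, molecular-rate arithmetic and
# WGD-window paralog extraction.
#
# Convention (shared with the test oracle and documented in the vignette):
# mutations to stop codons are excluded from the synonymous site fraction,
# i.e. per-codon synonymous sites S = sum over positions of
# n_syn_changes/3 and nonsynonymous sites N = 3 - S, so changes to stops
# count as nonsynonymous capacity.  Substitution pathways through stop
# codons are excluded; if every pathway is blocked the count falls back to
# all pathways with stop steps scored as nonsynonymous.

.codon_env <- new.env(parent = emptyenv())

# Lazily built lookup tables derived from the standard genetic code.
codon_tables <- function() {
  if (!is.null(.codon_env$tab)) return(.codon_env$tab)
  gc_tab <- Biostrings::GENETIC_CODE
  codons <- names(gc_tab)
  sense <- codons[gc_tab != "*"]
  bases <- c("A", "C", "G", "T")
  syn_sites <- stats::setNames(numeric(length(sense)), sense)
  syn_alt <- stats::setNames(vector("list", length(sense)), sense)
  nonsyn_alt <- stats::setNames(vector("list", length(sense)), sense)
  for (cd in sense) {
    s <- 0; sa <- character(0); na <- character(0)
    for (p in 1:3) {
      for (b in bases) {
        if (substr(cd, p, p) == b) next
        alt <- cd
        substr(alt, p, p) <- b
        if (gc_tab[[alt]] == "*") next     # stop: excluded from syn fraction
        if (gc_tab[[alt]] == gc_tab[[cd]]) {
          s <- s + 1 / 3
          sa <- c(sa, alt)
        } else {
          na <- c(na, alt)
        }
      }
    }
    syn_sites[[cd]] <- s
    syn_alt[[cd]] <- sa
    nonsyn_alt[[cd]] <- na
  }
  .codon_env$tab <- list(gc = gc_tab, sense = sense, syn_sites = syn_sites,
                         syn_alt = syn_alt, nonsyn_alt = nonsyn_alt)
  .codon_env$diff_memo <- new.env(parent = emptyenv())
  .codon_env$tab
}

split_codons <- function(seq) {
  n <- nchar(seq)
  if (n %% 3L != 0L) stop("sequence length not a multiple of 3")
  substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
}

perms_of <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in perms_of(v[-i])) out <- c(out, list(c(v[i], rest)))
  out
}

# Pathway-averaged synonymous/nonsynonymous difference counts for one codon
# pair (memoized; at most 61*61 distinct pairs).
ng86_diff_counts <- function(c1, c2) {
  tab <- codon_tables()
  key <- paste0(c1, c2)
  memo <- .codon_env$diff_memo
  hit <- memo[[key]]
  if (!is.null(hit)) return(hit)
  b1 <- strsplit(c1, "")[[1L]]
  b2 <- strsplit(c2, "")[[1L]]
  pos <- which(b1 != b2)
  if (!length(pos)) {
    res <- c(sd = 0, nd = 0)
    memo[[key]] <- res
    return(res)
  }
  gc_tab <- tab$gc
  score_path <- function(ord, allow_stops) {
    cur <- c1; s <- 0; n <- 0
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- b2[p]
      if (gc_tab[[nxt]] == "*" && !allow_stops) return(NULL)
      if (gc_tab[[nxt]] == gc_tab[[cur]]) s <- s + 1 else n <- n + 1
      cur <- nxt
    }
    c(s, n)
  }
  paths <- perms_of(pos)
  counted <- Filter(Negate(is.null), lapply(paths, score_path,
                                            allow_stops = FALSE))
  if (!length(counted))
    counted <- lapply(paths, score_path, allow_stops = TRUE)
  m <- do.call(rbind, counted)
  res <- c(sd = mean(m[, 1L]), nd = mean(m[, 2L]))
  memo[[key]] <- res
  res
}

jc_correct <- function(p) -0.75 * log(1 - 4 * p / 3)

#' Pairwise Ka/Ks by Nei-Gojobori counting
#'
#' Counts expected synonymous and nonsynonymous sites per codon (averaged
#' over the two sequences), pathway-averages substitution counts for
#' multi-hit codons, and applies the Jukes-Cantor multiple-hit correction.
#' Codon columns containing gaps, ambiguity codes or stop codons are
#' skipped; a proportion of differences above the correction domain guard
#' (`pd > 0.74`) in either class flags the estimate as saturated and caps
#' the corresponding rate at 3.0.
#'
#' @param alignment A codon alignment: list with elements `seq_a`, `seq_b`
#'   (gapped CDS strings of equal length, gaps in whole-codon triples), as
#'   produced by [backtranslate_alignment()] or [codon_alignment()].
#' @return List of class `ks_estimate`: `ks`, `ka`, `s_sites`, `n_sites`,
#'   `sd`, `nd`, `codons` (comparable codon count), `saturated`.
#' @export
estimate_pairwise_ks <- function(alignment) {
  tab <- codon_tables()
  ca <- split_codons(alignment$seq_a)
  cb <- split_codons(alignment$seq_b)
  if (length(ca) != length(cb)) stop("aligned sequences differ in length")
  ok <- ca %in% tab$sense & cb %in% tab$sense
  ca <- ca[ok]; cb <- cb[ok]
  if (!length(ca)) stop("no comparable codon columns in alignment")
  s_sites <- sum((tab$syn_sites[ca] + tab$syn_sites[cb]) / 2)
  n_sites <- 3 * length(ca) - s_sites
  sd_tot <- 0; nd_tot <- 0
  for (i in which(ca != cb)) {
    d <- ng86_diff_counts(ca[i], cb[i])
    sd_tot <- sd_tot + d[["sd"]]
    nd_tot <- nd_tot + d[["nd"]]
  }
  ps <- sd_tot / s_sites
  pn <- nd_tot / n_sites
  saturated <- FALSE
  if (ps > 0.74) { ks <- 3.0; saturated <- TRUE } else ks <- jc_correct(ps)
  if (pn > 0.74) { ka <- 3.0; saturated <- TRUE } else ka <- jc_correct(pn)
  structure(list(ks = ks, ka = ka, s_sites = s_sites, n_sites = n_sites,
                 sd = sd_tot, nd = nd_tot, codons = length(ca),
                 saturated = saturated),
            class = "ks_estimate")
}

#' @export
print.ks_estimate <- function(x, ...) {
  cat(sprintf("<ks_estimate> Ks = %.4f, Ka = %.4f (%d codons%s)\n",
              x$ks, x$ka, x$codons,
              if (x$saturated) ", saturated" else ""))
  invisible(x)
}

translate_cds <- function(cds) {
  tab <- codon_tables()
  cods <- split_codons(cds)
  aa <- tab$gc[cods]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Back-translate a protein alignment to a codon alignment
#'
#' Replaces each aligned amino acid by its source codon and each protein
#' gap by the codon gap `"---"`.  Terminal stop codons on the CDS are
#' stripped before validation; the ungapped protein must equal the
#' standard-code translation of its CDS.
#'
#' @param prot_a,prot_b Gapped protein sequences (equal length).
#' @param cds_a,cds_b Ungapped coding sequences for the two proteins.
#' @param gene_a,gene_b Optional identifiers carried through.
#' @return A codon alignment list: `seq_a`, `seq_b`, `gene_a`, `gene_b`,
#'   `codons`.
#' @export
backtranslate_alignment <- function(prot_a, prot_b, cds_a, cds_b,
                                    gene_a = "a", gene_b = "b") {
  if (nchar(prot_a) != nchar(prot_b))
    stop("protein alignment rows differ in length")
  strip_stop <- function(cds, prot) {
    if (nchar(cds) %% 3L != 0L)
      stop("CDS length is not a multiple of 3")
    if (nchar(cds) == 3L * (nchar(prot) + 1L) &&
        translate_cds(substr(cds, nchar(cds) - 2L, nchar(cds))) == "*")
      cds <- substr(cds, 1L, nchar(cds) - 3L)
    cds
  }
  back_one <- function(prot_gapped, cds, label) {
    prot <- gsub("-", "", prot_gapped, fixed = TRUE)
    cds <- strip_stop(cds, prot)
    if (nchar(cds) != 3L * nchar(prot))
      stop("CDS length is not 3x protein length for ", label)
    trans <- translate_cds(cds)
    if (trans != prot) {
      bad <- which(strsplit(trans, "")[[1L]] != strsplit(prot, "")[[1L]])[1L]
      stop("translation mismatch for ", label, " at residue ", bad, ": CDS ",
           "gives '", substr(trans, bad, bad), "', protein has '",
           substr(prot, bad, bad), "'")
    }
    cods <- split_codons(cds)
    cols <- strsplit(prot_gapped, "")[[1L]]
    out <- character(length(cols))
    j <- 0L
    for (i in seq_along(cols)) {
      if (cols[i] == "-") out[i] <- "---"
      else { j <- j + 1L; out[i] <- cods[j] }
    }
    paste(out, collapse = "")
  }
  list(seq_a = back_one(prot_a, cds_a, gene_a),
       seq_b = back_one(prot_b, cds_b, gene_b),
       gene_a = gene_a, gene_b = gene_b, codons = nchar(prot_a))
}

#' Codon alignment of two equal-length ungapped CDS
#'
#' Trivial columnwise pairing for homologous coding sequences that contain
#' no indels (e.g. simulator output).
#'
#' @param cds_a,cds_b Ungapped CDS strings of equal length (multiple of 3).
#' @param gene_a,gene_b Optional identifiers.
#' @return A codon alignment list (see [backtranslate_alignment()]).
#' @export
codon_alignment <- function(cds_a, cds_b, gene_a = "a", gene_b = "b") {
  if (nchar(cds_a) != nchar(cds_b))
    stop("codon_alignment() requires equal-length CDS; align proteins and ",
         "use backtranslate_alignment() instead")
  list(seq_a = cds_a, seq_b = cds_b, gene_a = gene_a, gene_b = gene_b,
       codons = nchar(cds_a) / 3L)
}

#' Batch Ka/Ks over a table of gene pairs
#'
#' @param pairs `data.frame` with columns `gene_a`, `gene_b`.
#' @param cds Named character vector of ungapped CDS keyed by gene id.
#' @return `data.frame`: `gene_a`, `gene_b`, `ks`, `ka`, `s_sites`,
#'   `n_sites`, `saturated`.  Pairs with missing sequences or mismatched
#'   lengths are skipped with a warning.
#' @export
ks_batch <- function(pairs, cds) {
  rows <- vector("list", nrow(pairs))
  skipped <- 0L
  for (i in seq_len(nrow(pairs))) {
    a <- pairs$gene_a[i]; b <- pairs$gene_b[i]
    if (is.na(cds[a]) || is.na(cds[b]) ||
        nchar(cds[[a]]) != nchar(cds[[b]])) {
      skipped <- skipped + 1L
      next
    }
    e <- estimate_pairwise_ks(codon_alignment(cds[[a]], cds[[b]], a, b))
    rows[[i]] <- data.frame(gene_a = a, gene_b = b, ks = e$ks, ka = e$ka,
                            s_sites = e$s_sites, n_sites = e$n_sites,
                            saturated = e$saturated, stringsAsFactors = FALSE)
  }
  if (skipped)
    warning(skipped, " pair(s) skipped (missing CDS or length mismatch)")
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(gene_a = character(),
                                      gene_b = character(), ks = numeric(),
                                      ka = numeric(), s_sites = numeric(),
                                      n_sites = numeric(),
                                      saturated = logical(),
                                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Single-copy orthogroups
#'
#' Restricts a completed multi-genome orthogroup table to groups containing
#' exactly one member from each requested genome (and members from no other
#' genome are required among the requested set).
#'
#' @param orthogroups Orthogroup table (`og_id`, `genome_id`, `gene_id`).
#' @param genomes Character vector of genome ids that must each contribute
#'   exactly one gene.
#' @return The subset of `orthogroups` (restricted to `genomes`) whose
#'   groups are strictly 1:1:...:1.
#' @export
single_copy_orthologs <- function(orthogroups, genomes) {
  og <- orthogroups[orthogroups$genome_id %in% genomes, , drop = FALSE]
  if (!nrow(og)) return(og)
  cnt <- table(og$og_id, og$genome_id)
  full <- rownames(cnt)[apply(cnt, 1L, function(r)
    all(r[genomes] == 1L)) & rowSums(cnt) == length(genomes)]
  out <- og[og$og_id %in% full, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect peaks in a Ks distribution
#'
#' Gaussian kernel density over `[0, cap]`; peaks are local maxima whose
#' density exceeds `prominence` times the global maximum, ordered by
#' location.  For each peak the median of the values within one bandwidth
#' of the mode is also reported (the distribution mode and the
#' peak-adjacent median are both of interest when dating events).
#'
#' @param values Numeric Ks values; non-finite values and values above
#'   `cap` are dropped.
#' @param bandwidth Kernel bandwidth; default is Silverman's rule computed
#'   on the values `<= 2`.
#' @param cap Upper bound of the evaluated range (default 3, the
#'   saturation cap).
#' @param prominence Minimum peak density as a fraction of the maximum
#'   density (default 0.05).
#' @return List of class `ks_distribution`: `values`, `bandwidth`, `peaks`
#'   (`data.frame` with `location`, `density`, `median_nearby`).
#' @export
ks_peak <- function(values, bandwidth = NULL, cap = 3, prominence = 0.05) {
  v <- values[is.finite(values) & values >= 0 & values <= cap]
  if (length(v) < 20L)
    stop("ks_peak() needs at least 20 finite values, got ", length(v))
  if (stats::sd(v) == 0) {
    peaks <- data.frame(location = v[1L], density = Inf,
                        median_nearby = v[1L])
    return(structure(list(values = v, bandwidth = 0, peaks = peaks),
                     class = "ks_distribution"))
  }
  if (is.null(bandwidth)) {
    core <- v[v <= 2]
    if (length(core) < 2L || stats::sd(core) == 0) core <- v
    bandwidth <- stats::bw.nrd0(core)
  }
  den <- stats::density(v, bw = bandwidth, from = 0,
                        to = min(cap, max(v) + 3 * bandwidth), n = 1024L)
  y <- den$y
  is_max <- c(FALSE, y[2:(length(y) - 1L)] > y[1:(length(y) - 2L)] &
                y[2:(length(y) - 1L)] >= y[3:length(y)], FALSE)
  is_max <- is_max & y >= prominence * max(y)
  loc <- den$x[is_max]
  peaks <- data.frame(
    location = loc, density = y[is_max],
    median_nearby = vapply(loc, function(m) {
      nb <- v[abs(v - m) <= bandwidth]
      if (length(nb)) stats::median(nb) else NA_real_
    }, numeric(1L)))
  peaks <- peaks[order(peaks$location), , drop = FALSE]
  rownames(peaks) <- NULL
  structure(list(values = v, bandwidth = bandwidth, peaks = peaks),
            class = "ks_distribution")
}

#' @export
print.ks_distribution <- function(x, ...) {
  cat(sprintf("<ks_distribution> %d values, bandwidth %.4f\n",
              length(x$values), x$bandwidth))
  print(x$peaks)
  invisible(x)
}

#' Substitution rate per site per year from a Ks peak
#'
#' `R = Ks / (2 T)`: the synonymous divergence accumulates along both
#' lineages since their split at time `T`.
#'
#' @param ks Synonymous divergence at the peak (substitutions per
#'   synonymous site).
#' @param divergence_time Divergence age in years.
#' @return The rate in substitutions per site per year (numeric).
#' @export
rate_per_site_year <- function(ks, divergence_time) {
  if (!is.finite(divergence_time) || divergence_time <= 0)
    stop("divergence_time must be positive")
  if (ks < 0) stop("ks must be non-negative")
  ks / (2 * divergence_time)
}

#' Extract paralog pairs within a Ks window
#'
#' Keeps intra-genome paralog pairs whose Ks falls inside the closed
#' window, e.g. the lineage-specific WGD peak window.
#'
#' @param ks_table `data.frame` with a `ks` column (and optionally a
#'   `saturated` flag; saturated pairs are excluded).
#' @param window Numeric length-2, `c(low, high)`, endpoints inclusive.
#' @return The subset of `ks_table` inside the window.
#' @export
extract_wgd_paralogs <- function(ks_table, window = c(0.33, 0.45)) {
  if (window[1L] > window[2L]) stop("window low > high")
  keep <- is.finite(ks_table$ks) & ks_table$ks >= window[1L] &
    ks_table$ks <= window[2L]
  if (!is.null(ks_table$saturated)) keep <- keep & !ks_table$saturated
  out <- ks_table[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
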