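# Gene models, annotations, homology hit tables and per-window genome tracks.
#
# Internal coordinates are 0-based half-open; GFF3 I/O converts to and from
# the format's native 1-based inclusive convention.  Gene rank is the
# 0-based ordinal position of a gene along its chromosome ordered by start
# (ties by end, then gene_id), ignoring strand: rank space is the coordinate
# system for all collinearity and radius rules.

#' Construct a genome annotation
#'
#' Bundles a set of gene models with chromosome lengths and a ploidy
#' declaration into the container consumed by the synteny pipeline.
#' Per-chromosome gene ranks are (re)assigned from the coordinates.
#'
#' @param genome_id Single string naming the genome.
#' @param genes `data.frame` with columns `gene_id`, `chromosome`, `start`
#'   (0-based), `end` (half-open), `strand` (`"+"`/`"-"`).
#' @param chromosome_lengths Named numeric vector, chromosome -> length (bp).
#'   If `NULL`, lengths are taken as the maximum gene end per chromosome.
#' @param ploidy Integer haplotype count of the assembly the gene set
#'   represents (used by the per-haplotype hit cull).
#' @return An object of class `genome_annotation`: a list with fields
#'   `genome_id`, `ploidy`, `chromosome_lengths` and `genes` (the input
#'   genes with a `rank` column added).
#' @export
genome_annotation <- function(genome_id, genes, chromosome_lengths = NULL,
                              ploidy = 1L) {
  stopifnot(is.character(genome_id), length(genome_id) == 1L)
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  req <- c("gene_id", "chromosome", "start", "end", "strand")
  miss <- setdiff(req, names(genes))
  if (length(miss))
    stop("genes is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene_id in genome '", genome_id, "': ",
         genes$gene_id[duplicated(genes$gene_id)][1L])
  if (any(genes$start >= genes$end))
    stop("gene with start >= end: ",
         genes$gene_id[genes$start >= genes$end][1L])
  if (!all(genes$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  if (is.null(chromosome_lengths)) {
    chromosome_lengths <- tapply(genes$end, genes$chromosome, max)
    chromosome_lengths <- stats::setNames(as.numeric(chromosome_lengths),
                                          names(chromosome_lengths))
  }
  unknown <- setdiff(unique(genes$chromosome), names(chromosome_lengths))
  if (length(unknown))
    stop("gene on chromosome absent from chromosome_lengths: ", unknown[1L])
  too_long <- genes$end > chromosome_lengths[genes$chromosome]
  if (any(too_long))
    stop("gene end exceeds chromosome length: ", genes$gene_id[too_long][1L])
  genes <- assign_ranks(genes)
  structure(list(genome_id = genome_id, ploidy = as.integer(ploidy),
                 chromosome_lengths = chromosome_lengths, genes = genes),
            class = "genome_annotation")
}

# Per-chromosome 0-based ranks by ascending start; ties broken by ascending
# end then lexicographic gene_id.  Row order of the result follows rank.
assign_ranks <- function(genes) {
  o <- order(genes$chromosome, genes$start, genes$end, genes$gene_id)
  genes <- genes[o, , drop = FALSE]
  genes$rank <- stats::ave(seq_len(nrow(genes)), genes$chromosome,
                           FUN = function(i) seq_along(i) - 1L)
  rownames(genes) <- NULL
  genes
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("<genome_annotation> %s: %d genes on %d chromosomes (ploidy %d)\n",
              x$genome_id, nrow(x$genes), length(x$chromosome_lengths),
              x$ploidy))
  invisible(x)
}

#' Read gene models from a GFF3 file
#'
#' Parses `gene` features (ID attribute required) from a GFF3 file and
#' converts the 1-based inclusive coordinates to the internal 0-based
#' half-open convention.  Chromosome lengths are taken from
#' `##sequence-region` pragmas when present.
#'
#' @param path Path to a GFF3 file.
#' @param genome_id Genome identifier to attach.
#' @param ploidy Haplotype count (see [genome_annotation()]).
#' @return A [genome_annotation()] object.
#' @export
read_annotation <- function(path, genome_id, ploidy = 1L) {
  lines <- readLines(path)
  lens <- c()
  seqreg <- grep("^##sequence-region", lines)
  for (i in seqreg) {
    f <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(f) >= 4L) lens[f[2L]] <- as.numeric(f[4L])
  }
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  rows <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(rows)
  if (any(nf != 9L))
    stop("malformed GFF3 line ", idx[nf != 9L][1L], ": expected 9 fields, got ",
         nf[nf != 9L][1L])
  m <- do.call(rbind, rows)
  is_gene <- m[, 3L] == "gene"
  m <- m[is_gene, , drop = FALSE]
  gidx <- idx[is_gene]
  mm <- regexpr("(^|;)ID=[^;]+", m[, 9L])
  if (any(mm == -1L))
    stop("malformed GFF3 line ", gidx[mm == -1L][1L],
         ": gene without ID attribute")
  id <- sub("^;?ID=", "", regmatches(m[, 9L], mm))
  genes <- data.frame(gene_id = id, chromosome = m[, 1L],
                      start = as.numeric(m[, 4L]) - 1,
                      end = as.numeric(m[, 5L]),
                      strand = m[, 7L], stringsAsFactors = FALSE)
  genome_annotation(genome_id, genes,
                    chromosome_lengths = if (length(lens)) lens else NULL,
                    ploidy = ploidy)
}

#' Write an annotation back to GFF3
#'
#' Inverse of [read_annotation()]: emits `##sequence-region` pragmas and one
#' `gene` feature per gene model in native 1-based inclusive coordinates.
#'
#' @param annotation A [genome_annotation()].
#' @param path Output file path.
#' @export
write_annotation <- function(annotation, path) {
  g <- annotation$genes
  hdr <- c("##gff-version 3",
           sprintf("##sequence-region %s 1 %d",
                   names(annotation$chromosome_lengths),
                   as.integer(annotation$chromosome_lengths)))
  body <- sprintf("%s\t%s\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                  g$chromosome, annotation$genome_id,
                  as.integer(g$start) + 1L, as.integer(g$end),
                  g$strand, g$gene_id)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a 12-column tabular homology hit file
#'
#' Consumes the tab-separated output format of all-vs-all protein aligners
#' (query, target, %identity, alignment length, mismatches, gap opens,
#' qstart, qend, tstart, tend, e-value, bit score).  Self-hits are retained
#' and flagged.
#'
#' @param path Path to the hit table.
#' @return `data.frame` with one row per hit; columns `query_gene`,
#'   `target_gene`, `percent_identity`, `length`, `mismatches`, `gapopen`,
#'   `qstart`, `qend`, `tstart`, `tend`, `evalue`, `bit_score`, `self_hit`.
#' @export
read_hit_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(empty_hits())
  rows <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(rows)
  if (any(nf != 12L))
    stop("malformed hit table line ", which(nf != 12L)[1L],
         ": expected 12 columns, got ", nf[nf != 12L][1L])
  m <- do.call(rbind, rows)
  h <- data.frame(query_gene = m[, 1L], target_gene = m[, 2L],
                  stringsAsFactors = FALSE)
  num <- c("percent_identity", "length", "mismatches", "gapopen", "qstart",
           "qend", "tstart", "tend", "evalue", "bit_score")
  for (i in seq_along(num)) h[[num[i]]] <- as.numeric(m[, i + 2L])
  h$self_hit <- h$query_gene == h$target_gene
  h
}

empty_hits <- function() {
  data.frame(query_gene = character(), target_gene = character(),
             percent_identity = numeric(), length = numeric(),
             mismatches = numeric(), gapopen = numeric(), qstart = numeric(),
             qend = numeric(), tstart = numeric(), tend = numeric(),
             evalue = numeric(), bit_score = numeric(),
             self_hit = logical(), stringsAsFactors = FALSE)
}

#' Write homology hits in 12-column tabular format
#'
#' @param hits Hit `data.frame` as returned by [read_hit_table()].
#' @param path Output file path.
#' @export
write_hit_table <- function(hits, path) {
  cols <- c("query_gene", "target_gene", "percent_identity", "length",
            "mismatches", "gapopen", "qstart", "qend", "tstart", "tend",
            "evalue", "bit_score")
  utils::write.table(hits[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Shared windowed-count engine: each feature falls in exactly one window,
# chosen by its (0-based) position.
windowed_counts <- function(positions, chrom_len, window_size) {
  n_win <- max(1L, ceiling(chrom_len / window_size))
  idx <- pmin(floor(positions / window_size) + 1L, n_win)
  tabulate(idx, nbins = n_win)
}

#' Per-megabase (or arbitrary window) feature tracks
#'
#' Counts positioned features into fixed windows along each chromosome of an
#' annotation, in the style of per-megabase genome-overview tracks (gene
#' density, heterozygous SNPs per Mb, ...).  A feature is assigned to the
#' single window containing its start position.
#'
#' @param annotation A [genome_annotation()] providing chromosome lengths.
#' @param features `data.frame` with columns `chromosome` and `position`
#'   (0-based bp).  Defaults to the annotation's own genes (by `start`),
#'   giving a gene-density track.
#' @param window_size Window width in bp (default 1 Mb).
#' @return `data.frame` with columns `chromosome`, `window_start`, `value`;
#'   window counts on each chromosome sum to its feature count.
#' @export
compute_windowed_tracks <- function(annotation, features = NULL,
                                    window_size = 1e6) {
  stopifnot(window_size > 0)
  if (is.null(features))
    features <- data.frame(chromosome = annotation$genes$chromosome,
                           position = annotation$genes$start)
  unknown <- setdiff(unique(features$chromosome),
                     names(annotation$chromosome_lengths))
  if (length(unknown))
    stop("feature on unknown chromosome: ", unknown[1L])
  out <- lapply(names(annotation$chromosome_lengths), function(ch) {
    len <- annotation$chromosome_lengths[[ch]]
    pos <- features$position[features$chromosome == ch]
    v <- windowed_counts(pos, len, window_size)
    data.frame(chromosome = ch,
               window_start = (seq_along(v) - 1) * window_size,
               value = v, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
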