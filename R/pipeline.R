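# End-to-end orchestration: simulate (or load) inputs, run synteny,
# Ks dating, gene-family and population-rate stages, and write a report
# bundle with a machine-readable manifest.

#' Run the full comparative pipeline on simulated genomes
#'
#' Executes simulate -> synteny -> Ks -> families (-> popgen) and writes
#' a chromosome synteny summary, Ks peak report with rate conversions, an
#' expansion/tandem report, track TSVs, and a JSON manifest recording
#' every parameter and input checksum.  Any stage failure aborts with the
#' stage name and cause.
#'
#' @param config A [sim_config()]; its seed drives every stage.
#' @param outdir Output directory.
#' @param params A [synteny_params()].
#' @param divergence_times Divergence ages (years) used for the
#'   rate-per-site-per-year bracket.
#' @param ne,generation_time Ancestral population size and generation
#'   time (years) for the mutation-rate conversions.
#' @param run_popgen Include the profile-based theta stage (default
#'   TRUE).
#' @param wgd_window Ks window for WGD paralog extraction.
#' @return Invisibly, a list with each stage's results and the manifest.
#' @export
run_full_pipeline <- function(config = sim_config(), outdir = "results",
                              params = synteny_params(),
                              divergence_times = c(57.2e6, 64.6e6),
                              ne = 112421, generation_time = 15,
                              run_popgen = TRUE,
                              wgd_window = c(0.33, 0.45)) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  manifest <- list(created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   seed = config$seed,
                   config = unclass(config), synteny_params = unclass(params),
                   stages = character(0))
  done <- function(s) manifest$stages <<- c(manifest$stages, s)

  sim <- stage("simulate", simulate_genomes(config))
  hits <- stage("simulate", simulate_hit_table(sim))
  done("simulate")

  ann_a <- sim$annotations$genomeA
  ann_b <- sim$annotations$genomeB
  syn <- stage("synteny", synteny_run(hits, ann_a, ann_b, params))
  utils::write.table(syn$summary, file.path(outdir, "synteny_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(syn$blocks$blocks, file.path(outdir, "blocks.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(syn$orthogroups, file.path(outdir, "orthogroups.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  done("synteny")

  ks <- stage("ks_dating", {
    og_pairs <- syn$classes[syn$classes$label == "ortholog", , drop = FALSE]
    ortho_ks <- ks_batch(og_pairs[, c("gene_a", "gene_b")], sim$cds)
    par_pairs <- syn$classes[syn$classes$label == "paralog", , drop = FALSE]
    paralog_ks <- if (nrow(par_pairs))
      ks_batch(par_pairs[, c("gene_a", "gene_b")], sim$cds) else NULL
    ortho_peak <- ks_peak(ortho_ks$ks[!ortho_ks$saturated])
    rates <- vapply(divergence_times, function(tt)
      rate_per_site_year(ortho_peak$peaks$location[
        which.max(ortho_peak$peaks$density)], tt), numeric(1L))
    wgd <- if (!is.null(paralog_ks) && sum(!paralog_ks$saturated) >= 20L)
      list(peak = ks_peak(paralog_ks$ks[!paralog_ks$saturated]),
           window_pairs = extract_wgd_paralogs(paralog_ks, wgd_window))
    else NULL
    list(ortho_ks = ortho_ks, paralog_ks = paralog_ks,
         ortho_peak = ortho_peak, rates = rates, wgd = wgd)
  })
  utils::write.table(ks$ortho_ks, file.path(outdir, "ortholog_ks.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  peak_report <- data.frame(
    quantity = c("ortholog_ks_mode",
                 paste0("rate_site_year_T", divergence_times)),
    value = c(ks$ortho_peak$peaks$location[
      which.max(ks$ortho_peak$peaks$density)], ks$rates))
  utils::write.table(peak_report, file.path(outdir, "ks_peaks.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  done("ks_dating")

  fam <- stage("families", {
    expansions <- classify_expansion(syn$orthogroups, "genomeA",
                                     mode = "species_specific")
    arrays <- detect_tandem_arrays(
      ann_a, stats::setNames(syn$orthogroups$og_id,
                             syn$orthogroups$gene_id))
    overlap <- expansion_tandem_overlap(expansions, syn$orthogroups,
                                        arrays, "genomeA")
    list(expansions = expansions, arrays = arrays, overlap = overlap)
  })
  utils::write.table(fam$expansions, file.path(outdir, "expansions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(fam$arrays, file.path(outdir, "tandem_arrays.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  done("families")

  pg <- NULL
  if (run_popgen) {
    pg <- stage("popgen", {
      prof <- simulate_profiles(config$n_sites, config$heterozygosity,
                                config$coverage, config$error_rate)
      est <- estimate_theta_ml(prof$profiles)
      mug <- mu_per_generation(est$theta, ne)
      list(theta = est, mu_generation = mug,
           mu_year = mu_per_year(mug, generation_time))
    })
    jsonlite::write_json(
      list(theta = pg$theta$theta, ci_low = pg$theta$ci_low,
           ci_high = pg$theta$ci_high, error_rate = pg$theta$error_rate,
           mu_per_generation = pg$mu_generation,
           mu_per_year = pg$mu_year),
      file.path(outdir, "popgen.json"), auto_unbox = TRUE, digits = NA)
    done("popgen")
  }

  track <- compute_windowed_tracks(ann_a)
  utils::write.table(track, file.path(outdir, "gene_density.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  written <- list.files(outdir, full.names = TRUE)
  manifest$outputs <- lapply(stats::setNames(written, basename(written)),
                             function(f) unname(tools::md5sum(f)))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(sim = sim, synteny = syn, ks = ks, families = fam,
                 popgen = pg, manifest = manifest))
}
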