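#' Run the simulate -> classify -> half-life pipeline end to end
#'
#' Generates a synthetic experiment, writes its genome/annotations/counts
#' to `out_dir`, classifies every simulated sequence against the
#' generated reference, runs the half-life analysis
#' (size normalization, T0 normalization, stable-set identification,
#' decay-factor correction, exponential fitting, class summaries), and
#' writes every result as TSV together with a JSON run manifest (package
#' version, seed, parameter echo, file checksums).
#'
#' @param out_dir Output directory (created if needed).
#' @param params A [sim_params()] object.
#' @param norm_method Passed to [size_normalize()].
#' @param cap_h Half-life cap; default the last timepoint.
#' @param noise Passed to [simulate_timecourse()].
#' @return Invisibly, a list with the in-memory results (`sim`,
#'   `classified`, `fits`, `summary`, `factors`) and `files` (named paths).
#' @export
run_pipeline <- function(out_dir, params = sim_params(),
                         norm_method = "rpm", cap_h = NULL, noise = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)

  sim <- simulate_experiment(params, noise = noise)
  Biostrings::writeXStringSet(sim$toy$genome, p("genome.fa"))
  write_models_bed(sim$toy$models, p("models.bed"))
  if (length(sim$toy$mirnas) > 0) {
    Biostrings::writeXStringSet(sim$toy$mirnas, p("mirnas.fa"))
  }
  write_truth_tsv(sim$truth, p("truth.tsv"))
  write_counts_tsv(sim$timecourse$counts, p("counts.tsv"),
                   samples = sim$timecourse$samples)
  write_sample_sheet(sim$timecourse$samples, p("samples.tsv"))

  ref <- build_reference(sim$toy$genome, sim$toy$models, sim$toy$mirnas)
  totals <- sim$timecourse$counts |>
    dplyr::group_by(.data$seq_id) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop")
  classified <- classify_reads(
    tibble::tibble(sequence = sim$truth$sequence,
                   count = totals$count[match(sim$truth$seq_id,
                                              totals$seq_id)]),
    ref)
  readr::write_tsv(
    classified |>
      dplyr::select("sequence", "count", "length", "class", "basis_locus",
                    "n_mappings", "min_mismatches", "cca_softclip"),
    p("classified.tsv"))

  norm <- size_normalize(sim$timecourse$counts, sim$timecourse$samples,
                         method = norm_method) |>
    t0_normalize()
  stable <- identify_stable(norm)
  factors <- decay_factors(norm, stable)
  dnorm <- apply_decay_normalization(norm, factors)
  fits <- fit_decay_all(dnorm, cap_h = cap_h)
  smry <- class_summaries(fits, norm)

  readr::write_tsv(tidy(fits), p("fits.tsv"))
  readr::write_tsv(smry, p("class_summary.tsv"))
  readr::write_tsv(factors, p("normalization_report.tsv"))

  files <- c(
    genome = p("genome.fa"), models = p("models.bed"),
    truth = p("truth.tsv"), counts = p("counts.tsv"),
    samples = p("samples.tsv"), classified = p("classified.tsv"),
    fits = p("fits.tsv"), class_summary = p("class_summary.tsv"),
    normalization_report = p("normalization_report.tsv")
  )
  manifest <- list(
    package = "trfdecay",
    version = as.character(utils::packageVersion("trfdecay")),
    created = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = params$seed,
    params = params[setdiff(names(params),
                            c("decay_rate_dist", "rip_enrichment_dist"))],
    decay_rate_dist = params$decay_rate_dist,
    rip_enrichment_dist = params$rip_enrichment_dist,
    norm_method = norm_method,
    cap_h = if (is.null(cap_h)) max(params$timepoints_h) else cap_h,
    md5 = as.list(tools::md5sum(unname(files)))
  )
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(sim = sim, classified = classified, fits = fits,
                 summary = smry, factors = factors,
                 files = c(files, manifest = p("manifest.json"))))
}
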