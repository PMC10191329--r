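#' Parameters for the synthetic small-RNA experiment generator
#'
#' Bundles every knob of the synthetic-data generator: how many donor loci
#' per fragment class, the actinomycin-D time-course design, per-class decay
#' rate distributions, the stable sub-population, sequencing depth and
#' negative-binomial overdispersion, spike-in controls, shrinkage of the
#' whole RNA pool under transcription shut-off, and per-class RIP enrichment
#' distributions.
#'
#' Defaults emulate a transcription shut-off experiment in a human cell
#' line: six timepoints (0--12 h) in triplicate; trailer fragments (tRF-1)
#' with a median half-life of 0.3 h and no stable sub-population; mature-end
#' fragments (tRF-5/tRF-3) with median half-life 6 h, a quarter of them
#' stable; miRNAs 90% stable with a 20 h residual median half-life; a
#' background (unannotated) RNA mass making up half of each library and
#' decaying at 0.08 per hour, which is what makes stable species *appear*
#' to increase in library-relative counts over the chase.
#'
#' Decay rates are drawn log-normally: `decay_rate_dist[[class]]` gives the
#' median rate k (per hour) and the log-scale sigma. A fraction
#' `stable_fraction[[class]]` of sequences instead gets k = 0 exactly.
#' RIP enrichment folds are drawn the same way from `rip_enrichment_dist`.
#'
#' @param seed Integer seed; the generator uses a single documented RNG
#'   stream derived from it (see Details of the individual generators).
#' @param n_genes_per_class Named integer vector, fragment class to number
#'   of donor genes. tRNA classes each get their own pre-tRNA locus; the
#'   miRNA entry sizes the miRNA reference set.
#' @param timepoints_h Non-negative hours, sorted ascending, containing 0.
#' @param replicates Libraries per timepoint (>= 1).
#' @param decay_rate_dist Named list, class -> c(median_k, sigma).
#' @param stable_fraction Named numeric in \[0,1\], class -> fraction with
#'   k = 0 exactly.
#' @param depth Expected total mapped reads per library (including the
#'   unannotated background mass).
#' @param nb_dispersion Negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2); must be > 0.
#' @param spike_in_n Number of exogenous spike-in species of fixed absolute
#'   abundance.
#' @param total_rna_decay_k Per-hour decay rate of the unannotated
#'   background RNA pool under transcription shut-off.
#' @param background_fraction Fraction of the t = 0 library made up by the
#'   background pool.
#' @param a0_meanlog,a0_sdlog Log-normal parameters of per-sequence initial
#'   absolute abundance.
#' @param rip_enrichment_dist Named list, class -> c(median_fold, sigma).
#' @param trf1_jitter_max Maximum 3'-end shortening (nt) of simulated
#'   tRF-1s, emulating variable Pol III termination. Set 0 to disable.
#'
#' @return A `trf_sim_params` list.
#' @export
#' @examples
#' p <- sim_params(seed = 7, replicates = 2, depth = 1e5)
#' p$timepoints_h
sim_params <- function(seed = 1L,
                       n_genes_per_class = c(
                         "tRF-1" = 40L, "tRF-5" = 30L, "tRF-3" = 30L,
                         "tRF-leader" = 8L, "intron-tRF" = 12L,
                         "misc-tRF" = 12L, "miRNA" = 60L
                       ),
                       timepoints_h = c(0, 1, 2, 4, 8, 12),
                       replicates = 3L,
                       decay_rate_dist = list(
                         "tRF-1"      = c(log(2) / 0.3, 0.35),
                         "tRF-5"      = c(log(2) / 6,   0.30),
                         "tRF-3"      = c(log(2) / 6,   0.30),
                         "tRF-leader" = c(log(2) / 1,   0.35),
                         "intron-tRF" = c(log(2) / 2,   0.35),
                         "misc-tRF"   = c(log(2) / 4,   0.35),
                         "miRNA"      = c(log(2) / 20,  0.30)
                       ),
                       stable_fraction = c(
                         "tRF-1" = 0, "tRF-5" = 0.25, "tRF-3" = 0.25,
                         "tRF-leader" = 0, "intron-tRF" = 0,
                         "misc-tRF" = 0.1, "miRNA" = 0.9
                       ),
                       depth = 5e5,
                       nb_dispersion = 0.05,
                       spike_in_n = 20L,
                       total_rna_decay_k = 0.08,
                       background_fraction = 0.5,
                       a0_meanlog = log(100),
                       a0_sdlog = 1,
                       rip_enrichment_dist = list(
                         "tRF-1"      = c(0.5, 0.25),
                         "tRF-5"      = c(1.0, 0.25),
                         "tRF-3"      = c(1.5, 0.25),
                         "tRF-leader" = c(0.5, 0.25),
                         "intron-tRF" = c(0.5, 0.25),
                         "misc-tRF"   = c(1.0, 0.25),
                         "miRNA"      = c(2.0, 0.25)
                       ),
                       trf1_jitter_max = 3L) {
  seed <- as.integer(seed)
  if (is.na(seed)) abort("`seed` must be an integer.")
  if (any(n_genes_per_class < 0) || sum(n_genes_per_class) == 0) {
    abort("`n_genes_per_class` must be non-negative with at least one class > 0.")
  }
  if (is.unsorted(timepoints_h, strictly = TRUE) || any(timepoints_h < 0)) {
    abort("`timepoints_h` must be strictly ascending and non-negative.")
  }
  if (timepoints_h[1] != 0) abort("`timepoints_h` must include 0.")
  if (replicates < 1) abort("`replicates` must be >= 1.")
  rates <- vapply(decay_rate_dist, `[`, numeric(1), 1)
  if (any(rates < 0) || any(vapply(decay_rate_dist, `[`, numeric(1), 2) < 0)) {
    abort("decay rates and sigmas must be >= 0.")
  }
  if (any(stable_fraction < 0 | stable_fraction > 1)) {
    abort("`stable_fraction` entries must lie in [0, 1].")
  }
  if (nb_dispersion <= 0) abort("`nb_dispersion` must be > 0.")
  if (depth <= 0) abort("`depth` must be > 0.")
  if (total_rna_decay_k < 0) abort("`total_rna_decay_k` must be >= 0.")
  if (background_fraction < 0 || background_fraction >= 1) {
    abort("`background_fraction` must lie in [0, 1).")
  }

  structure(
    list(
      seed = seed,
      n_genes_per_class = n_genes_per_class,
      timepoints_h = timepoints_h,
      replicates = as.integer(replicates),
      decay_rate_dist = decay_rate_dist,
      stable_fraction = stable_fraction,
      depth = depth,
      nb_dispersion = nb_dispersion,
      spike_in_n = as.integer(spike_in_n),
      total_rna_decay_k = total_rna_decay_k,
      background_fraction = background_fraction,
      a0_meanlog = a0_meanlog,
      a0_sdlog = a0_sdlog,
      rip_enrichment_dist = rip_enrichment_dist,
      trf1_jitter_max = as.integer(trf1_jitter_max)
    ),
    class = "trf_sim_params"
  )
}

#' @export
print.trf_sim_params <- function(x, ...) {
  cat("<trf_sim_params>\n")
  cat("  seed:", x$seed, "\n")
  cat("  genes/class:",
      paste(names(x$n_genes_per_class), x$n_genes_per_class,
            sep = "=", collapse = ", "), "\n")
  cat("  timepoints (h):", paste(x$timepoints_h, collapse = ", "),
      "x", x$replicates, "replicates\n")
  cat("  depth:", format(x$depth, big.mark = ","),
      " NB dispersion:", x$nb_dispersion,
      " spike-ins:", x$spike_in_n, "\n")
  cat("  background pool:", x$background_fraction, "of library, k =",
      x$total_rna_decay_k, "/h\n")
  invisible(x)
}
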