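# Shared machinery: expected library composition at a set of timepoints.
# Absolute abundances decay as A0 * exp(-k t); an unannotated background
# mass (a fixed fraction of the t = 0 pool) decays at total_rna_decay_k,
# so the denominator shrinks and stable species' shares rise.
expected_shares <- function(truth, params, timepoints_h,
                            enrichment = NULL) {
  A0 <- truth$true_a0
  k <- truth$true_k
  bg0 <- params$background_fraction / (1 - params$background_fraction) * sum(A0)
  abund <- outer(A0, timepoints_h, function(a, t) a) *
    exp(-outer(k, timepoints_h))
  if (!is.null(enrichment)) abund <- abund * enrichment
  bg <- bg0 * exp(-params$total_rna_decay_k * timepoints_h)
  total <- colSums(abund) + bg
  list(share = sweep(abund, 2, total, "/"), bg_share = bg / total)
}

nb_draw <- function(mu, dispersion, noise) {
  if (!noise) return(mu)
  rnbinom(length(mu), mu = mu, size = 1 / dispersion)
}

#' Simulate an actinomycin-D time-course count matrix
#'
#' Realises sequencing libraries from a ground-truth table: the absolute
#' abundance of sequence i at time t is `A0_i * exp(-k_i * t)`; expected
#' library counts are `depth` times the sequence's share of the total RNA
#' pool at t (annotated species plus a decaying unannotated background
#' mass), drawn negative-binomially per sequence per library. Spike-in
#' species keep constant absolute abundance, so their library-relative
#' counts rise as the pool shrinks -- the compositional artifact that
#' decay-profile normalization later corrects. The per-library
#' `total_count` includes the realised background mass, so total mapped
#' reads fluctuate around `depth`.
#'
#' RNG: seeds at `seed` (default `params$seed + 2`); libraries are drawn
#' in timepoint-major, replicate-minor order, annotated rows first, then
#' the background mass.
#'
#' @param truth Ground-truth tibble from [simulate_truth()] (or any tibble
#'   with `seq_id`, `class`, `true_k`, `true_a0`, `is_spike`).
#' @param params A [sim_params()] object.
#' @param noise If `FALSE`, counts are the exact negative-binomial means
#'   (no sampling); useful for closed-form checks.
#' @param seed Integer seed for this draw.
#' @return A `trf_timecourse` list: `counts` (long tibble: `seq_id`,
#'   `class`, `is_spike`, `library`, `timepoint_h`, `replicate`, `count`)
#'   and `samples` (tibble: `library`, `timepoint_h`, `replicate`,
#'   `condition`, `fraction`, `total_count`).
#' @export
#' @examples
#' p <- sim_params(seed = 1, n_genes_per_class = c("tRF-1" = 2, "miRNA" = 3))
#' tc <- simulate_timecourse(simulate_truth(make_toy_genome(p), p), p)
#' head(tc$counts)
simulate_timecourse <- function(truth, params, noise = TRUE,
                                seed = params$seed + 2L) {
  stopifnot(inherits(params, "trf_sim_params"))
  if (params$nb_dispersion <= 0) abort("`nb_dispersion` must be > 0.")
  if (params$timepoints_h[1] != 0) abort("`timepoints_h` must include 0.")
  set.seed(seed)

  sh <- expected_shares(truth, params, params$timepoints_h)
  tp <- params$timepoints_h
  out <- vector("list", length(tp) * params$replicates)
  samples <- vector("list", length(out))
  idx <- 1L
  for (j in seq_along(tp)) {
    for (r in seq_len(params$replicates)) {
      lib <- sprintf("t%g_r%d", tp[j], r)
      cnt <- nb_draw(params$depth * sh$share[, j], params$nb_dispersion, noise)
      bg_cnt <- nb_draw(params$depth * sh$bg_share[j], params$nb_dispersion,
                        noise)
      out[[idx]] <- tibble::tibble(
        seq_id = truth$seq_id, class = truth$class, is_spike = truth$is_spike,
        library = lib, timepoint_h = tp[j], replicate = r, count = cnt
      )
      samples[[idx]] <- tibble::tibble(
        library = lib, timepoint_h = tp[j], replicate = r,
        condition = "actD", fraction = "total",
        total_count = sum(cnt) + bg_cnt
      )
      idx <- idx + 1L
    }
  }
  structure(
    list(counts = dplyr::bind_rows(out), samples = dplyr::bind_rows(samples)),
    class = "trf_timecourse"
  )
}

#' @export
print.trf_timecourse <- function(x, ...) {
  cat("<trf_timecourse>", dplyr::n_distinct(x$counts$seq_id), "sequences x",
      nrow(x$samples), "libraries\n")
  invisible(x)
}

#' Simulate a matched RIP / input library pair
#'
#' Input libraries realise the steady-state (t = 0) composition; RIP
#' libraries multiply each sequence's absolute abundance by its true
#' enrichment fold before renormalising to library depth, emulating an
#' Argonaute immunoprecipitation sequenced to the same depth as its input.
#' Spike-ins and the background pool carry enrichment 1, so spike-in-based
#' normalization recovers the configured folds on the absolute scale.
#'
#' @param truth Ground-truth tibble (see [simulate_truth()]).
#' @param params A [sim_params()] object.
#' @param enrichment Optional numeric vector overriding
#'   `truth$true_enrichment` (same order as `truth`).
#' @param condition Condition label recorded in the sample sheet.
#' @param noise,seed As in [simulate_timecourse()]; the default seed is
#'   `params$seed + 11`, so distinct conditions should pass distinct seeds.
#' @return A `trf_timecourse` list whose `samples` carry
#'   `fraction` in `c("input", "rip")` and the given `condition`.
#' @export
#' @examples
#' p <- sim_params(seed = 1, n_genes_per_class = c("tRF-1" = 2, "miRNA" = 3))
#' truth <- simulate_truth(make_toy_genome(p), p)
#' rip <- simulate_rip_pair(truth, p)
#' rip$samples
simulate_rip_pair <- function(truth, params, enrichment = NULL,
                              condition = "control", noise = TRUE,
                              seed = params$seed + 11L) {
  stopifnot(inherits(params, "trf_sim_params"))
  if (params$nb_dispersion <= 0) abort("`nb_dispersion` must be > 0.")
  enr <- if (is.null(enrichment)) truth$true_enrichment else enrichment
  if (length(enr) != nrow(truth) || any(!is.finite(enr)) || any(enr < 0)) {
    abort("`enrichment` must be a finite non-negative vector, one per sequence.")
  }
  set.seed(seed)

  sh_in <- expected_shares(truth, params, 0)
  sh_rip <- expected_shares(truth, params, 0, enrichment = enr)
  out <- list(); samples <- list(); idx <- 1L
  for (frac in c("input", "rip")) {
    sh <- if (frac == "input") sh_in else sh_rip
    for (r in seq_len(params$replicates)) {
      lib <- sprintf("%s_%s_r%d", condition, frac, r)
      cnt <- nb_draw(params$depth * sh$share[, 1], params$nb_dispersion, noise)
      bg_cnt <- nb_draw(params$depth * sh$bg_share[1], params$nb_dispersion,
                        noise)
      out[[idx]] <- tibble::tibble(
        seq_id = truth$seq_id, class = truth$class, is_spike = truth$is_spike,
        library = lib, timepoint_h = 0, replicate = r, count = cnt
      )
      samples[[idx]] <- tibble::tibble(
        library = lib, timepoint_h = 0, replicate = r,
        condition = condition, fraction = frac,
        total_count = sum(cnt) + bg_cnt
      )
      idx <- idx + 1L
    }
  }
  structure(
    list(counts = dplyr::bind_rows(out), samples = dplyr::bind_rows(samples)),
    class = "trf_timecourse"
  )
}

#' Run the whole generator: genome, truth, and time-course counts
#'
#' Convenience wrapper chaining [make_toy_genome()], [simulate_truth()] and
#' [simulate_timecourse()] under one parameter set.
#'
#' @param params A [sim_params()] object.
#' @param noise Passed to [simulate_timecourse()].
#' @return A `trf_sim` list: `toy` (genome + models + miRNAs), `truth`,
#'   and `timecourse`.
#' @export
#' @examples
#' sim <- simulate_experiment(sim_params(
#'   seed = 1, n_genes_per_class = c("tRF-1" = 2, "miRNA" = 3)))
#' names(sim)
simulate_experiment <- function(params, noise = TRUE) {
  toy <- make_toy_genome(params)
  truth <- simulate_truth(toy, params)
  tc <- simulate_timecourse(truth, params, noise = noise)
  structure(list(toy = toy, truth = truth, timecourse = tc),
            class = "trf_sim")
}
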