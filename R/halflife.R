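#' Library-size normalization of a long count table
#'
#' `rpm` scales each library to reads per million using the per-library
#' total mapped count (taken from `samples$total_count` when available,
#' else the column sum). `spike_in` divides by the library's spike-in
#' count sum and rescales by the mean spike-in sum across libraries, so
#' counts are on an absolute scale anchored by the exogenous controls.
#'
#' @param counts Long tibble with at least `seq_id`, `library`, `count`
#'   (as in `simulate_timecourse()$counts`).
#' @param samples Optional sample sheet with `library` and `total_count`.
#' @param method `"rpm"` or `"spike_in"`.
#' @param spike_ids Sequence ids of spike-ins; defaults to rows flagged
#'   `is_spike` when that column is present.
#' @return The input tibble with a `norm` column added.
#' @export
#' @examples
#' tc <- tibble::tibble(seq_id = "s1", library = "L1", count = 4)
#' size_normalize(tc, tibble::tibble(library = "L1", total_count = 2e6))
size_normalize <- function(counts, samples = NULL,
                           method = c("rpm", "spike_in"),
                           spike_ids = NULL) {
  method <- match.arg(method)
  counts <- tibble::as_tibble(counts)
  if (method == "rpm") {
    if (!is.null(samples) && "total_count" %in% names(samples)) {
      tot <- samples |> dplyr::select("library", "total_count")
    } else {
      tot <- counts |>
        dplyr::group_by(.data$library) |>
        dplyr::summarise(total_count = sum(.data$count), .groups = "drop")
    }
    bad <- tot$library[tot$total_count <= 0]
    if (length(bad) > 0) {
      abort(paste0("Zero library total in: ", paste(bad, collapse = ", ")))
    }
    counts |>
      dplyr::left_join(tot, by = "library") |>
      dplyr::mutate(norm = .data$count * 1e6 / .data$total_count) |>
      dplyr::select(-"total_count")
  } else {
    if (is.null(spike_ids)) {
      if (!"is_spike" %in% names(counts)) {
        abort("spike_in mode needs `spike_ids` or an `is_spike` column.")
      }
      spike_ids <- unique(counts$seq_id[counts$is_spike])
    }
    sp <- counts |>
      dplyr::filter(.data$seq_id %in% spike_ids) |>
      dplyr::group_by(.data$library) |>
      dplyr::summarise(spike_sum = sum(.data$count), .groups = "drop")
    missing <- setdiff(unique(counts$library), sp$library)
    bad <- c(missing, sp$library[sp$spike_sum <= 0])
    if (length(bad) > 0) {
      abort(paste0("Zero spike-in sum in: ", paste(bad, collapse = ", ")))
    }
    counts |>
      dplyr::left_join(sp, by = "library") |>
      dplyr::mutate(norm = .data$count / .data$spike_sum *
                      mean(sp$spike_sum)) |>
      dplyr::select(-"spike_sum")
  }
}

#' Normalize each sequence to its mean t = 0 level
#'
#' Divides every normalized value by the sequence's mean normalized count
#' across the t = 0 replicates, so each retained sequence's t = 0 mean is
#' exactly 1. Sequences with a zero (or absent) t = 0 mean are excluded;
#' their ids are recorded in the `"excluded"` attribute and reported.
#'
#' @param counts Long tibble with `seq_id`, `timepoint_h` and `norm`
#'   (see [size_normalize()]).
#' @return The tibble with a `rel_t0` column, t0-absent sequences removed.
#' @export
t0_normalize <- function(counts) {
  if (!"norm" %in% names(counts)) {
    abort("Run size_normalize() first: `norm` column missing.")
  }
  t0 <- counts |>
    dplyr::filter(.data$timepoint_h == 0) |>
    dplyr::group_by(.data$seq_id) |>
    dplyr::summarise(t0_mean = mean(.data$norm), .groups = "drop")
  excluded <- union(
    t0$seq_id[t0$t0_mean <= 0],
    setdiff(unique(counts$seq_id), t0$seq_id)
  )
  if (length(excluded) > 0) {
    message(length(excluded),
            " sequence(s) without signal at t = 0 excluded from ",
            "T0 normalization.")
  }
  out <- counts |>
    dplyr::inner_join(dplyr::filter(t0, .data$t0_mean > 0), by = "seq_id") |>
    dplyr::mutate(rel_t0 = .data$norm / .data$t0_mean) |>
    dplyr::select(-"t0_mean")
  attr(out, "excluded") <- excluded
  out
}

#' Identify the stable small-RNA set
#'
#' A sequence is called stable when its T0-relative values *apparently
#' increase* over the chase -- operationalised as a positive ordinary
#' least-squares slope against time over all replicate points -- and it is
#' detected (raw count > 0) in at least one library of every timepoint.
#' Stable species appear to increase because the total RNA pool shrinks
#' under transcription shut-off while their absolute abundance does not.
#'
#' @param counts Long tibble with `seq_id`, `timepoint_h`, `count` and
#'   `rel_t0` (see [t0_normalize()]).
#' @return Tibble: `seq_id`, `slope`, `detected_all_timepoints`, `stable`.
#'   Errors if the stable set comes out empty (decay normalization would
#'   be undefined).
#' @export
identify_stable <- function(counts) {
  if (!"rel_t0" %in% names(counts)) {
    abort("Run t0_normalize() first: `rel_t0` column missing.")
  }
  if (dplyr::n_distinct(counts$timepoint_h) < 2) {
    abort("At least two timepoints are required.")
  }
  out <- counts |>
    dplyr::group_by(.data$seq_id) |>
    dplyr::summarise(
      slope = stats::coef(lm(rel_t0 ~ timepoint_h,
                             data = dplyr::pick(dplyr::everything())))[2],
      detected_all_timepoints = all(tapply(.data$count, .data$timepoint_h,
                                           function(x) any(x > 0))),
      .groups = "drop"
    ) |>
    dplyr::mutate(stable = .data$slope > 0 & .data$detected_all_timepoints)
  if (!any(out$stable)) {
    abort(paste0(
      "No stable sequences found: decay-profile normalization is ",
      "undefined. Check that the input spans enough timepoints or add ",
      "spike-ins."))
  }
  out
}

#' Per-timepoint decay factors from the stable set
#'
#' The decay factor at timepoint t is the arithmetic mean, over stable
#' sequences, of each sequence's mean T0-relative value at t. By
#' construction the factor at t = 0 is exactly 1.
#'
#' @param counts Long tibble with `rel_t0` (see [t0_normalize()]).
#' @param stable Stable-set tibble from [identify_stable()], or a
#'   character vector of stable `seq_id`s.
#' @return Tibble: `timepoint_h`, `decay_factor`, `n_stable`.
#' @export
decay_factors <- function(counts, stable) {
  ids <- if (is.data.frame(stable)) stable$seq_id[stable$stable] else stable
  if (length(ids) == 0) abort("Stable set is empty.")
  counts |>
    dplyr::filter(.data$seq_id %in% ids) |>
    dplyr::group_by(.data$seq_id, .data$timepoint_h) |>
    dplyr::summarise(seq_mean = mean(.data$rel_t0), .groups = "drop") |>
    dplyr::group_by(.data$timepoint_h) |>
    dplyr::summarise(decay_factor = mean(.data$seq_mean),
                     n_stable = dplyr::n(), .groups = "drop")
}

#' Divide T0-relative values by their timepoint's decay factor
#'
#' After this correction the stable-set mean trajectory equals 1 at every
#' timepoint (to machine precision), and unstable sequences' trajectories
#' follow their true exponential decay in expectation.
#'
#' @param counts Long tibble with `rel_t0`.
#' @param factors Tibble from [decay_factors()].
#' @return The tibble with a `decay_norm` column.
#' @export
apply_decay_normalization <- function(counts, factors) {
  if (any(factors$decay_factor <= 0)) {
    abort("Decay factors must be positive.")
  }
  counts |>
    dplyr::left_join(dplyr::select(factors, "timepoint_h", "decay_factor"),
                     by = "timepoint_h") |>
    dplyr::mutate(decay_norm = .data$rel_t0 / .data$decay_factor) |>
    dplyr::select(-"decay_factor")
}

#' Expression filtering and the highly-expressed flag
#'
#' Removes sequences with fewer than `min_total` raw reads summed across
#' all libraries, and flags a sequence highly expressed when any library
#' reaches `high_threshold` normalized counts (inclusive).
#'
#' @param counts Long tibble with `seq_id`, `count` and (for the flag)
#'   `norm`.
#' @param min_total Minimum summed raw count (default 10).
#' @param high_threshold Normalized-count threshold (default 50).
#' @return The filtered tibble with a `highly_expressed` column.
#' @export
expression_filters <- function(counts, min_total = 10, high_threshold = 50) {
  if (nrow(counts) == 0) {
    return(dplyr::mutate(tibble::as_tibble(counts),
                         highly_expressed = logical(0)))
  }
  per_seq <- counts |>
    dplyr::group_by(.data$seq_id) |>
    dplyr::summarise(
      total_raw = sum(.data$count),
      highly_expressed = if ("norm" %in% names(counts))
        any(.data$norm >= high_threshold) else any(.data$count >= high_threshold),
      .groups = "drop"
    )
  counts |>
    dplyr::inner_join(
      per_seq |> dplyr::filter(.data$total_raw >= min_total) |>
        dplyr::select("seq_id", "highly_expressed"),
      by = "seq_id"
    )
}

#' Class-level turnover summaries
#'
#' Summarises fitted half-lives and expression per class: the number of
#' sequences, the median half-life (capped values enter as the cap), the
#' median normalized expression at t = 0, and the median log2 fold change
#' between two requested timepoints, computed per sequence as
#' `log2((mean norm at t_b + pc) / (mean norm at t_a + pc))`.
#'
#' @param fits A `trf_decay_fits` tibble from [fit_decay_all()] (must
#'   carry a `class` column).
#' @param counts Long tibble with `seq_id`, `timepoint_h` and `norm`.
#' @param t_a,t_b Timepoints (hours) compared by the fold change.
#' @param pseudocount Added to both means (normalized-count units).
#' @return Tibble: `class`, `n`, `median_half_life_h`, `median_expr_t0`,
#'   `median_log2fc`. Classes with zero members are omitted with a note.
#' @export
class_summaries <- function(fits, counts, t_a = 0, t_b = 1,
                            pseudocount = 0.5) {
  if (nrow(fits) == 0) abort("`fits` is empty.")
  if (!"class" %in% names(fits)) abort("`fits` must carry a `class` column.")
  expr <- counts |>
    dplyr::filter(.data$timepoint_h %in% c(t_a, t_b)) |>
    dplyr::group_by(.data$seq_id, .data$timepoint_h) |>
    dplyr::summarise(m = mean(.data$norm), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "timepoint_h", values_from = "m",
                       names_prefix = "t_") |>
    dplyr::rename(expr_a = paste0("t_", t_a), expr_b = paste0("t_", t_b)) |>
    dplyr::mutate(log2fc = log2((.data$expr_b + pseudocount) /
                                  (.data$expr_a + pseudocount)))
  out <- fits |>
    tibble::as_tibble() |>
    dplyr::inner_join(expr, by = "seq_id") |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(
      n = dplyr::n(),
      median_half_life_h = median(.data$half_life_h, na.rm = TRUE),
      median_expr_t0 = median(.data$expr_a),
      median_log2fc = median(.data$log2fc),
      .groups = "drop"
    )
  absent <- setdiff(unique(fits$class), out$class)
  if (length(absent) > 0) {
    message("Classes with no summarisable members omitted: ",
            paste(absent, collapse = ", "))
  }
  out
}
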