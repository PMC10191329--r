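#' Per-sequence RIP / input fold enrichment
#'
#' For every sequence and condition computes
#' `fold = (mean normalized RIP count + pc) / (mean normalized input
#' count + pc)`, the descriptive statistic behind statements like "0.5
#' fold enrichment in control, 1.6 fold upon depletion". Replicates enter
#' as means per fraction.
#'
#' @param counts Long tibble with `seq_id`, `library` and `norm`
#'   (see [size_normalize()]).
#' @param samples Sample sheet with `library`, `condition` and `fraction`
#'   (values `input` / `rip`).
#' @param pseudocount Added to both means (normalized-count units).
#' @return Tibble: `seq_id`, `condition`, `mean_input`, `mean_rip`,
#'   `fold` (plus `class` when present in `counts`).
#' @export
fold_enrichment <- function(counts, samples, pseudocount = 0.5) {
  if (!"norm" %in% names(counts)) {
    abort("Run size_normalize() first: `norm` column missing.")
  }
  des <- samples |> dplyr::select("library", "condition", "fraction")
  if (!all(c("input", "rip") %in% des$fraction)) {
    abort("`samples` must contain both input and rip libraries.")
  }
  counts |>
    dplyr::inner_join(des, by = "library") |>
    dplyr::filter(.data$fraction %in% c("input", "rip")) |>
    dplyr::group_by(dplyr::across(dplyr::any_of(c("seq_id", "class"))),
                    .data$condition, .data$fraction) |>
    dplyr::summarise(m = mean(.data$norm), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "fraction", values_from = "m",
                       names_prefix = "mean_") |>
    dplyr::mutate(fold = (.data$mean_rip + pseudocount) /
                    (.data$mean_input + pseudocount))
}

#' Class-wise shift of RIP association between two conditions
#'
#' Per sequence of each class computes
#' `log2((mean norm in condition_b + pc) / (mean norm in condition_a +
#' pc))` within the chosen fraction, and summarises the median and count
#' per class. Effect sizes only; no significance testing.
#'
#' @param counts Long tibble with `seq_id`, `class`, `library`, `norm`.
#' @param samples Sample sheet with `library`, `condition`, `fraction`.
#' @param condition_a,condition_b Condition labels (a = baseline).
#' @param fraction Which fraction to compare (default `"rip"`).
#' @param pseudocount Added to both means.
#' @return A `trf_class_shift` list: `summary` (tibble `class`, `n`,
#'   `median_log2fc`) and `per_sequence` (tibble with per-sequence
#'   log2 fold changes).
#' @export
class_shift <- function(counts, samples, condition_a, condition_b,
                        fraction = "rip", pseudocount = 0.5) {
  des <- samples |> dplyr::select("library", "condition", "fraction")
  have <- unique(des$condition)
  if (!all(c(condition_a, condition_b) %in% have)) {
    abort("Both conditions must be present in the sample sheet.")
  }
  per_seq <- counts |>
    dplyr::inner_join(des, by = "library") |>
    dplyr::filter(.data$fraction == !!fraction,
                  .data$condition %in% c(condition_a, condition_b)) |>
    dplyr::group_by(dplyr::across(dplyr::any_of(c("seq_id", "class"))),
                    .data$condition) |>
    dplyr::summarise(m = mean(.data$norm), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "m") |>
    dplyr::mutate(log2fc = log2((.data[[condition_b]] + pseudocount) /
                                  (.data[[condition_a]] + pseudocount)))
  summary <- per_seq |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(n = dplyr::n(), median_log2fc = median(.data$log2fc),
                     .groups = "drop")
  structure(list(summary = summary, per_sequence = per_seq),
            class = "trf_class_shift")
}

#' @export
print.trf_class_shift <- function(x, ...) {
  cat("<trf_class_shift>\n")
  print(x$summary)
  invisible(x)
}

#' Total normalized abundance of a class per condition
#'
#' Sum over sequences of the class of their mean normalized count in the
#' chosen fraction, per condition. Sums are additive over disjoint class
#' partitions.
#'
#' @param counts Long tibble with `seq_id`, `class`, `library`, `norm`.
#' @param samples Sample sheet with `library`, `condition`, `fraction`.
#' @param fraction `"input"` or `"rip"`.
#' @param classes Class labels to report (default: all present).
#' @return Tibble: `condition`, `class`, `total_norm`.
#' @export
total_class_abundance <- function(counts, samples, fraction,
                                  classes = NULL) {
  if (!fraction %in% c("input", "rip", "total")) {
    abort("`fraction` must be one of input, rip, total.")
  }
  des <- samples |> dplyr::select("library", "condition", "fraction")
  df <- counts |>
    dplyr::inner_join(des, by = "library") |>
    dplyr::filter(.data$fraction == !!fraction)
  if (!is.null(classes)) df <- dplyr::filter(df, .data$class %in% classes)
  df |>
    dplyr::group_by(.data$condition, .data$class, .data$seq_id) |>
    dplyr::summarise(m = mean(.data$norm), .groups = "drop") |>
    dplyr::group_by(.data$condition, .data$class) |>
    dplyr::summarise(total_norm = sum(.data$m), .groups = "drop")
}
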