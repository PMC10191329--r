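# Plotting surface: thin ggplot2 wrappers over the result tibbles.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Half-life distribution by class
#'
#' Boxplot of fitted half-lives per class (capped values sit at the cap),
#' mirroring the usual presentation of turnover by small-RNA class.
#'
#' @param object A `trf_decay_fits` tibble from [fit_decay_all()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.trf_decay_fits <- function(object, ...) {
  df <- tidy(object)
  if (!"class" %in% names(df)) df$class <- "all"
  df <- df[!is.na(df$half_life_h), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$half_life_h)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.4, size = 0.8) +
    ggplot2::labs(x = NULL, y = "half-life (h)") +
    ggplot2::theme_minimal()
}

#' Metagene coverage profile
#'
#' @param object A `trf_metagene_profile` from [compute_profile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.trf_metagene_profile <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$offset, y = .data$coverage)) +
    ggplot2::geom_area(alpha = 0.4) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0.5, linetype = "dashed") +
    ggplot2::labs(x = sprintf("offset from %s anchor (nt)",
                              attr(object, "anchor")),
                  y = "mean coverage per gene") +
    ggplot2::theme_minimal()
}

#' Class-wise RIP shift boxplot
#'
#' @param object A `trf_class_shift` from [class_shift()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.trf_class_shift <- function(object, ...) {
  ggplot2::ggplot(object$per_sequence,
                  ggplot2::aes(x = .data$class, y = .data$log2fc)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.4, size = 0.8) +
    ggplot2::labs(x = NULL, y = "log2 fold change (RIP)") +
    ggplot2::theme_minimal()
}

#' Decay trajectories with fitted curves for selected sequences
#'
#' @param counts Long tibble with `seq_id`, `timepoint_h` and the value
#'   column used for fitting.
#' @param fits A `trf_decay_fits` tibble.
#' @param seq_ids Sequences to draw.
#' @param value Value column name (default `"decay_norm"`).
#' @return A ggplot object.
#' @export
plot_trajectories <- function(counts, fits, seq_ids,
                              value = "decay_norm") {
  df <- counts |>
    dplyr::filter(.data$seq_id %in% seq_ids) |>
    dplyr::select("seq_id", "timepoint_h", value = dplyr::all_of(value))
  fd <- tidy(fits) |> dplyr::filter(.data$seq_id %in% seq_ids)
  tt <- seq(0, max(df$timepoint_h), length.out = 100)
  curves <- fd |>
    dplyr::rowwise() |>
    dplyr::reframe(seq_id = .data$seq_id, timepoint_h = tt,
                   value = .data$a0 * exp(-.data$k * tt))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$timepoint_h, y = .data$value)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curves, colour = "steelblue") +
    ggplot2::facet_wrap(~seq_id, scales = "free_y") +
    ggplot2::labs(x = "time after transcription shut-off (h)",
                  y = "decay-normalized abundance") +
    ggplot2::theme_minimal()
}
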