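#' Fit first-order exponential decay to one trajectory
#'
#' Fits `A(t) = A0 * exp(-k * t)` by nonlinear least squares over
#' `A0 > 0`, `k >= 0`, initialised from a log-linear regression on the
#' positive values (zeros stay in the least-squares objective, they are
#' only excluded from the initialiser). The half-life is `ln(2) / k`;
#' when `k = 0` or the implied half-life exceeds `cap_h` (by default the
#' last observed timepoint, mirroring a 12 h chase) it is reported as the
#' cap with `capped = TRUE`.
#'
#' @param t Numeric hours (replicate points may repeat timepoints).
#' @param value Abundances (typically decay-normalized T0-relative
#'   counts, so A0 is near 1).
#' @param cap_h Half-life reporting cap in hours.
#' @param min_points Minimum points required; fewer gives a skipped row.
#' @return One-row tibble: `a0`, `k`, `half_life_h`, `capped`, `rss`,
#'   `n_points`, `status` (`"ok"`, `"fallback_loglin"` on
#'   non-convergence, `"skipped_few_points"`).
#' @export
#' @examples
#' fit_decay(c(0, 1, 2), c(100, 50, 25))  # k = ln 2, half-life 1 h
fit_decay <- function(t, value, cap_h = max(t), min_points = 3L) {
  stopifnot(length(t) == length(value))
  ok <- is.finite(t) & is.finite(value)
  t <- t[ok]; value <- value[ok]
  n <- length(t)
  if (n < min_points || dplyr::n_distinct(t) < 2) {
    return(tibble::tibble(
      a0 = NA_real_, k = NA_real_, half_life_h = NA_real_, capped = NA,
      rss = NA_real_, n_points = n, status = "skipped_few_points"
    ))
  }
  pos <- value > 0
  if (sum(pos) >= 2 && dplyr::n_distinct(t[pos]) >= 2) {
    init <- unname(stats::coef(lm(log(value[pos]) ~ t[pos])))
    a0_0 <- exp(init[1])
    k0 <- max(-init[2], 0)
  } else {
    a0_0 <- max(mean(value), 1e-8)
    k0 <- 0
  }
  sse <- function(p) sum((value - p[1] * exp(-p[2] * t))^2)
  opt <- tryCatch(
    optim(c(a0_0, k0), sse, method = "L-BFGS-B",
          lower = c(1e-12, 0), upper = c(Inf, 1e4),
          control = list(factr = 1e3, maxit = 500)),
    error = function(e) NULL
  )
  if (is.null(opt) || opt$convergence != 0) {
    a0 <- a0_0; k <- k0; rss <- sse(c(a0, k)); status <- "fallback_loglin"
  } else {
    a0 <- unname(opt$par[1]); k <- unname(opt$par[2]); rss <- opt$value
    status <- "ok"
  }
  if (k < 1e-12) k <- 0   # numerically flat trajectories report k = 0 exactly
  hl <- if (k > 0) log(2) / k else Inf
  capped <- !is.finite(hl) || hl > cap_h
  tibble::tibble(
    a0 = a0, k = k, half_life_h = min(hl, cap_h), capped = capped,
    rss = rss, n_points = n, status = status
  )
}

#' Fit exponential decay per sequence across a normalized time course
#'
#' Applies [fit_decay()] to every sequence's trajectory of
#' decay-normalized values. Replicates enter as independent points by
#' default; `replicate_mode = "mean"` first averages replicates per
#' timepoint.
#'
#' @param counts Long tibble with `seq_id`, `timepoint_h`, and the value
#'   column (optionally `class`, carried through).
#' @param value Name of the value column (default `"decay_norm"`).
#' @param cap_h Half-life cap; defaults to the largest observed timepoint.
#' @param replicate_mode `"points"` or `"mean"`.
#' @param min_points Passed to [fit_decay()].
#' @return A `trf_decay_fits` tibble, one row per sequence, with the
#'   [fit_decay()] columns plus `seq_id` (and `class` if present). The
#'   cap is stored in the `"cap_h"` attribute.
#' @export
fit_decay_all <- function(counts, value = "decay_norm", cap_h = NULL,
                          replicate_mode = c("points", "mean"),
                          min_points = 3L) {
  replicate_mode <- match.arg(replicate_mode)
  if (!value %in% names(counts)) {
    abort(paste0("Column `", value, "` not found."))
  }
  if (is.null(cap_h)) cap_h <- max(counts$timepoint_h)
  df <- counts |>
    dplyr::select("seq_id", dplyr::any_of("class"), "timepoint_h",
                  value = dplyr::all_of(value))
  if (replicate_mode == "mean") {
    df <- df |>
      dplyr::group_by(dplyr::across(dplyr::any_of(c("seq_id", "class"))),
                      .data$timepoint_h) |>
      dplyr::summarise(value = mean(.data$value), .groups = "drop")
  }
  out <- df |>
    dplyr::group_by(dplyr::across(dplyr::any_of(c("seq_id", "class")))) |>
    dplyr::group_modify(~ fit_decay(.x$timepoint_h, .x$value, cap_h = cap_h,
                                    min_points = min_points)) |>
    dplyr::ungroup()
  n_skip <- sum(out$status == "skipped_few_points")
  if (n_skip > 0) {
    message(n_skip, " sequence(s) skipped: fewer than ", min_points,
            " usable points.")
  }
  attr(out, "cap_h") <- cap_h
  class(out) <- c("trf_decay_fits", class(out))
  out
}

#' @export
print.trf_decay_fits <- function(x, ...) {
  cat("<trf_decay_fits> ", nrow(x), " sequences; cap ",
      attr(x, "cap_h"), " h; ", sum(x$capped, na.rm = TRUE),
      " capped\n", sep = "")
  NextMethod()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-sequence decay-fit table
#'
#' @param x A `trf_decay_fits` object.
#' @param ... Unused.
#' @return A plain tibble of the per-sequence fits.
#' @export
tidy.trf_decay_fits <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "trf_decay_fits")
  tibble::as_tibble(out)
}

#' One-row summary of a decay-fit set
#'
#' @param x A `trf_decay_fits` object.
#' @param ... Unused.
#' @return Tibble with sequence counts, the cap, and median k/half-life.
#' @export
glance.trf_decay_fits <- function(x, ...) {
  tibble::tibble(
    n_sequences = nrow(x),
    n_fit = sum(x$status != "skipped_few_points"),
    n_capped = sum(x$capped, na.rm = TRUE),
    cap_h = attr(x, "cap_h"),
    median_k = median(x$k, na.rm = TRUE),
    median_half_life_h = median(x$half_life_h, na.rm = TRUE)
  )
}
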