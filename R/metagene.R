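#' Strand-aware metagene coverage profile anchored at tRNA boundaries
#'
#' Aggregates read coverage around a common anchor across a set of tRNA
#' gene models, in transcript orientation (minus-strand genes flipped).
#' Offsets follow the convention `+1` = first base downstream of the
#' anchor, `-1` = last base upstream; there is no offset 0. Anchors:
#' `"mature_3p"` (the 3' end of the mature tRNA span, so the trailer is
#' offsets `+1 ...`) or `"gene_5p"` (the locus 5' end). Every base
#' covered by a read contributes the read's count to that offset
#' (`mode = "coverage"`); `mode = "end5"` counts only the read's 5' end,
#' for eCLIP-style data. Windows truncated by chromosome bounds keep the
#' in-bounds part. Only reads on the gene's strand contribute.
#'
#' @param reads Tibble of read intervals: `chrom`, `start`, `end`
#'   (0-based half-open), `strand`, `count` (see [reads_to_intervals()]).
#' @param models Gene-model tibble.
#' @param anchor `"mature_3p"` or `"gene_5p"`.
#' @param upstream,downstream Window sizes in nt (>= 1 each side
#'   recommended; `upstream = 0` is allowed).
#' @param mode `"coverage"` or `"end5"`.
#' @param per_million Optional total mapped read count; when given,
#'   values are additionally scaled to reads per million.
#' @return A `trf_metagene_profile` tibble: `offset`, `coverage` (mean
#'   per gene), with anchor/window metadata in attributes.
#' @export
compute_profile <- function(reads, models,
                            anchor = c("mature_3p", "gene_5p"),
                            upstream = 10L, downstream = 100L,
                            mode = c("coverage", "end5"),
                            per_million = NULL) {
  anchor <- match.arg(anchor)
  mode <- match.arg(mode)
  if (nrow(models) == 0) abort("No gene models supplied.")
  if (downstream < 1 || upstream < 0) {
    abort("Window must have downstream >= 1 and upstream >= 0.")
  }
  offsets <- c(if (upstream > 0) -(upstream:1), seq_len(downstream))
  acc <- stats::setNames(numeric(length(offsets)), offsets)

  for (i in seq_len(nrow(models))) {
    g <- models[i, ]
    # Genomic coordinate (0-based) of the anchor boundary: the first base
    # downstream of the anchor in transcript orientation.
    if (anchor == "mature_3p") {
      if (g$strand == "+") {
        first_down <- g$start + g$leader_len + g$mature_len + g$intron_len
        step <- 1L
      } else {
        first_down <- g$end - 1L - (g$leader_len + g$mature_len + g$intron_len)
        step <- -1L
      }
    } else {  # gene_5p
      if (g$strand == "+") { first_down <- g$start; step <- 1L }
      else { first_down <- g$end - 1L; step <- -1L }
    }
    # offsets > 0: first_down + step*(offset-1); offsets < 0: upstream side.
    pos <- ifelse(offsets > 0,
                  first_down + step * (offsets - 1L),
                  first_down + step * offsets)
    rr <- reads[reads$chrom == g$chrom & reads$strand == g$strand, ,
                drop = FALSE]
    if (nrow(rr) == 0) next
    for (j in seq_len(nrow(rr))) {
      if (mode == "coverage") {
        covered <- pos >= rr$start[j] & pos < rr$end[j]
      } else {
        end5 <- if (g$strand == "+") rr$start[j] else rr$end[j] - 1L
        covered <- pos == end5
      }
      if (any(covered)) acc[covered] <- acc[covered] + rr$count[j]
    }
  }
  val <- acc / nrow(models)
  if (!is.null(per_million)) val <- val * 1e6 / per_million
  out <- tibble::tibble(offset = offsets, coverage = unname(val))
  attr(out, "anchor") <- anchor
  attr(out, "window") <- c(upstream = upstream, downstream = downstream)
  attr(out, "mode") <- mode
  class(out) <- c("trf_metagene_profile", class(out))
  out
}

#' Offset-wise comparison of two metagene profiles
#'
#' Aligns two profiles computed with the same anchor and window and
#' reports the per-offset difference and log2 ratio (with pseudocount).
#'
#' @param profile_a,profile_b `trf_metagene_profile` objects.
#' @param pseudocount Added to both values in the ratio.
#' @return Tibble: `offset`, `coverage_a`, `coverage_b`, `diff`,
#'   `log2_ratio`.
#' @export
compare_profiles <- function(profile_a, profile_b, pseudocount = 0.5) {
  same <- identical(attr(profile_a, "anchor"), attr(profile_b, "anchor")) &&
    identical(attr(profile_a, "window"), attr(profile_b, "window"))
  if (!same || !identical(profile_a$offset, profile_b$offset)) {
    abort("Profiles have mismatched anchors or windows.")
  }
  tibble::tibble(
    offset = profile_a$offset,
    coverage_a = profile_a$coverage,
    coverage_b = profile_b$coverage,
    diff = profile_b$coverage - profile_a$coverage,
    log2_ratio = log2((profile_b$coverage + pseudocount) /
                        (profile_a$coverage + pseudocount))
  )
}
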