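# Shared fixtures and independent oracles used across test files.

# Small generator setup: a handful of loci per class keeps references tiny.
small_params <- function(seed = 1, ...) {
  sim_params(
    seed = seed,
    n_genes_per_class = c(
      "tRF-1" = 4L, "tRF-5" = 3L, "tRF-3" = 3L, "tRF-leader" = 2L,
      "intron-tRF" = 3L, "misc-tRF" = 2L, "miRNA" = 5L
    ),
    depth = 1e5, spike_in_n = 5L,
    ...
  )
}

# Independent brute-force mapper: enumerates every end-to-end alignment of
# `seq` against every reference string and counts mismatching characters
# directly. Applies the same documented output conventions as the mapper
# (CCA suffix must match exactly on mature_cca refs and the read must
# extend past the last templated base; exact hits suppress 1-mismatch
# hits) but shares no scanning code with it.
brute_map <- function(seq, reference, max_mismatch = 1L) {
  q <- strsplit(seq, "")[[1]]
  n <- length(q)
  hits <- list()
  for (rid in names(reference$refs)) {
    ref <- strsplit(as.character(reference$refs[[rid]]), "")[[1]]
    info <- reference$info[reference$info$ref_id == rid, ]
    if (length(ref) < n) next
    for (s in 0:(length(ref) - n)) {
      mmpos <- which(q != ref[(s + 1):(s + n)]) - 1L
      if (length(mmpos) > max_mismatch) next
      if (info$kind == "mature_cca") {
        e <- s + n
        if (e <= info$mature_len) next
        if (any(s + mmpos >= info$mature_len)) next
      }
      hits[[length(hits) + 1L]] <- data.frame(
        ref_id = rid, start = s, mismatches = length(mmpos)
      )
    }
  }
  out <- do.call(rbind, hits)
  if (is.null(out)) {
    return(data.frame(ref_id = character(), start = integer(),
                      mismatches = integer()))
  }
  if (any(out$mismatches == 0)) out <- out[out$mismatches == 0, ]
  out[order(out$ref_id, out$start), , drop = FALSE]
}

# Mutate one base in the middle of a sequence (guaranteed different base).
mutate_middle <- function(seq) {
  i <- max(2L, nchar(seq) %/% 2L)
  old <- substr(seq, i, i)
  new <- setdiff(c("A", "C", "G", "T"), old)[1]
  paste0(substr(seq, 1, i - 1L), new, substr(seq, i + 1L, nchar(seq)))
}

# Reverse-complement an entire toy genome, flipping strands and
# coordinates of every model, for the strand-symmetry property.
flip_toy <- function(toy) {
  glen <- setNames(Biostrings::width(toy$genome), names(toy$genome))
  flipped <- Biostrings::reverseComplement(toy$genome)
  models <- toy$models
  L <- glen[models$chrom]
  new_start <- L - models$end
  models$end <- L - models$start
  models$start <- new_start
  models$strand <- ifelse(models$strand == "+", "-", "+")
  list(genome = flipped, models = models, mirnas = toy$mirnas)
}

# Brute-force per-base metagene oracle: walks every gene base by base in
# transcript orientation and tallies read counts covering each offset.
brute_profile <- function(reads, models, upstream, downstream) {
  offsets <- c(if (upstream > 0) -(upstream:1), seq_len(downstream))
  acc <- setNames(numeric(length(offsets)), offsets)
  for (i in seq_len(nrow(models))) {
    g <- models[i, ]
    mat_end_tx <- g$leader_len + g$mature_len + g$intron_len
    for (o in offsets) {
      # transcript-frame position of this offset (0-based, within pre frame
      # extended beyond the locus where needed)
      tx_pos <- if (o > 0) mat_end_tx + o - 1L else mat_end_tx + o
      gpos <- if (g$strand == "+") g$start + tx_pos else g$end - 1L - tx_pos
      rr <- reads[reads$chrom == g$chrom & reads$strand == g$strand, ]
      for (j in seq_len(nrow(rr))) {
        if (gpos >= rr$start[j] && gpos < rr$end[j]) {
          acc[as.character(o)] <- acc[as.character(o)] + rr$count[j]
        }
      }
    }
  }
  unname(acc) / nrow(models)
}

# Profiled-A0 grid search over k: independent SSE-minimisation oracle for
# the exponential fit.
grid_fit <- function(t, value, k_grid = seq(0, 10, by = 1e-3)) {
  best <- c(k = NA_real_, a0 = NA_real_, sse = Inf)
  for (k in k_grid) {
    ek <- exp(-k * t)
    a0 <- sum(value * ek) / sum(ek^2)
    sse <- sum((value - a0 * ek)^2)
    if (sse < best["sse"]) best <- c(k = k, a0 = a0, sse = sse)
  }
  best
}
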