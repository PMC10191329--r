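#' Build a searchable pre-tRNA reference from a genome and gene models
#'
#' For each locus emits three transcript-oriented reference sequences: the
#' full pre-tRNA (`pre` = leader + mature-with-intron + trailer), the
#' spliced mature body (`mature`), and the mature body with the
#' non-templated 3' `CCA` appended (`mature_cca`); minus-strand loci are
#' reverse-complemented. An optional miRNA reference set is carried along
#' with kind `mirna`.
#'
#' @param genome Named [Biostrings::DNAStringSet] of chromosomes.
#' @param models Gene-model tibble as produced by [make_toy_genome()] /
#'   [read_models_bed()] (0-based half-open genomic coordinates plus
#'   transcript-structure lengths).
#' @param mirnas Optional [Biostrings::DNAStringSet] of mature miRNAs.
#' @return A `trf_reference` list: `refs` (named `DNAStringSet`) and
#'   `info` (tibble keyed by `ref_id` with `locus_id`, `kind`,
#'   `leader_len`, `trailer_off`, `pre_len`, `mature_len`,
#'   `intron_start`, `intron_end` -- intron bounds in pre-tRNA frame).
#' @export
#' @examples
#' toy <- make_toy_genome(sim_params(seed = 1,
#'   n_genes_per_class = c("tRF-1" = 2, "miRNA" = 2)))
#' ref <- build_reference(toy$genome, toy$models, toy$mirnas)
#' ref$info
build_reference <- function(genome, models, mirnas = NULL) {
  missing_chr <- setdiff(unique(models$chrom), names(genome))
  if (length(missing_chr) > 0) {
    abort(paste0("Chromosome(s) not in genome: ",
                 paste(missing_chr, collapse = ", ")))
  }
  refs <- character(0)
  info <- vector("list", nrow(models))
  for (i in seq_len(nrow(models))) {
    r <- models[i, ]
    tx <- locus_transcript(genome, r)
    L <- r$leader_len
    pre_len <- nchar(tx)
    trailer_off <- L + r$mature_len + r$intron_len
    has_intron <- !is.na(r$intron_offset) && r$intron_len > 0
    i_s <- if (has_intron) L + r$intron_offset else NA_integer_
    i_e <- if (has_intron) i_s + r$intron_len else NA_integer_
    mature <- if (has_intron) {
      paste0(substr(tx, L + 1L, i_s), substr(tx, i_e + 1L, trailer_off))
    } else {
      substr(tx, L + 1L, trailer_off)
    }
    ids <- paste0(r$locus_id, c("|pre", "|mature", "|mature_cca"))
    refs[ids] <- c(tx, mature, paste0(mature, "CCA"))
    info[[i]] <- tibble::tibble(
      ref_id = ids, locus_id = r$locus_id,
      kind = c("pre", "mature", "mature_cca"),
      leader_len = L, trailer_off = trailer_off, pre_len = pre_len,
      mature_len = r$mature_len,
      intron_start = i_s, intron_end = i_e
    )
  }
  info <- dplyr::bind_rows(info)
  if (!is.null(mirnas) && length(mirnas) > 0) {
    mir <- as.character(mirnas)
    refs[names(mirnas)] <- mir
    info <- dplyr::bind_rows(info, tibble::tibble(
      ref_id = names(mirnas), locus_id = names(mirnas), kind = "mirna",
      leader_len = NA_integer_, trailer_off = NA_integer_,
      pre_len = NA_integer_, mature_len = NA_integer_,
      intron_start = NA_integer_, intron_end = NA_integer_
    ))
  }
  structure(list(refs = Biostrings::DNAStringSet(refs), info = info),
            class = "trf_reference")
}

#' @export
print.trf_reference <- function(x, ...) {
  cat("<trf_reference>", sum(x$info$kind == "pre"), "pre-tRNA loci,",
      sum(x$info$kind == "mirna"), "miRNAs\n")
  invisible(x)
}

# 0-based positions (within the reference window) where read and reference
# disagree, for a hit starting at 0-based `start`.
mismatch_positions <- function(read, refseq, start) {
  a <- strsplit(read, "")[[1]]
  b <- strsplit(substr(refseq, start + 1L, start + nchar(read)), "")[[1]]
  which(a != b) - 1L
}

#' Map one small-RNA sequence end-to-end against the reference
#'
#' Reports every position in any reference sequence (pre-tRNA, spliced
#' mature, mature + CCA, miRNA) where the query aligns end-to-end with
#' Hamming distance at most `max_mismatch` (no indels). If any exact match
#' exists, 1-mismatch hits are dropped. `N` in the query counts as a
#' mismatch. Hits on the `mature_cca` reference are kept only when the
#' read extends past the last templated base (otherwise the `mature` hit
#' already reports them) and only when the non-templated suffix matches
#' `CCA` exactly -- mismatches are never spent inside the CCA.
#'
#' @param seq Uppercase DNA sequence (T for U), length >= 15.
#' @param reference A `trf_reference` from [build_reference()].
#' @param max_mismatch Maximum Hamming distance (default 1).
#' @return Tibble with one row per hit: `ref_id`, `locus_id`, `kind`,
#'   `start`, `end` (0-based half-open, reference frame), `mismatches`,
#'   `cca_softclip`, plus the locus geometry columns of the reference
#'   (`leader_len`, `trailer_off`, `pre_len`, `mature_len`, intron bounds).
#' @export
#' @examples
#' toy <- make_toy_genome(sim_params(seed = 1,
#'   n_genes_per_class = c("tRF-1" = 2, "miRNA" = 2)))
#' ref <- build_reference(toy$genome, toy$models, toy$mirnas)
#' trailer <- as.character(ref$refs[["tRNA-001|pre"]])
#' map_sequence(substr(trailer, nchar(trailer) - 17, nchar(trailer)), ref)
map_sequence <- function(seq, reference, max_mismatch = 1L) {
  if (!grepl("^[ACGTN]+$", seq)) {
    abort("Sequence contains characters outside the ACGTN alphabet.")
  }
  if (nchar(seq) < 15) {
    abort("Sequences shorter than 15 nt are rejected upstream; got a shorter one.")
  }
  pat <- Biostrings::DNAString(seq)
  m <- Biostrings::vmatchPattern(pat, reference$refs,
                                 max.mismatch = max_mismatch, fixed = TRUE)
  starts <- Biostrings::startIndex(m)
  hits <- list()
  for (i in seq_along(starts)) {
    st <- starts[[i]]
    if (is.null(st) || length(st) == 0) next
    st <- st[st >= 1 & st + nchar(seq) - 1L <= length(reference$refs[[i]])]
    if (length(st) == 0) next
    mm <- Biostrings::neditStartingAt(pat, reference$refs[[i]],
                                      starting.at = st, with.indels = FALSE)
    hits[[length(hits) + 1L]] <- tibble::tibble(
      ref_id = names(reference$refs)[i],
      start = st - 1L, end = st - 1L + nchar(seq), mismatches = as.integer(mm)
    )
  }
  if (length(hits) == 0) {
    return(tibble::tibble(
      ref_id = character(), locus_id = character(), kind = character(),
      start = integer(), end = integer(), mismatches = integer(),
      cca_softclip = logical(), leader_len = integer(),
      trailer_off = integer(), pre_len = integer(), mature_len = integer(),
      intron_start = integer(), intron_end = integer()
    ))
  }
  out <- dplyr::bind_rows(hits)
  out <- dplyr::left_join(out, reference$info, by = "ref_id")

  # CCA handling: keep mature_cca hits only if the read runs past the last
  # templated base with an exactly matching CCA suffix.
  is_cca <- out$kind == "mature_cca"
  drop <- rep(FALSE, nrow(out))
  for (j in which(is_cca)) {
    if (out$end[j] <= out$mature_len[j]) { drop[j] <- TRUE; next }
    if (out$mismatches[j] > 0) {
      refseq <- as.character(reference$refs[[out$ref_id[j]]])
      mp <- mismatch_positions(seq, refseq, out$start[j])
      if (any(out$start[j] + mp >= out$mature_len[j])) drop[j] <- TRUE
    }
  }
  out <- out[!drop, , drop = FALSE]
  if (nrow(out) > 0 && any(out$mismatches == 0)) {
    out <- out[out$mismatches == 0, , drop = FALSE]
  }
  out$cca_softclip <- out$kind == "mature_cca" & out$end > out$mature_len
  dplyr::select(out, "ref_id", "locus_id", "kind", "start", "end",
                "mismatches", "cca_softclip", "leader_len", "trailer_off",
                "pre_len", "mature_len", "intron_start", "intron_end")
}

# Candidate class labels for one mapping row, in the pre-tRNA or mature
# coordinate frame, under the configured boundary tolerances.
candidate_classes <- function(map, tol_5p, tol_boundary) {
  s <- map$start; e <- map$end
  out <- character(0)
  cca <- FALSE
  if (map$kind == "mirna") return(list(classes = "miRNA", cca = FALSE))
  if (map$kind == "pre") {
    L <- map$leader_len; Toff <- map$trailer_off
    if (s >= Toff && s <= Toff + tol_boundary) out <- c(out, "tRF-1")
    if (s >= L - tol_5p && s <= L + tol_5p && s >= 0) out <- c(out, "tRF-5")
    if (e == Toff) out <- c(out, "tRF-3")
    if (e - 1L >= L - 1L - tol_boundary && e - 1L <= L - 1L) {
      out <- c(out, "tRF-leader")
    }
    if (!is.na(map$intron_start) &&
        s >= map$intron_start - tol_boundary &&
        e <= map$intron_end + tol_boundary) {
      out <- c(out, "intron-tRF")
    }
    if (length(out) == 0 && s < Toff && e > L) out <- "misc-tRF"
  } else {
    M <- map$mature_len
    if (s <= tol_5p) out <- c(out, "tRF-5")
    if (map$kind == "mature" && e == M) out <- c(out, "tRF-3")
    if (map$kind == "mature_cca" && e > M && e <= M + 3L) {
      out <- c(out, "tRF-3"); cca <- TRUE
    }
    if (length(out) == 0) out <- "misc-tRF"
  }
  list(classes = out, cca = cca)
}

#' Assign a positional class to one set of mappings
#'
#' Applies the per-locus positional rule set to transcript-frame offsets:
#' tRF-1 if the 5' end lies within `tol_boundary` of the first trailer
#' base; tRF-leader if the 3' end lies within `tol_boundary` of the last
#' leader base; tRF-5 if the 5' end sits at mature position 0 (within
#' `tol_5p`); tRF-3 if the 3' end coincides with the mature terminus,
#' matching mature or mature+CCA (the non-templated CCA is flagged, never
#' counted as mismatch); intron-tRF if the read lies inside an intron
#' block (within `tol_boundary`); misc-tRF for other mature-body overlaps.
#' Conflicts across rules/loci resolve by fixed precedence
#' miRNA > tRF-1 > tRF-5 > tRF-3 > tRF-leader > intron-tRF > misc-tRF.
#'
#' @param mappings Tibble from [map_sequence()].
#' @param tol_5p Tolerance (nt) on the tRF-5 5'-end anchor (default 1).
#' @param tol_boundary Tolerance (nt) on trailer/leader/intron boundaries
#'   (default 2).
#' @param precedence Character vector overriding the conflict order.
#' @return A list: `class`, `basis_locus`, `basis_kind`, `cca_softclip`.
#'   Empty mappings give class `"unassigned"`.
#' @export
classify_mapping <- function(mappings, tol_5p = 1L, tol_boundary = 2L,
                             precedence = CLASS_PRECEDENCE) {
  if (nrow(mappings) == 0) {
    return(list(class = "unassigned", basis_locus = NA_character_,
                basis_kind = NA_character_, cca_softclip = FALSE))
  }
  cand <- vector("list", nrow(mappings))
  for (j in seq_len(nrow(mappings))) {
    cand[[j]] <- candidate_classes(mappings[j, ], tol_5p, tol_boundary)
  }
  all_classes <- unlist(lapply(cand, `[[`, "classes"))
  for (cls in precedence) {
    hit <- which(vapply(cand, function(x) cls %in% x$classes, logical(1)))
    if (length(hit) > 0) {
      j <- hit[1]
      return(list(
        class = cls,
        basis_locus = mappings$locus_id[j],
        basis_kind = mappings$kind[j],
        cca_softclip = cls == "tRF-3" && cand[[j]]$cca
      ))
    }
  }
  list(class = "unassigned", basis_locus = NA_character_,
       basis_kind = NA_character_, cca_softclip = FALSE)
}

#' Collapse a raw read stream into unique counted sequences
#'
#' Identical sequences are merged with summed counts; sequences shorter
#' than `min_len` (default 15 nt, i.e. only reads longer than 14 nt are
#' kept) are discarded. Distinct-length isoforms stay distinct sequences.
#'
#' @param reads Character vector of raw read sequences, or a data frame
#'   with columns `sequence` and `count` to be re-aggregated.
#' @param min_len Minimum retained read length.
#' @return Tibble with `sequence` and `count`, sorted by decreasing count.
#' @export
#' @examples
#' collapse_reads(c("ACGTACGTACGTACGTA", "ACGTACGTACGTACGTA", "TTTTT"))
collapse_reads <- function(reads, min_len = 15L) {
  if (is.data.frame(reads)) {
    df <- tibble::as_tibble(reads)
  } else {
    df <- tibble::tibble(sequence = as.character(reads), count = 1L)
  }
  df |>
    dplyr::filter(nchar(.data$sequence) >= min_len) |>
    dplyr::group_by(.data$sequence) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$count))
}

#' Classify collapsed small-RNA sequences against a pre-tRNA reference
#'
#' Maps every unique sequence with [map_sequence()] (Hamming distance at
#' most `max_mismatch`, exact matches preferred) and assigns one class per
#' sequence with [classify_mapping()]. Counting is sequence-centric: each
#' unique sequence is one countable unit regardless of how many loci it
#' maps to.
#'
#' @param reads Tibble with `sequence` and `count` (see
#'   [collapse_reads()]), or a character vector of unique sequences.
#' @param reference A `trf_reference` from [build_reference()].
#' @param max_mismatch,tol_5p,tol_boundary,precedence Passed through to
#'   the mapper and rule set.
#' @return A `trf_classified` tibble: `sequence`, `count`, `length`,
#'   `class`, `basis_locus`, `basis_kind`, `n_mappings`,
#'   `min_mismatches`, `cca_softclip`, and a `mappings` list-column.
#' @export
#' @examples
#' p <- sim_params(seed = 1, n_genes_per_class = c("tRF-1" = 2, "miRNA" = 2))
#' toy <- make_toy_genome(p)
#' truth <- simulate_truth(toy, p)
#' ref <- build_reference(toy$genome, toy$models, toy$mirnas)
#' cl <- classify_reads(truth$sequence, ref)
#' table(cl$class)
classify_reads <- function(reads, reference, max_mismatch = 1L,
                           tol_5p = 1L, tol_boundary = 2L,
                           precedence = CLASS_PRECEDENCE) {
  if (!is.data.frame(reads)) {
    reads <- tibble::tibble(sequence = as.character(reads), count = 1L)
  }
  reads <- tibble::as_tibble(reads)
  short <- nchar(reads$sequence) < 15
  if (any(short)) {
    warn(sprintf("%d sequence(s) shorter than 15 nt dropped.", sum(short)))
    reads <- reads[!short, , drop = FALSE]
  }
  rows <- vector("list", nrow(reads))
  for (i in seq_len(nrow(reads))) {
    maps <- map_sequence(reads$sequence[i], reference,
                         max_mismatch = max_mismatch)
    asg <- classify_mapping(maps, tol_5p = tol_5p,
                            tol_boundary = tol_boundary,
                            precedence = precedence)
    rows[[i]] <- tibble::tibble(
      sequence = reads$sequence[i], count = reads$count[i],
      length = nchar(reads$sequence[i]),
      class = asg$class, basis_locus = asg$basis_locus,
      basis_kind = asg$basis_kind, n_mappings = nrow(maps),
      min_mismatches = if (nrow(maps) > 0) min(maps$mismatches) else
        NA_integer_,
      cca_softclip = asg$cca_softclip,
      mappings = list(maps)
    )
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("trf_classified", class(out))
  out
}

#' Project classified reads onto genomic intervals
#'
#' Converts each read's winning mapping into genomic coordinates using the
#' gene models, for downstream metagene profiling or BED export. Pre-tRNA
#' frame mappings project directly; mature-frame mappings project through
#' the exon structure where the read does not cross the splice junction.
#' The non-templated CCA of tRF-3s is trimmed before projection. Reads
#' whose only mappings cannot be projected (splice-junction spanning or
#' miRNA-reference hits) are skipped with a message.
#'
#' @param classified A `trf_classified` tibble from [classify_reads()].
#' @param models The gene-model tibble the reference was built from.
#' @return Tibble of read intervals: `chrom`, `start`, `end` (0-based
#'   half-open), `strand`, `count`, `sequence`, `class`, `locus_id`.
#' @export
reads_to_intervals <- function(classified, models) {
  mi <- models |>
    dplyr::select("locus_id", "chrom", "strand", "start", "end",
                  "leader_len", "mature_len", "intron_len", "intron_offset")
  rows <- list(); skipped <- 0L
  for (i in seq_len(nrow(classified))) {
    maps <- classified$mappings[[i]]
    if (nrow(maps) == 0) next
    bl <- classified$basis_locus[i]
    m <- maps[maps$locus_id == bl, , drop = FALSE]
    pre <- m[m$kind == "pre", , drop = FALSE]
    if (nrow(pre) > 0) {
      s_tx <- pre$start[1]; e_tx <- pre$end[1]
    } else {
      mat <- m[m$kind %in% c("mature", "mature_cca"), , drop = FALSE]
      if (nrow(mat) == 0) { skipped <- skipped + 1L; next }
      g <- mi[mi$locus_id == bl, ]
      s_m <- mat$start[1]
      e_m <- min(mat$end[1], g$mature_len)      # trim the CCA
      exon1 <- if (!is.na(g$intron_offset)) g$intron_offset else g$mature_len
      if (s_m < exon1 && e_m > exon1) { skipped <- skipped + 1L; next }
      shift <- if (s_m >= exon1) g$intron_len else 0L
      s_tx <- g$leader_len + s_m + shift
      e_tx <- g$leader_len + e_m + shift
    }
    g <- mi[mi$locus_id == bl, ]
    if (nrow(g) == 0) { skipped <- skipped + 1L; next }
    if (g$strand == "+") {
      gs <- g$start + s_tx; ge <- g$start + e_tx
    } else {
      gs <- g$end - e_tx; ge <- g$end - s_tx
    }
    rows[[length(rows) + 1L]] <- tibble::tibble(
      chrom = g$chrom, start = gs, end = ge, strand = g$strand,
      count = classified$count[i], sequence = classified$sequence[i],
      class = classified$class[i], locus_id = bl
    )
  }
  if (skipped > 0) {
    message(skipped, " read(s) could not be projected to genomic coordinates.")
  }
  dplyr::bind_rows(rows)
}
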