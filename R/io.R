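# Readers and writers for the package's on-disk formats: FASTA (via
# Biostrings), a BED12 gene-model dialect (thick = mature span incl.
# intron, blocks = mature exons; blocks need not abut the locus ends, so
# the file is written/read directly rather than through generic BED
# importers), counts TSV (first column seq_id, one column per library),
# sample sheet TSV, and the generator truth TSV. TSVs carry "#" metadata
# lines.

#' Write / read a FASTA file with `id_xCOUNT` headers
#'
#' The collapsed-read convention: each record's name is
#' `<id>_x<count>`.
#'
#' @param x Tibble with `sequence`, `count` and an id column
#'   (`seq_id`, or row number if absent).
#' @param path Output file.
#' @return `write_fasta_counts()` the path, invisibly;
#'   `read_fasta_counts()` a tibble `seq_id`, `sequence`, `count`.
#' @export
write_fasta_counts <- function(x, path) {
  ids <- if ("seq_id" %in% names(x)) x$seq_id else sprintf("seq%05d", seq_len(nrow(x)))
  ss <- Biostrings::DNAStringSet(x$sequence)
  names(ss) <- sprintf("%s_x%d", ids, as.integer(x$count))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' @rdname write_fasta_counts
#' @export
read_fasta_counts <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  nm <- names(ss)
  m <- regmatches(nm, regexec("^(.*)_x(\\d+)$", nm))
  bad <- vapply(m, length, integer(1)) != 3
  if (any(bad)) {
    abort(paste0("Malformed FASTA count header (want id_xCOUNT) at record ",
                 which(bad)[1], ": ", nm[which(bad)[1]]))
  }
  tibble::tibble(
    seq_id = vapply(m, `[`, character(1), 2),
    sequence = unname(as.character(ss)),
    count = as.integer(vapply(m, `[`, character(1), 3))
  )
}

#' Write / read pre-tRNA gene models as BED12
#'
#' Dialect: one record per locus spanning leader through trailer;
#' `thickStart`/`thickEnd` hold the mature span (introns included);
#' blocks are the mature exons. Leader/trailer lengths and the intron
#' are recovered strand-aware on read.
#'
#' @param models Gene-model tibble (as from [make_toy_genome()]).
#' @param path File path.
#' @return The path, invisibly; the reader returns a model tibble.
#' @export
write_models_bed <- function(models, path) {
  rows <- character(nrow(models))
  for (i in seq_len(nrow(models))) {
    g <- models[i, ]
    pre_mature <- g$mature_len + g$intron_len
    if (g$strand == "+") {
      thick_s <- g$start + g$leader_len
    } else {
      thick_s <- g$start + g$trailer_len
    }
    thick_e <- thick_s + pre_mature
    if (is.na(g$intron_offset) || g$intron_len == 0) {
      sizes <- pre_mature; starts <- 0L
    } else {
      e1 <- g$intron_offset
      e2 <- g$mature_len - e1
      if (g$strand == "+") {
        sizes <- c(e1, e2); starts <- c(0L, e1 + g$intron_len)
      } else {
        sizes <- c(e2, e1); starts <- c(0L, e2 + g$intron_len)
      }
    }
    starts <- starts + (thick_s - g$start)  # blockStarts relative to chromStart
    rows[i] <- paste(
      g$chrom, g$start, g$end, g$locus_id, 0, g$strand,
      thick_s, thick_e, "0,0,0", length(sizes),
      paste0(paste(sizes, collapse = ","), ","),
      paste0(paste(starts, collapse = ","), ","),
      sep = "\t"
    )
  }
  header <- paste0(
    "# BED12 pre-tRNA gene models: thickStart/thickEnd = mature span ",
    "(introns included), blocks = mature exons")
  writeLines(c(header, rows), path)
  invisible(path)
}

#' @rdname write_models_bed
#' @export
read_models_bed <- function(path) {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "#") & nzchar(ln)]
  f <- strsplit(ln, "\t")
  bad <- vapply(f, length, integer(1)) != 12
  if (any(bad)) {
    abort(paste0("Line ", which(bad)[1], ": expected 12 BED fields, got ",
                 length(f[[which(bad)[1]]]), "."))
  }
  rows <- vector("list", length(f))
  for (i in seq_along(f)) {
    v <- f[[i]]
    start <- as.integer(v[2]); end <- as.integer(v[3])
    strand <- v[6]
    thick_s <- as.integer(v[7]); thick_e <- as.integer(v[8])
    sizes <- as.integer(strsplit(v[11], ",")[[1]])
    starts <- as.integer(strsplit(v[12], ",")[[1]])
    pre_mature <- thick_e - thick_s
    mature_len <- sum(sizes)
    intron_len <- pre_mature - mature_len
    if (strand == "+") {
      leader_len <- thick_s - start
      trailer_len <- end - thick_e
      intron_offset <- if (intron_len > 0) sizes[1] else NA_integer_
    } else {
      leader_len <- end - thick_e
      trailer_len <- thick_s - start
      # genomically-first block is the transcript-last exon on minus strand
      intron_offset <- if (intron_len > 0) sizes[length(sizes)] else NA_integer_
    }
    rows[[i]] <- tibble::tibble(
      locus_id = v[4], chrom = v[1], strand = strand,
      start = start, end = end,
      leader_len = leader_len, mature_len = mature_len,
      intron_len = intron_len, intron_offset = intron_offset,
      trailer_len = trailer_len
    )
  }
  dplyr::bind_rows(rows)
}

#' Write / read a counts TSV (sequence x library)
#'
#' First column `seq_id`, then one column per library. The reader
#' validates that every count is a non-negative number and reports the
#' offending row and library otherwise.
#'
#' @param counts Long tibble with `seq_id`, `library`, `count`.
#' @param path File path.
#' @param samples Optional sample sheet giving the library column order.
#' @return The path invisibly; the reader returns the long tibble.
#' @export
write_counts_tsv <- function(counts, path, samples = NULL) {
  wide <- counts |>
    dplyr::select("seq_id", "library", "count") |>
    tidyr::pivot_wider(names_from = "library", values_from = "count",
                       values_fill = 0)
  if (!is.null(samples)) {
    wide <- wide[, c("seq_id", samples$library)]
  }
  readr::write_tsv(wide, path)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  wide <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  if (names(wide)[1] != "seq_id") {
    abort("Counts TSV must have `seq_id` as its first column.")
  }
  long <- tidyr::pivot_longer(wide, -"seq_id", names_to = "library",
                              values_to = "count")
  bad <- which(!is.finite(long$count) | long$count < 0)
  if (length(bad) > 0) {
    b <- long[bad[1], ]
    abort(sprintf(
      "Invalid count for sequence %s in library %s (value %s).",
      b$seq_id, b$library, format(b$count)))
  }
  long
}

#' Write / read the sample sheet TSV
#'
#' Columns: `library`, `timepoint_h`, `replicate`, `condition`,
#' `fraction` (one of input/rip/total) and `total_count`.
#'
#' @param samples Sample-sheet tibble.
#' @param path File path.
#' @return The path invisibly; the reader returns the tibble.
#' @export
write_sample_sheet <- function(samples, path) {
  readr::write_tsv(samples, path)
  invisible(path)
}

#' @rdname write_sample_sheet
#' @export
read_sample_sheet <- function(path) {
  s <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  need <- c("library", "timepoint_h", "replicate", "condition", "fraction")
  missing <- setdiff(need, names(s))
  if (length(missing) > 0) {
    abort(paste0("Sample sheet lacks column(s): ",
                 paste(missing, collapse = ", ")))
  }
  bad <- which(!s$fraction %in% c("input", "rip", "total"))
  if (length(bad) > 0) {
    abort(sprintf("Row %d: fraction must be input/rip/total, got '%s'.",
                  bad[1], s$fraction[bad[1]]))
  }
  s
}

#' Write / read the generator ground-truth TSV
#'
#' @param truth Truth tibble from [simulate_truth()].
#' @param path File path.
#' @return The path invisibly; the reader returns the tibble.
#' @export
write_truth_tsv <- function(truth, path) {
  readr::write_tsv(truth, path)
  invisible(path)
}

#' @rdname write_truth_tsv
#' @export
read_truth_tsv <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  col_types = readr::cols(
                    locus_id = readr::col_character()))
}
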