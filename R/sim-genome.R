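#' Generate a toy genome with pre-tRNA gene models and a miRNA reference
#'
#' Builds two small chromosomes carrying non-overlapping pre-tRNA loci on
#' alternating strands, each with a leader (8--15 nt), a mature body
#' (70--90 nt) optionally interrupted by a single intron inserted one base
#' 3' of the anticodon, and a trailer (8--25 nt) whose coding-strand
#' sequence ends in `TTTT` (the Pol III poly-U terminator). Loci are
#' separated by gaps of at least 50 nt. A set of random miRNA reference
#' sequences (20--23 nt) is emitted alongside.
#'
#' Each locus is a designated donor of one fragment class (see
#' [simulate_truth()]); donor loci of tRF-1s get trailers of 18--25 nt and
#' tRF-leader donors get 15 nt leaders so the emitted fragment passes the
#' 15 nt read-length floor.
#'
#' RNG: seeds the stream at `params$seed` and draws, per locus in order,
#' structural lengths then sequence bases, then gap lengths/bases, then the
#' miRNA sequences. Identical params give byte-identical output.
#'
#' @param params A [sim_params()] object.
#' @return A `trf_toy_genome` list with elements `genome`
#'   (named [Biostrings::DNAStringSet]), `models` (tibble of gene models,
#'   one row per locus) and `mirnas` ([Biostrings::DNAStringSet]).
#' @export
#' @examples
#' toy <- make_toy_genome(sim_params(seed = 1))
#' toy$models
make_toy_genome <- function(params) {
  stopifnot(inherits(params, "trf_sim_params"))
  counts <- params$n_genes_per_class
  trna_classes <- setdiff(names(counts), "miRNA")
  donor <- rep(trna_classes, times = counts[trna_classes])
  if (length(donor) == 0) {
    abort("At least one tRNA fragment class must have a positive gene count.")
  }

  set.seed(params$seed)
  n_loci <- length(donor)
  anticodon_exon <- 37L  # mature bases 5' of the intron insertion point

  loci <- vector("list", n_loci)
  for (i in seq_len(n_loci)) {
    cls <- donor[i]
    leader_len <- if (cls == "tRF-leader") 15L else sample(8:15, 1)
    mature_len <- sample(70:90, 1)
    has_intron <- cls == "intron-tRF" || runif(1) < 0.15
    intron_len <- if (cls == "intron-tRF") {
      sample(17:30, 1)
    } else if (has_intron) sample(10:30, 1) else 0L
    trailer_len <- if (cls == "tRF-1") sample(18:25, 1) else sample(8:25, 1)

    leader <- random_dna(leader_len)
    mature <- random_dna(mature_len)
    intron <- if (intron_len > 0) random_dna(intron_len) else ""
    trailer <- paste0(random_dna(trailer_len - 4L), "TTTT")

    # Pre-tRNA transcript: leader + exon1 + intron + exon2 + trailer.
    tx <- paste0(
      leader,
      substr(mature, 1, anticodon_exon), intron,
      substr(mature, anticodon_exon + 1L, mature_len),
      trailer
    )
    loci[[i]] <- list(
      donor_class = cls, leader_len = leader_len, mature_len = mature_len,
      intron_len = as.integer(intron_len),
      intron_offset = if (intron_len > 0) anticodon_exon else NA_integer_,
      trailer_len = trailer_len, tx = tx
    )
  }

  # Lay loci alternately on chr1/chr2, alternating strands, >= 50 nt gaps.
  chrom <- rep(c("chr1", "chr2"), length.out = n_loci)
  strand <- rep(c("+", "-"), length.out = n_loci)
  chr_seq <- c(chr1 = "", chr2 = "")
  rows <- vector("list", n_loci)
  for (i in seq_len(n_loci)) {
    ch <- chrom[i]
    gap <- random_dna(sample(50:120, 1))
    chr_seq[ch] <- paste0(chr_seq[ch], gap)
    start <- nchar(chr_seq[ch])  # 0-based
    locus_seq <- if (strand[i] == "+") loci[[i]]$tx else
      reverse_complement(loci[[i]]$tx)
    chr_seq[ch] <- paste0(chr_seq[ch], locus_seq)
    rows[[i]] <- tibble::tibble(
      locus_id = sprintf("tRNA-%03d", i),
      chrom = ch, strand = strand[i],
      start = start, end = nchar(chr_seq[ch]),
      leader_len = loci[[i]]$leader_len,
      mature_len = loci[[i]]$mature_len,
      intron_len = loci[[i]]$intron_len,
      intron_offset = loci[[i]]$intron_offset,
      trailer_len = loci[[i]]$trailer_len,
      donor_class = loci[[i]]$donor_class
    )
  }
  chr_seq <- vapply(chr_seq, function(s) paste0(s, random_dna(60)), character(1))
  models <- dplyr::bind_rows(rows)

  n_mir <- if ("miRNA" %in% names(counts)) counts[["miRNA"]] else 0L
  mirnas <- character(0)
  if (n_mir > 0) {
    mirnas <- vapply(seq_len(n_mir),
                     function(j) random_dna(sample(20:23, 1)), character(1))
    names(mirnas) <- sprintf("mir-%03d", seq_len(n_mir))
  }

  structure(
    list(
      genome = Biostrings::DNAStringSet(chr_seq),
      models = models,
      mirnas = Biostrings::DNAStringSet(mirnas)
    ),
    class = "trf_toy_genome"
  )
}

#' @export
print.trf_toy_genome <- function(x, ...) {
  cat("<trf_toy_genome>", length(x$genome), "chromosomes,",
      nrow(x$models), "pre-tRNA loci,", length(x$mirnas), "miRNAs\n")
  invisible(x)
}

# Transcript-oriented pre-tRNA sequence of one model row.
locus_transcript <- function(genome, model_row) {
  m <- model_row
  chrom <- as.character(genome[[m$chrom]])
  if (m$end > nchar(chrom) || m$start < 0) {
    abort(sprintf("Locus %s has out-of-bounds interval on %s.",
                  m$locus_id, m$chrom))
  }
  s <- substr(chrom, m$start + 1L, m$end)
  if (m$strand == "-") s <- reverse_complement(s)
  s
}

#' Draw per-sequence ground truth for a toy genome
#'
#' Emits one fragment per donor locus (an exact substring of the simulated
#' pre-tRNA at the class-defining position; tRF-3s carry a non-templated
#' 3' `CCA`; tRF-1s get 0--`trf1_jitter_max` nt of 3' shortening), the
#' miRNA reference sequences, and `spike_in_n` exogenous spike-in species,
#' together with each sequence's true decay rate, initial absolute
#' abundance and RIP enrichment fold.
#'
#' RNG: seeds at `params$seed + 1`, drawing in order: per-locus fragment
#' geometry, stable flags, decay rates, initial abundances, enrichment
#' folds, then spike-in sequences.
#'
#' @param toy A `trf_toy_genome` from [make_toy_genome()].
#' @param params The same [sim_params()] used to build it.
#' @return A tibble (`SimTruth`): `seq_id`, `sequence`, `class`,
#'   `locus_id`, `true_k` (per hour), `true_a0`, `true_enrichment`,
#'   `is_spike`. Spike-ins carry class `"spike-in"`, k = 0, enrichment 1.
#' @export
#' @examples
#' p <- sim_params(seed = 1)
#' truth <- simulate_truth(make_toy_genome(p), p)
#' dplyr::count(truth, class)
simulate_truth <- function(toy, params) {
  stopifnot(inherits(toy, "trf_toy_genome"), inherits(params, "trf_sim_params"))
  set.seed(params$seed + 1L)
  m <- toy$models

  frag <- vector("list", nrow(m))
  for (i in seq_len(nrow(m))) {
    r <- m[i, ]
    tx <- locus_transcript(toy$genome, r)
    L <- r$leader_len
    pre_mature_len <- r$mature_len + r$intron_len   # mature span incl intron
    trailer_off <- L + pre_mature_len               # 0-based first trailer base
    seq <- switch(
      r$donor_class,
      "tRF-1" = {
        jit <- if (params$trf1_jitter_max > 0)
          sample(0:params$trf1_jitter_max, 1) else 0L
        len <- r$trailer_len - jit
        substr(tx, trailer_off + 1L, trailer_off + len)
      },
      "tRF-leader" = substr(tx, 1L, L),
      "tRF-5" = substr(tx, L + 1L, L + sample(16:22, 1)),
      "tRF-3" = {
        len <- sample(16:22, 1)
        mat_end <- trailer_off                       # last mature base (1-based)
        paste0(substr(tx, mat_end - len + 1L, mat_end), "CCA")
      },
      "intron-tRF" = {
        i_s <- L + r$intron_offset                   # 0-based intron start
        len <- sample(15:min(22L, r$intron_len), 1)
        off <- sample(0:min(2L, r$intron_len - len), 1)
        substr(tx, i_s + off + 1L, i_s + off + len)
      },
      "misc-tRF" = {
        st <- sample(5:8, 1)                         # 0-based mature offset
        len <- sample(16:22, 1)
        substr(tx, L + st + 1L, L + st + len)
      }
    )
    frag[[i]] <- tibble::tibble(
      seq_id = sprintf("frag-%03d", i), sequence = seq,
      class = r$donor_class, locus_id = r$locus_id
    )
  }
  truth <- dplyr::bind_rows(frag)
  if (length(toy$mirnas) > 0) {
    truth <- dplyr::bind_rows(truth, tibble::tibble(
      seq_id = names(toy$mirnas),
      sequence = as.character(toy$mirnas),
      class = "miRNA", locus_id = NA_character_
    ))
  }

  n <- nrow(truth)
  stable_p <- params$stable_fraction[truth$class]
  stable_p[is.na(stable_p)] <- 0
  is_stable <- runif(n) < stable_p
  med_k <- vapply(params$decay_rate_dist[truth$class], `[`, numeric(1), 1)
  sig_k <- vapply(params$decay_rate_dist[truth$class], `[`, numeric(1), 2)
  k <- rlnorm(n, meanlog = log(med_k), sdlog = sig_k)
  k[is_stable] <- 0
  a0 <- rlnorm(n, params$a0_meanlog, params$a0_sdlog)
  med_e <- vapply(params$rip_enrichment_dist[truth$class], `[`, numeric(1), 1)
  sig_e <- vapply(params$rip_enrichment_dist[truth$class], `[`, numeric(1), 2)
  enr <- rlnorm(n, meanlog = log(med_e), sdlog = sig_e)

  truth$true_k <- k
  truth$true_a0 <- a0
  truth$true_enrichment <- enr
  truth$is_spike <- FALSE

  if (params$spike_in_n > 0) {
    sp_seq <- vapply(seq_len(params$spike_in_n),
                     function(j) random_dna(sample(20:30, 1)), character(1))
    tries <- 0
    while (anyDuplicated(c(truth$sequence, sp_seq)) && tries < 20) {
      dup <- duplicated(c(truth$sequence, sp_seq))[nrow(truth) + seq_along(sp_seq)]
      sp_seq[dup] <- vapply(which(dup),
                            function(j) random_dna(sample(20:30, 1)), character(1))
      tries <- tries + 1
    }
    truth <- dplyr::bind_rows(truth, tibble::tibble(
      seq_id = sprintf("spike-%03d", seq_len(params$spike_in_n)),
      sequence = sp_seq, class = "spike-in", locus_id = NA_character_,
      true_k = 0, true_a0 = exp(params$a0_meanlog),
      true_enrichment = 1, is_spike = TRUE
    ))
  }
  if (anyDuplicated(truth$sequence)) {
    abort("Simulated sequences collide; use a different seed.")
  }
  truth
}
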