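p_cls <- small_params(seed = 5)
toy_cls <- make_toy_genome(p_cls)
truth_cls <- simulate_truth(toy_cls, p_cls)
ref_cls <- build_reference(toy_cls$genome, toy_cls$models, toy_cls$mirnas)

test_that("reference transcripts match genomic substrings strand-aware", {
  m <- toy_cls$models
  plus <- m[m$strand == "+", ][1, ]
  minus <- m[m$strand == "-", ][1, ]
  chr_p <- as.character(toy_cls$genome[[plus$chrom]])
  chr_m <- as.character(toy_cls$genome[[minus$chrom]])
  expect_identical(
    as.character(ref_cls$refs[[paste0(plus$locus_id, "|pre")]]),
    substr(chr_p, plus$start + 1, plus$end))
  expect_identical(
    as.character(ref_cls$refs[[paste0(minus$locus_id, "|pre")]]),
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(
      substr(chr_m, minus$start + 1, minus$end)))))

  # spliced mature = exon blocks concatenated, intron absent
  intr <- m[m$intron_len > 0, ][1, ]
  pre <- as.character(ref_cls$refs[[paste0(intr$locus_id, "|pre")]])
  mat <- as.character(ref_cls$refs[[paste0(intr$locus_id, "|mature")]])
  L <- intr$leader_len
  e1 <- intr$intron_offset
  expect_identical(
    mat,
    paste0(substr(pre, L + 1, L + e1),
           substr(pre, L + e1 + intr$intron_len + 1,
                  L + intr$mature_len + intr$intron_len)))
  expect_equal(nchar(mat), intr$mature_len)
  expect_identical(
    as.character(ref_cls$refs[[paste0(intr$locus_id, "|mature_cca")]]),
    paste0(mat, "CCA"))

  # out-of-bounds interval names the locus
  bad <- m[1, ]; bad$end <- bad$end + 10000L
  expect_error(build_reference(toy_cls$genome, bad), bad$locus_id)
})

test_that("mapping agrees exactly with a brute-force Hamming scan", {
  # toy reference well under 5 kb
  expect_lt(sum(Biostrings::width(ref_cls$refs)), 5000 * 3)
  set.seed(99)
  queries <- c(
    truth_cls$sequence,
    vapply(sample(truth_cls$sequence[!truth_cls$is_spike], 15), mutate_middle,
           character(1)),
    vapply(1:5, function(i) paste(sample(c("A", "C", "G", "T"), 20, TRUE),
                                  collapse = ""), character(1))
  )
  for (q in queries) {
    got <- map_sequence(q, ref_cls)
    want <- brute_map(q, ref_cls)
    got <- got[order(got$ref_id, got$start), ]
    expect_identical(got$ref_id, want$ref_id)
    expect_identical(got$start, want$start)
    expect_identical(got$mismatches, want$mismatches)
  }
})

test_that("mapping prefers exact hits and validates its input", {
  pre_id <- ref_cls$info$ref_id[ref_cls$info$kind == "pre"][1]
  pre <- as.character(ref_cls$refs[[pre_id]])
  exact <- substr(pre, 5, 22)
  hit <- map_sequence(exact, ref_cls)
  expect_true(all(hit$mismatches == 0))
  mut <- mutate_middle(exact)
  hit1 <- map_sequence(mut, ref_cls)
  expect_true(all(hit1$mismatches == 1))
  expect_error(map_sequence("ACGTACGTACGTACX", ref_cls), "alphabet")
  expect_error(map_sequence("ACGTACGTACGT", ref_cls), "15")
})

test_that("a sequence shared by two paralogous loci maps to both", {
  m2 <- toy_cls$models[1:2, ]
  # duplicate locus 1 under a new id at locus 2's slot on the same genome
  m2$locus_id <- c("tRNA-001", "tRNA-dup")
  m2[2, c("chrom", "strand", "start", "end", "leader_len", "mature_len",
          "intron_len", "intron_offset", "trailer_len")] <-
    m2[1, c("chrom", "strand", "start", "end", "leader_len", "mature_len",
            "intron_len", "intron_offset", "trailer_len")]
  ref2 <- build_reference(toy_cls$genome, m2)
  pre <- as.character(ref2$refs[["tRNA-001|pre"]])
  q <- substr(pre, 3, 20)
  hits <- map_sequence(q, ref2)
  expect_setequal(unique(hits$locus_id), c("tRNA-001", "tRNA-dup"))
  want <- brute_map(q, ref2)
  expect_equal(nrow(hits), nrow(want))
})

test_that("positional rules assign the expected classes", {
  m <- toy_cls$models
  g <- m[m$donor_class == "tRF-1", ][1, ]
  pre <- as.character(ref_cls$refs[[paste0(g$locus_id, "|pre")]])
  Toff <- g$leader_len + g$mature_len + g$intron_len
  L <- g$leader_len

  trf1 <- substr(pre, Toff + 1, Toff + 18)
  expect_identical(classify_mapping(map_sequence(trf1, ref_cls))$class, "tRF-1")

  trf5 <- substr(pre, L + 1, L + 18)
  expect_identical(classify_mapping(map_sequence(trf5, ref_cls))$class, "tRF-5")

  leader_read <- substr(pre, 1, L)
  if (nchar(leader_read) >= 15) {
    expect_identical(classify_mapping(map_sequence(leader_read, ref_cls))$class,
                     "tRF-leader")
  }

  # tRF-3 with non-templated CCA absent from the genome
  mat <- as.character(ref_cls$refs[[paste0(g$locus_id, "|mature")]])
  trf3 <- paste0(substr(mat, nchar(mat) - 17, nchar(mat)), "CCA")
  expect_false(grepl(trf3, pre, fixed = TRUE))
  asg <- classify_mapping(map_sequence(trf3, ref_cls))
  expect_identical(asg$class, "tRF-3")
  expect_true(asg$cca_softclip)

  # genomically-templated tRF-3 (no CCA) also anchors at the mature 3' end
  trf3g <- substr(mat, nchar(mat) - 17, nchar(mat))
  expect_identical(classify_mapping(map_sequence(trf3g, ref_cls))$class, "tRF-3")

  gi <- m[m$donor_class == "intron-tRF", ][1, ]
  prei <- as.character(ref_cls$refs[[paste0(gi$locus_id, "|pre")]])
  i_s <- gi$leader_len + gi$intron_offset
  intron_read <- substr(prei, i_s + 1, i_s + 16)
  expect_identical(classify_mapping(map_sequence(intron_read, ref_cls))$class,
                   "intron-tRF")

  misc <- substr(pre, L + 7, L + 26)
  expect_identical(classify_mapping(map_sequence(misc, ref_cls))$class,
                   "misc-tRF")

  expect_identical(
    classify_mapping(map_sequence(paste(rep("A", 20), collapse = ""),
                                  ref_cls))$class,
    "unassigned")
})

test_that("miRNA hits outrank tRF rules in cross-reference conflicts", {
  g <- toy_cls$models[toy_cls$models$donor_class == "tRF-1", ][1, ]
  pre <- as.character(ref_cls$refs[[paste0(g$locus_id, "|pre")]])
  Toff <- g$leader_len + g$mature_len + g$intron_len
  trf1 <- substr(pre, Toff + 1, Toff + 18)
  mir2 <- Biostrings::DNAStringSet(c(toy_cls$mirnas,
                                     Biostrings::DNAStringSet(c(planted = trf1))))
  ref2 <- build_reference(toy_cls$genome, toy_cls$models, mir2)
  expect_identical(classify_mapping(map_sequence(trf1, ref2))$class, "miRNA")
})

test_that("read collapsing merges isoforms and drops sub-15 nt reads", {
  s1 <- strrep("ACGT", 5)          # 20 nt
  s2 <- paste0(strrep("ACGT", 5), "A")  # distinct isoform stays distinct
  short <- "ACGTACGTACGTAC"        # 14 nt, dropped
  cc <- collapse_reads(c(s1, s1, s2, short))
  expect_identical(cc$count[cc$sequence == s1], 2L)
  expect_identical(cc$count[cc$sequence == s2], 1L)
  expect_false(short %in% cc$sequence)

  set.seed(7)
  uniq <- vapply(1:50, function(i)
    paste(sample(c("A", "C", "G", "T"), sample(14:24, 1), TRUE),
          collapse = ""), character(1))
  stream <- sample(uniq, 10000, replace = TRUE)
  kept <- nchar(stream) >= 15
  cc2 <- collapse_reads(stream)
  expect_identical(sum(cc2$count), sum(kept))        # brute-force tally
  expect_identical(nrow(cc2), length(unique(stream[kept])))
})

test_that("classification recovers simulated truth and tolerates one mismatch", {
  p0 <- small_params(seed = 5, trf1_jitter_max = 0)
  toy0 <- make_toy_genome(p0)
  truth0 <- simulate_truth(toy0, p0)
  ref0 <- build_reference(toy0$genome, toy0$models, toy0$mirnas)
  cl <- classify_reads(truth0$sequence, ref0)
  keep <- !truth0$is_spike
  expect_gte(mean(cl$class[keep] == truth0$class[keep]), 0.99)
  expect_true(all(cl$class[truth0$is_spike] == "unassigned"))

  # exactly one class per sequence, counts conserved
  expect_identical(nrow(cl), length(truth0$sequence))
  expect_true(all(cl$class %in% class_labels()))

  # a single internal substitution leaves the assignment unchanged
  set.seed(11)
  pick <- sample(which(keep & truth0$class != "tRF-3"), 12)
  mut <- vapply(truth0$sequence[pick], mutate_middle, character(1))
  cl_mut <- classify_reads(unname(mut), ref0)
  expect_identical(cl_mut$class, cl$class[pick])
})

test_that("class assignments are invariant under genome reverse-complementation", {
  flipped <- flip_toy(toy_cls)
  ref_f <- build_reference(flipped$genome, flipped$models, flipped$mirnas)
  seqs <- truth_cls$sequence[!truth_cls$is_spike]
  cl_a <- classify_reads(seqs, ref_cls)
  cl_b <- classify_reads(seqs, ref_f)
  expect_identical(cl_a$class, cl_b$class)
})

test_that("classified reads project onto correct genomic intervals", {
  cl <- classify_reads(truth_cls$sequence[!truth_cls$is_spike], ref_cls)
  iv <- suppressMessages(reads_to_intervals(cl, toy_cls$models))
  expect_true(all(iv$end - iv$start >= 15))
  # projected interval re-extracts the read (or its templated part)
  for (i in seq_len(min(nrow(iv), 25))) {
    chr <- as.character(toy_cls$genome[[iv$chrom[i]]])
    g <- substr(chr, iv$start[i] + 1, iv$end[i])
    if (iv$strand[i] == "-") {
      g <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(g)))
    }
    templated <- sub("CCA$", "", iv$sequence[i])
    expect_true(g == iv$sequence[i] || g == templated)
  }
})
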