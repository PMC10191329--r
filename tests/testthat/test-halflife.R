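# Small long-format fixture: two sequences, three timepoints, duplicates.
toy_counts <- function() {
  tidyr::expand_grid(
    seq_id = c("a", "b"),
    timepoint_h = c(0, 6, 12),
    replicate = 1:2
  ) |>
    dplyr::mutate(
      library = sprintf("t%g_r%d", timepoint_h, replicate),
      count = ifelse(seq_id == "a",
                     100 * (1 + timepoint_h / 12),   # apparent increase
                     100 * 2^(-timepoint_h / 6))     # decays
    )
}

test_that("rpm normalization scales by library totals and is depth-invariant", {
  tc <- tibble::tibble(seq_id = "s1", library = "L1", count = 4)
  out <- size_normalize(tc, tibble::tibble(library = "L1", total_count = 2e6))
  expect_equal(out$norm, 2.0)

  two <- tibble::tibble(
    seq_id = rep(c("x", "y"), 2),
    library = rep(c("L1", "L2"), each = 2),
    count = c(10, 30, 20, 60)  # same composition, double depth
  )
  rpm <- size_normalize(two)
  expect_equal(rpm$norm[rpm$library == "L1"], rpm$norm[rpm$library == "L2"])

  bad <- tibble::tibble(seq_id = "s", library = "empty", count = 0)
  expect_error(size_normalize(bad), "empty")
})

test_that("spike-in normalization flattens truly stable sequences", {
  p <- sim_params(seed = 2, n_genes_per_class = c("tRF-1" = 1L),
                  spike_in_n = 5L)
  truth <- tibble::tibble(
    seq_id = c("stable", sprintf("sp%d", 1:5)), sequence = NA_character_,
    class = c("sim", rep("spike-in", 5)), locus_id = NA_character_,
    true_k = 0, true_a0 = 100, true_enrichment = 1,
    is_spike = c(FALSE, rep(TRUE, 5))
  )
  tc <- simulate_timecourse(truth, p, noise = FALSE)
  out <- size_normalize(tc$counts, method = "spike_in")
  st <- out$norm[out$seq_id == "stable"]
  expect_equal(st, rep(st[1], length(st)), tolerance = 1e-10)

  expect_error(size_normalize(dplyr::mutate(tc$counts, is_spike = FALSE),
                              method = "spike_in"),
               "spike")
})

test_that("T0 normalization anchors every sequence at mean 1 and reports exclusions", {
  tc <- size_normalize(toy_counts())
  rel <- t0_normalize(tc)
  t0_means <- rel |>
    dplyr::filter(timepoint_h == 0) |>
    dplyr::group_by(seq_id) |>
    dplyr::summarise(m = mean(rel_t0))
  expect_equal(t0_means$m, rep(1, nrow(t0_means)))

  one <- tc |> dplyr::mutate(norm = ifelse(seq_id == "b" & timepoint_h == 0,
                                           0, norm))
  expect_message(rel2 <- t0_normalize(one), "excluded")
  expect_identical(attr(rel2, "excluded"), "b")
  expect_false("b" %in% rel2$seq_id)

  # direct value check: t0 mean 10, value 5 -> 0.5
  df <- tibble::tibble(seq_id = "z", timepoint_h = c(0, 0, 1),
                       library = c("a", "b", "c"), count = 1,
                       norm = c(8, 12, 5))
  expect_equal(t0_normalize(df)$rel_t0, c(0.8, 1.2, 0.5))
})

test_that("stable sequences are the ones apparently increasing over time", {
  rel <- t0_normalize(size_normalize(toy_counts()))
  st <- identify_stable(rel)
  expect_true(st$stable[st$seq_id == "a"])    # 1 -> 1.5 -> 2
  expect_false(st$stable[st$seq_id == "b"])   # 1 -> 0.5 -> 0.25

  all_down <- rel |> dplyr::filter(seq_id == "b")
  expect_error(identify_stable(all_down), "stable")
})

test_that("stable-set recovery on generator output has sensitivity >= 0.9", {
  p <- small_params(seed = 3)
  truth <- simulate_truth(make_toy_genome(p), p)
  tc <- simulate_timecourse(truth, p)
  rel <- t0_normalize(size_normalize(tc$counts, tc$samples))
  st <- identify_stable(rel) |>
    dplyr::inner_join(truth[, c("seq_id", "true_k")], by = "seq_id")
  truly <- st[st$true_k == 0, ]
  expect_gte(mean(truly$stable), 0.9)
})

test_that("decay factors are stable-set means with factor(0) = 1", {
  df <- tibble::tibble(
    seq_id = rep(c("s1", "s2", "s3"), each = 2),
    timepoint_h = rep(c(0, 1), 3),
    rel_t0 = c(1, 1.2, 1, 0.8, 1, 1.0)
  )
  fac <- decay_factors(df, c("s1", "s2", "s3"))
  expect_equal(fac$decay_factor[fac$timepoint_h == 0], 1)
  expect_equal(fac$decay_factor[fac$timepoint_h == 1], 1.0)

  # pool halving by 12 h: stable species appear to double
  p <- sim_params(seed = 1, background_fraction = 0.5, total_rna_decay_k = 2,
                  n_genes_per_class = c("tRF-1" = 1L), spike_in_n = 0L,
                  replicates = 1)
  truth <- tibble::tibble(
    seq_id = c("u", "v"), sequence = NA_character_, class = "sim",
    locus_id = NA_character_, true_k = 0, true_a0 = 100,
    true_enrichment = 1, is_spike = FALSE
  )
  tc <- simulate_timecourse(truth, p, noise = FALSE)
  rel <- t0_normalize(size_normalize(tc$counts, tc$samples))
  fac2 <- decay_factors(rel, c("u", "v"))
  expect_equal(fac2$decay_factor[fac2$timepoint_h == 12], 2, tolerance = 1e-6)
})

test_that("decay normalization pins the stable-set mean at 1 and is idempotent", {
  p <- small_params(seed = 4)
  truth <- simulate_truth(make_toy_genome(p), p)
  tc <- simulate_timecourse(truth, p)
  rel <- t0_normalize(size_normalize(tc$counts, tc$samples))
  st <- identify_stable(rel)
  fac <- decay_factors(rel, st)
  dn <- apply_decay_normalization(rel, fac)

  stable_ids <- st$seq_id[st$stable]
  check <- dn |>
    dplyr::filter(seq_id %in% stable_ids) |>
    dplyr::group_by(seq_id, timepoint_h) |>
    dplyr::summarise(m = mean(decay_norm), .groups = "drop") |>
    dplyr::group_by(timepoint_h) |>
    dplyr::summarise(m = mean(m))
  expect_equal(check$m, rep(1, nrow(check)), tolerance = 1e-12)

  # second pass: factors recomputed on already-normalized values are all 1
  dn2 <- dn |> dplyr::mutate(rel_t0 = decay_norm)
  fac2 <- decay_factors(dn2, st)
  expect_equal(fac2$decay_factor, rep(1, nrow(fac2)), tolerance = 1e-12)

  expect_error(apply_decay_normalization(
    rel, dplyr::mutate(fac, decay_factor = 0)), "positive")
})

test_that("exponential fitting matches closed forms and the grid-search oracle", {
  f <- fit_decay(c(0, 1, 2), c(100, 50, 25))
  expect_equal(f$k, log(2), tolerance = 1e-7)
  expect_equal(f$half_life_h, 1, tolerance = 1e-6)
  expect_false(f$capped)

  # constant trajectory: k = 0, half-life reported at the 12 h cap
  fc <- fit_decay(c(0, 1, 2, 4, 8, 12), rep(3, 6), cap_h = 12)
  expect_equal(fc$k, 0)
  expect_equal(fc$half_life_h, 12)
  expect_true(fc$capped)

  # noisy trajectories agree with an independent profiled grid search
  set.seed(21)
  for (k_true in c(0.2, 0.6931, 2.31)) {
    t <- rep(c(0, 1, 2, 4, 8, 12), each = 3)
    v <- exp(-k_true * t) * exp(rnorm(length(t), 0, 0.15))
    fit <- fit_decay(t, v, cap_h = 12)
    oracle <- grid_fit(t, v)
    expect_equal(fit$k, unname(oracle["k"]), tolerance = 2e-3)
    expect_lte(fit$rss, oracle["sse"] + 1e-9)
  }

  # NB-counting noise at k = 2.31 (half-life 0.30 h): within 30% of truth
  p <- sim_params(seed = 6, background_fraction = 0, total_rna_decay_k = 0,
                  n_genes_per_class = c("tRF-1" = 1L), spike_in_n = 0L)
  truth <- tibble::tibble(
    seq_id = c("fast", "anchor"), sequence = NA_character_, class = "sim",
    locus_id = NA_character_, true_k = c(2.31, 0), true_a0 = c(5000, 100),
    true_enrichment = 1, is_spike = FALSE
  )
  tc <- simulate_timecourse(truth, p, seed = 61)
  rel <- t0_normalize(size_normalize(tc$counts, tc$samples))
  dn <- apply_decay_normalization(rel, decay_factors(rel, "anchor"))
  traj <- dn |> dplyr::filter(seq_id == "fast")
  fnb <- fit_decay(traj$timepoint_h, traj$decay_norm, cap_h = 12)
  expect_lt(abs(fnb$half_life_h - 0.30) / 0.30, 0.30)

  # too few points are skipped with a reason
  expect_identical(fit_decay(c(0, 1), c(1, 0.5))$status, "skipped_few_points")
})

test_that("half-life is strictly decreasing in k and exact at k = ln 2", {
  ks <- c(0.1, 0.3, log(2), 1.5, 3, 6)
  t <- c(0, 0.25, 0.5, 1, 2, 4)
  hl <- vapply(ks, function(k) {
    fit_decay(t, exp(-k * t), cap_h = 100)$half_life_h
  }, numeric(1))
  expect_true(all(diff(hl) < 0))
  expect_equal(hl[3], 1, tolerance = 1e-6)
})

test_that("rpm-normalized results are invariant to rescaling one library", {
  p <- small_params(seed = 8)
  truth <- simulate_truth(make_toy_genome(p), p)
  tc <- simulate_timecourse(truth, p)
  run <- function(counts, samples) {
    rel <- t0_normalize(size_normalize(counts, samples))
    dn <- apply_decay_normalization(rel, decay_factors(rel, identify_stable(rel)))
    tidy(fit_decay_all(dn))
  }
  a <- run(tc$counts, tc$samples)
  lib1 <- tc$samples$library[1]
  scaled <- tc$counts |>
    dplyr::mutate(count = ifelse(library == lib1, count * 7, count))
  ssheet <- tc$samples |>
    dplyr::mutate(total_count = ifelse(library == lib1, total_count * 7,
                                       total_count))
  b <- run(scaled, ssheet)
  expect_equal(a$k, b$k, tolerance = 1e-8)
})

test_that("expression filtering applies the 10-read floor and 50-count flag", {
  cnt <- tibble::tibble(
    seq_id = rep(c("lo", "edge", "hi"), each = 2),
    library = rep(c("L1", "L2"), 3),
    count = c(4, 5, 5, 5, 100, 100),
    norm = c(4, 5, 50, 30, 200, 25)
  )
  out <- expression_filters(cnt)
  expect_false("lo" %in% out$seq_id)          # 9 reads total: removed
  expect_true(all(out$highly_expressed[out$seq_id == "edge"]))  # >= 50 inclusive
  empty <- expression_filters(cnt[0, ])
  expect_identical(nrow(empty), 0L)
})

test_that("class summaries aggregate half-lives and fold changes per class", {
  counts <- tidyr::expand_grid(seq_id = c("s1", "s2"),
                               timepoint_h = c(0, 1, 2), replicate = 1) |>
    dplyr::mutate(
      library = sprintf("t%g", timepoint_h),
      class = "tRF-1",
      value = ifelse(seq_id == "s1", exp(-log(2) * timepoint_h),
                     exp(-log(2) / 3 * timepoint_h)),
      norm = ifelse(seq_id == "s1", 200 * value, 80 * value),
      count = norm
    )
  fits <- fit_decay_all(counts, value = "value", cap_h = 12)
  expect_equal(sort(fits$half_life_h), c(1, 3), tolerance = 1e-6)
  sm <- class_summaries(fits, counts, t_a = 0, t_b = 1, pseudocount = 0)
  expect_equal(sm$median_half_life_h, 2, tolerance = 1e-6)
  expect_equal(sm$median_log2fc, median(c(-1, -1 / 3)))

  # the documented -3 log2FC example: 200 rpm at 0 h, 25 rpm at 1 h
  df <- tibble::tibble(seq_id = "q", class = "tRF-1",
                       timepoint_h = c(0, 1), library = c("A", "B"),
                       count = c(200, 25), norm = c(200, 25),
                       value = c(200, 25))
  f1 <- fit_decay_all(df, value = "value", cap_h = 12, min_points = 2)
  sm1 <- class_summaries(f1, df, pseudocount = 0)
  expect_equal(sm1$median_log2fc, -3)
})
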