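# DTW distance and K-medoid clustering of beats.

test_that("DTW matches hand-checkable alignments", {
  expect_equal(dtw_distance(c(0, 1, 0), c(0, 1, 0)), 0)
  expect_equal(dtw_distance(c(0, 1, 0), c(0, 1, 1, 0)), 0)
  expect_equal(dtw_distance(c(0, 0, 0), c(1, 1, 1)), 3)
  expect_error(dtw_distance(numeric(0), 1), "nonempty")
})

test_that("DTW is symmetric, nonnegative and zero on identical inputs", {
  set.seed(4)
  for (rep in 1:25) {
    x <- rnorm(sample(3:40, 1))
    y <- rnorm(sample(3:40, 1))
    d <- dtw_distance(x, y)
    expect_gte(d, 0)
    expect_equal(d, dtw_distance(y, x))
    expect_equal(dtw_distance(x, x), 0)
  }
})

test_that("DTW equals brute-force path enumeration on short sequences", {
  seqs <- enumerate_sequences(3, alphabet = 0:2)
  for (i in seq_along(seqs)) {
    for (j in seq(i, length(seqs))) {
      expect_equal(dtw_distance(seqs[[i]], seqs[[j]]),
                   dtw_brute(seqs[[i]], seqs[[j]]))
    }
  }
  set.seed(21)
  for (rep in 1:100) {
    x <- rnorm(sample(2:6, 1))
    y <- rnorm(sample(2:6, 1))
    expect_equal(dtw_distance(x, y), dtw_brute(x, y))
  }
})

test_that("pairwise DTW matrix is symmetric with zero diagonal", {
  set.seed(2)
  wf <- lapply(1:6, function(i) rnorm(30))
  D <- dtw_pairwise(wf)
  expect_equal(D, t(D))
  expect_equal(diag(D), rep(0, 6))
  expect_equal(D[2, 5], dtw_distance(wf[[2]], wf[[5]]))
})

test_that("identical beats collapse to a zero-objective clustering", {
  bs <- normalize_beats(make_beat_set(rep(list(c(1, 2, 1, 0.5)), 12)))
  cr <- k_medoids_dtw(bs, K = 2, seed = 1)
  expect_true(cr$converged)
  expect_lte(cr$iterations, 2)
  expect_equal(tail(cr$objective_trace, 1), 0)
  expect_equal(intra_cluster_distance(cr, bs, normalized = TRUE), 0)
})

test_that("two repeated templates are recovered exactly", {
  tpl1 <- sin(2 * pi * seq(0, 1, length.out = 60))
  tpl2 <- sin(4 * pi * seq(0, 1, length.out = 60))^2
  wf <- c(rep(list(tpl1), 10), rep(list(tpl2), 10))
  # distinct RR so the heart-rate relabelling convention is well defined
  bs <- normalize_beats(make_beat_set(wf, rr = c(rep(0.9, 10),
                                                 rep(1.0, 10))))
  cr <- k_medoids_dtw(bs, K = 2, seed = 3)
  expect_true(cr$converged)
  expect_equal(tail(cr$objective_trace, 1), 0)
  expect_equal(cr$labels, c(rep(1L, 10), rep(2L, 10)))
  expect_equal(cr$C1$normalized, tpl1 / max(abs(tpl1)))
  expect_equal(cr$C2$normalized, tpl2 / max(abs(tpl2)))
})

test_that("objective is non-increasing and seeds reproduce results", {
  set.seed(6)
  wf <- lapply(1:30, function(i) {
    base <- if (i %% 2) sin(2 * pi * seq(0, 1, length.out = 80)) else
      cos(2 * pi * seq(0, 1, length.out = 90))
    base + rnorm(length(base), 0, 0.3)
  })
  bs <- normalize_beats(make_beat_set(wf))
  cr1 <- k_medoids_dtw(bs, K = 2, seed = 10)
  cr2 <- k_medoids_dtw(bs, K = 2, seed = 10)
  expect_identical(cr1$labels, cr2$labels)
  expect_identical(cr1$medoid_index, cr2$medoid_index)
  expect_true(all(diff(cr1$objective_trace) <= 1e-12))
})

test_that("clustering is invariant to beat order under deterministic init", {
  set.seed(14)
  wf <- lapply(1:20, function(i) {
    base <- if (i <= 10) sin(2 * pi * seq(0, 1, length.out = 70)) else
      1 - abs(seq(-1, 1, length.out = 70))
    base + rnorm(70, 0, 0.2)
  })
  rr <- seq(0.85, 1.04, by = 0.01)
  perm <- sample(20)
  bs1 <- normalize_beats(make_beat_set(wf, rr = rr))
  bs2 <- normalize_beats(make_beat_set(wf[perm], rr = rr[perm]))
  cr1 <- k_medoids_dtw(bs1, K = 2, init = "farthest")
  cr2 <- k_medoids_dtw(bs2, K = 2, init = "farthest")
  expect_identical(cr1$labels[perm], cr2$labels)
})

test_that("planted two-regime beats are recovered at >= 95% agreement", {
  cfg <- scg_config(duration_s = 40, cluster_mod_depth = 0.6,
                    noise_sd = 0.05, seed = 12)
  gen <- generate_recording(cfg)
  rec <- gen$record
  fs <- rec$fs
  scg <- moving_average(bandpass_zero_phase(rec$channels$scg_dv, fs), 5)
  bs <- normalize_beats(segment_beats(scg, fs, gen$truth$r_times))
  cr <- k_medoids_dtw(bs, K = 2, seed = 1)
  planted <- gen$truth$planted_label[seq_along(bs$beats)]
  agree <- max(mean(cr$labels == planted), mean(cr$labels != planted))
  expect_gte(agree, 0.95)
  # cluster-1-faster labelling convention
  hr <- 60 / vapply(bs$beats, `[[`, numeric(1), "rr_s")
  expect_gt(mean(hr[cr$labels == 1]), mean(hr[cr$labels == 2]))
})

test_that("K exceeding the number of beats is rejected", {
  bs <- normalize_beats(make_beat_set(list(c(1, 2), c(2, 1))))
  expect_error(k_medoids_dtw(bs, K = 3), "exceeds")
})

test_that("cluster-phase cross-tabulation scores the planted coupling", {
  cfg <- scg_config(duration_s = 40, cluster_mod_depth = 0.6,
                    noise_sd = 0.05, seed = 13)
  gen <- generate_recording(cfg)
  fs <- gen$record$fs
  scg <- moving_average(bandpass_zero_phase(gen$record$channels$scg_dv, fs), 5)
  bs <- normalize_beats(segment_beats(scg, fs, gen$truth$r_times))
  cr <- k_medoids_dtw(bs, K = 2, seed = 1)
  phases <- gen$truth$resp_phase[seq_along(bs$beats)]
  ct <- cross_tabulate_phase(cr, phases)
  expect_equal(dim(ct$table), c(2L, 4L))
  expect_equal(sum(ct$table), length(bs$beats))
  expect_gte(ct$association, 0.8)

  # no planted coupling: association near chance
  cfg0 <- scg_config(duration_s = 40, cluster_mod_depth = 0, seed = 13)
  gen0 <- generate_recording(cfg0)
  scg0 <- moving_average(bandpass_zero_phase(gen0$record$channels$scg_dv,
                                             gen0$record$fs), 5)
  bs0 <- normalize_beats(segment_beats(scg0, gen0$record$fs,
                                       gen0$truth$r_times))
  cr0 <- k_medoids_dtw(bs0, K = 2, seed = 1)
  ct0 <- cross_tabulate_phase(cr0, gen0$truth$resp_phase[seq_along(bs0$beats)])
  expect_lt(ct0$association, 0.8)

  expect_error(cross_tabulate_phase(cr, phases[-1]), "length")
})
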