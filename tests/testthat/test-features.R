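# Morphological variability, spectral ratios, cardiac timing intervals,
# per-cluster heart rate.

test_that("intra/inter distances match a direct summation oracle", {
  set.seed(5)
  wf <- lapply(1:14, function(i) {
    base <- if (i <= 7) c(0, 2, 4, 2, 0, 1, 0) else c(0, 1, 0, 3, 5, 3, 0)
    base + rnorm(7, 0, 0.2)
  })
  bs <- normalize_beats(make_beat_set(wf, rr = seq(0.87, 1.0, by = 0.01)))
  cr <- k_medoids_dtw(bs, K = 2, seed = 2)

  # independent oracle: brute-force DTW + literal summation of the two
  # defining formulas on the raw waveforms
  m <- list(cr$C1$raw, cr$C2$raw)
  n <- length(wf)
  intra_direct <- sum(vapply(seq_len(n), function(i) {
    dtw_brute(m[[cr$labels[i]]], bs$beats[[i]]$samples_raw)
  }, numeric(1))) / n
  inter_direct <- sum(vapply(seq_len(n), function(i) {
    dtw_brute(m[[3 - cr$labels[i]]], bs$beats[[i]]$samples_raw)
  }, numeric(1))) / n

  expect_equal(intra_cluster_distance(cr, bs), intra_direct)
  expect_equal(inter_cluster_distance(cr, bs), inter_direct)
})

test_that("degenerate clusterings give zero distances", {
  # two singleton clusters: each beat is its own medoid
  wf <- list(c(0, 1, 0), c(0, 2, 4, 0))
  bs <- normalize_beats(make_beat_set(wf, rr = c(0.9, 1.0)))
  cr <- k_medoids_dtw(bs, K = 2, seed = 1)
  expect_equal(intra_cluster_distance(cr, bs), 0)
  expect_equal(inter_cluster_distance(cr, bs),
               dtw_distance(wf[[1]], wf[[2]]))

  # all beats identical: intra and inter both vanish
  bs2 <- normalize_beats(make_beat_set(rep(list(c(1, 3, 1)), 10)))
  cr2 <- k_medoids_dtw(bs2, K = 2, seed = 1)
  expect_equal(intra_cluster_distance(cr2, bs2), 0)
  expect_equal(inter_cluster_distance(cr2, bs2), 0)
})

test_that("planted regime separation yields intra < inter", {
  for (seed in c(1, 2)) {
    cfg <- scg_config(duration_s = 30, cluster_mod_depth = 0.5,
                      noise_sd = 0.1, seed = seed)
    gen <- generate_recording(cfg)
    fs <- gen$record$fs
    scg <- moving_average(bandpass_zero_phase(gen$record$channels$scg_dv,
                                              fs), 5)
    bs <- normalize_beats(segment_beats(scg, fs, gen$truth$r_times))
    cr <- k_medoids_dtw(bs, K = 2, seed = 1)
    expect_lt(intra_cluster_distance(cr, bs),
              inter_cluster_distance(cr, bs))
  }
})

test_that("band energy ratios localize pure tones and sum to one", {
  fs <- 1000
  tt <- seq(0, 1 - 1 / fs, by = 1 / fs)
  tone15 <- sin(2 * pi * 15 * tt)
  sp <- band_energy_ratios(list(tone15, tone15), fs)
  expect_gte(sp$ratios[["11-20Hz"]], 0.99)
  expect_equal(sum(sp$ratios), 1, tolerance = 1e-6)

  tone35 <- sin(2 * pi * 35 * tt)
  sp35 <- band_energy_ratios(list(tone35, tone35), fs)
  expect_equal(which.max(sp35$ratios), 4L, ignore_attr = TRUE)

  # amplitude invariance
  sp_scaled <- band_energy_ratios(list(5 * tone15, 5 * tone15), fs)
  expect_equal(sp_scaled$ratios, sp$ratios)

  expect_error(band_energy_ratios(list(tone15), fs = 80), "fs")
})

test_that("AO/AC peaks are located on clean beat waveforms", {
  fs <- 1000
  beat <- make_beat_waveform(pep_ms = 70, lvep_ms = 300, fs = fs)
  f <- detect_ao_ac(beat, fs)
  expect_false(f$flagged)
  expect_lt(abs(f$ao_time - 0.140) * 1000, 5)   # q at 70 ms + PEP 70 ms
  expect_lt(abs(f$ac_time - 0.440) * 1000, 10)

  # absent AC packet: flagged undefined
  flat_ac <- make_beat_waveform(ac_amp = 0, fs = fs)
  f2 <- detect_ao_ac(flat_ac, fs)
  expect_true(f2$flagged)
  expect_true(is.na(f2$ac_time))

  # two equal maxima in the AO window resolve to the earlier peak
  w <- rep(0, 1000)
  w[c(151, 251)] <- 1      # peaks at 150 ms and 250 ms, equal height
  f3 <- detect_ao_ac(w, fs)
  expect_equal(f3$ao_time, 0.150)
})

test_that("PEP/LVEP recovery across a grid of planted intervals", {
  fs <- 1000
  for (pep in c(60, 90)) {
    for (lvep in c(260, 320)) {
      beat <- make_beat_waveform(pep_ms = pep, lvep_ms = lvep, fs = fs)
      f <- detect_ao_ac(beat, fs)
      cti <- compute_cti(0.07, f$ao_time, f$ac_time)
      expect_lt(abs(cti$pep_ms - pep), 5)
      expect_lt(abs(cti$lvep_ms - lvep), 5)
    }
  }
})

test_that("cardiac timing interval arithmetic and contracts", {
  cti <- compute_cti(0, 0.070, 0.370)
  expect_equal(cti$pep_ms, 70)
  expect_equal(cti$lvep_ms, 300)
  expect_equal(cti$pep_lvep_ratio, 70 / 300)

  expect_error(compute_cti(0.07, 0.07, 0.370), "ordering")
  expect_error(compute_cti(0, NA, 0.3), "NA")

  # averaging of the two medoids' values
  expect_equal(mean(c(70, 74)), 72)
  cr_avg <- list(pep = mean(c(70, 74)), lvep = mean(c(300, 290)))
  expect_equal(cr_avg$lvep, 295)
})

test_that("per-cluster heart rate summaries", {
  bs <- make_beat_set(rep(list(c(0, 1, 0)), 6), rr = rep(1, 6))
  hr <- heart_rate_by_cluster(bs, labels = rep(1:2, each = 3))
  expect_equal(hr$hr_mean, c(60, 60))
  expect_equal(hr$hr_se, c(0, 0))

  bs2 <- make_beat_set(rep(list(c(0, 1, 0)), 4), rr = c(0.9, 0.9, 1, 1))
  hr2 <- heart_rate_by_cluster(bs2, labels = c(1, 1, 2, 2))
  expect_equal(hr2$hr_mean, c(60 / 0.9, 60), tolerance = 1e-12)

  expect_error(heart_rate_by_cluster(bs2, labels = 1:3), "align")
})
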