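# Synthetic recording generator: RSA RR series, determinism, planted
# fiducials, respiratory-phase classification.

test_that("RR series follows the RSA model", {
  cfg0 <- scg_config(duration_s = 30, hr_mean = 60, rsa_depth = 0)
  rr0 <- generate_rr_series(cfg0)
  expect_true(all(rr0 == 1.0))

  cfg <- scg_config(duration_s = 120, hr_mean = 60, rsa_depth = 0.1,
                    resp_rate = 12)
  rr <- generate_rr_series(cfg)
  expect_true(all(rr >= 0.9 & rr <= 1.1))
  expect_equal(mean(rr), 1.0, tolerance = 0.01)
  # direct evaluation of the stated formula at the emitted beat times
  tt <- attr(rr, "t")
  expect_equal(as.numeric(rr),
               1.0 * (1 + 0.1 * sin(2 * pi * (12 / 60) * tt)))
  expect_lte(max(tt) + rr[length(rr)], 120)

  cfg60 <- scg_config(duration_s = 60, hr_mean = 60, rsa_depth = 0.08)
  n <- length(generate_rr_series(cfg60))
  expect_gte(n, 58)
  expect_lte(n, 62)
})

test_that("invalid configurations are rejected", {
  expect_error(scg_config(rsa_depth = 1), "rsa_depth")
  expect_error(scg_config(duration_s = -1), "duration_s")
  expect_error(scg_config(hr_mean = 150, pep_ms = 100, lvep_ms = 350),
               "min RR")
  expect_error(scg_config(session = 7), "session")
})

test_that("identical seeds reproduce recordings bit for bit", {
  cfg <- scg_config(duration_s = 12, seed = 42)
  a <- generate_recording(cfg)
  b <- generate_recording(cfg)
  expect_identical(a$record$channels, b$record$channels)
  expect_identical(a$truth$ao_times, b$truth$ao_times)

  c2 <- generate_recording(scg_config(duration_s = 12, seed = 43))
  expect_false(identical(a$record$channels$scg_dv,
                         c2$record$channels$scg_dv))
})

test_that("fiducial ordering and planted intervals hold beat-wise", {
  gen <- generate_recording(scg_config(duration_s = 30, seed = 3))
  tr <- gen$truth
  expect_true(all(tr$q_times < tr$r_times))
  expect_true(all(tr$r_times < tr$ao_times))
  expect_true(all(tr$ao_times < tr$ac_times))
  # planted PEP/LVEP deviate from the configured means only by jitter
  expect_lt(max(abs(tr$pep_ms - 70)), 5 * 2)     # 5 sigma at 2 ms jitter
  expect_lt(max(abs(tr$lvep_ms - 300)), 5 * sqrt(2) * 2)
  expect_equal(length(tr$r_times), length(tr$planted_label))
})

test_that("no modulation and no noise yields identical beats", {
  cfg <- scg_config(duration_s = 15, hr_mean = 60, rsa_depth = 0,
                    cluster_mod_depth = 0, noise_sd = 0,
                    baseline_wander_amp = 0, jitter_ms = 0, seed = 5)
  gen <- generate_recording(cfg)
  scg <- gen$record$channels$scg_dv
  fs <- gen$record$fs
  r <- gen$truth$r_times
  cuts <- lapply(seq_len(length(r) - 1), function(i) {
    idx <- (round((r[i] - 0.1) * fs) + 1):(round((r[i + 1] - 0.1) * fs))
    scg[idx]
  })
  for (i in seq_along(cuts)[-1]) {
    expect_equal(cuts[[i]], cuts[[1]], tolerance = 1e-12)
  }
})

test_that("respiratory phases partition a breath into four ordered arcs", {
  fs <- 100
  t <- seq(1 / fs, 4, by = 1 / fs)              # one 4 s breath
  vol <- 0.5 * (1 - cos(2 * pi * 0.25 * t))     # starts empty, inhaling
  flow <- 0.5 * 2 * pi * 0.25 * sin(2 * pi * 0.25 * t)
  ph <- classify_resp_phase(vol, flow, t)
  runs <- rle(as.character(ph))
  expect_equal(runs$values, c("LLV-INS", "HLV-INS", "HLV-EXP", "LLV-EXP"))
  expect_equal(sum(runs$lengths), length(t))

  # definitional spot checks
  expect_equal(as.character(classify_resp_phase(c(0.1, 0.2), c(1, 1),
                                                c(0, 1), at = 0)),
               "LLV-INS")
  expect_equal(as.character(classify_resp_phase(c(0.9, 0.8), c(-1, -1),
                                                c(0, 1), at = 0)),
               "HLV-EXP")
  # zero flow ties to expiration
  expect_equal(as.character(classify_resp_phase(c(0.1, 0.9), c(0, 0),
                                                c(0, 1), at = 0)),
               "LLV-EXP")
})

test_that("planted AO times are recoverable by the fiducial detector", {
  gen <- generate_recording(scg_config(duration_s = 20, seed = 9))
  rec <- gen$record
  tr <- gen$truth
  fs <- rec$fs
  scg <- moving_average(bandpass_zero_phase(rec$channels$scg_dv, fs), 5)
  for (i in 2:6) {
    start <- round((tr$r_times[i] - 0.1) * fs)
    beat <- scg[(start + 1):(start + round(tr$rr_s[i] * fs))]
    f <- detect_ao_ac(beat, fs)
    ao_abs <- start / fs + f$ao_time
    expect_lt(abs(ao_abs - tr$ao_times[i]) * 1000, 5)
  }
})

test_that("recordings round-trip through CSV + JSON sidecar", {
  gen <- generate_recording(scg_config(duration_s = 6, seed = 2,
                                       subject_id = "S07", session = 3))
  path <- file.path(tempdir(), "rec.csv")
  write_signal_record(gen$record, path)
  back <- read_signal_record(path)
  expect_equal(back$fs, gen$record$fs)
  expect_equal(back$subject_id, "S07")
  expect_equal(back$session, 3L)
  expect_equal(back$channels$scg_dv, gen$record$channels$scg_dv,
               tolerance = 1e-6)
})
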