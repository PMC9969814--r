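# Independent oracles and small fixture builders used across the suite.

# Brute-force DTW: recursive enumeration of every monotone warping path
# from (1,1) to (n,m) with steps {diagonal, down, right}, keeping the
# cheapest accumulated |x_i - y_j| cost. Branch-and-bound pruning on the
# running total is exact because local costs are nonnegative. Independent
# of the package's dynamic-programming kernel.
dtw_brute <- function(x, y) {
  n <- length(x)
  m <- length(y)
  best <- Inf
  rec <- function(i, j, acc) {
    acc <- acc + abs(x[i] - y[j])
    if (acc >= best) return(invisible())
    if (i == n && j == m) {
      best <<- acc
      return(invisible())
    }
    if (i < n && j < m) rec(i + 1, j + 1, acc)
    if (i < n) rec(i + 1, j, acc)
    if (j < m) rec(i, j + 1, acc)
    invisible()
  }
  rec(1, 1, 0)
  best
}

# All sequences of lengths 1..max_len over a small integer alphabet.
enumerate_sequences <- function(max_len, alphabet = 0:2) {
  out <- list()
  for (len in seq_len(max_len)) {
    grid <- do.call(expand.grid, rep(list(alphabet), len))
    out <- c(out, lapply(seq_len(nrow(grid)), function(r) {
      as.numeric(grid[r, ])
    }))
  }
  out
}

# Build a beat_set directly from a list of waveforms (bypasses the
# segmentation stage so clustering/features can be unit-tested on exactly
# known inputs). RR defaults to the waveform length at fs.
make_beat_set <- function(waveforms, fs = 1000, rr = NULL,
                          q_time = 0.07) {
  beats <- lapply(seq_along(waveforms), function(i) {
    w <- waveforms[[i]]
    rr_i <- if (is.null(rr)) length(w) / fs else rr[i]
    list(index = i, r_time = i * 1.0, start_sample = (i - 1L) * length(w),
         end_sample = (i - 1L) * length(w) + length(w),
         samples = w, rr_s = rr_i, hr_bpm = 60 / rr_i, q_time = q_time)
  })
  structure(list(fs = fs, beats = beats, normalized = FALSE,
                 posture = NA_character_, session = NA_integer_),
            class = "beat_set")
}

# A clean synthetic beat waveform built from first principles (not via
# generate_recording): R at 0.1 s into the beat, AO/AC packets at the
# given intervals. Used to test fiducial detection in isolation.
make_beat_waveform <- function(pep_ms = 70, lvep_ms = 300, rr_s = 1,
                               fs = 1000, ao_amp = 3, ac_amp = 1.5,
                               q_offset_s = 0.07) {
  tt <- seq(0, rr_s - 1 / fs, by = 1 / fs)
  ao_c <- q_offset_s + pep_ms / 1000
  ac_c <- ao_c + lvep_ms / 1000
  ao_amp * exp(-(tt - ao_c)^2 / (2 * 0.012^2)) *
    cos(2 * pi * 20 * (tt - ao_c)) +
    ac_amp * exp(-(tt - ac_c)^2 / (2 * 0.009^2)) *
    cos(2 * pi * 30 * (tt - ac_c))
}
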