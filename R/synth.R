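# Synthetic ECG + SCG + respiration generator with known ground truth.
#
# The generator emulates the features of real recordings that the analysis
# chain depends on: RR intervals modulated by respiratory sinus arrhythmia
# (RSA), an ECG with identifiable Q and R deflections, SCG beats built from
# two Gaussian-windowed wave packets (AO, aortic opening; AC, aortic
# closure) at configurable PEP/LVEP, a two-regime beat-morphology
# modulation coupled to respiratory phase, baseline wander, and additive
# Gaussian noise. Every planted event time and label is returned, so each
# downstream stage can be tested against ground truth.

#' Posture parameter presets
#'
#' Mean cardiac timing intervals and heart rate by posture. PEP lengthens
#' and LVEP shortens from supine to sitting (reduced venous return raises
#' sympathetic drive), and heart rate rises; the presets encode that
#' pattern (PEP 70 / 74 / 80.6 ms and LVEP 300 / 286.9 / 272 ms for supine,
#' 45 degree tilt and sitting).
#'
#' @param posture one of `"supine"`, `"tilt45"`, `"sitting"`.
#' @return named list with `pep_ms`, `lvep_ms`, `hr_mean`.
#' @export
posture_preset <- function(posture = c("supine", "tilt45", "sitting")) {
  posture <- match.arg(posture)
  switch(posture,
    supine  = list(pep_ms = 70,   lvep_ms = 300,   hr_mean = 65),
    tilt45  = list(pep_ms = 74,   lvep_ms = 286.9, hr_mean = 68),
    sitting = list(pep_ms = 80.6, lvep_ms = 272,   hr_mean = 70)
  )
}

#' Generator configuration
#'
#' Collects every knob of the synthetic recording in one validated object.
#'
#' @param duration_s record length in seconds (> 0).
#' @param fs sampling rate in Hz (>= 200; default 1000).
#' @param posture `"supine"`, `"tilt45"` or `"sitting"`; supplies defaults
#'   for `pep_ms`, `lvep_ms` and `hr_mean` via [posture_preset()].
#' @param hr_mean mean heart rate in beats/min.
#' @param rsa_depth fraction of the RR interval modulated by respiration
#'   (`0 <= rsa_depth < 1`); 0.08 is a typical resting depth for young
#'   adults.
#' @param resp_rate breathing rate in breaths/min.
#' @param pep_ms pre-ejection period (ECG Q point to AO peak), ms.
#' @param lvep_ms left-ventricular ejection period (AO to AC peak), ms.
#' @param cluster_mod_depth amplitude of the two-regime morphology
#'   modulation (0 disables it; beats then differ only by noise).
#' @param noise_sd additive Gaussian noise SD on the SCG channel, milli-g.
#' @param baseline_wander_amp respiration-locked baseline wander amplitude,
#'   milli-g.
#' @param jitter_ms beat-to-beat Gaussian jitter SD on PEP and LVEP, ms.
#' @param subject_id,session record metadata (session in 1..5).
#' @param seed integer; fully determines the generated record.
#' @return object of class `scg_config`.
#' @export
scg_config <- function(duration_s = 60, fs = 1000,
                       posture = "supine",
                       hr_mean = NULL, rsa_depth = 0.08, resp_rate = 15,
                       pep_ms = NULL, lvep_ms = NULL,
                       cluster_mod_depth = 0.3, noise_sd = 0.2,
                       baseline_wander_amp = 1, jitter_ms = 2,
                       subject_id = "S01", session = 1L, seed = 1L) {
  posture <- match.arg(posture, c("supine", "tilt45", "sitting"))
  preset <- posture_preset(posture)
  if (is.null(hr_mean)) hr_mean <- preset$hr_mean
  if (is.null(pep_ms)) pep_ms <- preset$pep_ms
  if (is.null(lvep_ms)) lvep_ms <- preset$lvep_ms

  if (!is_scalar_num(duration_s) || duration_s <= 0) {
    stopf("`duration_s` must be a positive number")
  }
  if (!is_scalar_num(fs) || fs < 200) stopf("`fs` must be >= 200 Hz")
  if (!is_scalar_num(rsa_depth) || rsa_depth < 0 || rsa_depth >= 1) {
    stopf("`rsa_depth` must lie in [0, 1): depth >= 1 allows negative RR")
  }
  if (!(session %in% 1:5)) stopf("`session` must be an integer in 1..5")
  min_rr_ms <- (60 / hr_mean) * (1 - rsa_depth) * 1000
  if (!(pep_ms > 0 && pep_ms + lvep_ms < min_rr_ms)) {
    stopf("need 0 < pep_ms < pep_ms + lvep_ms < min RR (%.0f ms)", min_rr_ms)
  }
  structure(list(
    duration_s = duration_s, fs = fs, posture = posture,
    hr_mean = hr_mean, rsa_depth = rsa_depth, resp_rate = resp_rate,
    pep_ms = pep_ms, lvep_ms = lvep_ms,
    cluster_mod_depth = cluster_mod_depth, noise_sd = noise_sd,
    baseline_wander_amp = baseline_wander_amp, jitter_ms = jitter_ms,
    subject_id = subject_id, session = as.integer(session),
    seed = as.integer(seed)
  ), class = "scg_config")
}

#' @export
print.scg_config <- function(x, ...) {
  cat(sprintf(
    "<scg_config> %s posture=%s session=%d: %gs @ %g Hz, HR %g bpm,\n",
    x$subject_id, x$posture, x$session, x$duration_s, x$fs, x$hr_mean))
  cat(sprintf(
    "  RSA depth %.2f @ %g br/min, PEP %g ms, LVEP %g ms, mod %.2f,\n",
    x$rsa_depth, x$resp_rate, x$pep_ms, x$lvep_ms, x$cluster_mod_depth))
  cat(sprintf("  noise sd %g mg, wander %g mg, seed %d\n",
              x$noise_sd, x$baseline_wander_amp, x$seed))
  invisible(x)
}

#' RR-interval series with respiratory sinus arrhythmia
#'
#' Deterministic RSA model: the i-th interval, starting at beat time
#' `t_i`, is `RR_i = (60/hr_mean) * (1 + rsa_depth * sin(2*pi*f_resp*t_i))`
#' with `f_resp = resp_rate/60` Hz. Beats are emitted until the next one
#' would fall outside the record; the cumulative sum never exceeds
#' `duration_s`.
#'
#' @param cfg an [scg_config()].
#' @param start_s time of the first beat relative to record start (s).
#' @return numeric vector of RR intervals in seconds; attribute `"t"`
#'   holds the corresponding beat onset times.
#' @export
generate_rr_series <- function(cfg, start_s = 0) {
  stopifnot(inherits(cfg, "scg_config"))
  f_resp <- cfg$resp_rate / 60
  rr0 <- 60 / cfg$hr_mean
  t <- start_s
  times <- numeric(0)
  rr <- numeric(0)
  repeat {
    rri <- rr0 * (1 + cfg$rsa_depth * sin(2 * pi * f_resp * t))
    if (t + rri > cfg$duration_s) break
    times <- c(times, t)
    rr <- c(rr, rri)
    t <- t + rri
  }
  structure(rr, t = times)
}

# Gaussian-windowed cosine packet centred at `center` (s): the packet's
# largest sample sits exactly at the centre, which is what makes the
# planted AO/AC times recoverable by peak picking.
gauss_packet <- function(t, center, amp, carrier_hz, sigma_s) {
  amp * exp(-(t - center)^2 / (2 * sigma_s^2)) *
    cos(2 * pi * carrier_hz * (t - center))
}

# In-place windowed packet addition: the Gaussian envelope is below 2e-14
# of its peak beyond 8 sigma, so evaluation is restricted to that window.
add_packet <- function(sig, fs, center, amp, carrier_hz, sigma_s) {
  lo <- max(1L, as.integer(floor((center - 8 * sigma_s) * fs)) + 1L)
  hi <- min(length(sig), as.integer(ceiling((center + 8 * sigma_s) * fs)) + 1L)
  if (hi < lo) return(sig)
  tt <- (seq.int(lo, hi) - 1) / fs
  sig[lo:hi] <- sig[lo:hi] +
    gauss_packet(tt, center, amp, carrier_hz, sigma_s)
  sig
}

#' Classify respiratory phase
#'
#' Labels a time point by lung-volume level and airflow direction:
#' inspiration (`INS`) iff flow > 0, expiration (`EXP`) otherwise (a flow
#' of exactly zero is classed as expiration); high lung volume (`HLV`) iff
#' the volume exceeds the mid-range (mean of the channel's min and max),
#' low (`LLV`) otherwise. The four labels partition each breath into four
#' contiguous arcs.
#'
#' @param lung_volume,flow numeric vectors sampled on the same grid.
#' @param times sample times (s) for the two channels.
#' @param at query times (s); each is matched to the nearest sample.
#' @return factor with levels `LLV-INS`, `HLV-INS`, `HLV-EXP`, `LLV-EXP`.
#' @export
classify_resp_phase <- function(lung_volume, flow, times, at = times) {
  if (length(lung_volume) != length(flow) ||
      length(flow) != length(times)) {
    stopf("`lung_volume`, `flow` and `times` must share one grid")
  }
  idx <- vapply(at, function(a) which.min(abs(times - a)), integer(1))
  mid <- (min(lung_volume) + max(lung_volume)) / 2
  ins <- flow[idx] > 0
  hlv <- lung_volume[idx] > mid
  lab <- ifelse(hlv,
                ifelse(ins, "HLV-INS", "HLV-EXP"),
                ifelse(ins, "LLV-INS", "LLV-EXP"))
  factor(lab, levels = resp_phase_levels())
}

resp_phase_levels <- function() c("LLV-INS", "HLV-INS", "HLV-EXP", "LLV-EXP")

#' Generate a synthetic ECG + SCG recording with ground truth
#'
#' Builds a multichannel record on a uniform time grid:
#'
#' * **ECG** (mV): per beat, a narrow positive R deflection and a small
#'   negative Q deflection 30 ms before R.
#' * **SCG, dorsoventral** (milli-g): per beat, an AO packet (~20 Hz
#'   carrier) centred `pep_ms` after Q and a smaller AC packet (~30 Hz
#'   carrier) centred `lvep_ms` after AO, plus respiration-locked baseline
#'   wander and white noise. Beat-to-beat PEP/LVEP jitter is Gaussian
#'   (`jitter_ms`).
#' * **Respiration**: `lung_volume` is a raised cosine at `resp_rate`,
#'   phased so that the high-lung-volume half-cycle coincides with the
#'   short-RR (fast heart rate) half of the RSA cycle, as observed in
#'   respiration-clustered SCG data; `flow` is its analytic derivative.
#'
#' Morphology is modulated between two regimes driven by the respiratory
#' phase at the R wave: beats in the high-lung-volume arc (`HLV-INS`,
#' `HLV-EXP`; planted label 1) get an extra low-frequency component after
#' AO, a wider AO packet and a stronger AC packet than beats in the
#' low-volume arc (label 2), with all three differences scaled by
#' `cluster_mod_depth`. These are shape (not pure amplitude) changes, so
#' they survive per-beat amplitude normalization, and the packet centres
#' are untouched, so planted PEP/LVEP remain recoverable.
#'
#' The same seed always reproduces the same record bit for bit.
#'
#' @param cfg an [scg_config()].
#' @return list with elements `record` (an `scg_record`: `fs`, `channels`
#'   data frame `time_s, ecg, scg_dv, lung_volume, flow`, plus metadata)
#'   and `truth` (an `scg_truth`: per-beat `r_times`, `q_times`,
#'   `ao_times`, `ac_times` in seconds, `planted_label` in \{1, 2\},
#'   `resp_phase`, and the realized per-beat `pep_ms`/`lvep_ms`).
#' @export
generate_recording <- function(cfg) {
  stopifnot(inherits(cfg, "scg_config"))
  with_local_seed(cfg$seed, {
    fs <- cfg$fs
    t <- seq(0, cfg$duration_s, by = 1 / fs)
    n <- length(t)
    f_resp <- cfg$resp_rate / 60
    theta <- 2 * pi * f_resp * t

    # Respiration: HLV arc aligned with the short-RR half of the RSA cycle.
    lung_volume <- 0.5 * (1 - sin(theta))
    flow <- -0.5 * 2 * pi * f_resp * cos(theta)

    # Beats; first R placed 0.5 s in so its segment window is complete.
    rr <- generate_rr_series(cfg, start_s = 0.5)
    r_times <- attr(rr, "t")
    nb <- length(r_times)
    if (nb < 3) stopf("record too short for a usable beat series")

    resp_phase <- classify_resp_phase(lung_volume, flow, t, at = r_times)
    planted_label <- ifelse(resp_phase %in% c("HLV-INS", "HLV-EXP"), 1L, 2L)

    q_times <- r_times - 0.030
    jit <- matrix(rnorm(2 * nb, 0, cfg$jitter_ms / 1000), ncol = 2)
    ao_times <- q_times + cfg$pep_ms / 1000 + jit[, 1]
    ac_times <- ao_times + cfg$lvep_ms / 1000 + jit[, 2]

    ecg <- rnorm(n, 0, cfg$noise_sd / 20)
    scg <- cfg$baseline_wander_amp * sin(theta) + rnorm(n, 0, cfg$noise_sd)

    m <- cfg$cluster_mod_depth
    for (i in seq_len(nb)) {
      sgn <- if (planted_label[i] == 1L) 1 else -1
      # ECG: R and Q deflections
      ecg <- add_packet(ecg, fs, r_times[i], 1.0, 0, 0.006)
      ecg <- add_packet(ecg, fs, q_times[i], -0.15, 0, 0.004)
      # SCG: AO + AC packets with regime-dependent shape
      ao_sigma <- 0.012 * (1 + 0.4 * m * sgn)
      ac_amp <- 1.5 * (1 + 0.4 * m * sgn)
      scg <- add_packet(scg, fs, ao_times[i], 3.0, 20, ao_sigma)
      scg <- add_packet(scg, fs, ac_times[i], ac_amp, 30, 0.009)
      if (m > 0) {
        scg <- add_packet(scg, fs, ao_times[i] + 0.045, 1.2 * m * sgn,
                          14, 0.010)
      }
    }

    record <- structure(list(
      fs = fs,
      channels = data.frame(time_s = t, ecg = ecg, scg_dv = scg,
                            lung_volume = lung_volume, flow = flow),
      subject_id = cfg$subject_id, posture = cfg$posture,
      session = cfg$session
    ), class = "scg_record")

    truth <- structure(list(
      r_times = r_times, q_times = q_times,
      ao_times = ao_times, ac_times = ac_times,
      planted_label = planted_label, resp_phase = resp_phase,
      pep_ms = (ao_times - q_times) * 1000,
      lvep_ms = (ac_times - ao_times) * 1000,
      rr_s = as.numeric(rr)
    ), class = "scg_truth")

    list(record = record, truth = truth)
  })
}

#' @export
print.scg_record <- function(x, ...) {
  cat(sprintf(
    "<scg_record> %s posture=%s session=%d: %d samples @ %g Hz (%s)\n",
    x$subject_id, x$posture, x$session, nrow(x$channels), x$fs,
    paste(setdiff(names(x$channels), "time_s"), collapse = ", ")))
  invisible(x)
}

#' Write / read a recording as CSV with a JSON metadata sidecar
#'
#' The CSV holds the channel table (`time_s, ecg, scg_dv, lung_volume,
#' flow`); `<path>.meta.json` holds sampling rate, subject, posture and
#' session.
#'
#' @param record an `scg_record`.
#' @param path CSV file path.
#' @return `write_signal_record` returns `path` invisibly;
#'   `read_signal_record` returns an `scg_record`.
#' @export
write_signal_record <- function(record, path) {
  stopifnot(inherits(record, "scg_record"))
  write.csv(record$channels, path, row.names = FALSE)
  meta <- list(fs = record$fs, subject_id = record$subject_id,
               posture = record$posture, session = record$session)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_signal_record
#' @param path CSV file path written by `write_signal_record`.
#' @export
read_signal_record <- function(path) {
  channels <- read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".meta.json"), simplifyVector = TRUE)
  structure(list(fs = meta$fs, channels = channels,
                 subject_id = meta$subject_id, posture = meta$posture,
                 session = as.integer(meta$session)),
            class = "scg_record")
}

#' Write ground truth as JSON
#'
#' @param truth an `scg_truth` as returned by [generate_recording()].
#' @param path output JSON path.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "scg_truth"))
  out <- unclass(truth)
  out$resp_phase <- as.character(out$resp_phase)
  jsonlite::write_json(out, path, digits = NA)
  invisible(path)
}
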