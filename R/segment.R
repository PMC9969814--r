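# ECG R-peak detection (Pan-Tompkins) and R-gated SCG beat segmentation.

#' Detect ECG R peaks (Pan-Tompkins)
#'
#' Classic Pan-Tompkins stages: band-pass ~5-15 Hz (zero-phase, so the
#' detected fiducials carry no filter lag), five-point derivative,
#' squaring, 150 ms moving-window integration, then adaptive dual
#' thresholds on the integrated signal with a 200 ms refractory period and
#' a search-back pass for missed beats. Each accepted detection is refined
#' to the raw-ECG maximum within +/- 75 ms.
#'
#' @param ecg numeric vector (mV).
#' @param fs sampling rate in Hz (>= 200); at least 2 s of signal.
#' @param refractory_s minimum R-R separation in seconds (default 0.2).
#' @param integration_s moving-window integration length in seconds
#'   (default 0.15).
#' @return ascending numeric vector of R times in seconds (empty for a
#'   flat or sub-threshold signal).
#' @export
detect_r_peaks <- function(ecg, fs, refractory_s = 0.2,
                           integration_s = 0.15) {
  if (fs < 200) stopf("`fs` must be >= 200 Hz")
  n <- length(ecg)
  if (n < 2 * fs) stopf("need at least 2 s of ECG")
  if (max(ecg) - min(ecg) < .Machine$double.eps^0.5) return(numeric(0))

  bp <- bandpass_zero_phase(ecg, fs, low = 5, high = 15, order = 4,
                            atten_db = 40)
  # centered five-point derivative
  dkern <- c(1, 2, 0, -2, -1) / 8
  deriv <- as.numeric(stats::filter(bp, dkern, sides = 2))
  deriv[is.na(deriv)] <- 0
  sq <- deriv^2
  win <- max(3L, as.integer(round(integration_s * fs)))
  if (win %% 2 == 0) win <- win + 1L
  mwi <- moving_average(sq, win)

  # candidate peaks: local maxima of the integrated signal that dominate
  # their refractory neighbourhood (the integrated QRS hump carries ripple
  # from the band-pass, so plain local maxima over-segment each beat)
  refr <- as.integer(round(refractory_s * fs))
  cand <- which(diff(sign(diff(mwi))) < 0) + 1L
  if (!length(cand)) return(numeric(0))
  cand <- cand[vapply(cand, function(p) {
    mwi[p] >= max(mwi[max(1L, p - refr):min(n, p + refr)])
  }, logical(1))]
  if (!length(cand)) return(numeric(0))

  init_n <- min(n, as.integer(2 * fs))
  spki <- max(mwi[seq_len(init_n)]) / 3
  npki <- mean(mwi[seq_len(init_n)]) / 2
  thr <- function() npki + 0.25 * (spki - npki)

  # peak slope in a 50 ms neighbourhood, used to tell genuine QRS
  # complexes from T waves / filter ring-down within 360 ms of a beat
  slope_win <- as.integer(round(0.025 * fs))
  slope_at <- function(p) {
    max(abs(deriv[max(1L, p - slope_win):min(n, p + slope_win)]))
  }

  qrs <- integer(0)
  noise_peaks <- integer(0)
  rr_recent <- numeric(0)
  last <- -Inf
  for (p in cand) {
    if (p - last < refr) next
    if (mwi[p] >= thr()) {
      if (is.finite(last) && (p - last) < 0.36 * fs &&
          slope_at(p) < 0.5 * slope_at(last)) {
        # low-slope peak shortly after a beat: ring-down, not a QRS
        npki <- 0.125 * mwi[p] + 0.875 * npki
        next
      }
      # search-back first: did we skip a beat since the last detection?
      if (length(rr_recent) >= 2 && length(qrs)) {
        rr_avg <- mean(utils::tail(rr_recent, 8))
        if ((p - last) > 1.66 * rr_avg) {
          miss <- cand[cand > last + refr & cand < p - refr]
          if (length(miss)) {
            mb <- miss[which.max(mwi[miss])]
            if (mwi[mb] >= 0.5 * thr()) {
              qrs <- c(qrs, mb)
              rr_recent <- c(rr_recent, mb - last)
              spki <- 0.25 * mwi[mb] + 0.75 * spki
              last <- mb
            }
          }
        }
      }
      if (length(qrs)) rr_recent <- c(rr_recent, p - last)
      qrs <- c(qrs, p)
      spki <- 0.125 * mwi[p] + 0.875 * spki
      last <- p
    } else {
      noise_peaks <- c(noise_peaks, p)
      npki <- 0.125 * mwi[p] + 0.875 * npki
    }
  }
  if (!length(qrs)) return(numeric(0))

  # refine to the raw-ECG maximum near each integrated-signal peak
  half <- as.integer(round(0.075 * fs))
  r_idx <- vapply(qrs, function(p) {
    lo <- max(1L, p - half)
    hi <- min(n, p + half)
    lo + which.max(ecg[lo:hi]) - 1L
  }, integer(1))
  r_idx <- sort(unique(r_idx))
  # collapse refinements that landed on the same R within the refractory
  if (length(r_idx) > 1) {
    keep <- rep(TRUE, length(r_idx))
    for (i in 2:length(r_idx)) {
      j <- max(which(keep[seq_len(i - 1)]))
      if (r_idx[i] - r_idx[j] < refr) {
        if (ecg[r_idx[i]] > ecg[r_idx[j]]) keep[j] <- FALSE else keep[i] <- FALSE
      }
    }
    r_idx <- r_idx[keep]
  }
  (r_idx - 1) / fs
}

#' Locate ECG Q points
#'
#' The Q point of each beat is taken as the ECG minimum in the 50 ms
#' window ending at the R peak, `[R - 50 ms, R)` - a fixed argmin-in-window
#' rule that covers the physiologic QR interval at resting heart rates.
#' A beat is flagged when the window is truncated by the record start or
#' when the minimum sits on the window's left edge (monotone window, no
#' clear Q deflection).
#'
#' @param ecg numeric vector (mV).
#' @param fs sampling rate in Hz.
#' @param r_times R-peak times in seconds (from [detect_r_peaks()]).
#' @param window_s search-window length before R in seconds (default 0.05).
#' @return data frame with columns `r_time`, `q_time` (NA when the window
#'   is empty) and `flagged`.
#' @export
detect_q_points <- function(ecg, fs, r_times, window_s = 0.05) {
  wlen <- as.integer(round(window_s * fs))
  out <- data.frame(r_time = r_times, q_time = NA_real_, flagged = FALSE)
  for (i in seq_along(r_times)) {
    r_idx <- as.integer(round(r_times[i] * fs)) + 1L
    lo <- r_idx - wlen
    truncated <- lo < 1L
    lo <- max(1L, lo)
    hi <- r_idx - 1L
    if (hi < lo) {
      out$flagged[i] <- TRUE
      next
    }
    w <- ecg[lo:hi]
    k <- which.min(w)
    out$q_time[i] <- (lo + k - 1L - 1L) / fs
    out$flagged[i] <- truncated || k == 1L
  }
  out
}

#' Segment an SCG trace into R-gated beats
#'
#' Beat `i` spans `[r_i - 0.1 s, r_{i+1} - 0.1 s)` in half-open, 0-based
#' sample indices: each beat starts 0.1 s before its R peak and ends 0.1 s
#' before the next one, so consecutive windows tile the record with no
#' gaps or overlaps and the last R peak yields no beat. A first R peak
#' earlier than 0.1 s into the record cannot host a full window and is
#' dropped with a message.
#'
#' @param scg numeric vector (milli-g).
#' @param fs sampling rate in Hz.
#' @param r_times ascending R-peak times in seconds (>= 2).
#' @param posture,session optional metadata carried on the result.
#' @return a `beat_set`: list with `fs`, `beats` (each beat a list with
#'   `index`, `r_time`, `start_sample`, `end_sample` (0-based, half-open),
#'   `samples`, `rr_s`, `hr_bpm`, `q_time` slot filled later), `normalized`
#'   flag and metadata.
#' @export
segment_beats <- function(scg, fs, r_times, posture = NA_character_,
                          session = NA_integer_) {
  if (length(r_times) < 2) stopf("need at least 2 R peaks to segment")
  if (is.unsorted(r_times, strictly = TRUE)) stopf("`r_times` must ascend")
  pre <- 0.1
  if (r_times[1] < pre) {
    message(sprintf("first R peak at %.3f s < %.1f s: first beat dropped",
                    r_times[1], pre))
    r_times <- r_times[-1]
    if (length(r_times) < 2) {
      return(structure(list(fs = fs, beats = list(), normalized = FALSE,
                            posture = posture, session = session),
                       class = "beat_set"))
    }
  }
  nb <- length(r_times) - 1
  beats <- vector("list", nb)
  for (i in seq_len(nb)) {
    start <- as.integer(round((r_times[i] - pre) * fs))      # 0-based
    end <- as.integer(round((r_times[i + 1] - pre) * fs))
    rr <- r_times[i + 1] - r_times[i]
    beats[[i]] <- list(index = i, r_time = r_times[i],
                       start_sample = start, end_sample = end,
                       samples = scg[(start + 1L):end],
                       rr_s = rr, hr_bpm = 60 / rr)
  }
  structure(list(fs = fs, beats = beats, normalized = FALSE,
                 posture = posture, session = session),
            class = "beat_set")
}

#' @export
print.beat_set <- function(x, ...) {
  cat(sprintf("<beat_set> %d beats @ %g Hz%s%s\n", length(x$beats), x$fs,
              if (isTRUE(x$normalized)) " (normalized)" else "",
              if (!is.na(x$posture)) paste0(", posture=", x$posture) else ""))
  invisible(x)
}

#' Normalize beats by their maximum amplitudes
#'
#' Divides each beat by its own maximum absolute amplitude, so every beat
#' peaks at |1|. Shape-based clustering runs on these normalized beats;
#' the original milli-g waveforms are retained (as `samples_raw`) so the
#' morphological distances can still be reported in physical units.
#'
#' @param bs a `beat_set`.
#' @return the `beat_set` with normalized `samples`, originals in
#'   `samples_raw`, and `normalized = TRUE`.
#' @export
normalize_beats <- function(bs) {
  stopifnot(inherits(bs, "beat_set"))
  bs$beats <- lapply(bs$beats, function(b) {
    peak <- max(abs(b$samples))
    if (peak == 0) stopf("beat %d is all-zero and cannot be normalized",
                         b$index)
    if (is.null(b$samples_raw)) b$samples_raw <- b$samples
    b$samples <- b$samples_raw / max(abs(b$samples_raw))
    b
  })
  bs$normalized <- TRUE
  bs
}

# Convenience extractors used throughout the package.
beat_waveforms <- function(bs, raw = FALSE) {
  lapply(bs$beats, function(b) {
    if (raw && !is.null(b$samples_raw)) b$samples_raw else b$samples
  })
}

beat_rr <- function(bs) vapply(bs$beats, `[[`, numeric(1), "rr_s")

#' Serialize a beat set
#'
#' Writes a JSON index (per-beat boundaries, RR, HR) and a CSV of beat
#' waveforms (one row per beat, NA-padded to the longest beat).
#'
#' @param bs a `beat_set`.
#' @param path_prefix output prefix; writes `<prefix>.json` and
#'   `<prefix>.csv`.
#' @export
write_beat_set <- function(bs, path_prefix) {
  stopifnot(inherits(bs, "beat_set"))
  idx <- data.frame(
    index = vapply(bs$beats, `[[`, numeric(1), "index"),
    r_time = vapply(bs$beats, `[[`, numeric(1), "r_time"),
    start_sample = vapply(bs$beats, `[[`, numeric(1), "start_sample"),
    end_sample = vapply(bs$beats, `[[`, numeric(1), "end_sample"),
    rr_s = vapply(bs$beats, `[[`, numeric(1), "rr_s"),
    hr_bpm = vapply(bs$beats, `[[`, numeric(1), "hr_bpm"))
  jsonlite::write_json(list(fs = bs$fs, normalized = bs$normalized,
                            posture = bs$posture, session = bs$session,
                            beats = idx),
                       paste0(path_prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  wf <- beat_waveforms(bs)
  maxlen <- max(lengths(wf))
  mat <- t(vapply(wf, function(w) c(w, rep(NA_real_, maxlen - length(w))),
                  numeric(maxlen)))
  write.csv(mat, paste0(path_prefix, ".csv"), row.names = FALSE)
  invisible(path_prefix)
}
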