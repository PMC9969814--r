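# Feature families computed from a clustered beat set: morphological
# variability (intra/inter-cluster DTW distances), spectral band-energy
# ratios of the cluster medoids, cardiac timing intervals (PEP/LVEP) read
# off the medoids, and per-cluster heart rate.

# Shared machinery for the two morphological variability measures.
# `swap = FALSE` pairs each beat with its own cluster's medoid (intra),
# `swap = TRUE` with the opposite medoid (inter). Distances are evaluated
# on the un-normalized (milli-g) waveforms by default so the variability
# is reported in physical units; clustering itself ran on normalized
# shapes (amplitude normalization does not materially affect the DTW
# ordering, but the reported variability should carry units).
cluster_distance <- function(cr, bs, swap, normalized = FALSE,
                             window = NULL) {
  stopifnot(inherits(cr, "cluster_result"), inherits(bs, "beat_set"))
  if (cr$n1 == 0 || cr$n2 == 0) stopf("both clusters must be non-empty")
  wf <- beat_waveforms(bs, raw = !normalized)
  slot <- if (normalized) "normalized" else "raw"
  m <- list(cr$C1[[slot]], cr$C2[[slot]])
  w <- if (is.null(window)) -1L else as.integer(window)
  total <- 0
  for (j in 1:2) {
    members <- wf[cr$labels == j]
    ref <- if (swap) m[[3 - j]] else m[[j]]
    total <- total + sum(.dtw_to_ref_cpp(members, as.numeric(ref), w))
  }
  total / (cr$n1 + cr$n2)
}

#' Intra-cluster morphological distance
#'
#' Mean DTW distance of every beat to its own cluster's medoid:
#' `(1/(n1+n2)) * (sum_i dtw(C1, X_i1) + sum_i dtw(C2, X_i2))`. Low values
#' indicate homogeneous beat morphology within each respiration-linked
#' group; well separated groups have low intra- and high inter-cluster
#' distance.
#'
#' @param cr a `cluster_result` with both clusters non-empty.
#' @param bs the clustered `beat_set`.
#' @param normalized if `FALSE` (default) distances are evaluated on the
#'   un-normalized milli-g waveforms (and so are reported in milli-g);
#'   `TRUE` uses the normalized shapes.
#' @param window optional Sakoe-Chiba half-width for the DTW kernel.
#' @return nonnegative scalar (milli-g by default).
#' @export
intra_cluster_distance <- function(cr, bs, normalized = FALSE,
                                   window = NULL) {
  cluster_distance(cr, bs, swap = FALSE, normalized = normalized,
                   window = window)
}

#' Inter-cluster morphological distance
#'
#' Mean DTW distance of every beat to the *opposite* cluster's medoid:
#' `(1/(n1+n2)) * (sum_i dtw(C2, X_i1) + sum_i dtw(C1, X_i2))`.
#'
#' @inheritParams intra_cluster_distance
#' @return nonnegative scalar (milli-g by default).
#' @export
inter_cluster_distance <- function(cr, bs, normalized = FALSE,
                                   window = NULL) {
  cluster_distance(cr, bs, swap = TRUE, normalized = normalized,
                   window = window)
}

#' Spectral band-energy ratios of the cluster medoids
#'
#' Periodogram energy of each medoid (Hann window, zero-padded to the next
#' power of two at least four times the waveform length) summed over five
#' frequency bands and divided by the energy in the 0.5-50 Hz reference
#' band; the two medoid distributions are then averaged. The nominal bands
#' 0.5-10, 11-20, 21-30, 31-40 and 41-50 Hz leave the inter-band hertz
#' unassigned, so they are implemented as contiguous half-open intervals
#' `[0.5, 10.5), [10.5, 20.5), [20.5, 30.5), [30.5, 40.5), [40.5, 50]`,
#' which tile the reference band exactly - hence the ratios sum to 1 by
#' construction.
#'
#' @param medoids list of two medoid waveforms (numeric vectors).
#' @param fs sampling rate in Hz (>= 100, so the bands are resolvable).
#' @return an `scg_spectrum`: list with `band_edges` (Hz), `ratios`
#'   (named, averaged over medoids), `per_medoid` (2 x 5 matrix) and
#'   `reference_band`.
#' @export
band_energy_ratios <- function(medoids, fs) {
  if (fs < 100) stopf("`fs` must be >= 100 Hz for 0.5-50 Hz band analysis")
  if (length(medoids) < 1) stopf("need at least one medoid waveform")
  edges <- c(0.5, 10.5, 20.5, 30.5, 40.5, 50)
  per <- t(vapply(medoids, function(x) {
    len <- length(x)
    hann <- 0.5 - 0.5 * cos(2 * pi * seq(0, len - 1) / (len - 1))
    xw <- (x - mean(x)) * hann
    nfft <- 2^ceiling(log2(4 * len))
    p <- Mod(fft(c(xw, rep(0, nfft - len))))^2
    freq <- (seq_len(nfft) - 1) * fs / nfft
    half <- freq <= fs / 2
    p <- p[half]; freq <- freq[half]
    total <- sum(p[freq >= edges[1] & freq <= edges[6]])
    vapply(seq_len(5), function(b) {
      hi_ok <- if (b == 5) freq <= edges[6] else freq < edges[b + 1]
      sum(p[freq >= edges[b] & hi_ok]) / total
    }, numeric(1))
  }, numeric(5)))
  band_names <- c("0.5-10Hz", "11-20Hz", "21-30Hz", "31-40Hz", "41-50Hz")
  colnames(per) <- band_names
  ratios <- colMeans(per)
  structure(list(band_edges = edges, ratios = ratios, per_medoid = per,
                 reference_band = c(0.5, 50)),
            class = "scg_spectrum")
}

#' @export
print.scg_spectrum <- function(x, ...) {
  cat("<scg_spectrum> band energy / total (0.5-50 Hz):\n")
  print(round(x$ratios, 4))
  invisible(x)
}

#' Locate AO and AC peaks on a beat medoid
#'
#' The SCG1 complex peak correlates with aortic opening (AO) and the SCG2
#' peak with aortic closure (AC). With the segmentation convention that a
#' beat starts 0.1 s before its R wave, AO is taken as the largest local
#' maximum in `(R, R + 200 ms]` and AC as the largest local maximum in
#' `(R + 250 ms, R + 450 ms]`, windows that bracket systole at resting
#' heart rates. Equal-height maxima resolve to the earlier peak. A window
#' with no local maximum yields `NA` and a flag.
#'
#' @param medoid numeric waveform starting 0.1 s before R.
#' @param fs sampling rate in Hz.
#' @param r_offset_s position of R within the beat (default 0.1 s).
#' @param ao_window,ac_window search windows in seconds relative to R.
#' @param min_height_frac a candidate peak must reach this fraction of the
#'   beat's maximum absolute amplitude to count (default 0.05); numerical
#'   ripple in an empty window is not a wave complex.
#' @return list with `ao_time`, `ac_time` (seconds from beat start, `NA`
#'   when undetected) and `flagged`.
#' @export
detect_ao_ac <- function(medoid, fs, r_offset_s = 0.1,
                         ao_window = c(0, 0.2), ac_window = c(0.25, 0.45),
                         min_height_frac = 0.05) {
  floor_amp <- min_height_frac * max(abs(medoid))
  peak_in <- function(win) {
    lo <- as.integer(floor((r_offset_s + win[1]) * fs)) + 2L  # open left edge
    hi <- min(length(medoid), as.integer(round((r_offset_s + win[2]) * fs)) + 1L)
    if (hi - lo < 2) return(NA_real_)
    seg <- medoid[lo:hi]
    k <- seq(2, length(seg) - 1)
    is_peak <- seg[k] > seg[k - 1] & seg[k] >= seg[k + 1] &
      seg[k] >= floor_amp
    if (!any(is_peak)) return(NA_real_)
    pk <- k[is_peak]
    best <- pk[which.max(seg[pk])]      # which.max: earliest of equal maxima
    (lo + best - 1L - 1L) / fs
  }
  ao <- peak_in(ao_window)
  ac <- peak_in(ac_window)
  list(ao_time = ao, ac_time = ac, flagged = is.na(ao) || is.na(ac))
}

#' Cardiac timing intervals from fiducial times
#'
#' PEP (pre-ejection period) is the interval from the ECG Q point to the
#' AO peak; LVEP (left-ventricular ejection period) from AO to AC. Both
#' are reported in milliseconds together with their ratio.
#'
#' @param q_time,ao_time,ac_time fiducial times in seconds on a common
#'   clock, with `q_time < ao_time < ac_time`.
#' @return list with `pep_ms`, `lvep_ms`, `pep_lvep_ratio`.
#' @examples
#' compute_cti(0, 0.070, 0.370)  # PEP 70 ms, LVEP 300 ms, ratio ~0.233
#' @export
compute_cti <- function(q_time, ao_time, ac_time) {
  if (any(is.na(c(q_time, ao_time, ac_time)))) {
    stopf("fiducial times contain NA")
  }
  if (!(q_time < ao_time && ao_time < ac_time)) {
    stopf("fiducial ordering violated: need q (%.4f) < ao (%.4f) < ac (%.4f)",
          q_time, ao_time, ac_time)
  }
  pep <- (ao_time - q_time) * 1000
  lvep <- (ac_time - ao_time) * 1000
  list(pep_ms = pep, lvep_ms = lvep, pep_lvep_ratio = pep / lvep)
}

#' Cardiac timing intervals for both cluster medoids
#'
#' Reads AO/AC off each medoid, combines them with that medoid beat's own
#' Q-point offset, and reports per-medoid PEP/LVEP plus their average (the
#' cluster-combined value used in posture comparisons).
#'
#' @param cr a `cluster_result`.
#' @param bs the clustered `beat_set` (beats must carry `q_time`, as
#'   attached by [run_pipeline()], or `q_offsets` must be given).
#' @param q_offsets optional numeric vector: per-beat Q time in seconds
#'   relative to beat start (overrides beat `q_time` slots).
#' @param ... passed to [detect_ao_ac()].
#' @return list with `per_cluster` data frame (cluster, q/ao/ac times in
#'   ms from beat start, pep, lvep, ratio) and `average` (mean of the two
#'   medoids' PEP, LVEP and ratio).
#' @export
cti_for_clusters <- function(cr, bs, q_offsets = NULL, ...) {
  stopifnot(inherits(cr, "cluster_result"), inherits(bs, "beat_set"))
  rows <- lapply(1:2, function(j) {
    mi <- cr$medoid_index[j]
    med <- if (j == 1) cr$C1$raw else cr$C2$raw
    q_rel <- if (!is.null(q_offsets)) q_offsets[mi] else bs$beats[[mi]]$q_time
    if (is.null(q_rel) || is.na(q_rel)) {
      stopf("no Q-point offset available for medoid beat %d", mi)
    }
    f <- detect_ao_ac(med, bs$fs, ...)
    if (f$flagged) {
      return(data.frame(cluster = j, q_ms = q_rel * 1000,
                        ao_ms = NA_real_, ac_ms = NA_real_,
                        pep_ms = NA_real_, lvep_ms = NA_real_,
                        pep_lvep_ratio = NA_real_))
    }
    cti <- compute_cti(q_rel, f$ao_time, f$ac_time)
    data.frame(cluster = j, q_ms = q_rel * 1000, ao_ms = f$ao_time * 1000,
               ac_ms = f$ac_time * 1000, pep_ms = cti$pep_ms,
               lvep_ms = cti$lvep_ms, pep_lvep_ratio = cti$pep_lvep_ratio)
  })
  per_cluster <- do.call(rbind, rows)
  list(per_cluster = per_cluster,
       average = list(pep_ms = mean(per_cluster$pep_ms),
                      lvep_ms = mean(per_cluster$lvep_ms),
                      pep_lvep_ratio = mean(per_cluster$pep_lvep_ratio)))
}

#' Heart rate by cluster
#'
#' Mean and standard error of the instantaneous heart rate (60/RR) within
#' each cluster. Under the cluster-1-faster labelling convention (see
#' [k_medoids_dtw()]), cluster 1's mean exceeds cluster 2's whenever
#' respiratory sinus arrhythmia couples heart rate to the clustered
#' respiratory regimes.
#'
#' @param bs a `beat_set`.
#' @param labels integer cluster labels aligned with the beats.
#' @return data frame with `cluster`, `n`, `hr_mean`, `hr_se` (SE is `NA`
#'   for singleton clusters; empty clusters yield `NA` mean).
#' @export
heart_rate_by_cluster <- function(bs, labels) {
  stopifnot(inherits(bs, "beat_set"))
  if (length(labels) != length(bs$beats)) {
    stopf("`labels` must align with the beats")
  }
  hr <- 60 / beat_rr(bs)
  do.call(rbind, lapply(sort(unique(labels)), function(j) {
    v <- hr[labels == j]
    data.frame(cluster = j, n = length(v),
               hr_mean = if (length(v)) mean(v) else NA_real_,
               hr_se = if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_)
  }))
}
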