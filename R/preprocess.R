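# Signal conditioning: zero-phase Chebyshev II band-pass, moving-average
# smoothing, and anti-aliased downsampling.
#
# The band-pass is designed in zero-pole-gain form and applied as a cascade
# of second-order sections (biquads). An order-4 band-pass prototype
# realises 8 poles; in direct transfer-function form those poles sit at
# |z| > 0.999 when the 0.5 Hz edge meets a 10 kHz sampling rate and the
# expanded polynomial is numerically unusable (this is why SOS filtering is
# the norm in scientific signal stacks). The analog Chebyshev II prototype
# is closed-form; the band transform and bilinear mapping come from the
# signal package.

# Analog Chebyshev II low-pass prototype (stopband edge 1 rad/s,
# stopband attenuation rs_db), as zero/pole/gain.
cheby2_prototype <- function(order, rs_db) {
  eps <- 1 / sqrt(10^(rs_db / 10) - 1)
  mu <- asinh(1 / eps) / order
  theta <- pi * (2 * seq_len(order) - 1) / (2 * order)
  pole <- 1 / (-sinh(mu) * sin(theta) + 1i * cosh(mu) * cos(theta))
  keep <- abs(cos(theta)) > 1e-12      # odd order: one zero at infinity
  zero <- 1i / cos(theta[keep])
  gain <- Re(prod(-pole) / prod(-zero))
  list(zero = zero, pole = pole, gain = gain)
}

# Digital Chebyshev II filter as second-order sections.
# w: normalized edge(s) in (0, 1), 1 = Nyquist. type: "pass" | "low" | "high".
cheby2_sos <- function(order, rs_db, w, type = c("pass", "low", "high")) {
  type <- match.arg(type)
  proto <- cheby2_prototype(order, rs_db)
  t_samp <- 2
  wa <- (2 / t_samp) * tan(pi * w / t_samp)
  zpg <- signal::Zpg(zero = proto$zero, pole = proto$pole, gain = proto$gain)
  zpg <- if (type == "high") {
    signal::sftrans(zpg, W = wa, stop = TRUE)
  } else {
    signal::sftrans(zpg, W = wa, stop = FALSE)
  }
  zpg <- signal::bilinear(zpg, T = t_samp)
  zpg_to_sos(zpg)
}

# Group conjugate zero/pole pairs into biquad sections, matching each pole
# pair with the nearest unused zero pair (poles nearest the unit circle
# first, so they are paired with close zeros for dynamic range).
zpg_to_sos <- function(zpg) {
  split_pairs <- function(v) {
    cplx <- v[Im(v) > 1e-9]
    re <- Re(v[abs(Im(v)) <= 1e-9])
    out <- lapply(cplx[order(-Mod(cplx))], function(z) c(z, Conj(z)))
    while (length(re) >= 2) {
      out <- c(out, list(re[1:2]))
      re <- re[-(1:2)]
    }
    if (length(re) == 1) out <- c(out, list(re[1]))
    out
  }
  poly_from_roots <- function(r) {
    coefs <- 1
    for (ri in r) coefs <- c(coefs, 0) - c(0, ri * coefs)
    Re(coefs)
  }
  pp <- split_pairs(zpg$pole)
  zz <- split_pairs(zpg$zero)
  used <- rep(FALSE, length(zz))
  sos <- vector("list", length(pp))
  for (i in seq_along(pp)) {
    d <- vapply(seq_along(zz), function(j) {
      if (used[j] || length(zz[[j]]) != length(pp[[i]])) Inf
      else Mod(pp[[i]][1] - zz[[j]][1])
    }, numeric(1))
    j <- which.min(d)
    z <- if (length(zz) && is.finite(d[j])) { used[j] <- TRUE; zz[[j]] }
         else numeric(0)
    sos[[i]] <- list(b = poly_from_roots(z), a = poly_from_roots(pp[[i]]))
  }
  list(sections = sos, gain = zpg$gain)
}

# Forward-backward filtering through an SOS cascade. The scalar gain is
# applied squared because the cascade is traversed twice.
sos_filtfilt <- function(sos, x) {
  for (s in sos$sections) {
    x <- signal::filtfilt(filt = s$b, a = s$a, x = x)
  }
  x * sos$gain^2
}

#' Zero-phase Chebyshev II band-pass filter
#'
#' Forward-backward (zero net phase) band-pass filtering with a Chebyshev
#' type II design, the standard conditioning step for chest-acceleration
#' and ECG traces: it removes baseline wander from respiration (below
#' `low`) and out-of-band noise (above `high`) without distorting wave
#' timing, which matters because cardiac timing intervals are read off the
#' filtered waveforms.
#'
#' The filter is applied as a cascade of second-order sections, which keeps
#' the design numerically sound even for a 0.5 Hz edge at a 10 kHz sampling
#' rate. Because the data pass through the filter twice, the effective
#' stopband attenuation is `2 * atten_db` and the passband droop is doubled
#' as well.
#'
#' @param x numeric vector, the signal.
#' @param fs sampling rate in Hz.
#' @param low,high band edges in Hz (defaults 0.5 and 50, the band that
#'   carries essentially all SCG energy in healthy subjects).
#' @param order band-pass prototype order (default 4; the realized filter
#'   has `2 * order` poles).
#' @param atten_db stopband attenuation of the one-way design in dB
#'   (default 40).
#' @return filtered numeric vector, same length as `x`.
#' @examples
#' fs <- 1000
#' t <- seq(0, 2, by = 1 / fs)
#' x <- sin(2 * pi * 20 * t) + 1      # 20 Hz tone on a DC pedestal
#' y <- bandpass_zero_phase(x, fs)
#' max(abs(y - sin(2 * pi * 20 * t))) # DC removed, tone nearly intact
#' @export
bandpass_zero_phase <- function(x, fs, low = 0.5, high = 50, order = 4,
                                atten_db = 40) {
  if (!is.numeric(x) || length(x) == 0) stopf("`x` must be a numeric vector")
  if (!(low > 0 && low < high && high < fs / 2)) {
    stopf("band edges must satisfy 0 < low < high < fs/2 (got %g, %g at fs=%g)",
          low, high, fs)
  }
  sos <- cheby2_sos(order, atten_db, c(low, high) / (fs / 2), type = "pass")
  sos_filtfilt(sos, x)
}

#' Centered moving-average smoother
#'
#' Mean over a centered window of `order` samples; at the edges the window
#' is truncated to the available samples (no padding, so no artificial
#' transients). A centered window is used because records are processed
#' offline and the rest of the chain is already zero-phase. Linear trends
#' are preserved in the interior (the symmetric mean of an arithmetic
#' sequence is its center value).
#'
#' @param x numeric vector.
#' @param order odd window length in samples (default 5).
#' @return smoothed vector, same length as `x`.
#' @examples
#' moving_average(c(0, 0, 1, 0, 0), order = 5)  # impulse -> five 0.2 values
#' @export
moving_average <- function(x, order = 5) {
  n <- length(x)
  if (order < 1 || order %% 2 == 0) stopf("`order` must be odd and >= 1")
  if (order > n) stopf("`order` (%d) exceeds signal length (%d)", order, n)
  k <- (order - 1) / 2
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - k, 1)
  hi <- pmin(seq_len(n) + k, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Anti-aliased downsampling
#'
#' Low-pass filters (zero-phase Chebyshev II, order 8, 60 dB, stopband edge
#' at the new Nyquist frequency) and then keeps every `fs_in/fs_out`-th
#' sample. Recordings are typically acquired at 10 kHz and reduced to
#' 1 kHz, at which the quadratic-time DTW comparisons downstream remain
#' affordable while the 0.5-50 Hz band of interest is untouched.
#'
#' @param x numeric vector.
#' @param fs_in input sampling rate in Hz; must be an integer multiple of
#'   `fs_out`.
#' @param fs_out output sampling rate in Hz (default 1000).
#' @return numeric vector of length `ceiling(length(x) * fs_out / fs_in)`.
#' @export
downsample <- function(x, fs_in, fs_out = 1000) {
  if (fs_out > fs_in) stopf("`fs_out` must not exceed `fs_in`")
  q <- fs_in / fs_out
  if (abs(q - round(q)) > 1e-9) {
    stopf("`fs_in` (%g) must be an integer multiple of `fs_out` (%g)",
          fs_in, fs_out)
  }
  q <- as.integer(round(q))
  if (q == 1L) return(x)
  sos <- cheby2_sos(8, 60, (fs_out / 2) / (fs_in / 2), type = "low")
  y <- sos_filtfilt(sos, x)
  y[seq(1, length(x), by = q)]
}
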