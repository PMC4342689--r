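# Windowing and spectral band-power features.

#' Frequency band
#'
#' @param b1,b2 Band edges in Hz, `0 <= b1 < b2`. The band is closed on bin
#'   centers; a lower edge above 0 excludes the DC bin.
#' @return Named numeric vector `c(b1 =, b2 =)` of class `frequency_band`.
#' @export
frequency_band <- function(b1, b2) {
  if (!is.numeric(b1) || !is.numeric(b2) || length(b1) != 1 || length(b2) != 1) {
    stop("band edges must be single numbers", call. = FALSE)
  }
  if (b1 < 0 || b2 <= b1) stop("band requires 0 <= b1 < b2", call. = FALSE)
  structure(c(b1 = b1, b2 = b2), class = "frequency_band")
}

#' Windowing configuration
#'
#' Fixed-length, non-overlapping analysis windows: 3.2 s at the 40 Hz
#' analysis rate, i.e. 128 samples per window. Windows tile the recording
#' left-to-right; a trailing remainder shorter than one window is discarded.
#'
#' @param window_seconds Window length in seconds (default 3.2).
#' @param analysis_rate_hz Analysis sampling rate in Hz (default 40).
#' @return A list with `window_seconds`, `analysis_rate_hz` and the derived
#'   `window_samples`.
#' @export
windowing_config <- function(window_seconds = 3.2, analysis_rate_hz = 40) {
  if (window_seconds <= 0 || analysis_rate_hz <= 0) {
    stop("window_seconds and analysis_rate_hz must be positive", call. = FALSE)
  }
  structure(
    list(window_seconds = window_seconds,
         analysis_rate_hz = analysis_rate_hz,
         window_samples = as.integer(round(window_seconds * analysis_rate_hz))),
    class = "windowing_config"
  )
}

#' Cut a recording into non-overlapping analysis windows
#'
#' @param rec An `accel_recording` already at the analysis rate.
#' @param cfg A [windowing_config()].
#' @return A list of windows, each a list with `index` (0-based), `start_time`
#'   (seconds, relative to the recording start), and `samples`
#'   (`window_samples` x 3 matrix). A recording shorter than one window gives
#'   an empty list.
#' @export
segment_windows <- function(rec, cfg = windowing_config()) {
  ws <- cfg$window_samples
  n <- n_samples(rec)
  nw <- n %/% ws
  if (nw == 0) return(list())
  lapply(seq_len(nw), function(i) {
    rows <- ((i - 1L) * ws + 1L):(i * ws)
    list(index = i - 1L,
         start_time = (i - 1L) * cfg$window_seconds,
         samples = rec$acc[rows, , drop = FALSE])
  })
}

# Indices, bin frequencies and fold coefficients for the one-sided spectrum
# of an m-point DFT (DC excluded; Nyquist bin unfolded when m is even).
one_sided_bins <- function(m, rate_hz) {
  m2 <- m %/% 2
  k <- seq_len(m2)
  coef <- rep(2, m2)
  if (m %% 2 == 0) coef[m2] <- 1
  list(k = k, freq = k * rate_hz / m, coef = coef)
}

#' One-sided periodogram of a multi-axis segment
#'
#' Mean-removed rectangular-window periodogram. Per axis, the power at bin k
#' is `coef * |X_k|^2 / m^2` with `coef = 2` for interior bins (folding the
#' conjugate half) and 1 at the Nyquist bin; axes are summed. The powers over
#' all bins in (0, Nyquist] add up to the mean-removed mean-square power of
#' the segment (Parseval), so band power is per-unit-time and independent of
#' segment duration for a stationary signal.
#'
#' @param samples Numeric vector or m x 3 matrix of accelerations in g.
#' @param rate_hz Sampling rate in Hz.
#' @return List with `freq` (Hz) and `power` (g^2 per bin, axes summed).
#' @export
segment_periodogram <- function(samples, rate_hz) {
  x <- as.matrix(samples)
  m <- nrow(x)
  if (m < 8) stop("segment too short for spectral analysis (m < 8)",
                  call. = FALSE)
  xc <- sweep(x, 2, colMeans(x))
  X <- stats::mvfft(xc)
  b <- one_sided_bins(m, rate_hz)
  p <- rowSums(Mod(X[b$k + 1L, , drop = FALSE])^2) * b$coef / m^2
  list(freq = b$freq, power = p)
}

#' Spectral band power of an acceleration segment
#'
#' Sums the one-sided periodogram (see [segment_periodogram()]) over
#' frequency bins whose center lies in the closed interval `[b1, b2]`, axes
#' summed. With `b1 > 0` the DC bin is excluded. The result is the
#' mean-square power (g^2) contributed by the band, invariant to segment
#' duration for a stationary signal and quadratic in signal amplitude.
#'
#' @param samples Numeric vector or m x 3 matrix (m >= 8) of accelerations
#'   in g.
#' @param band A [frequency_band()] or numeric `c(b1, b2)`.
#' @param rate_hz Sampling rate of the segment in Hz; `b2` must not exceed
#'   `rate_hz / 2`.
#' @return Non-negative scalar, g^2.
#' @export
band_power <- function(samples, band, rate_hz) {
  b1 <- band[[1]]; b2 <- band[[2]]
  if (b1 < 0 || b2 <= b1) stop("band requires 0 <= b1 < b2", call. = FALSE)
  if (b2 > rate_hz / 2 + 1e-9) {
    stop("band upper edge exceeds the Nyquist frequency", call. = FALSE)
  }
  pg <- segment_periodogram(samples, rate_hz)
  eps <- 1e-9
  sum(pg$power[pg$freq >= b1 - eps & pg$freq <= b2 + eps])
}

#' Walking-detection features of one window
#'
#' The two spectral features used to classify a window as walking or not:
#' the three-axis-summed band powers in the 0.1-3 Hz and 0.1-10 Hz ranges.
#'
#' @param window A window from [segment_windows()], or an m x 3 sample
#'   matrix.
#' @param rate_hz Analysis sampling rate (default 40).
#' @return Numeric vector `c(p_0.1_3, p_0.1_10)` in g^2.
#' @export
compute_phase1_features <- function(window, rate_hz = 40) {
  samples <- if (is.list(window)) window$samples else window
  c(band_power(samples, c(0.1, 3), rate_hz),
    band_power(samples, c(0.1, 10), rate_hz))
}

# Band-power feature matrix for all windows of a recording, vectorized over
# windows (one FFT batch per axis). Returns n_windows x n_bands.
window_band_powers <- function(rec, cfg = windowing_config(),
                               bands = list(c(0.1, 3), c(0.1, 10))) {
  ws <- cfg$window_samples
  rate <- cfg$analysis_rate_hz
  n <- n_samples(rec)
  nw <- n %/% ws
  if (nw == 0) {
    return(matrix(numeric(0), nrow = 0, ncol = length(bands)))
  }
  b <- one_sided_bins(ws, rate)
  pow <- matrix(0, nrow = length(b$k), ncol = nw)
  for (axis in 1:3) {
    seg <- matrix(rec$acc[seq_len(nw * ws), axis], nrow = ws, ncol = nw)
    seg <- sweep(seg, 2, colMeans(seg))
    X <- stats::mvfft(seg)
    pow <- pow + Mod(X[b$k + 1L, , drop = FALSE])^2 * (b$coef / ws^2)
  }
  eps <- 1e-9
  feats <- vapply(bands, function(bd) {
    sel <- b$freq >= bd[[1]] - eps & b$freq <= bd[[2]] + eps
    colSums(pow[sel, , drop = FALSE])
  }, numeric(nw))
  matrix(feats, nrow = nw, ncol = length(bands))
}
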