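# Stride segmentation and spectral gait-fluency scoring.
#
# A trunk-worn sensor sees one relative maximum in forward acceleration per
# initial contact (one per step, both feet). A stride spans two steps of the
# same foot, so strides pair contact event i with event i+2, stepping i by 2.

#' Peak-detection constraints for initial-contact events
#'
#' @param min_separation_s Minimum time between contacts in seconds (default
#'   0.35, a cadence ceiling of about 2.9 steps/s).
#' @param min_prominence_g Minimum topographic prominence of a peak in g
#'   (default 0.05).
#' @return A list of constraints.
#' @export
peak_params <- function(min_separation_s = 0.35, min_prominence_g = 0.05) {
  stopifnot(min_separation_s > 0, min_prominence_g >= 0)
  list(min_separation_s = min_separation_s,
       min_prominence_g = min_prominence_g)
}

#' Stride duration bounds
#'
#' @param min_s,max_s Physiological stride-duration bounds in seconds
#'   (defaults 0.5 and 4.0).
#' @return A list of bounds.
#' @export
stride_bounds <- function(min_s = 0.5, max_s = 4.0) {
  stopifnot(min_s > 0, max_s > min_s)
  list(min_s = min_s, max_s = max_s)
}

#' Interior sample range of a walking episode
#'
#' Gait initiation and termination are irrelevant to the fluency measurement,
#' so the first and last window of each detected walking episode are left out
#' of stride detection. Episodes of one or two windows have no interior and
#' yield an empty range.
#'
#' @param episode A one-row data.frame (or list) with `first_window` and
#'   `last_window`, 0-based window indices.
#' @param cfg A [windowing_config()].
#' @return Integer vector `c(start, end)`: 1-based inclusive sample indices
#'   into the analysis-rate recording, or `NULL` when the episode has fewer
#'   than 3 windows.
#' @export
trim_episode_boundaries <- function(episode, cfg = windowing_config()) {
  fw <- episode$first_window
  lw <- episode$last_window
  if (lw - fw + 1L < 3L) return(NULL)
  ws <- cfg$window_samples
  c(start = (fw + 1L) * ws + 1L, end = lw * ws)
}

# Topographic prominence of local maxima at positions `peaks` in `x`:
# height above the higher of the two key saddles (minima between the peak
# and the nearest higher ground on each side, or the signal edge).
peak_prominence <- function(x, peaks) {
  n <- length(x)
  vapply(peaks, function(p) {
    h <- x[p]
    left_min <- h
    j <- p - 1L
    while (j >= 1L && x[j] <= h) {
      if (x[j] < left_min) left_min <- x[j]
      j <- j - 1L
    }
    right_min <- h
    j <- p + 1L
    while (j <= n && x[j] <= h) {
      if (x[j] < right_min) right_min <- x[j]
      j <- j + 1L
    }
    h - max(left_min, right_min)
  }, numeric(1))
}

#' Detect initial-contact events in a forward acceleration signal
#'
#' Initial contacts appear as relative maxima of the forward trunk
#' acceleration. Candidate local maxima are filtered by minimum prominence
#' and a minimum separation (enforced greedily from the highest peak down),
#' mirroring the physiological cadence ceiling.
#'
#' @param forward_signal Numeric vector, forward acceleration in g at the
#'   analysis rate.
#' @param rate_hz Sampling rate in Hz (default 40).
#' @param params A [peak_params()].
#' @return data.frame with `sample_index` (1-based into `forward_signal`,
#'   increasing), `time` (seconds from the start of the signal) and
#'   `amplitude` (g). Zero rows when no peak qualifies.
#' @export
detect_initial_contacts <- function(forward_signal, rate_hz = 40,
                                    params = peak_params()) {
  x <- as.numeric(forward_signal)
  n <- length(x)
  empty <- data.frame(sample_index = integer(0), time = numeric(0),
                      amplitude = numeric(0))
  if (n < 3) return(empty)
  # strict rise on the left, non-rise on the right (plateaus keep first point)
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  if (length(cand) == 0) return(empty)
  prom <- peak_prominence(x, cand)
  cand <- cand[prom >= params$min_prominence_g]
  if (length(cand) == 0) return(empty)
  min_gap <- params$min_separation_s * rate_hz
  keep <- integer(0)
  for (p in cand[order(x[cand], decreasing = TRUE)]) {
    if (all(abs(keep - p) >= min_gap)) keep <- c(keep, p)
  }
  keep <- sort(keep)
  data.frame(sample_index = keep, time = (keep - 1L) / rate_hz,
             amplitude = x[keep])
}

#' Pair initial-contact events into strides
#'
#' A stride runs from contact event i to event i+2 (two steps, same foot),
#' with i stepping by 2 so that consecutive strides share only their boundary
#' event. Strides whose duration falls outside the configured bounds are
#' discarded. Fewer than 3 events yield no strides.
#'
#' @param events data.frame from [detect_initial_contacts()] (column
#'   `sample_index`, sorted).
#' @param rate_hz Sampling rate in Hz.
#' @param bounds A [stride_bounds()].
#' @return data.frame with `start`, `end` (1-based sample indices, half-open
#'   `[start, end)`) and `duration_s`.
#' @export
build_strides <- function(events, rate_hz = 40, bounds = stride_bounds()) {
  idx <- if (is.data.frame(events)) events$sample_index else as.integer(events)
  ne <- length(idx)
  if (ne < 3) {
    return(data.frame(start = integer(0), end = integer(0),
                      duration_s = numeric(0)))
  }
  i <- seq(1L, ne - 2L, by = 2L)
  out <- data.frame(start = idx[i], end = idx[i + 2L])
  out$duration_s <- (out$end - out$start) / rate_hz
  out[out$duration_s >= bounds$min_s & out$duration_s <= bounds$max_s, ,
      drop = FALSE]
}

#' Spectral fluency of one stride
#'
#' The fluency of a stride is the three-axis-summed spectral power of its
#' acceleration in the 0.1-10 Hz band (see [band_power()]), normalized per
#' unit time so strides of different durations are comparable. Higher values
#' indicate more fluent gait, i.e. a deeper ON state.
#'
#' @param samples m x 3 matrix of the stride's acceleration samples in g.
#' @param rate_hz Sampling rate in Hz (default 40).
#' @param band Fluency band (default `c(0.1, 10)` Hz).
#' @return Non-negative scalar (g^2), or `NA` for a segment too short to
#'   analyze (m < 8; such strides are dropped).
#' @export
stride_fluency <- function(samples, rate_hz = 40, band = c(0.1, 10)) {
  if (NROW(samples) < 8) return(NA_real_)
  band_power(samples, band, rate_hz)
}

# Fluencies of all strides of an episode; NA (too-short) strides dropped.
stride_fluencies <- function(strides, acc, rate_hz = 40, band = c(0.1, 10)) {
  if (nrow(strides) == 0) return(numeric(0))
  fl <- vapply(seq_len(nrow(strides)), function(i) {
    rows <- strides$start[i]:(strides$end[i] - 1L)
    stride_fluency(acc[rows, , drop = FALSE], rate_hz, band)
  }, numeric(1))
  fl[!is.na(fl)]
}

#' Aggregate stride fluencies to an episode-level decision value
#'
#' The fluencies of one gait episode are averaged after disregarding the two
#' initial and two final strides (gait build-up and wind-down). With fewer
#' than 5 strides no interior stride survives the exclusion and the mean is
#' undefined; `stride_count` always reports the pre-exclusion count, which
#' the >=10-stride evaluation filter uses.
#'
#' @param fluencies Numeric vector of per-stride fluencies, in stride order.
#' @return List with `stride_count` and `mean_fluency` (`NA` if undefined).
#' @export
episode_fluency <- function(fluencies) {
  n <- length(fluencies)
  mean_fl <- if (n >= 5) mean(fluencies[3:(n - 2)]) else NA_real_
  list(stride_count = n, mean_fluency = mean_fl)
}

#' Area under the ROC curve by rank statistic
#'
#' Wilcoxon formulation with midranks, so ties contribute 1/2.
#'
#' @param scores Numeric scores (higher = more likely positive).
#' @param labels Logical or two-level vector; `TRUE` (or the second level) is
#'   the positive class.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  pos <- if (is.logical(labels)) labels else {
    y <- as.factor(labels)
    if (nlevels(droplevels(y)) != 2) {
      stop("auroc requires exactly two classes", call. = FALSE)
    }
    y == levels(droplevels(y))[2]
  }
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("auroc requires both classes", call. = FALSE)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Search candidate frequency bands for maximal ON/OFF discrimination
#'
#' For every candidate band, each stride is scored by its band power (axes
#' summed, duration-normalized) and the AUROC of that score for ON vs OFF is
#' computed. The winning band is the argmax, ties broken lexicographically
#' (first candidate in grid order).
#'
#' @param stride_samples List of m x 3 acceleration matrices, one per stride.
#' @param labels Per-stride motor state, `"ON"`/`"OFF"` (ON is the positive
#'   class: fluency is higher in ON).
#' @param rate_hz Sampling rate in Hz.
#' @param candidates data.frame of bands from [enumerate_band_candidates()].
#' @return List with `best` (named numeric `c(b1, b2)`), `auc` (vector over
#'   candidates) and `candidates`.
#' @export
auc_band_search <- function(stride_samples, labels, rate_hz = 40,
                            candidates = enumerate_band_candidates()) {
  y <- factor(as.character(labels), levels = c("OFF", "ON"))
  if (any(is.na(y)) || nlevels(droplevels(y)) != 2) {
    stop("labels must contain both ON and OFF", call. = FALSE)
  }
  ns <- length(stride_samples)
  nc <- nrow(candidates)
  eps <- 1e-9
  # per-stride cumulative spectra allow O(1) band sums per candidate
  scores <- matrix(0, nrow = ns, ncol = nc)
  for (s in seq_len(ns)) {
    pg <- segment_periodogram(stride_samples[[s]], rate_hz)
    cs <- c(0, cumsum(pg$power))
    lo <- findInterval(candidates$b1 - eps, pg$freq)
    hi <- findInterval(candidates$b2 + eps, pg$freq)
    scores[s, ] <- cs[hi + 1L] - cs[lo + 1L]
  }
  pos <- y == "ON"
  r <- apply(scores, 2, rank)
  n1 <- sum(pos); n0 <- sum(!pos)
  auc <- (colSums(r[pos, , drop = FALSE]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  best_i <- which.max(auc)  # which.max returns the first maximum: ties
                            # resolve to the lexicographically first band
  list(best = c(b1 = candidates$b1[best_i], b2 = candidates$b2[best_i]),
       auc = auc, candidates = candidates)
}
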