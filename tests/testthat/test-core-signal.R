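# Data model, I/O, resampling, windowing, band power.

test_that("recordings validate their sensor contract", {
  t4 <- (0:3) / 200
  acc <- matrix(0.1, 4, 3)
  rec <- accel_recording(t4, acc, 200)
  expect_s3_class(rec, "accel_recording")
  expect_equal(length(rec$time_s), 4)
  expect_equal(rec$sampling_rate_hz, 200)

  expect_error(accel_recording(rev(t4), acc, 200), "strictly increasing")
  expect_error(accel_recording(t4, acc, 100), "inconsistent")
  expect_warning(accel_recording(t4, matrix(7, 4, 3), 200), "6 g")
  bad_roles <- default_axis_roles()
  bad_roles$forward$axis <- "ax"  # no longer a bijection
  expect_error(accel_recording(t4, acc, 200, axis_roles = bad_roles),
               "bijection")
})

test_that("CSV round trip preserves a recording to 1e-9", {
  sched <- schedule_params(total_duration_s = 30, phase_median_s = 20,
                           phase_min_s = 10, bout_rate_per_hour = 240,
                           bout_min_s = 4, bout_median_s = 6, bout_max_s = 8,
                           min_gap_s = 2)
  pat <- simulate_patient(sched = sched, seed = 5, sampling_rate_hz = 50)
  path <- file.path(tempdir(), "rec.csv")
  write_recording(pat$recording, path)
  back <- load_recording(path)
  expect_equal(back$time_s, pat$recording$time_s, tolerance = 1e-9)
  expect_equal(unname(back$acc), unname(pat$recording$acc), tolerance = 1e-9)
  expect_equal(back$sampling_rate_hz, 50)
  expect_equal(back$patient_id, pat$recording$patient_id)

  # missing column is a format error
  bad <- file.path(tempdir(), "bad.csv")
  writeLines(c("time_s,ax_g,ay_g", "0,0,0"), bad)
  expect_error(load_recording(bad), "columns")
})

test_that("resampling 200->40 Hz preserves in-band tones and rejects aliases", {
  r2 <- resample_to_analysis_rate(tone_recording(2), 40)
  expect_equal(r2$sampling_rate_hz, 40)
  expect_true(abs(length(r2$time_s) - 400) <= 1)
  # amplitude-1 tone has mean-square power 0.5 g^2; preserved within 1%
  expect_equal(band_power(r2$acc, c(0.1, 19.9), 40), 0.5, tolerance = 0.01)

  # a 25 Hz tone must not alias into the output band
  r25 <- resample_to_analysis_rate(tone_recording(25), 40)
  expect_lt(band_power(r25$acc, c(0.1, 19.9), 40), 0.01 * 0.5)

  # content at/above the target Nyquist attenuated by >= 40 dB; the filter
  # transient at the record edges is excluded (1 s each end)
  r22 <- resample_to_analysis_rate(tone_recording(22), 40)
  n22 <- nrow(r22$acc)
  expect_lt(band_power(r22$acc[41:(n22 - 40), ], c(0.1, 19.9), 40),
            1e-4 * 0.5)

  expect_error(resample_to_analysis_rate(r2, 200), "upsampling")
  # idempotence at the analysis rate
  again <- resample_to_analysis_rate(r2, 40)
  expect_identical(again$acc, r2$acc)
})

test_that("windows tile the recording and discard the remainder", {
  cfg <- windowing_config()
  mk <- function(n) {
    accel_recording((0:(n - 1)) / 40, matrix(rnorm(3 * n), n, 3), 40)
  }
  expect_length(segment_windows(mk(128), cfg), 1)
  w <- segment_windows(mk(1000), cfg)
  expect_length(w, 7)
  expect_equal(vapply(w, function(x) nrow(x$samples), numeric(1)),
               rep(128, 7))
  expect_equal(vapply(w, `[[`, numeric(1), "start_time"), (0:6) * 3.2)
  expect_length(segment_windows(mk(127), cfg), 0)
  # conservation: consumed samples = n_windows * 128, remainder < 128
  expect_lt(1000 - 7 * 128, 128)
})

test_that("band power matches a brute-force DFT oracle", {
  # single-axis 2.5 Hz tone, amplitude 1 g: mean-square power 0.5 g^2
  w <- tone_window(2.5)
  p <- band_power(w, c(0.1, 10), 40)
  expect_equal(p, 0.5, tolerance = 1e-9)
  expect_equal(p, dft_band_power_oracle(w, c(0.1, 10), 40), tolerance = 1e-6)

  expect_equal(band_power(matrix(0, 128, 3), c(0.1, 10), 40), 0)
  # randomized segments against the oracle
  set.seed(42)
  for (i in 1:10) {
    m <- sample(c(16, 50, 128), 1)
    x <- matrix(rnorm(3 * m), m, 3)
    b1 <- runif(1, 0, 15); b2 <- b1 + runif(1, 0.5, 4)
    expect_equal(band_power(x, c(b1, b2), 40),
                 dft_band_power_oracle(x, c(b1, b2), 40),
                 tolerance = 1e-9)
  }
  expect_error(band_power(matrix(0, 128, 3), c(0.1, 25), 40), "Nyquist")
})

test_that("band power obeys Parseval, nesting, offset and scaling laws", {
  set.seed(7)
  x <- matrix(rnorm(3 * 128), 128, 3)
  # nested bands are monotone
  expect_lte(band_power(x, c(0.1, 3), 40), band_power(x, c(0.1, 10), 40))
  # partition of (0, Nyquist] sums to total mean-removed mean-square power
  edges <- c(1e-6, 2, 5, 10, 15, 20)
  parts <- vapply(seq_len(length(edges) - 1), function(i) {
    band_power(x, c(edges[i] + 1e-7, edges[i + 1]), 40)
  }, numeric(1))
  total <- sum(apply(x, 2, function(v) mean((v - mean(v))^2)))
  expect_equal(sum(parts), total, tolerance = 1e-9)
  # quadratic amplitude scaling, offset invariance
  expect_equal(band_power(3 * x, c(0.1, 10), 40),
               9 * band_power(x, c(0.1, 10), 40), tolerance = 1e-9)
  expect_equal(band_power(x + 0.7, c(0.1, 10), 40),
               band_power(x, c(0.1, 10), 40), tolerance = 1e-9)
})

test_that("phase-1 features are the 0.1-3 and 0.1-10 Hz band powers", {
  expect_equal(compute_phase1_features(matrix(0, 128, 3)), c(0, 0))
  # bin-centered tones (k * 40/128 Hz) avoid leakage across band edges
  f2 <- compute_phase1_features(tone_window(2.5))
  expect_equal(f2[1], f2[2], tolerance = 1e-9)  # 2.5 Hz lies in both bands
  expect_equal(f2[2], 0.5, tolerance = 1e-9)
  f8 <- compute_phase1_features(tone_window(7.5))
  expect_lt(f8[1], 1e-9)
  expect_equal(f8[2], 0.5, tolerance = 1e-9)
  # bulk path agrees with the per-window path
  set.seed(3)
  n <- 3 * 128
  rec <- accel_recording((0:(n - 1)) / 40, matrix(rnorm(3 * n), n, 3), 40)
  bulk <- onoffgait:::window_band_powers(rec)
  wins <- segment_windows(rec)
  per <- t(vapply(wins, compute_phase1_features, numeric(2)))
  expect_equal(unname(bulk), unname(per), tolerance = 1e-12)
})
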