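# Independent oracles and shared fixtures, built in code.

# Brute-force O(m^2) DFT band-power oracle: mean removal, explicit cosine and
# sine sums per bin, conjugate-half folding. Independent of the fft path.
dft_band_power_oracle <- function(samples, band, rate_hz) {
  x <- as.matrix(samples)
  m <- nrow(x)
  idx <- 0:(m - 1)
  total <- 0
  for (j in seq_len(ncol(x))) {
    xc <- x[, j] - mean(x[, j])
    for (k in seq_len(m %/% 2)) {
      f <- k * rate_hz / m
      if (f >= band[1] - 1e-9 && f <= band[2] + 1e-9) {
        re <- sum(xc * cos(2 * pi * k * idx / m))
        im <- sum(xc * sin(2 * pi * k * idx / m))
        coef <- if (m %% 2 == 0 && k == m %/% 2) 1 else 2
        total <- total + coef * (re^2 + im^2) / m^2
      }
    }
  }
  total
}

# Single-axis tone recording (signal on ax, zeros elsewhere).
tone_recording <- function(freq_hz, rate_hz = 200, duration_s = 10,
                           amplitude = 1) {
  t <- seq(0, duration_s - 1 / rate_hz, by = 1 / rate_hz)
  accel_recording(t, cbind(amplitude * sin(2 * pi * freq_hz * t), 0 * t,
                           0 * t), rate_hz)
}

# Tone window (m x 3) for feature tests.
tone_window <- function(freq_hz, m = 128, rate_hz = 40, amplitude = 1) {
  t <- (0:(m - 1)) / rate_hz
  cbind(amplitude * sin(2 * pi * freq_hz * t), 0 * t, 0 * t)
}

# Expensive shared fixtures, computed once per test run.
.fixture_env <- new.env(parent = emptyenv())
fixture <- function(key, fn) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, fn(), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

test_walking_model <- function() {
  fixture("walking_model", function() {
    train_default_walking_model(seed = 2)
  })
}

# One 1-hour synthetic patient at default gait parameters, processed through
# the full detection pipeline.
test_patient_run <- function() {
  fixture("patient_run", function() {
    sched <- schedule_params(total_duration_s = 3600, phase_median_s = 1500,
                             phase_min_s = 900)
    pat <- simulate_patient(sched = sched, seed = 11)
    model <- test_walking_model()
    res <- process_recording(pat$recording, model)
    list(pat = pat, res = res,
         rec40 = resample_to_analysis_rate(pat$recording))
  })
}

# Truth-derived stride/contact expectations for one trimmed episode range.
truth_contacts_in_range <- function(pat, rec40, rng) {
  if (is.null(rng)) return(numeric(0))
  t0 <- rec40$time_s[rng["start"]]
  t1 <- rec40$time_s[rng["end"]]
  tc <- pat$truth$contacts$time
  tc[tc >= t0 & tc <= t1]
}
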