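# Synthetic waist-accelerometer cohorts with ground truth.
#
# The simulator emulates the validation setting: a 200 Hz waist sensor worn
# for a few hours of habitual activity, alternating rest and walking bouts,
# with motor phases alternating ON/OFF. Walking is a sum of three harmonics
# of the step frequency per body axis; the forward axis is phase-aligned so
# its maxima mark initial contacts, which are recorded as ground truth. The
# ON state has higher harmonic amplitudes (by the fluency contrast) and a
# faster cadence than OFF, so spectral power in 0.1-10 Hz is systematically
# higher in ON.

#' Gait waveform parameters for the simulator
#'
#' @param step_frequency_hz Named vector of step frequencies (steps per
#'   second) per state; defaults ON 1.9, OFF 1.5, both within the 0.5-3 Hz
#'   physiological range.
#' @param fluency_contrast Ratio of ON to OFF harmonic amplitudes (>= 1,
#'   default 1.8). Band power scales with its square.
#' @param base_amplitudes_g 3 x 3 matrix of OFF-state harmonic amplitudes in
#'   g: rows vertical/forward/lateral, columns harmonics 1-3. Vertical
#'   dominates; the forward fundamental is strong enough to give one clear
#'   contact peak per step.
#' @param noise_sd_g White accelerometer noise SD in g (default 0.03).
#' @param gravity_g Gravity bias on the vertical axis (default +1 g).
#' @param drift_amplitude_g,drift_freq_hz Slow posture-drift sinusoid added
#'   to the vertical and forward axes during rest (defaults 0.02 g at
#'   0.05 Hz).
#' @return A parameter list.
#' @export
gait_model_params <- function(step_frequency_hz = c(ON = 1.9, OFF = 1.5),
                              fluency_contrast = 1.8,
                              base_amplitudes_g = rbind(
                                vertical = c(0.30, 0.12, 0.05),
                                forward  = c(0.22, 0.10, 0.05),
                                lateral  = c(0.12, 0.05, 0.02)),
                              noise_sd_g = 0.03,
                              gravity_g = 1,
                              drift_amplitude_g = 0.02,
                              drift_freq_hz = 0.05) {
  if (any(step_frequency_hz < 0.5 | step_frequency_hz > 3)) {
    stop("step frequencies must lie in [0.5, 3] Hz", call. = FALSE)
  }
  if (fluency_contrast < 1) stop("fluency_contrast must be >= 1", call. = FALSE)
  if (any(base_amplitudes_g < 0)) {
    stop("harmonic amplitudes must be >= 0", call. = FALSE)
  }
  list(step_frequency_hz = step_frequency_hz,
       fluency_contrast = fluency_contrast,
       base_amplitudes_g = base_amplitudes_g,
       noise_sd_g = noise_sd_g, gravity_g = gravity_g,
       drift_amplitude_g = drift_amplitude_g, drift_freq_hz = drift_freq_hz)
}

#' Activity schedule parameters for the simulator
#'
#' Defaults emulate the validation protocol: 3-5 hours of monitoring with
#' ON/OFF phases of roughly 1.5 h median duration (motor phases typically
#' last 1-3 h), and walking bouts dense enough to give a decision every few
#' minutes, matching the observed output rate of the method on real
#' recordings.
#'
#' @param total_duration_s Total monitored time in seconds; `NULL` (default)
#'   draws uniformly from 3-5 hours.
#' @param phase_median_s,phase_sdlog Lognormal motor-phase duration: median
#'   (default 5400 s = 1.5 h) and log-SD (default 0.4).
#' @param phase_min_s Minimum phase duration (default 1200 s), so that phases
#'   survive the 5-minute transition margins.
#' @param intermediate_fraction Probability that a phase (after the first
#'   two) is INTERMEDIATE (default 0.1); such phases exist to exercise the
#'   exclusion path.
#' @param bout_rate_per_hour Mean walking-bout rate during a phase
#'   (default 30).
#' @param bout_median_s,bout_sdlog Lognormal bout duration: median (default
#'   40 s) and log-SD (default 0.5).
#' @param bout_min_s,bout_max_s Bout duration clamp (defaults 15 and 180 s).
#' @param min_gap_s Minimum rest gap between bouts (default 10 s).
#' @param diary_latency_s Observer reporting latency: interior diary
#'   boundaries lag the true state change by this many seconds (default 30).
#' @return A parameter list.
#' @export
schedule_params <- function(total_duration_s = NULL,
                            phase_median_s = 5400, phase_sdlog = 0.4,
                            phase_min_s = 1200,
                            intermediate_fraction = 0.1,
                            bout_rate_per_hour = 30,
                            bout_median_s = 40, bout_sdlog = 0.5,
                            bout_min_s = 15, bout_max_s = 180,
                            min_gap_s = 10,
                            diary_latency_s = 30) {
  if (bout_min_s > phase_min_s) {
    stop("infeasible schedule: minimum bout longer than minimum phase",
         call. = FALSE)
  }
  if (!is.null(total_duration_s) && total_duration_s <= 0) {
    stop("total_duration_s must be positive", call. = FALSE)
  }
  list(total_duration_s = total_duration_s,
       phase_median_s = phase_median_s, phase_sdlog = phase_sdlog,
       phase_min_s = phase_min_s,
       intermediate_fraction = intermediate_fraction,
       bout_rate_per_hour = bout_rate_per_hour,
       bout_median_s = bout_median_s, bout_sdlog = bout_sdlog,
       bout_min_s = bout_min_s, bout_max_s = bout_max_s,
       min_gap_s = min_gap_s,
       diary_latency_s = diary_latency_s)
}

# Draw the motor-phase timeline. The first two phases are one ON and one OFF
# (random order) so both classes are represented; later phases alternate with
# an occasional INTERMEDIATE. scarce_off / all-ON patients get a single phase.
draw_phases <- function(total, sched, scarce_off) {
  if (scarce_off) {
    return(data.frame(start_s = 0, end_s = total, state = "ON"))
  }
  rdur <- function() {
    max(sched$phase_min_s,
        stats::rlnorm(1, meanlog = log(sched$phase_median_s),
                      sdlog = sched$phase_sdlog))
  }
  first_two <- sample(c("ON", "OFF"))
  states <- character(0); durs <- numeric(0)
  t <- 0; last_main <- first_two[2]
  k <- 0
  while (t < total) {
    k <- k + 1
    if (k <= 2) {
      st <- first_two[k]
      # keep room for the second mandatory phase
      d <- if (k == 1) {
        max(min(rdur(), total - sched$phase_min_s), total / 4)
      } else rdur()
      last_main <- st
    } else if (stats::runif(1) < sched$intermediate_fraction) {
      st <- "INTERMEDIATE"; d <- rdur()
    } else {
      st <- if (last_main == "ON") "OFF" else "ON"
      last_main <- st
      d <- rdur()
    }
    d <- min(d, total - t)
    states <- c(states, st); durs <- c(durs, d)
    t <- t + d
  }
  ends <- cumsum(durs)
  data.frame(start_s = c(0, ends[-length(ends)]), end_s = ends,
             state = states)
}

# Place walking bouts inside one phase: exponential gaps at the configured
# rate, lognormal durations, all bouts strictly inside the phase.
draw_bouts <- function(phase_start, phase_end, sched) {
  rate <- sched$bout_rate_per_hour / 3600
  t <- phase_start
  starts <- numeric(0); ends <- numeric(0)
  repeat {
    gap <- max(sched$min_gap_s, stats::rexp(1, rate))
    dur <- min(sched$bout_max_s,
               max(sched$bout_min_s,
                   stats::rlnorm(1, log(sched$bout_median_s),
                                 sched$bout_sdlog)))
    if (t + gap + dur > phase_end) break
    starts <- c(starts, t + gap); ends <- c(ends, t + gap + dur)
    t <- t + gap + dur
  }
  data.frame(start_s = starts, end_s = ends)
}

#' Simulate one patient's recording, diary, and ground truth
#'
#' Generates a 200 Hz triaxial recording: gravity bias plus white noise
#' everywhere, slow posture drift during rest, and a state-dependent
#' three-harmonic gait waveform during walking bouts. The diary equals the
#' true motor-state timeline with interior boundaries delayed by the
#' reporting latency. Deterministic under `seed`.
#'
#' @param gait A [gait_model_params()].
#' @param sched A [schedule_params()].
#' @param seed Integer seed.
#' @param patient_id Identifier.
#' @param scarce_off If `TRUE`, the patient records no OFF phase at all,
#'   constructing the "not enough motor data" exclusion case.
#' @param sampling_rate_hz Sensor rate (default 200).
#' @return Object of class `synthetic_patient`: `recording`
#'   (an `accel_recording`), `diary` (a `diary_timeline`) and `truth` (list
#'   with `phases`, `bouts` — including per-bout `state` and `cadence_hz` —
#'   and `contacts`, a data.frame of true initial-contact times).
#' @export
simulate_patient <- function(gait = gait_model_params(),
                             sched = schedule_params(),
                             seed = 1, patient_id = "sim-1",
                             scarce_off = FALSE,
                             sampling_rate_hz = 200) {
  with_seed(seed, {
    total <- sched$total_duration_s
    if (is.null(total)) total <- stats::runif(1, 3 * 3600, 5 * 3600)
    phases <- draw_phases(total, sched, scarce_off)
    bouts <- do.call(rbind, lapply(seq_len(nrow(phases)), function(i) {
      b <- draw_bouts(phases$start_s[i], phases$end_s[i], sched)
      if (nrow(b) == 0) return(NULL)
      b$state <- phases$state[i]
      b
    }))
    if (is.null(bouts)) {
      bouts <- data.frame(start_s = numeric(0), end_s = numeric(0),
                          state = character(0))
    }
    n <- round(total * sampling_rate_hz)
    t <- (seq_len(n) - 1) / sampling_rate_hz
    acc <- matrix(stats::rnorm(3 * n, sd = gait$noise_sd_g), n, 3)
    colnames(acc) <- c("ax", "ay", "az")
    roles <- default_axis_roles()
    col_of <- vapply(roles, function(r) r$axis, character(1))
    # gravity bias and rest-time posture drift on the vertical axis
    acc[, col_of["vertical"]] <- acc[, col_of["vertical"]] + gait$gravity_g
    if (gait$drift_amplitude_g > 0) {
      drift <- gait$drift_amplitude_g * sin(2 * pi * gait$drift_freq_hz * t)
      acc[, col_of["vertical"]] <- acc[, col_of["vertical"]] + drift
      acc[, col_of["forward"]] <- acc[, col_of["forward"]] + 0.5 * drift
    }
    # fixed per-patient harmonic phase offsets (forward stays at 0 so that
    # forward-axis maxima coincide with initial contacts)
    phase_off <- list(vertical = stats::runif(3, 0, 2 * pi),
                      forward = c(0, 0, 0),
                      lateral = stats::runif(3, 0, 2 * pi))
    amp_scale <- c(OFF = 1, ON = gait$fluency_contrast,
                   INTERMEDIATE = (1 + gait$fluency_contrast) / 2)
    f_on <- gait$step_frequency_hz[["ON"]]
    f_off <- gait$step_frequency_hz[["OFF"]]
    cadence <- c(OFF = f_off, ON = f_on, INTERMEDIATE = (f_on + f_off) / 2)
    contacts <- list()
    if (nrow(bouts) > 0) {
      bouts$cadence_hz <- unname(cadence[bouts$state])
      for (b in seq_len(nrow(bouts))) {
        b0 <- bouts$start_s[b]; b1 <- bouts$end_s[b]
        f <- bouts$cadence_hz[b]
        sc <- amp_scale[[bouts$state[b]]]
        idx <- which(t >= b0 & t < b1)
        tt <- t[idx] - b0
        for (role in names(roles)) {
          a <- gait$base_amplitudes_g[role, ] * sc
          wave <- a[1] * cos(2 * pi * f * tt + phase_off[[role]][1]) +
            a[2] * cos(2 * pi * 2 * f * tt + phase_off[[role]][2]) +
            a[3] * cos(2 * pi * 3 * f * tt + phase_off[[role]][3])
          cn <- col_of[[role]]
          acc[idx, cn] <- acc[idx, cn] + roles[[role]]$sign * wave
        }
        ct <- b0 + seq(0, b1 - b0 - 1e-9, by = 1 / f)
        contacts[[b]] <- data.frame(time = ct, bout = b,
                                    state = bouts$state[b])
      }
    }
    contacts <- if (length(contacts)) do.call(rbind, contacts) else
      data.frame(time = numeric(0), bout = integer(0), state = character(0))
    # diary: interior boundaries lag the true change by the reporting latency
    db <- phases
    if (nrow(db) > 1) {
      lag <- pmin(sched$diary_latency_s,
                  (db$end_s[-1] - db$start_s[-1]) / 2)
      db$end_s[-nrow(db)] <- db$end_s[-nrow(db)] + lag
      db$start_s[-1] <- db$start_s[-1] + lag
    }
    rec <- suppressWarnings(
      accel_recording(t, acc, sampling_rate_hz, patient_id = patient_id,
                      axis_roles = roles))
    structure(
      list(recording = rec,
           diary = diary_timeline(db$start_s, db$end_s, db$state),
           truth = list(phases = phases, bouts = bouts, contacts = contacts),
           seed = seed, gait = gait, sched = sched,
           scarce_off = scarce_off),
      class = "synthetic_patient")
  })
}

#' @export
print.synthetic_patient <- function(x, ...) {
  cat(sprintf(
    "<synthetic_patient> %s: %.1f h, %d phases, %d walking bouts%s\n",
    x$recording$patient_id, diff(range(x$recording$time_s)) / 3600,
    nrow(x$truth$phases), nrow(x$truth$bouts),
    if (x$scarce_off) " (scarce OFF)" else ""))
  invisible(x)
}

#' Deterministic per-patient plan for a synthetic cohort
#'
#' Draws per-patient jitter (step frequencies +/- 0.1 Hz, amplitude scale
#' x U(0.85, 1.15)) and per-patient seeds from `base_seed`, and flags the
#' last `n_scarce_off` patients as recording no OFF data (to exercise the
#' exclusion path of the validation protocol).
#'
#' @param n_patients Cohort size (>= 1).
#' @param gait,sched Base parameter lists.
#' @param base_seed Integer base seed.
#' @param n_scarce_off Number of patients constructed with no OFF decisions.
#' @param jitter Apply per-patient parameter jitter (default `TRUE`).
#' @return List of per-patient specs: `patient_id`, `seed`, `gait`, `sched`,
#'   `scarce_off`.
#' @export
cohort_plan <- function(n_patients, gait = gait_model_params(),
                        sched = schedule_params(), base_seed = 1,
                        n_scarce_off = 0, jitter = TRUE) {
  stopifnot(n_patients >= 1, n_scarce_off <= n_patients)
  with_seed(base_seed, {
    lapply(seq_len(n_patients), function(i) {
      g <- gait
      if (jitter) {
        g$step_frequency_hz <- stats::setNames(
          pmin(3, pmax(0.5, g$step_frequency_hz + stats::runif(2, -0.1, 0.1))),
          names(g$step_frequency_hz))
        g$base_amplitudes_g <- g$base_amplitudes_g *
          stats::runif(1, 0.85, 1.15)
      }
      list(patient_id = sprintf("sim-%02d", i),
           seed = base_seed + 7919L * i,
           gait = g, sched = sched,
           scarce_off = i > n_patients - n_scarce_off)
    })
  })
}

#' Simulate a cohort of synthetic patients
#'
#' @inheritParams cohort_plan
#' @return List of `synthetic_patient` objects.
#' @export
simulate_cohort <- function(n_patients, gait = gait_model_params(),
                            sched = schedule_params(), base_seed = 1,
                            n_scarce_off = 0, jitter = TRUE) {
  plan <- cohort_plan(n_patients, gait, sched, base_seed, n_scarce_off,
                      jitter)
  lapply(plan, simulate_from_spec)
}

#' Instantiate one patient from a [cohort_plan()] spec
#'
#' @param spec One element of a [cohort_plan()].
#' @return A `synthetic_patient`.
#' @export
simulate_from_spec <- function(spec) {
  simulate_patient(gait = spec$gait, sched = spec$sched, seed = spec$seed,
                   patient_id = spec$patient_id,
                   scarce_off = spec$scarce_off)
}
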