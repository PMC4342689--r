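# End-to-end pipeline: recording -> walking episodes -> stride fluencies ->
# episode decisions -> diary-validated report.

#' Run configuration with the method's default parameters
#'
#' Defaults: 3.2 s windows at the 40 Hz analysis rate, walking features in
#' the 0.1-3 and 0.1-10 Hz bands, fluency band 0.1-10 Hz, 20% calibration
#' fraction with 30 random repeats, 300 s transition margins, and the
#' 10-stride segment filter.
#'
#' @param ... Named overrides of any default entry.
#' @return A named list.
#' @export
default_run_config <- function(...) {
  cfg <- list(
    window_seconds = 3.2,
    analysis_rate_hz = 40,
    walking_bands = list(c(0.1, 3), c(0.1, 10)),
    fluency_band = c(0.1, 10),
    min_peak_separation_s = 0.35,
    min_peak_prominence_g = 0.05,
    stride_min_s = 0.5,
    stride_max_s = 4.0,
    calibration_fraction = 0.2,
    n_repeats = 30,
    margin_s = 300,
    min_strides = 10,
    seed = 1
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) {
    stop(sprintf("unknown config entries: %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  cfg[names(over)] <- over
  cfg
}

#' Load a run configuration from a YAML file
#'
#' Entries present in the file override the defaults of
#' [default_run_config()]; unknown keys are an error.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return A config list.
#' @export
load_run_config <- function(path = NULL) {
  if (is.null(path)) return(default_run_config())
  if (!file.exists(path)) {
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  }
  over <- yaml::read_yaml(path)
  do.call(default_run_config, over)
}

config_objects <- function(cfg) {
  list(win = windowing_config(cfg$window_seconds, cfg$analysis_rate_hz),
       peaks = peak_params(cfg$min_peak_separation_s,
                           cfg$min_peak_prominence_g),
       bounds = stride_bounds(cfg$stride_min_s, cfg$stride_max_s))
}

#' Process one recording into episode decisions
#'
#' Resamples to the analysis rate, detects walking windows and episodes,
#' trims episode boundaries, detects initial contacts, builds strides,
#' scores per-stride fluency and aggregates to episode mean fluency.
#'
#' @param rec An `accel_recording` (any rate >= the analysis rate).
#' @param model A trained `walking_model`.
#' @param cfg A run configuration (see [default_run_config()]).
#' @return List with `decisions` (data.frame `episode_id`, `start_s`,
#'   `end_s`, `timestamp_s` = episode midpoint, `stride_count`,
#'   `mean_fluency`; one row per episode, `mean_fluency` `NA` when fewer than
#'   5 strides), `labels` (per-window walking flags), `episodes`, and
#'   `contacts` (detected initial contacts with absolute `time_s`).
#' @export
process_recording <- function(rec, model, cfg = default_run_config()) {
  obj <- config_objects(cfg)
  rec40 <- resample_to_analysis_rate(rec, cfg$analysis_rate_hz)
  det <- detect_walking(rec40, model, obj$win)
  eps <- det$episodes
  rows <- vector("list", nrow(eps))
  contacts <- vector("list", nrow(eps))
  fwd <- axis_signal(rec40, "forward")
  for (i in seq_len(nrow(eps))) {
    rng <- trim_episode_boundaries(eps[i, ], obj$win)
    count <- 0L; mean_fl <- NA_real_
    if (!is.null(rng)) {
      seg <- fwd[rng["start"]:rng["end"]]
      ev <- detect_initial_contacts(seg, cfg$analysis_rate_hz, obj$peaks)
      if (nrow(ev) > 0) {
        gidx <- ev$sample_index + rng["start"] - 1L
        contacts[[i]] <- data.frame(episode_id = eps$episode_id[i],
                                    time_s = rec40$time_s[gidx],
                                    amplitude = ev$amplitude)
      }
      strides <- build_strides(ev, cfg$analysis_rate_hz, obj$bounds)
      if (nrow(strides) > 0) {
        strides$start <- strides$start + rng["start"] - 1L
        strides$end <- strides$end + rng["start"] - 1L
        fl <- stride_fluencies(strides, rec40$acc, cfg$analysis_rate_hz,
                               cfg$fluency_band)
        ef <- episode_fluency(fl)
        count <- ef$stride_count; mean_fl <- ef$mean_fluency
      }
    }
    rows[[i]] <- data.frame(episode_id = eps$episode_id[i],
                            start_s = eps$start_time[i],
                            end_s = eps$end_time[i],
                            timestamp_s = (eps$start_time[i] +
                                             eps$end_time[i]) / 2,
                            stride_count = count,
                            mean_fluency = mean_fl)
  }
  decisions <- if (length(rows)) do.call(rbind, rows) else
    data.frame(episode_id = integer(0), start_s = numeric(0),
               end_s = numeric(0), timestamp_s = numeric(0),
               stride_count = integer(0), mean_fluency = numeric(0))
  contacts <- contacts[!vapply(contacts, is.null, logical(1))]
  list(decisions = decisions,
       labels = det$labels,
       episodes = eps,
       contacts = if (length(contacts)) do.call(rbind, contacts) else NULL)
}

#' Episode decisions that carry a defined mean fluency
#'
#' Episodes with fewer than 5 strides have no interior stride after the 2+2
#' exclusion and emit no decision.
#'
#' @param decisions Output `decisions` of [process_recording()].
#' @return The subset with defined `mean_fluency`.
#' @export
emitted_decisions <- function(decisions) {
  decisions[!is.na(decisions$mean_fluency), , drop = FALSE]
}

#' Train the default walking model on simulated development data
#'
#' Emulates the development protocol: the window classifier is trained
#' across several supervised subjects, not on the deployment patient.
#' A small development cohort is simulated with the usual per-subject
#' parameter jitter so the walking class covers the deployment range of
#' cadences and amplitudes (a single training subject leaves gaps between
#' its ON and OFF feature clusters that the RBF boundary will exclude).
#' Windows are labeled walking when at least half of their samples fall
#' inside a true bout, and the RBF-SVM window classifier is trained on the
#' two default band-power features.
#'
#' @param seed Integer seed (simulation and CV folds).
#' @param cfg Run configuration.
#' @param duration_s Supervised recording length per subject
#'   (default 600 s).
#' @param n_subjects Number of simulated development subjects (default 6).
#' @return A `walking_model`.
#' @export
train_default_walking_model <- function(seed = 1,
                                        cfg = default_run_config(),
                                        duration_s = 600,
                                        n_subjects = 6) {
  obj <- config_objects(cfg)
  sched <- schedule_params(total_duration_s = duration_s,
                           phase_median_s = duration_s / 3,
                           phase_min_s = duration_s / 6,
                           bout_rate_per_hour = 90,
                           bout_min_s = 10, bout_median_s = 25,
                           bout_max_s = 60, min_gap_s = 8,
                           diary_latency_s = 0)
  plan <- cohort_plan(n_subjects, sched = sched, base_seed = seed)
  feats <- list(); labels <- list()
  for (spec in plan) {
    pat <- simulate_from_spec(spec)
    rec40 <- resample_to_analysis_rate(pat$recording, cfg$analysis_rate_hz)
    feats[[spec$patient_id]] <-
      window_band_powers(rec40, obj$win, cfg$walking_bands)
    labels[[spec$patient_id]] <-
      window_walking_labels(rec40, pat$truth$bouts, obj$win)
  }
  wcfg <- walking_classifier_config(seed = seed, bands = cfg$walking_bands)
  train_walking_model(do.call(rbind, feats), unlist(labels), wcfg)
}

# True per-window walking labels: walking when >= 50% of the window lies
# inside a ground-truth bout.
window_walking_labels <- function(rec40, bouts, win = windowing_config()) {
  ws <- win$window_samples
  nw <- n_samples(rec40) %/% ws
  t0 <- rec40$time_s[1]
  starts <- t0 + (seq_len(nw) - 1L) * win$window_seconds
  mids <- vapply(starts, function(s) {
    if (nrow(bouts) == 0) return(0)
    lo <- pmax(s, bouts$start_s); hi <- pmin(s + win$window_seconds,
                                             bouts$end_s)
    sum(pmax(0, hi - lo))
  }, numeric(1))
  mids >= 0.5 * win$window_seconds
}

#' Run the full study on a synthetic cohort
#'
#' Simulates each patient of the plan, processes the recording into episode
#' decisions, labels them against the diary (transition margins,
#' intermediate/undefined exclusion), and runs the repeated-split validation
#' protocol. Patients are processed one at a time so raw 200 Hz signals are
#' not held simultaneously.
#'
#' @param plan A [cohort_plan()].
#' @param model A `walking_model`; `NULL` trains the default model with
#'   `cfg$seed`.
#' @param cfg Run configuration.
#' @return List with `report` (a `validation_report`), `labeled` (per-patient
#'   scored decisions), `accounting` (per-patient drop-reason counts) and
#'   `decision_interval_min` (mean minutes between emitted decisions, all
#'   segments and >= `min_strides` variants).
#' @export
run_study <- function(plan, model = NULL, cfg = default_run_config()) {
  if (is.null(model)) model <- train_default_walking_model(cfg$seed, cfg)
  labeled <- list()
  accounting <- list()
  intervals_all <- numeric(0)
  intervals_10 <- numeric(0)
  for (spec in plan) {
    pat <- simulate_from_spec(spec)
    res <- process_recording(pat$recording, model, cfg)
    dec <- emitted_decisions(res$decisions)
    lab <- label_decisions(dec, pat$diary, margin_s = cfg$margin_s)
    labeled[[spec$patient_id]] <- lab$scored
    accounting[[spec$patient_id]] <-
      c(n_decisions = nrow(dec), n_scored = nrow(lab$scored),
        table(factor(lab$dropped$reason,
                     levels = c("no gold standard", "straddles transition",
                                "transition margin", "intermediate",
                                "undefined"))))
    iv <- mean_decision_interval_min(dec$timestamp_s)
    iv10 <- mean_decision_interval_min(
      filter_min_strides(dec, cfg$min_strides)$timestamp_s)
    if (!is.na(iv)) intervals_all <- c(intervals_all, iv)
    if (!is.na(iv10)) intervals_10 <- c(intervals_10, iv10)
  }
  report <- run_validation(labeled, n_repeats = cfg$n_repeats,
                           base_seed = cfg$seed,
                           fraction = cfg$calibration_fraction,
                           min_strides = cfg$min_strides)
  list(report = report,
       labeled = labeled,
       accounting = accounting,
       decision_interval_min = c(all_segments = mean(intervals_all),
                                 min_strides = mean(intervals_10)),
       model = model)
}
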