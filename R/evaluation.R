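# Validation protocol: diary alignment, exclusion rules, confusion metrics,
# and the repeated-split per-patient / cohort report.
#
# Throughout, OFF is the positive class: a true positive is an OFF decision
# in an OFF diary interval.

diary_states <- c("ON", "OFF", "INTERMEDIATE", "UNDEFINED")

#' Gold-standard diary timeline
#'
#' An ordered, gap-free sequence of labeled motor-state intervals recorded by
#' a trained observer and confirmed by the patient. States are ON, OFF,
#' INTERMEDIATE (patient reports a state between ON and OFF) or UNDEFINED
#' (patient and observer disagree).
#'
#' @param start_s,end_s Interval bounds in seconds; intervals must tile the
#'   monitored span without gaps or overlaps.
#' @param state Character vector of states.
#' @return data.frame of class `diary_timeline`.
#' @export
diary_timeline <- function(start_s, end_s, state) {
  d <- data.frame(start_s = as.numeric(start_s), end_s = as.numeric(end_s),
                  state = as.character(state))
  if (nrow(d) == 0) stop("diary must have at least one interval", call. = FALSE)
  if (!all(d$state %in% diary_states)) {
    stop(sprintf("diary states must be one of: %s",
                 paste(diary_states, collapse = ", ")), call. = FALSE)
  }
  d <- d[order(d$start_s), , drop = FALSE]
  if (any(d$end_s <= d$start_s)) {
    stop("diary intervals must have end > start", call. = FALSE)
  }
  if (nrow(d) > 1 &&
      any(abs(d$start_s[-1] - d$end_s[-nrow(d)]) > 1e-6)) {
    stop("diary intervals must tile the span without gaps or overlaps",
         call. = FALSE)
  }
  rownames(d) <- NULL
  class(d) <- c("diary_timeline", "data.frame")
  d
}

#' Read / write a diary CSV (`start_s,end_s,state`)
#'
#' @param path File path.
#' @return [read_diary()]: a `diary_timeline`.
#' @export
read_diary <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("diary file not found: %s", path), call. = FALSE)
  }
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("start_s", "end_s", "state")
  if (!all(need %in% names(d))) {
    stop("diary CSV must have columns start_s,end_s,state", call. = FALSE)
  }
  diary_timeline(d$start_s, d$end_s, d$state)
}

#' @rdname read_diary
#' @param diary A `diary_timeline`.
#' @export
write_diary <- function(diary, path) {
  utils::write.csv(as.data.frame(diary)[, c("start_s", "end_s", "state")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# State at time t (start-inclusive, end-exclusive); NA outside the span.
diary_state_at <- function(diary, t) {
  i <- findInterval(t, diary$start_s)
  out <- rep(NA_character_, length(t))
  ok <- i >= 1 & t < diary$end_s[pmax(i, 1)]
  out[ok] <- diary$state[i[ok]]
  out
}

merge_intervals <- function(start, end) {
  if (length(start) == 0) {
    return(data.frame(start_s = numeric(0), end_s = numeric(0)))
  }
  o <- order(start)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  out_s <- numeric(0); out_e <- numeric(0)
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me) {
      me <- max(me, end[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- start[i]; me <- end[i]
    }
  }
  data.frame(start_s = c(out_s, ms), end_s = c(out_e, me))
}

#' Time intervals excluded around motor-phase transitions
#'
#' Five minutes of signal before the start and after the termination of a
#' motor phase are excluded as synchronization-error margin between the
#' algorithm and the gold standard (the observer and patient need time to
#' notice and report a change). Overlapping margins are merged.
#'
#' @param diary A `diary_timeline`.
#' @param margin_s Margin in seconds on each side of a transition
#'   (default 300).
#' @return data.frame of merged excluded intervals (`start_s`, `end_s`); zero
#'   rows when the diary has no transition between differing states.
#' @export
transition_exclusion_mask <- function(diary, margin_s = 300) {
  n <- nrow(diary)
  if (n < 2) return(data.frame(start_s = numeric(0), end_s = numeric(0)))
  b <- diary$end_s[-n][diary$state[-n] != diary$state[-1]]
  merge_intervals(b - margin_s, b + margin_s)
}

in_intervals <- function(t, intervals) {
  if (nrow(intervals) == 0) return(rep(FALSE, length(t)))
  vapply(t, function(x) any(x >= intervals$start_s & x <= intervals$end_s),
         logical(1))
}

#' Label algorithm decisions against the diary gold standard
#'
#' Each decision is looked up in the diary at its episode midpoint and either
#' receives an ON/OFF gold label or is dropped with a reason code:
#' `"no gold standard"` (midpoint outside the diary span),
#' `"straddles transition"` (episode start and end fall in differing states),
#' `"transition margin"` (midpoint within the 5-minute synchronization
#' margin), `"intermediate"` or `"undefined"` (diary state excluded from
#' scoring). The bookkeeping identity `nrow(scored) + nrow(dropped) ==
#' nrow(decisions)` always holds.
#'
#' @param decisions data.frame with `timestamp_s` (episode midpoint) and,
#'   optionally, `start_s`/`end_s` for the straddle check.
#' @param diary A `diary_timeline`.
#' @param mask Excluded intervals; defaults to
#'   `transition_exclusion_mask(diary, margin_s)`.
#' @param margin_s Margin used when `mask` is not supplied.
#' @return List with `scored` (decisions plus a `label` column) and `dropped`
#'   (decisions plus a `reason` column).
#' @export
label_decisions <- function(decisions, diary, mask = NULL, margin_s = 300) {
  if (is.null(mask)) mask <- transition_exclusion_mask(diary, margin_s)
  n <- nrow(decisions)
  reason <- rep(NA_character_, n)
  ts <- decisions$timestamp_s
  st <- diary_state_at(diary, ts)
  reason[is.na(st)] <- "no gold standard"
  if (all(c("start_s", "end_s") %in% names(decisions))) {
    s0 <- diary_state_at(diary, decisions$start_s)
    s1 <- diary_state_at(diary, pmin(decisions$end_s,
                                     max(diary$end_s) - 1e-9))
    straddle <- is.na(reason) & !is.na(s0) & !is.na(s1) & s0 != s1
    reason[straddle] <- "straddles transition"
  }
  reason[is.na(reason) & in_intervals(ts, mask)] <- "transition margin"
  reason[is.na(reason) & st == "INTERMEDIATE"] <- "intermediate"
  reason[is.na(reason) & st == "UNDEFINED"] <- "undefined"
  keep <- is.na(reason)
  scored <- decisions[keep, , drop = FALSE]
  scored$label <- factor(st[keep], levels = c("OFF", "ON"))
  dropped <- decisions[!keep, , drop = FALSE]
  dropped$reason <- reason[!keep]
  rownames(scored) <- rownames(dropped) <- NULL
  list(scored = scored, dropped = dropped)
}

#' Keep decisions from walking segments with at least `min_strides` strides
#'
#' @param decisions data.frame with a `stride_count` column.
#' @param min_strides Inclusive lower bound (default 10).
#' @return Filtered data.frame.
#' @export
filter_min_strides <- function(decisions, min_strides = 10) {
  decisions[decisions$stride_count >= min_strides, , drop = FALSE]
}

#' Confusion counts and validity metrics, OFF as the positive class
#'
#' Sensitivity = TP/(TP+FN), specificity = TN/(TN+FP), PPV = TP/(TP+FP),
#' NPV = TN/(TN+FN). A zero denominator leaves the metric undefined (`NA`),
#' rendered as "-" in printed reports.
#'
#' @param pred,truth Vectors of `"ON"`/`"OFF"`.
#' @return List with `counts` (named TP/FP/TN/FN) and `metrics` (named
#'   sensitivity/specificity/ppv/npv).
#' @export
confusion_metrics <- function(pred, truth) {
  p <- motor_factor(pred); t <- motor_factor(truth)
  stopifnot(length(p) == length(t))
  TP <- sum(p == "OFF" & t == "OFF")
  FP <- sum(p == "OFF" & t == "ON")
  TN <- sum(p == "ON" & t == "ON")
  FN <- sum(p == "ON" & t == "OFF")
  safe_div <- function(a, b) if (b == 0) NA_real_ else a / b
  list(counts = c(TP = TP, FP = FP, TN = TN, FN = FN),
       metrics = c(sensitivity = safe_div(TP, TP + FN),
                   specificity = safe_div(TN, TN + FP),
                   ppv = safe_div(TP, TP + FP),
                   npv = safe_div(TN, TN + FN)))
}

#' Mean interval between consecutive decisions, in minutes
#'
#' @param timestamps_s Decision timestamps in seconds.
#' @return Mean of successive differences in minutes (`NA` for < 2
#'   decisions).
#' @export
mean_decision_interval_min <- function(timestamps_s) {
  if (length(timestamps_s) < 2) return(NA_real_)
  mean(diff(sort(timestamps_s))) / 60
}

metric_names <- c("sensitivity", "specificity", "ppv", "npv")

# One patient's repeated-split validation: mean/SD of each metric over
# repeats. Returns NULL if calibration is infeasible.
validate_patient <- function(decisions, n_repeats, base_seed, fraction) {
  y <- decisions$label
  if (sum(y == "ON") < 2 || sum(y == "OFF") < 2) return(NULL)
  per_rep <- matrix(NA_real_, nrow = n_repeats, ncol = length(metric_names),
                    dimnames = list(NULL, metric_names))
  for (r in seq_len(n_repeats)) {
    seed_r <- base_seed + r
    sp <- make_split(y, fraction = fraction, seed = seed_r)
    thr <- suppressWarnings(
      fit_threshold(decisions$mean_fluency[sp$calibration],
                    y[sp$calibration], seed = seed_r))
    pred <- classify_motor_state(decisions$mean_fluency[sp$evaluation], thr)
    per_rep[r, ] <- confusion_metrics(pred, y[sp$evaluation])$metrics
  }
  list(mean = colMeans(per_rep, na.rm = TRUE),
       sd = apply(per_rep, 2, stats::sd, na.rm = TRUE),
       per_repeat = per_rep)
}

#' Run the full repeated-split validation protocol over a cohort
#'
#' For each patient and each variant (all walking segments; segments with at
#' least `min_strides` strides): repeat `n_repeats` times a stratified random
#' 20% calibration split, fit the patient threshold on the calibration set,
#' classify the evaluation set, and compute sensitivity, specificity, PPV and
#' NPV (OFF positive). Per-patient means and SDs over repeats are aggregated
#' into cohort mean, median and IQR (type-7 quantiles), omitting undefined
#' values pairwise. Patients with fewer than 2 scored decisions in either
#' class are reported as excluded for that variant. Repeat r uses seed
#' `base_seed + r`.
#'
#' @param labeled_by_patient Named list, one scored-decision data.frame per
#'   patient (columns `label`, `mean_fluency`, `stride_count`; see
#'   [label_decisions()]).
#' @param n_repeats Number of random splits (default 30).
#' @param base_seed Integer base seed.
#' @param fraction Calibration fraction (default 0.2).
#' @param min_strides Stride filter for the second variant (default 10).
#' @return Object of class `validation_report`: per variant, `per_patient`
#'   (one row per included patient with decision counts and metric mean/SD)
#'   plus `cohort` (mean/median/IQR per metric) and `excluded` (patient ids).
#' @export
run_validation <- function(labeled_by_patient, n_repeats = 30, base_seed = 1,
                           fraction = 0.2, min_strides = 10) {
  ids <- names(labeled_by_patient)
  if (is.null(ids)) ids <- as.character(seq_along(labeled_by_patient))
  variants <- list(all_segments = function(d) d,
                   min_strides = function(d) filter_min_strides(d, min_strides))
  out <- lapply(variants, function(filt) {
    rows <- list(); excluded <- character(0)
    for (i in seq_along(labeled_by_patient)) {
      d <- filt(labeled_by_patient[[i]])
      res <- validate_patient(d, n_repeats, base_seed, fraction)
      if (is.null(res)) {
        excluded <- c(excluded, ids[i])
        next
      }
      row <- data.frame(patient_id = ids[i],
                        n_off = sum(d$label == "OFF"),
                        n_on = sum(d$label == "ON"))
      for (m in metric_names) {
        row[[paste0(m, "_mean")]] <- res$mean[[m]]
        row[[paste0(m, "_sd")]] <- res$sd[[m]]
      }
      rows[[length(rows) + 1L]] <- row
    }
    per_patient <- if (length(rows)) do.call(rbind, rows) else NULL
    cohort <- NULL
    if (!is.null(per_patient)) {
      cohort <- do.call(rbind, lapply(metric_names, function(m) {
        v <- per_patient[[paste0(m, "_mean")]]
        v <- v[!is.na(v)]
        data.frame(metric = m,
                   mean = mean(v),
                   median = stats::median(v),
                   iqr_lo = unname(stats::quantile(v, 0.25, type = 7)),
                   iqr_hi = unname(stats::quantile(v, 0.75, type = 7)),
                   n_patients = length(v))
      }))
    }
    list(per_patient = per_patient, cohort = cohort, excluded = excluded)
  })
  structure(list(variants = out, n_repeats = n_repeats,
                 base_seed = base_seed, fraction = fraction,
                 min_strides = min_strides),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  fmt <- function(v) ifelse(is.na(v), "-", sprintf("%.2f", v))
  for (vn in names(x$variants)) {
    v <- x$variants[[vn]]
    cat(sprintf("== %s (%d repeats) ==\n", vn, x$n_repeats))
    if (length(v$excluded)) {
      cat("excluded patients:", paste(v$excluded, collapse = ", "), "\n")
    }
    if (!is.null(v$cohort)) {
      for (i in seq_len(nrow(v$cohort))) {
        r <- v$cohort[i, ]
        cat(sprintf("  %-12s mean %s  median %s  IQR %s-%s (n=%d)\n",
                    r$metric, fmt(r$mean), fmt(r$median), fmt(r$iqr_lo),
                    fmt(r$iqr_hi), r$n_patients))
      }
    } else {
      cat("  no patient could be validated\n")
    }
  }
  invisible(x)
}

# JSON-friendly representation of a validation report.
report_to_list <- function(report) {
  lapply(report$variants, function(v) {
    list(per_patient = v$per_patient, cohort = v$cohort,
         excluded = v$excluded)
  })
}
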