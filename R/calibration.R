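# Patient-specific ON/OFF threshold calibration.
#
# Episode fluencies are scalar, so the linear-kernel maximum-margin separator
# fitted to a calibration subset reduces to a single threshold: the zero
# crossing of the SVM decision function. Fluency above the threshold is ON;
# equal or below is OFF.

motor_factor <- function(labels) {
  factor(as.character(labels), levels = c("OFF", "ON"))
}

calibration_infeasible <- function(msg) {
  stop(structure(class = c("calibration_infeasible", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Split labeled decisions into calibration and evaluation sets
#'
#' Stratified random split: `ceiling(fraction * n)` decisions per class go to
#' calibration, the remainder to evaluation. Patients without at least 2
#' decisions in each class cannot be calibrated and raise a
#' `calibration_infeasible` error (such patients are reported as excluded by
#' the validation protocol). The split is deterministic under `seed`; the
#' protocol repeats it (30 times by default) to wash out arbitrary selection.
#'
#' @param labels Vector of `"ON"`/`"OFF"` gold labels, one per decision.
#' @param fraction Calibration fraction (default 0.2).
#' @param seed Integer seed.
#' @return List with `calibration` and `evaluation` (sorted integer indices),
#'   `fraction`, `seed`.
#' @export
make_split <- function(labels, fraction = 0.2, seed = 1) {
  y <- motor_factor(labels)
  if (any(is.na(y))) stop("labels must be ON or OFF", call. = FALSE)
  tab <- table(y)
  if (any(tab < 2)) {
    calibration_infeasible(
      "not enough ON/OFF decisions to calibrate (need >= 2 per class)")
  }
  cal <- with_seed(seed, {
    unlist(lapply(levels(y), function(lev) {
      idx <- which(y == lev)
      sample(idx, ceiling(fraction * length(idx)))
    }))
  })
  cal <- sort(cal)
  list(calibration = cal,
       evaluation = setdiff(seq_along(y), cal),
       fraction = fraction, seed = seed)
}

# CV accuracy of a 1-D linear SVM at one cost value.
linear_svm_cv_accuracy <- function(x, y, C, folds, seed) {
  fold_of <- stratified_folds(y, folds, seed)
  cw <- svm_class_weights(y)
  correct <- 0L
  for (f in seq_len(folds)) {
    tr <- fold_of != f
    if (!any(!tr) || nlevels(droplevels(y[tr])) < 2) next
    fit <- e1071::svm(matrix(x[tr], ncol = 1), y[tr], kernel = "linear",
                      cost = C, scale = FALSE, class.weights = cw)
    pred <- predict(fit, matrix(x[!tr], ncol = 1))
    correct <- correct + sum(pred == y[!tr])
  }
  correct / length(y)
}

#' Fit a patient-specific ON/OFF fluency threshold
#'
#' Trains a linear-kernel SVM on the 1-D calibration fluencies and takes the
#' threshold from the zero crossing of its decision function (for separable
#' data this is the midpoint of the inner boundary points, the maximum-margin
#' solution). The cost C is chosen by cross-validated accuracy: 10-fold when
#' at least 10 patterns are available in every class, otherwise 2-fold (the
#' minimum). Ties favor the largest C, consistent with the maximum-margin
#' rationale. Classes are weighted inversely to frequency since OFF is
#' typically the minority class.
#'
#' @param fluency Numeric calibration fluencies.
#' @param labels `"ON"`/`"OFF"` per value; both classes required.
#' @param C_grid Candidate costs (default `2^seq(-5, 15, 2)`).
#' @param seed Integer seed (CV fold assignment).
#' @param patient_id Identifier carried in the result.
#' @return Object of class `patient_threshold` with `theta`,
#'   `cv_folds_used`, `C`, per-class calibration sizes and `seed`.
#' @export
fit_threshold <- function(fluency, labels, C_grid = 2^seq(-5, 15, by = 2),
                          seed = 1, patient_id = "unknown") {
  x <- as.numeric(fluency)
  y <- motor_factor(labels)
  tab <- table(y)
  if (any(tab == 0)) {
    calibration_infeasible("both ON and OFF values are required")
  }
  new_thr <- function(theta, folds, C) {
    structure(list(patient_id = patient_id, theta = theta,
                   cv_folds_used = folds, C = C,
                   calibration_size = as.list(tab), seed = seed),
              class = "patient_threshold")
  }
  if (length(unique(x)) == 1 ||
      isTRUE(all.equal(sort(unique(x[y == "ON"])),
                       sort(unique(x[y == "OFF"]))))) {
    warning("degenerate separation: classes have identical fluency values; ",
            "threshold set at the common value", call. = FALSE)
    return(new_thr(stats::median(x), NA_integer_, NA_real_))
  }
  folds <- if (min(tab) >= 10) 10L else 2L
  acc <- vapply(C_grid, function(C) {
    linear_svm_cv_accuracy(x, y, C, folds, seed)
  }, numeric(1))
  best <- max(acc)
  C_star <- max(C_grid[acc >= best - 1e-12])
  cw <- svm_class_weights(y)
  fit <- e1071::svm(matrix(x, ncol = 1), y, kernel = "linear", cost = C_star,
                    scale = FALSE, class.weights = cw)
  w <- sum(fit$coefs * fit$SV)
  theta <- if (abs(w) < 1e-12) {
    warning("flat decision function; using midpoint of class medians",
            call. = FALSE)
    (stats::median(x[y == "ON"]) + stats::median(x[y == "OFF"])) / 2
  } else {
    fit$rho / w
  }
  new_thr(theta, folds, C_star)
}

#' @export
print.patient_threshold <- function(x, ...) {
  cat(sprintf("<patient_threshold> %s: theta=%.6g (C=%g, %s-fold CV, n=%s)\n",
              x$patient_id, x$theta, x$C,
              ifelse(is.na(x$cv_folds_used), "-", x$cv_folds_used),
              paste(names(x$calibration_size), unlist(x$calibration_size),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

#' Classify episode fluencies against a patient threshold
#'
#' ON when the episode mean fluency is strictly above the threshold; OFF when
#' equal or lower.
#'
#' @param mean_fluency Numeric vector of episode mean fluencies (must be
#'   defined; episodes with undefined fluency emit no decision).
#' @param thr A `patient_threshold` (or a bare numeric threshold).
#' @return Factor with levels `OFF`, `ON`.
#' @export
classify_motor_state <- function(mean_fluency, thr) {
  theta <- if (inherits(thr, "patient_threshold")) thr$theta else thr
  if (any(is.na(mean_fluency))) {
    stop("mean_fluency must be defined for every decision", call. = FALSE)
  }
  factor(ifelse(mean_fluency > theta, "ON", "OFF"), levels = c("OFF", "ON"))
}

#' Save per-patient thresholds as JSON
#'
#' @param thresholds A `patient_threshold` or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_thresholds <- function(thresholds, path) {
  if (inherits(thresholds, "patient_threshold")) thresholds <- list(thresholds)
  payload <- lapply(thresholds, function(t) {
    list(patient_id = t$patient_id, theta = t$theta,
         cv_folds_used = t$cv_folds_used, C = t$C,
         calibration_size = t$calibration_size, seed = t$seed)
  })
  writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}
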