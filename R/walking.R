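# Walking detection: band-candidate enumeration, ReliefF feature ranking,
# RBF-SVM window classifier, and episode assembly.

# Run code with a private RNG stream, restoring the caller's .Random.seed.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Enumerate candidate frequency bands on a regular grid
#'
#' All ordered pairs `[b1, b2]` with `b2 > b1` drawn from the grid
#' `{step, 2*step, ..., max_hz}`. With the defaults (0.1 Hz step up to
#' 20 Hz) the grid has 200 values and there are 19,900 candidates, in
#' lexicographic order.
#'
#' @param grid_step Grid spacing in Hz (default 0.1). Must divide `max_hz`.
#' @param max_hz Upper grid limit in Hz (default 20, the analysis Nyquist).
#' @return A data.frame with columns `b1`, `b2`.
#' @export
enumerate_band_candidates <- function(grid_step = 0.1, max_hz = 20) {
  k <- max_hz / grid_step
  if (abs(k - round(k)) > 1e-9) {
    stop("grid_step must divide max_hz", call. = FALSE)
  }
  grid <- seq_len(round(k)) * grid_step
  n <- length(grid)
  i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(a) (a + 1L):n))
  data.frame(b1 = grid[i], b2 = grid[j])
}

#' ReliefF feature weights for a binary classification problem
#'
#' Deterministic ReliefF: every instance serves as an anchor; for each anchor
#' the k nearest same-class neighbors (hits) and k nearest other-class
#' neighbors (misses) are found under Manhattan distance on range-scaled
#' features, and each feature's weight accumulates the miss-minus-hit
#' absolute difference, normalized by `n * k`. Higher weight means more
#' class-discriminative. For two classes the standard prior-probability
#' miss weighting reduces to 1.
#'
#' @param features n x p numeric matrix.
#' @param labels Length-n vector with exactly two distinct values.
#' @param k_neighbors Neighbors per class (default 10); must be smaller than
#'   both class sizes.
#' @return Numeric vector of p feature weights.
#' @export
relieff_rank <- function(features, labels, k_neighbors = 10) {
  X <- as.matrix(features)
  y <- as.factor(labels)
  if (nlevels(droplevels(y)) != 2) {
    stop("relieff_rank requires exactly two classes", call. = FALSE)
  }
  y <- droplevels(y)
  n <- nrow(X); p <- ncol(X)
  k <- as.integer(k_neighbors)
  if (k < 1 || k >= min(table(y))) {
    stop("k_neighbors must be >= 1 and smaller than both class sizes",
         call. = FALSE)
  }
  rng <- apply(X, 2, range)
  denom <- rng[2, ] - rng[1, ]
  denom[denom == 0] <- 1
  Xs <- sweep(sweep(X, 2, rng[1, ]), 2, denom, "/")
  D <- as.matrix(stats::dist(Xs, method = "manhattan"))
  W <- numeric(p)
  for (i in seq_len(n)) {
    same <- which(y == y[i]); same <- same[same != i]
    other <- which(y != y[i])
    hits <- same[order(D[i, same])][seq_len(k)]
    misses <- other[order(D[i, other])][seq_len(k)]
    anchor <- Xs[i, ]
    W <- W +
      colSums(abs(sweep(Xs[misses, , drop = FALSE], 2, anchor))) -
      colSums(abs(sweep(Xs[hits, , drop = FALSE], 2, anchor)))
  }
  W / (n * k)
}

#' Configuration for the walking-window classifier
#'
#' An RBF-kernel SVM over the two band-power features, with C and gamma
#' chosen by stratified 10-fold cross-validation over logarithmic grids.
#' Classes are weighted inversely to their frequency because rest dominates
#' daily recordings.
#'
#' @param C_grid,gamma_grid Candidate values (defaults `2^seq(-5, 15, 2)` and
#'   `2^seq(-15, 3, 2)`).
#' @param cv_folds Number of stratified folds (default 10).
#' @param seed Integer seed controlling fold assignment.
#' @param bands List of two frequency bands used as features (defaults
#'   0.1-3 Hz and 0.1-10 Hz, ordered by upper edge).
#' @return A config list.
#' @export
walking_classifier_config <- function(C_grid = 2^seq(-5, 15, by = 2),
                                      gamma_grid = 2^seq(-15, 3, by = 2),
                                      cv_folds = 10,
                                      seed = 1,
                                      bands = list(c(0.1, 3), c(0.1, 10))) {
  stopifnot(length(C_grid) >= 1, length(gamma_grid) >= 1, cv_folds >= 2)
  bands <- bands[order(vapply(bands, function(b) b[[2]], numeric(1)))]
  list(C_grid = C_grid, gamma_grid = gamma_grid, cv_folds = cv_folds,
       seed = seed, bands = bands)
}

# Stratified fold assignment (1..folds) for a factor y, seeded.
stratified_folds <- function(y, folds, seed) {
  assign_f <- integer(length(y))
  with_seed(seed, {
    for (lev in levels(y)) {
      idx <- which(y == lev)
      assign_f[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
  })
  assign_f
}

svm_class_weights <- function(y) {
  tab <- table(y)
  w <- sum(tab) / (length(tab) * tab)
  stats::setNames(as.numeric(w), names(tab))
}

# Grid-search CV accuracy for an SVM; returns best (C, gamma, accuracy).
# Ties resolve to the earliest grid point (C ascending, gamma ascending).
svm_grid_cv <- function(X, y, C_grid, gamma_grid, folds, seed,
                        kernel = "radial") {
  fold_of <- stratified_folds(y, folds, seed)
  cw <- svm_class_weights(y)
  best <- list(C = NA_real_, gamma = NA_real_, accuracy = -Inf)
  for (C in C_grid) {
    for (g in gamma_grid) {
      correct <- 0L
      for (f in seq_len(folds)) {
        tr <- fold_of != f; te <- !tr
        if (!any(te) || nlevels(droplevels(y[tr])) < 2) next
        fit <- e1071::svm(X[tr, , drop = FALSE], y[tr], kernel = kernel,
                          cost = C, gamma = g, scale = FALSE,
                          class.weights = cw)
        correct <- correct + sum(predict(fit, X[te, , drop = FALSE]) == y[te])
      }
      acc <- correct / length(y)
      if (acc > best$accuracy) best <- list(C = C, gamma = g, accuracy = acc)
    }
  }
  best
}

#' Train the walking/not-walking window classifier
#'
#' Fits an RBF-kernel SVM to window features (band powers in the configured
#' bands), choosing C and gamma by stratified cross-validated accuracy.
#' Features are standardized with training statistics stored in the model.
#' Rows are sorted canonically before fitting so the result does not depend
#' on training-set order.
#'
#' @param features n x 2 matrix of window band powers (columns in `cfg$bands`
#'   order).
#' @param labels Length-n vector coercible to the levels
#'   `c("not_walking", "walking")` (logical `TRUE` = walking is accepted).
#' @param cfg A [walking_classifier_config()].
#' @return An object of class `walking_model`.
#' @export
train_walking_model <- function(features, labels,
                                cfg = walking_classifier_config()) {
  X <- as.matrix(features)
  y <- walking_factor(labels)
  if (nlevels(droplevels(y)) != 2) {
    stop("training labels must contain both classes", call. = FALSE)
  }
  if (min(table(y)) < cfg$cv_folds) {
    stop("need at least cv_folds examples per class", call. = FALSE)
  }
  ord <- do.call(order, c(list(y), lapply(seq_len(ncol(X)), function(j) X[, j])))
  X <- X[ord, , drop = FALSE]; y <- y[ord]
  center <- colMeans(X)
  scale_ <- apply(X, 2, stats::sd)
  scale_[scale_ == 0] <- 1
  Xs <- sweep(sweep(X, 2, center), 2, scale_, "/")
  best <- svm_grid_cv(Xs, y, cfg$C_grid, cfg$gamma_grid, cfg$cv_folds,
                      cfg$seed)
  cw <- svm_class_weights(y)
  fit <- e1071::svm(Xs, y, kernel = "radial", cost = best$C,
                    gamma = best$gamma, scale = FALSE, class.weights = cw)
  dv1 <- attr(predict(fit, Xs[1, , drop = FALSE], decision.values = TRUE),
              "decision.values")
  structure(
    list(bands = cfg$bands,
         C = best$C, gamma = best$gamma, cv_accuracy = best$accuracy,
         center = center, scale = scale_,
         sv = unname(as.matrix(fit$SV)),
         coefs = as.numeric(fit$coefs),
         rho = as.numeric(fit$rho),
         # positive decision value means this class (libsvm convention:
         # first label in the decision-value column name)
         positive_class = strsplit(colnames(dv1), "/")[[1]][1],
         levels = levels(y),
         n_train = nrow(Xs),
         seed = cfg$seed,
         version = "1.0"),
    class = "walking_model"
  )
}

walking_factor <- function(labels) {
  if (is.logical(labels)) {
    labels <- ifelse(labels, "walking", "not_walking")
  }
  factor(as.character(labels), levels = c("not_walking", "walking"))
}

#' @export
print.walking_model <- function(x, ...) {
  cat(sprintf(
    "<walking_model v%s> RBF SVM: C=%g gamma=%g, CV accuracy %.3f, %d SVs\n",
    x$version, x$C, x$gamma, x$cv_accuracy, nrow(x$sv)))
  invisible(x)
}

# Decision values of a walking_model on raw (unstandardized) features;
# positive = walking.
walking_decision_values <- function(model, features) {
  X <- as.matrix(features)
  Xs <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  sv <- model$sv
  # RBF kernel matrix between SVs and query points
  d2 <- outer(rowSums(sv^2), rowSums(Xs^2), "+") - 2 * tcrossprod(sv, Xs)
  d2[d2 < 0] <- 0
  dv <- drop(crossprod(exp(-model$gamma * d2), model$coefs)) - model$rho
  if (model$positive_class == "walking") dv else -dv
}

#' Predict walking labels for window features
#'
#' A window lying exactly on the decision boundary is labeled not-walking
#' (conservative: avoids spurious strides).
#'
#' @param model A `walking_model`.
#' @param features n x 2 matrix of band powers.
#' @return Logical vector, `TRUE` = walking.
#' @export
predict_walking <- function(model, features) {
  walking_decision_values(model, features) > 0
}

#' Maximal runs of walking windows
#'
#' @param labels Logical per-window walking labels.
#' @param cfg A [windowing_config()] (for episode times).
#' @param t0 Recording start time in seconds (added to episode times).
#' @return data.frame with `episode_id`, `first_window`, `last_window`
#'   (0-based window indices), `start_time`, `end_time` (seconds).
#' @export
episodes_from_labels <- function(labels, cfg = windowing_config(), t0 = 0) {
  if (length(labels) == 0 || !any(labels)) {
    return(data.frame(episode_id = integer(0), first_window = integer(0),
                      last_window = integer(0), start_time = numeric(0),
                      end_time = numeric(0)))
  }
  r <- rle(as.logical(labels))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  fw <- starts[keep] - 1L
  lw <- ends[keep] - 1L
  data.frame(episode_id = seq_along(keep),
             first_window = fw, last_window = lw,
             start_time = t0 + fw * cfg$window_seconds,
             end_time = t0 + (lw + 1L) * cfg$window_seconds)
}

#' Detect walking windows and assemble walking episodes
#'
#' @param rec40 An `accel_recording` at the analysis rate.
#' @param model A trained `walking_model`.
#' @param cfg A [windowing_config()].
#' @return List with `labels` (logical per window), `episodes`
#'   (see [episodes_from_labels()]) and `features` (window band powers).
#' @export
detect_walking <- function(rec40, model, cfg = windowing_config()) {
  if (abs(rec40$sampling_rate_hz - cfg$analysis_rate_hz) >
      1e-6 * cfg$analysis_rate_hz) {
    stop("recording must be at the analysis rate; resample first",
         call. = FALSE)
  }
  feats <- window_band_powers(rec40, cfg, model$bands)
  labels <- predict_walking(model, feats)
  t0 <- if (n_samples(rec40)) rec40$time_s[1] else 0
  list(labels = labels,
       episodes = episodes_from_labels(labels, cfg, t0 = t0),
       features = feats)
}

#' Save a walking model as a versioned JSON container
#'
#' The payload (bands, kernel parameters, support data) is serialized as
#' canonical JSON with an embedded MD5 checksum that [load_walking_model()]
#' verifies.
#'
#' @param model A `walking_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_walking_model <- function(model, path) {
  payload <- list(
    version = model$version,
    bands = lapply(model$bands, as.numeric),
    C = model$C, gamma = model$gamma, cv_accuracy = model$cv_accuracy,
    center = as.numeric(model$center), scale = as.numeric(model$scale),
    sv = model$sv, coefs = model$coefs, rho = model$rho,
    positive_class = model$positive_class, levels = model$levels,
    n_train = model$n_train, seed = model$seed
  )
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA)
  writeLines(jsonlite::toJSON(
    list(checksum = md5_string(js), payload = payload),
    auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' Load a walking model from JSON, verifying its checksum
#'
#' @param path Path written by [save_walking_model()].
#' @return A `walking_model`.
#' @export
load_walking_model <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  js <- jsonlite::toJSON(obj$payload, auto_unbox = TRUE, digits = NA)
  if (!identical(md5_string(js), obj$checksum)) {
    stop("walking model file failed its checksum", call. = FALSE)
  }
  p <- obj$payload
  structure(
    list(bands = lapply(seq_len(nrow(p$bands)), function(i) p$bands[i, ]),
         C = p$C, gamma = p$gamma, cv_accuracy = p$cv_accuracy,
         center = p$center, scale = p$scale,
         sv = matrix(p$sv, ncol = length(p$center)),
         coefs = p$coefs, rho = p$rho,
         positive_class = p$positive_class, levels = p$levels,
         n_train = p$n_train, seed = p$seed, version = p$version),
    class = "walking_model"
  )
}

md5_string <- function(s) {
  f <- tempfile()
  on.exit(unlink(f))
  writeChar(as.character(s), f, eos = NULL)
  unname(tools::md5sum(f))
}
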