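# Band-candidate enumeration, ReliefF, SVM walking classifier, episodes.

test_that("band-candidate grid enumerates all ordered pairs", {
  cand <- enumerate_band_candidates()
  expect_equal(nrow(cand), choose(200, 2))  # 19,900
  expect_true(all(cand$b2 > cand$b1))
  # lexicographic order
  expect_equal(cand$b1[1:3], c(0.1, 0.1, 0.1))
  expect_equal(cand$b2[1:2], c(0.2, 0.3))
  one <- enumerate_band_candidates(0.5, 1)
  expect_equal(nrow(one), 1)
  expect_equal(unlist(one), c(b1 = 0.5, b2 = 1.0))
  expect_error(enumerate_band_candidates(0.3, 20), "divide")
})

test_that("ReliefF matches a hand-worked trace and ranks separability", {
  # 6 points, 1 feature, k = 1: miss-hit margins are 0.7,0.6,0.5,0.5,0.6,0.7
  # so W = 3.6 / (6*1) = 0.6
  x <- matrix(c(0, 0.1, 0.2, 0.8, 0.9, 1.0), ncol = 1)
  y <- c(0, 0, 0, 1, 1, 1)
  expect_equal(relieff_rank(x, y, k_neighbors = 1), 0.6, tolerance = 1e-12)

  set.seed(10)
  n <- 60
  lab <- rep(c(0, 1), each = n / 2)
  informative <- lab + rnorm(n, sd = 0.05)
  noise <- rnorm(n)
  W <- relieff_rank(cbind(informative, noise), lab, k_neighbors = 5)
  expect_gt(W[1], W[2])
  # duplicated columns receive equal weight
  W2 <- relieff_rank(cbind(informative, informative), lab, k_neighbors = 5)
  expect_equal(W2[1], W2[2], tolerance = 1e-12)
  expect_error(relieff_rank(cbind(informative), rep(1, n), 5), "two classes")
})

test_that("ReliefF on the full candidate grid favors the step-frequency band", {
  set.seed(21)
  rate <- 40; m <- 128
  t <- (0:(m - 1)) / rate
  mk_win <- function(walk) {
    g <- if (walk) {
      0.4 * sin(2 * pi * 1.8 * t + runif(1, 0, 2 * pi)) +
        0.15 * sin(2 * pi * 3.6 * t + runif(1, 0, 2 * pi))
    } else 0
    cbind(g + rnorm(m, sd = 0.03), rnorm(m, sd = 0.03), rnorm(m, sd = 0.03))
  }
  wins <- c(lapply(1:30, function(i) mk_win(TRUE)),
            lapply(1:30, function(i) mk_win(FALSE)))
  lab <- rep(c(1, 0), each = 30)
  cand <- enumerate_band_candidates()
  rec <- accel_recording((0:(60 * m - 1)) / rate, do.call(rbind, wins), rate)
  feats <- onoffgait:::window_band_powers(
    rec, bands = lapply(seq_len(nrow(cand)), function(i) unlist(cand[i, ])))
  W <- relieff_rank(feats, lab, k_neighbors = 10)
  step_band <- which(cand$b1 == 1.5 & cand$b2 == 2.5)
  high_band <- which(cand$b1 == 15.0 & cand$b2 == 19.0)
  expect_gt(W[step_band], W[high_band])
})

test_that("SVM training recovers separable clusters and fails on noise labels", {
  set.seed(4)
  n <- 100
  X <- rbind(matrix(rnorm(2 * n, 0, 0.5), n, 2),
             matrix(rnorm(2 * n, 4, 0.5), n, 2))
  y <- rep(c(FALSE, TRUE), each = n)
  cfg <- walking_classifier_config(seed = 9, C_grid = 2^seq(-3, 7, 2),
                                   gamma_grid = 2^seq(-7, 1, 2))
  m <- train_walking_model(X, y, cfg)
  expect_gte(m$cv_accuracy, 0.95)
  expect_true(all(predict_walking(m, X) == y))

  y_shuf <- sample(y)
  m0 <- train_walking_model(X, y_shuf, cfg)
  expect_gte(m0$cv_accuracy, 0.35)
  expect_lte(m0$cv_accuracy, 0.65)

  # length-1 grids are taken as-is
  cfg1 <- walking_classifier_config(C_grid = 8, gamma_grid = 0.25, seed = 1)
  m1 <- train_walking_model(X, y, cfg1)
  expect_equal(m1$C, 8)
  expect_equal(m1$gamma, 0.25)

  expect_error(train_walking_model(X, rep(TRUE, 2 * n), cfg), "both classes")
})

test_that("training is invariant to the order of the training set", {
  set.seed(5)
  n <- 60
  X <- rbind(matrix(rnorm(2 * n, 0, 1), n, 2),
             matrix(rnorm(2 * n, 2.5, 1), n, 2))
  y <- rep(c(FALSE, TRUE), each = n)
  cfg <- walking_classifier_config(seed = 7, C_grid = 2^seq(-1, 5, 2),
                                   gamma_grid = 2^seq(-5, 1, 2))
  m1 <- train_walking_model(X, y, cfg)
  perm <- sample(2 * n)
  m2 <- train_walking_model(X[perm, ], y[perm], cfg)
  expect_equal(m1$C, m2$C)
  expect_equal(m1$gamma, m2$gamma)
  expect_equal(m1$sv, m2$sv)
  expect_equal(m1$coefs, m2$coefs)
  expect_equal(m1$rho, m2$rho)
})

test_that("episodes are maximal runs of walking windows", {
  cfg <- windowing_config()
  ep <- episodes_from_labels(c(TRUE, TRUE, FALSE, TRUE), cfg)
  expect_equal(nrow(ep), 2)
  expect_equal(ep$first_window, c(0, 3))
  expect_equal(ep$last_window, c(1, 3))
  expect_equal(ep$start_time, c(0, 3 * 3.2))
  expect_equal(ep$end_time, c(2 * 3.2, 4 * 3.2))
  expect_equal(nrow(episodes_from_labels(rep(FALSE, 5), cfg)), 0)

  # partition property: episode windows reproduce the walking labels exactly
  set.seed(8)
  lab <- runif(200) < 0.4
  ep <- episodes_from_labels(lab, cfg)
  covered <- unlist(lapply(seq_len(nrow(ep)), function(i) {
    ep$first_window[i]:ep$last_window[i]
  }))
  expect_equal(sort(covered), which(lab) - 1L)
  expect_equal(anyDuplicated(covered), 0L)
  # no two adjacent episodes
  if (nrow(ep) > 1) {
    expect_true(all(ep$first_window[-1] > ep$last_window[-nrow(ep)] + 1L))
  }
})

test_that("simulated walking bouts are recovered as episodes", {
  run <- test_patient_run()
  det <- detect_walking(run$rec40, test_walking_model())
  eps <- det$episodes
  bouts <- run$pat$truth$bouts
  # each bout of >= 10 s overlaps exactly one episode by >= 80% of its windows
  long <- bouts[bouts$end_s - bouts$start_s >= 10, ]
  cfg <- windowing_config()
  hits <- vapply(seq_len(nrow(long)), function(b) {
    ov <- pmin(eps$end_time, long$end_s[b]) -
      pmax(eps$start_time, long$start_s[b])
    any(ov >= 0.8 * (long$end_s[b] - long$start_s[b]))
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("walking models survive a JSON round trip with checksum", {
  m <- test_walking_model()
  path <- file.path(tempdir(), "model.json")
  save_walking_model(m, path)
  m2 <- load_walking_model(path)
  set.seed(13)
  X <- cbind(10^runif(50, -4, 0), 10^runif(50, -4, 0))
  expect_equal(onoffgait:::walking_decision_values(m, X),
               onoffgait:::walking_decision_values(m2, X), tolerance = 1e-9)
  # tampering breaks the checksum
  txt <- readLines(path)
  writeLines(sub("\"rho\":", "\"rho\": 1e9, \"x\":", txt), path)
  expect_error(load_walking_model(path), "checksum")
})
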