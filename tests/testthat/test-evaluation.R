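# Diary alignment, exclusion rules, confusion metrics, validation report.

simple_diary <- function() {
  diary_timeline(c(0, 3600, 7200), c(3600, 7200, 10800),
                 c("ON", "OFF", "ON"))
}

test_that("diaries validate tiling and state vocabulary", {
  d <- simple_diary()
  expect_s3_class(d, "diary_timeline")
  expect_error(diary_timeline(c(0, 100), c(50, 150), c("ON", "OFF")),
               "gaps")
  expect_error(diary_timeline(0, 100, "GOOD"), "states")
  expect_error(diary_timeline(100, 100, "ON"), "end > start")
  # state lookup: start-inclusive, end-exclusive, NA outside
  expect_equal(onoffgait:::diary_state_at(d, c(0, 3599.9, 3600, 10800, -1)),
               c("ON", "ON", "OFF", NA, NA))
  # CSV round trip
  path <- file.path(tempdir(), "diary.csv")
  write_diary(d, path)
  expect_equal(as.data.frame(read_diary(path)), as.data.frame(d))
})

test_that("transition margins are 5 minutes each side, merged when close", {
  d <- simple_diary()
  m <- transition_exclusion_mask(d)
  expect_equal(m$start_s, c(3300, 6900))
  expect_equal(m$end_s, c(3900, 7500))
  # no differing-state transition -> empty mask
  flat <- diary_timeline(c(0, 100), c(100, 200), c("ON", "ON"))
  expect_equal(nrow(transition_exclusion_mask(flat)), 0)
  # two transitions 400 s apart merge into one 1000 s interval
  close <- diary_timeline(c(0, 1000, 1400), c(1000, 1400, 2400),
                          c("ON", "OFF", "ON"))
  mc <- transition_exclusion_mask(close)
  expect_equal(nrow(mc), 1)
  expect_equal(mc$end_s - mc$start_s, 1000)
})

test_that("decision labeling applies every drop reason and the identity", {
  d <- diary_timeline(c(0, 3600, 7200, 9000, 10000),
                      c(3600, 7200, 9000, 10000, 12000),
                      c("ON", "OFF", "INTERMEDIATE", "UNDEFINED", "ON"))
  dec <- data.frame(
    timestamp_s = c(1800, 3500, 3800, 5400, 8100, 9500, 13000, 11500),
    start_s     = c(1700, 3400, 3700, 5300, 8000, 9400, 12900, 11400),
    end_s       = c(1900, 3600, 3900, 5500, 8200, 9600, 13100, 11600),
    stride_count = 12, mean_fluency = 1)
  lab <- label_decisions(dec, d)
  expect_equal(nrow(lab$scored) + nrow(lab$dropped), nrow(dec))
  # decisions wholly inside ON/OFF intervals and clear of margins are scored
  expect_equal(as.character(lab$scored$label), c("ON", "OFF", "ON"))
  expect_equal(lab$scored$timestamp_s, c(1800, 5400, 11500))
  r <- setNames(lab$dropped$reason, lab$dropped$timestamp_s)
  # the episode at 3500 spans the 3600 boundary: straddle takes precedence
  expect_equal(unname(r["3500"]), "straddles transition")
  # the episode at 3800 sits inside OFF but within 300 s of the transition
  expect_equal(unname(r["3800"]), "transition margin")
  expect_equal(unname(r["8100"]), "intermediate")
  expect_equal(unname(r["9500"]), "undefined")
  expect_equal(unname(r["13000"]), "no gold standard")
})

test_that("episodes straddling a diary transition are dropped", {
  d <- diary_timeline(c(0, 1000), c(1000, 2000), c("ON", "OFF"))
  dec <- data.frame(timestamp_s = 1400, start_s = 900, end_s = 1900,
                    stride_count = 20, mean_fluency = 1)
  lab <- label_decisions(dec, d, mask = data.frame(start_s = numeric(0),
                                                   end_s = numeric(0)))
  expect_equal(nrow(lab$scored), 0)
  expect_equal(lab$dropped$reason, "straddles transition")
})

test_that("the minimum-stride filter is inclusive at the bound", {
  dec <- data.frame(stride_count = c(4, 10, 25), mean_fluency = 1:3)
  kept <- filter_min_strides(dec)
  expect_equal(kept$stride_count, c(10, 25))
  expect_equal(nrow(filter_min_strides(dec, min_strides = 26)), 0)
})

test_that("confusion metrics match hand counts with OFF positive", {
  pred <- c(rep("OFF", 9), rep("ON", 1), rep("ON", 18), rep("OFF", 2))
  truth <- c(rep("OFF", 10), rep("ON", 20))
  cm <- confusion_metrics(pred, truth)
  expect_equal(cm$counts, c(TP = 9, FP = 2, TN = 18, FN = 1))
  expect_equal(cm$metrics[["sensitivity"]], 0.9)
  expect_equal(cm$metrics[["specificity"]], 0.9)
  expect_equal(cm$metrics[["ppv"]], 9 / 11)
  expect_equal(cm$metrics[["npv"]], 18 / 19)
  # degenerate: no OFF truth -> sensitivity undefined
  cm0 <- confusion_metrics(c("ON", "ON"), c("ON", "ON"))
  expect_true(is.na(cm0$metrics[["sensitivity"]]))
  expect_equal(cm0$metrics[["specificity"]], 1)
  # perfect prediction
  cmp <- confusion_metrics(truth, truth)
  expect_true(all(cmp$metrics == 1))
  # randomized tables against an independent recount
  set.seed(14)
  for (i in 1:20) {
    n <- sample(10:60, 1)
    tr <- sample(c("ON", "OFF"), n, replace = TRUE)
    pr <- sample(c("ON", "OFF"), n, replace = TRUE)
    cm <- confusion_metrics(pr, tr)
    tp <- sum(pr == "OFF" & tr == "OFF"); fn <- sum(pr == "ON" & tr == "OFF")
    tn <- sum(pr == "ON" & tr == "ON"); fp <- sum(pr == "OFF" & tr == "ON")
    expect_equal(sum(cm$counts), n)
    if (tp + fn > 0) expect_equal(cm$metrics[["sensitivity"]], tp / (tp + fn))
    if (tn + fp > 0) expect_equal(cm$metrics[["specificity"]], tn / (tn + fp))
  }
})

test_that("mean decision interval is the mean gap in minutes", {
  expect_equal(mean_decision_interval_min(c(0, 60, 180)), 1.5)
  expect_true(is.na(mean_decision_interval_min(42)))
  expect_equal(mean_decision_interval_min(c(180, 0, 60)), 1.5)  # order-free
})

test_that("repeated-split validation is perfect on separable patients", {
  set.seed(50)
  mk_patient <- function() {
    n <- 40
    lab <- onoffgait:::motor_factor(rep(c("OFF", "ON"), each = n / 2))
    data.frame(label = lab,
               mean_fluency = c(runif(n / 2, 0.5, 1), runif(n / 2, 2, 3)),
               stride_count = sample(5:40, n, replace = TRUE))
  }
  patients <- list(p1 = mk_patient(), p2 = mk_patient(),
                   p3 = data.frame(label = onoffgait:::motor_factor(rep("ON", 6)),
                                   mean_fluency = runif(6),
                                   stride_count = 20))
  rep_ <- run_validation(patients, n_repeats = 10, base_seed = 99)
  v <- rep_$variants$all_segments
  expect_equal(v$excluded, "p3")  # single-class patient is excluded
  expect_equal(nrow(v$per_patient), 2)
  expect_true(all(v$per_patient$sensitivity_mean == 1))
  expect_true(all(v$per_patient$specificity_sd == 0))
  expect_true(all(v$cohort$mean == 1))
  # determinism
  rep2 <- run_validation(patients, n_repeats = 10, base_seed = 99)
  expect_identical(report_to_list(rep_), report_to_list(rep2))
  # printing renders without error and shows the excluded patient
  out <- capture.output(print(rep_))
  expect_true(any(grepl("p3", out)))
})

test_that("undefined metrics print as a dash", {
  patients <- list(pa = data.frame(
    label = onoffgait:::motor_factor(c(rep("OFF", 12), rep("ON", 12))),
    mean_fluency = c(runif(12, 0, 1), runif(12, 2, 3)),
    stride_count = 3))
  rep_ <- run_validation(patients, n_repeats = 3, base_seed = 5)
  # the stride-filtered variant has no decisions at all -> patient excluded
  expect_equal(rep_$variants$min_strides$excluded, "pa")
  out <- capture.output(print(rep_))
  expect_true(any(grepl("no patient could be validated", out)))
})
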