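test_that("Pan-Tompkins recovers synthetic R peaks and tracks amplitude", {
  p <- synth_params(duration_s = 30, mean_hr_bpm = 60, snr_db = 20, seed = 2)
  s <- generate_record(p)
  ecg <- preprocess_channel(s$record, "ecg")
  r <- detect_r_peaks(ecg, s$record$fs)
  expect_true(abs(length(r) - length(s$truth_r_peaks)) <= 1)
  err <- vapply(r, function(t) min(abs(s$truth_r_peaks - t)), numeric(1))
  expect_lt(max(err), 0.010)

  # adaptive thresholds make detection scale-invariant
  r_scaled <- detect_r_peaks(100 * ecg, s$record$fs)
  expect_equal(r_scaled, r)

  expect_length(detect_r_peaks(numeric(20000), 1000), 0)
  expect_error(detect_r_peaks(rnorm(100), 1000),
               class = "cardiomatch_length_error")
})

test_that("cycle-based classification follows the worked example and conserves counts", {
  m <- classify_detections(c(1.01, 2.00, 2.20), c(1, 2, 3))
  expect_equal(m$tp, 2)
  expect_equal(m$fp, 1)
  expect_equal(m$fn, 1)
  expect_equal(m$detection_labels, c("TP", "TP", "FP"))

  ref <- sort(runif(20, 0, 60))
  m2 <- classify_detections(ref, ref)
  expect_equal(c(m2$tp, m2$fp, m2$fn), c(20, 0, 0))

  m3 <- classify_detections(numeric(0), c(1, 2, 3))
  expect_equal(c(m3$tp, m3$fp, m3$fn), c(0, 0, 3))

  expect_error(classify_detections(c(2, 1), c(1, 2)),
               class = "cardiomatch_precondition_error")
  expect_error(classify_detections(1, 5),
               class = "cardiomatch_precondition_error")
})

test_that("classification agrees with the literal cycle-rule oracle on random instances", {
  set.seed(31)
  for (rep in 1:25) {
    n_ref <- sample(2:12, 1)
    ref <- sort(runif(n_ref, 0, 12))
    det <- sort(runif(sample(0:12, 1), 0, 12))
    m <- classify_detections(det, ref)
    o <- oracle_classify(det, ref)
    expect_equal(m$tp, o$tp)
    expect_equal(m$fp, o$fp)
    expect_equal(m$fn, o$fn)
    # conservation invariants
    expect_equal(m$tp + m$fn, n_ref)
    expect_equal(m$tp + m$fp, length(det))
  }
})

test_that("tolerance-gated classification demotes distant nearest detections", {
  m <- classify_detections(c(1.3, 2.0), c(1, 2, 3), tolerance_s = 0.1)
  expect_equal(c(m$tp, m$fp, m$fn), c(1, 1, 2))
})

test_that("sensitivity and PPV reproduce the published worked examples", {
  # FCG healthy: 1422 of 1434 reference heartbeats -> 99.2%
  expect_equal(round(sensitivity_ppv(list(tp = 1422, fp = 10,
                                          fn = 12))$sensitivity_pct, 1),
               99.2)
  # SCG healthy: 78,212 of 79,937 -> 97.8%
  expect_equal(round(sensitivity_ppv(list(tp = 78212, fp = 0,
                                          fn = 79937 - 78212))$sensitivity_pct, 1),
               97.8)
  m <- sensitivity_ppv(list(tp = 10, fp = 0, fn = 0))
  expect_equal(m$sensitivity_pct, 100)
  expect_equal(m$ppv_pct, 100)
  expect_error(sensitivity_ppv(list(tp = 0, fp = 0, fn = 0)),
               class = "cardiomatch_undefined_metric_error")
})

test_that("IBI pairing drops exactly the intervals touched by errors", {
  # perfect detection: n - 1 pairs
  ref <- seq(1, 10)
  m <- classify_detections(ref, ref)
  p <- pair_ibis_excluding_errors(m)
  expect_length(p$reference_ms, 9)
  expect_equal(p$detected_ms, p$reference_ms)

  # one interior FN at reference beat 5: both adjacent IBIs excluded
  det_fn <- ref[-5]
  m_fn <- classify_detections(det_fn, ref)
  p_fn <- pair_ibis_excluding_errors(m_fn)
  expect_length(p_fn$reference_ms, 7)
  expect_false(any(p_fn$reference_ms > 1500))  # no doubled interval leaks

  # one FP between two TPs: the spanning IBI excluded
  det_fp <- sort(c(ref, 5.4))
  m_fp <- classify_detections(det_fp, ref)
  p_fp <- pair_ibis_excluding_errors(m_fp)
  expect_length(p_fp$reference_ms, 8)

  # size bound: never more than min(n_det, n_ref) - 1 pairs
  set.seed(41)
  for (rep in 1:10) {
    ref_r <- sort(runif(sample(2:10, 1), 0, 10))
    det_r <- sort(runif(sample(1:10, 1), 0, 10))
    pr <- pair_ibis_excluding_errors(classify_detections(det_r, ref_r))
    expect_lte(length(pr$reference_ms),
               max(0, min(length(det_r), length(ref_r)) - 1))
  }
})

test_that("OLS regression recovers exact linear relations with tight CIs", {
  x <- as.numeric(1:100)
  r <- ols_regression_with_ci(x, x)
  expect_equal(r$slope, 1, tolerance = 1e-12)
  expect_equal(r$intercept_ms, 0, tolerance = 1e-9)
  expect_equal(r$r_squared, 1, tolerance = 1e-12)

  r2 <- ols_regression_with_ci(x, 2 * x + 3)
  expect_equal(r2$slope, 2, tolerance = 1e-12)
  expect_equal(r2$intercept_ms, 3, tolerance = 1e-9)

  expect_error(ols_regression_with_ci(rep(1, 10), rnorm(10)),
               class = "cardiomatch_degenerate_error")
  expect_error(ols_regression_with_ci(1:2, 1:2),
               class = "cardiomatch_precondition_error")
})

test_that("Bland-Altman handles degenerate, normal and non-normal differences", {
  x <- rnorm(50, 800, 50)
  ba0 <- bland_altman(x, x)
  expect_equal(ba0$bias_ms, 0)
  expect_equal(c(ba0$loa_low_ms, ba0$loa_high_ms), c(0, 0))

  ba4 <- bland_altman(x, x + 4)
  expect_equal(ba4$bias_ms, 4)
  expect_equal(ba4$loa_high_ms - ba4$loa_low_ms, 0)

  set.seed(51)
  d <- rnorm(2000, 0, 3)
  ban <- bland_altman(x = numeric(2000), y = d)
  expect_equal(ban$method, "parametric")
  expect_equal(ban$loa_high_ms, 1.96 * 3, tolerance = 0.15)
  expect_lt(ban$ci_bias[1], ban$bias_ms)

  # strongly skewed differences take the percentile branch
  dsk <- rexp(2000) - 1
  bask <- bland_altman(numeric(2000), dsk)
  expect_equal(bask$method, "percentile")
  expect_equal(bask$bias_ms, median(dsk))
  expect_equal(bask$loa_low_ms, unname(quantile(dsk, 0.025)),
               tolerance = 1e-12)
  expect_true(bask$loa_low_ms <= bask$bias_ms &
              bask$bias_ms <= bask$loa_high_ms)

  expect_error(bland_altman(1:5, 1:5),
               class = "cardiomatch_sample_size_error")
})
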