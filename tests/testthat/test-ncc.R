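test_that("NCC is exactly +-1 where the signal contains (anti)copies of the template", {
  set.seed(13)
  tpl <- rnorm(120)
  sig <- rnorm(2000)
  sig[501:620] <- 3 * tpl + 2          # affine copy at lag 500 (0-based)
  sig[1201:1320] <- -tpl               # negated copy at lag 1200
  ncc <- normalized_cross_correlation(sig, tpl)
  expect_length(ncc$values, 2000 - 120 + 1)
  expect_equal(ncc$values[501], 1, tolerance = 1e-12)
  expect_equal(ncc$values[1201], -1, tolerance = 1e-12)
  expect_lte(max(abs(ncc$values)), 1 + 1e-9)
})

test_that("fast NCC matches the brute-force Pearson loop at every lag", {
  set.seed(17)
  for (rep in 1:5) {
    sig <- rnorm(2000)
    tpl <- rnorm(120)
    fast <- normalized_cross_correlation(sig, tpl)$values
    expect_lt(max(abs(fast - ncc_brute_force(sig, tpl))), 1e-10)
  }
})

test_that("degenerate templates and zero-variance windows are handled", {
  expect_error(normalized_cross_correlation(rnorm(100), rep(2, 10)),
               class = "cardiomatch_degenerate_template_error")
  sig <- c(rep(0, 50), rnorm(50))
  ncc <- normalized_cross_correlation(sig, rnorm(10))
  expect_equal(ncc$values[1:20], numeric(20))  # flat windows -> 0, not NaN
  expect_error(normalized_cross_correlation(rnorm(5), rnorm(10)),
               class = "cardiomatch_length_error")
})

test_that("NCC peak pruning keeps the higher of two close peaks", {
  fs <- 100
  # peaks 0.3 s apart (30 samples), heights 0.9 / 0.8, prominences > 0.5
  v <- numeric(200)
  v[49:51] <- c(0.45, 0.9, 0.45)
  v[79:81] <- c(0.4, 0.8, 0.4)
  ncc <- structure(list(values = v, fs = fs, template_length = 10),
                   class = "ncc_series")
  lags <- detect_ncc_peaks(ncc)
  expect_length(lags, 1)
  expect_equal(lags, 49)               # 0-based lag of the 0.9 peak

  # sub-threshold prominence everywhere -> empty
  ncc2 <- structure(list(values = 0.2 * sin(seq(0, 20, by = 0.1)), fs = fs,
                         template_length = 10),
                    class = "ncc_series")
  expect_length(detect_ncc_peaks(ncc2), 0)
})

test_that("beat reconstruction applies the anchor convention", {
  tpl <- structure(list(waveform = rnorm(701), fs = 1000,
                        anchor_offset_samples = 200L,
                        source_window_index = 0L, score = 1,
                        scores = NULL, beat_time_s = NA_real_),
                   class = "heartbeat_template")
  beats <- beats_from_ncc_peaks(4800L, tpl, fs = 1000)
  expect_equal(beats$beat_times_s, 5.000)
  expect_length(beats_from_ncc_peaks(integer(0), tpl, 1000)$beat_times_s, 0)
})

test_that("IBI computation is the scaled first difference of beat times", {
  expect_equal(compute_ibis(c(1.0, 1.8, 2.9))$ibis_ms, c(800, 1100))
  expect_length(compute_ibis(2.5)$ibis_ms, 0)
  expect_equal(compute_ibis(seq(0, by = 0.75, length.out = 20))$ibis_ms,
               rep(750, 19))
})

test_that("detection is invariant to positive rescaling and equivariant to shifts", {
  p <- synth_params(duration_s = 40, snr_db = 20, seed = 4)
  s <- generate_record(p)
  det <- detect_heartbeats(s$record, "scg")

  rec_scaled <- s$record
  rec_scaled$samples$scg <- 7.3 * rec_scaled$samples$scg
  det_scaled <- detect_heartbeats(rec_scaled, "scg")
  expect_equal(det_scaled$beats$beat_times_s, det$beats$beat_times_s)

  # exact shift equivariance at the matching layer: delaying the signal by
  # d samples shifts every NCC peak, hence every beat, by exactly d/fs
  d <- 256L
  fs <- s$record$fs
  x <- preprocess_channel(s$record, "scg")
  tpl <- det$template
  lags1 <- detect_ncc_peaks(normalized_cross_correlation(x, tpl$waveform,
                                                         fs = fs))
  x_shift <- c(numeric(d), x)
  lags2 <- detect_ncc_peaks(normalized_cross_correlation(x_shift,
                                                         tpl$waveform,
                                                         fs = fs))
  # ignore any peak born in the splice region at the start
  lags2 <- lags2[lags2 >= d + length(tpl$waveform)]
  keep1 <- lags1[lags1 + d >= d + length(tpl$waveform)]
  expect_equal(lags2, keep1 + d)
  b1 <- beats_from_ncc_peaks(keep1, tpl, fs)$beat_times_s
  b2 <- beats_from_ncc_peaks(lags2, tpl, fs)$beat_times_s
  expect_equal(b2, b1 + d / fs, tolerance = 1e-12)
})

test_that("returned beats always honour the 0.5 s distance floor", {
  # adversarial: short-IBI pathological record with artifact bursts
  p <- synth_params(duration_s = 60, mean_hr_bpm = 100, snr_db = 10,
                    preset = "pathological", seed = 6)
  s <- generate_record(p)
  s <- inject_spurious_bursts(s, n = 8, magnitude = 2, seed = 7,
                              protect_s = c(0, 10))
  det <- detect_heartbeats(s$record, "scg")
  expect_true(all(diff(det$beats$beat_times_s) >= 0.5 - 1e-9))
})

test_that("whole-pipeline errors propagate with their classes", {
  rec0 <- waveform_record(list(scg = numeric(30000)), 1000, c(scg = "scg"))
  expect_error(detect_heartbeats(rec0),
               class = "cardiomatch_no_reliable_window_error")
  rec_short <- waveform_record(list(scg = rnorm(2000)), 1000,
                               c(scg = "scg"))
  expect_error(detect_heartbeats(rec_short),
               class = "cardiomatch_length_error")
  rec_ecg <- waveform_record(list(e = rnorm(30000)), 1000, c(e = "ecg"))
  expect_error(detect_heartbeats(rec_ecg),
               class = "cardiomatch_config_error")
})
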