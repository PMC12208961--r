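# short Gaussian-windowed 15 Hz burst, the simplest heartbeat-like packet
burst_at <- function(t, center, width = 0.1, freq = 15) {
  exp(-0.5 * ((t - center) / (width / 6))^2) * cos(2 * pi * freq * (t - center))
}

test_that("envelope of a stationary passband tone is flat at 1", {
  fs <- 1000
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  env <- compute_envelope(sin(2 * pi * 15 * t), fs)
  inner <- env$values[(2 * fs):(8 * fs)]
  expect_gte(min(inner), 0.9)
  expect_equal(max(env$values), 1)
  expect_true(all(env$values >= 0))
})

test_that("flat segments are rejected as degenerate", {
  expect_error(compute_envelope(numeric(5000), 1000),
               class = "cardiomatch_degenerate_segment_error")
})

test_that("a single symmetric burst yields an envelope maximum at its centre", {
  fs <- 1000
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  env <- compute_envelope(burst_at(t, 5), fs)
  peak_t <- (which.max(env$values) - 1) / fs
  expect_lt(abs(peak_t - 5), 0.020)
})

test_that("envelope peak picking honours the 0.25 prominence floor", {
  fs <- 1000
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  # two bumps with envelope prominences ~1.0 and ~0.1 (amp^4 scaling:
  # 0.56^4 ~ 0.1)
  seg <- burst_at(t, 3) + 0.56 * burst_at(t, 7)
  env <- compute_envelope(seg, fs)
  pk <- detect_envelope_peaks(env)
  expect_length(pk, 1)
  expect_lt(abs(pk - 3), 0.05)

  # 8 periodic bursts in 10 s
  seg8 <- Reduce(`+`, lapply(seq(1, 9.4, by = 1.2), function(ctr)
    burst_at(t, ctr)))
  pk8 <- detect_envelope_peaks(compute_envelope(seg8, fs))
  expect_length(pk8, 8)

  env_flat <- structure(list(values = numeric(1000), fs = fs,
                             window_start_s = 0),
                        class = "envelope_series")
  expect_length(detect_envelope_peaks(env_flat), 0)
})

test_that("window reliability implements the beat-count and MAD gates", {
  r3 <- assess_window_reliability(c(1, 2, 3))
  expect_false(r3$reliable)
  expect_identical(r3$reasons, "too_few_beats")

  r10 <- assess_window_reliability(seq(0.5, 9.5, by = 1))
  expect_true(r10$reliable)
  expect_equal(r10$mad_ms, 0)

  # IBIs {400, 400, 1500, 1500, 400} ms: mean 840, MAD 528 >= 335
  beats <- cumsum(c(0.5, 0.4, 0.4, 1.5, 1.5, 0.4))
  r6 <- assess_window_reliability(beats)
  expect_equal(r6$mad_ms, 528)
  expect_false(r6$reliable)
  expect_identical(r6$reasons, "high_mad")
})

test_that("candidate segmentation drops edge beats and anchors at the peak sample", {
  fs <- 1000
  set.seed(5)
  seg <- rnorm(10 * fs)
  # peak at 0.1 s lacks its 200 ms pre-interval and must be dropped
  cands <- segment_candidate_beats(seg, fs, c(0.1, 5.0, 7.0))
  expect_length(cands$candidates, 2)
  expect_equal(cands$beat_times_s, c(5.0, 7.0))
  expect_equal(cands$anchor_offset_samples, 200)
  expect_length(cands$candidates[[1]], 701)
  # candidate covers samples 4800..5500 (0-based); anchor sample = peak
  expect_equal(cands$candidates[[1]], seg[4801:5501])
  expect_equal(cands$candidates[[1]][201], seg[5001])

  cands5 <- segment_candidate_beats(seg, fs, seq(1, 9, by = 2))
  expect_length(cands5$candidates, 5)

  expect_error(segment_candidate_beats(seg, fs, c(0.1, 9.95)),
               class = "cardiomatch_insufficient_candidates_error")
})

test_that("template scoring picks the most consistently similar beat", {
  fs <- 1000
  t <- seq(0, 0.7, by = 1 / fs)
  a <- burst_at(t, 0.2)
  set.seed(9)
  noise <- rnorm(length(t))
  # near-identical heartbeat-like candidates vs one noise candidate (exact
  # duplicates would hand the noise candidate a zero-SD correlation set and
  # an unbounded score under the SD-floor rule)
  reps <- lapply(1:5, function(i) a + 0.01 * rnorm(length(a)))
  cands <- structure(list(candidates = c(reps, list(noise)),
                          anchor_offset_samples = 200,
                          beat_times_s = 1:6),
                     class = "template_candidates")
  tpl <- score_and_select_template(cands, fs = fs)
  expect_lt(tpl$beat_time_s, 6)      # a burst-like beat, not the noise
  expect_gt(cor(tpl$waveform, a), 0.99)

  # all-identical candidates: SD floor applies, earliest beat wins
  cands_id <- structure(list(candidates = list(a, a, a, a),
                             anchor_offset_samples = 200,
                             beat_times_s = 1:4),
                        class = "template_candidates")
  expect_equal(score_and_select_template(cands_id, fs = fs)$beat_time_s, 1)

  cands_bad <- structure(list(candidates = list(a, a[-1]),
                              anchor_offset_samples = 200,
                              beat_times_s = 1:2),
                         class = "template_candidates")
  expect_error(score_and_select_template(cands_bad),
               class = "cardiomatch_precondition_error")
  cands_flat <- structure(list(candidates = list(a, numeric(length(a))),
                               anchor_offset_samples = 200,
                               beat_times_s = 1:2),
                          class = "template_candidates")
  expect_error(score_and_select_template(cands_flat),
               class = "cardiomatch_degenerate_candidate_error")
})

test_that("template scores agree with the brute-force all-vs-all oracle", {
  set.seed(21)
  for (rep in 1:5) {
    n <- sample(3:12, 1)
    cands <- lapply(seq_len(n), function(i) rnorm(80))
    cs <- structure(list(candidates = cands, anchor_offset_samples = 10,
                         beat_times_s = seq_len(n)),
                    class = "template_candidates")
    tpl <- score_and_select_template(cs)
    expect_equal(tpl$scores, oracle_template_scores(cands),
                 tolerance = 1e-12)
    expect_equal(tpl$score, max(oracle_template_scores(cands)),
                 tolerance = 1e-12)
  }
})

test_that("window scanning skips unreliable windows and errors when none qualify", {
  fs <- 1000
  t10 <- seq(0, 10 - 1 / fs, by = 1 / fs)
  # window 0: only 3 bursts; window 1: 8 clean bursts
  w0 <- Reduce(`+`, lapply(c(2, 5, 8), function(ctr) burst_at(t10, ctr)))
  w1 <- Reduce(`+`, lapply(seq(1, 9.4, by = 1.2), function(ctr)
    burst_at(t10, ctr)))
  tpl <- auto_select_template(c(w0, w1), fs)
  expect_equal(tpl$source_window_index, 1)
  expect_false(tpl$windows_examined[[1]]$reliable)
  expect_true(tpl$windows_examined[[2]]$reliable)

  expect_error(auto_select_template(numeric(20000), fs),
               class = "cardiomatch_no_reliable_window_error")
  expect_error(auto_select_template(rnorm(100), fs),
               class = "cardiomatch_length_error")
})

test_that("template export and import round-trip", {
  fs <- 500
  t <- seq(0, 0.7, by = 1 / fs)
  tpl <- structure(list(waveform = burst_at(t, 0.2), fs = fs,
                        anchor_offset_samples = 100L,
                        source_window_index = 2L, score = 12.5,
                        scores = NULL, beat_time_s = 21),
                   class = "heartbeat_template")
  path <- withr::local_tempfile(fileext = ".csv")
  write_template_csv(path, tpl)
  back <- read_template_csv(path)
  expect_equal(back$waveform, tpl$waveform, tolerance = 1e-12)
  expect_equal(back$anchor_offset_samples, 100L)
  expect_equal(back$fs, fs)
})
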