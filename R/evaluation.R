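# Statistical assessment of detected beats against an ECG (or ground-truth)
# reference: cycle-based TP/FP/FN classification, sensitivity/PPV, IBI
# pairing with error exclusion, regression and Bland-Altman agreement.

# run `expr` under a fixed RNG seed without disturbing the caller's RNG
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Classify detections against reference beats (TP / FP / FN)
#'
#' Reference beats partition time into cardiac cycles: cycle `i` is the
#' half-open interval between the midpoints flanking reference beat `i`
#' (the first and last cycles extend to the record bounds). Each detection
#' is assigned to the cycle containing it. Within a cycle, the detection
#' nearest the reference beat is the true positive; any further detections
#' in the same cycle are false positives, and cycles containing no detection
#' are false negatives.
#'
#' @param detected sorted detected beat times (seconds).
#' @param reference sorted reference beat times (seconds), length >= 2.
#' @param tolerance_s optional absolute tolerance: if set, the nearest
#'   detection in a cycle only counts as TP when it lies within
#'   `tolerance_s` of the reference beat (used when scoring against
#'   synthetic ground truth).
#' @return a `beat_match`: list with counts `tp`, `fp`, `fn`,
#'   `detection_labels` (`"TP"`/`"FP"` per detection) and `cycle_match`
#'   (per reference beat, the index of its matched detection or `NA`).
#' @export
classify_detections <- function(detected, reference, tolerance_s = NULL) {
  if (is.unsorted(detected, strictly = FALSE) ||
      is.unsorted(reference, strictly = FALSE))
    cm_error("beat times must be sorted", "cardiomatch_precondition_error")
  n_ref <- length(reference)
  if (n_ref < 2L)
    cm_error("need at least 2 reference beats",
             "cardiomatch_precondition_error")
  mids <- (reference[-n_ref] + reference[-1]) / 2
  cycle_of <- findInterval(detected, mids) + 1L
  labels <- rep("FP", length(detected))
  cycle_match <- rep(NA_integer_, n_ref)
  for (i in seq_len(n_ref)) {
    in_cycle <- which(cycle_of == i)
    if (!length(in_cycle)) next
    best <- in_cycle[which.min(abs(detected[in_cycle] - reference[i]))]
    if (!is.null(tolerance_s) &&
        abs(detected[best] - reference[i]) > tolerance_s) next
    labels[best] <- "TP"
    cycle_match[i] <- best
  }
  tp <- sum(labels == "TP")
  fp <- sum(labels == "FP")
  fn <- sum(is.na(cycle_match))
  stopifnot(tp + fn == n_ref, tp + fp == length(detected))
  structure(list(tp = tp, fp = fp, fn = fn, detection_labels = labels,
                 cycle_match = cycle_match, detected = detected,
                 reference = reference),
            class = "beat_match")
}

#' Sensitivity and positive predictive value
#'
#' `sensitivity = 100 * TP / (TP + FN)`, `PPV = 100 * TP / (TP + FP)`, as
#' percentages. Raw values are returned; the print method reports one
#' decimal, matching the usual reporting convention.
#'
#' @param match a `beat_match` from [classify_detections()], or a list with
#'   `tp`, `fp`, `fn` counts.
#' @return a `detection_metrics`: list with `tp`, `fp`, `fn`,
#'   `sensitivity_pct`, `ppv_pct`.
#' @export
sensitivity_ppv <- function(match) {
  tp <- match$tp; fp <- match$fp; fn <- match$fn
  if (tp + fn == 0 || tp + fp == 0)
    cm_error("sensitivity/PPV undefined: zero denominator",
             "cardiomatch_undefined_metric_error")
  structure(list(tp = tp, fp = fp, fn = fn,
                 sensitivity_pct = 100 * tp / (tp + fn),
                 ppv_pct = 100 * tp / (tp + fp)),
            class = "detection_metrics")
}

#' @export
print.detection_metrics <- function(x, ...) {
  cat(sprintf("TP %d  FP %d  FN %d  |  sensitivity %.1f%%  PPV %.1f%%\n",
              x$tp, x$fp, x$fn, x$sensitivity_pct, x$ppv_pct))
  invisible(x)
}

#' Pair detected and reference IBIs, excluding detection errors
#'
#' The inter-beat interval between reference beats `i` and `i + 1` is
#' retained only when both bounding beats were matched (TP) and no false
#' positive falls between their matched detections; IBIs touched by a
#' missed or spurious beat are excluded from the agreement analyses.
#'
#' @param match a `beat_match` from [classify_detections()].
#' @return list with equal-length numeric vectors `reference_ms` and
#'   `detected_ms`.
#' @export
pair_ibis_excluding_errors <- function(match) {
  stopifnot(inherits(match, "beat_match"))
  ref <- match$reference; det <- match$detected
  cm <- match$cycle_match
  fp_times <- det[match$detection_labels == "FP"]
  ref_ms <- numeric(0); det_ms <- numeric(0)
  for (i in seq_len(length(ref) - 1L)) {
    a <- cm[i]; b <- cm[i + 1L]
    if (is.na(a) || is.na(b)) next
    if (length(fp_times) && any(fp_times > det[a] & fp_times < det[b])) next
    ref_ms <- c(ref_ms, (ref[i + 1L] - ref[i]) * 1000)
    det_ms <- c(det_ms, (det[b] - det[a]) * 1000)
  }
  list(reference_ms = ref_ms, detected_ms = det_ms)
}

#' Ordinary least squares regression with confidence intervals
#'
#' Regresses detected on reference IBIs. Slope and intercept 95% CIs come
#' from the t distribution; the CI for `R^2` is obtained by Fisher
#' z-transforming the Pearson correlation and squaring the transformed
#' bounds.
#'
#' @param x reference IBIs (ms), non-constant, length >= 3.
#' @param y detected IBIs (ms), same length.
#' @return a `regression_result`: list with `slope`, `intercept_ms`,
#'   `r_squared`, `ci_slope`, `ci_intercept_ms`, `ci_r_squared`, `n`.
#' @export
ols_regression_with_ci <- function(x, y) {
  n <- length(x)
  if (n < 3L || length(y) != n)
    cm_error("need equal-length x, y with n >= 3",
             "cardiomatch_precondition_error")
  if (var(x) == 0)
    cm_error("constant reference IBIs: regression undefined",
             "cardiomatch_degenerate_error")
  fit <- lm(y ~ x)
  ci <- suppressWarnings(confint(fit, level = 0.95))
  r <- cor(x, y)
  z <- atanh(min(max(r, -1 + 1e-15), 1 - 1e-15))
  zse <- 1 / sqrt(n - 3)
  r_ci <- tanh(z + c(-1, 1) * qnorm(0.975) * zse)
  r2_ci <- sort(r_ci^2)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept_ms = unname(coef(fit)[1]),
                 r_squared = r^2,
                 ci_slope = unname(ci[2, ]),
                 ci_intercept_ms = unname(ci[1, ]),
                 ci_r_squared = r2_ci, n = n),
            class = "regression_result")
}

#' Bland-Altman agreement analysis with non-normal fallback
#'
#' Computes paired differences `d = y - x` and tests them for normality
#' (Shapiro-Wilk at alpha 0.05; for n > 5000 a deterministic stride
#' subsample of 5000 is tested). If normal, the bias is `mean(d)` and the
#' limits of agreement `mean(d) +- 1.96 sd(d)`, with standard Bland-Altman
#' confidence intervals. Otherwise the bias is the median and the limits are
#' the 2.5th and 97.5th percentiles (linear-interpolation quantiles), with
#' bootstrap confidence intervals (2000 resamples, seeded).
#'
#' @param x reference measurements (e.g. ECG IBIs, ms).
#' @param y test measurements (e.g. detected IBIs, ms), same length >= 10.
#' @param boot_seed seed for the bootstrap in the percentile branch.
#' @return a `bland_altman_result`: list with `bias_ms`, `loa_low_ms`,
#'   `loa_high_ms`, `ci_bias`, `ci_loa_low`, `ci_loa_high`, `method`
#'   (`"parametric"` or `"percentile"`), `normality_p`, `n`.
#' @export
bland_altman <- function(x, y, boot_seed = 20260924L) {
  n <- length(x)
  if (n < 10L || length(y) != n)
    cm_error("need equal-length x, y with n >= 10",
             "cardiomatch_sample_size_error")
  d <- y - x
  d_test <- if (n > 5000) d[round(seq(1, n, length.out = 5000))] else d
  norm_p <- if (var(d_test) == 0) 0 else shapiro.test(d_test)$p.value
  if (norm_p >= 0.05) {
    bias <- mean(d); s <- sd(d)
    loa <- bias + c(-1, 1) * 1.96 * s
    tq <- qt(0.975, n - 1)
    ci_bias <- bias + c(-1, 1) * tq * s / sqrt(n)
    se_loa <- s * sqrt(1 / n + 1.96^2 / (2 * (n - 1)))
    out <- list(bias_ms = bias, loa_low_ms = loa[1], loa_high_ms = loa[2],
                ci_bias = ci_bias,
                ci_loa_low = loa[1] + c(-1, 1) * tq * se_loa,
                ci_loa_high = loa[2] + c(-1, 1) * tq * se_loa,
                method = "parametric", normality_p = norm_p, n = n)
  } else {
    bias <- median(d)
    loa <- unname(quantile(d, c(0.025, 0.975), type = 7))
    boot <- with_local_seed(boot_seed, {
      vapply(seq_len(2000), function(i) {
        db <- d[sample.int(n, n, replace = TRUE)]
        c(median(db), quantile(db, c(0.025, 0.975), type = 7))
      }, numeric(3))
    })
    ci <- apply(boot, 1, quantile, probs = c(0.025, 0.975), type = 7)
    out <- list(bias_ms = bias, loa_low_ms = loa[1], loa_high_ms = loa[2],
                ci_bias = unname(ci[, 1]), ci_loa_low = unname(ci[, 2]),
                ci_loa_high = unname(ci[, 3]),
                method = "percentile", normality_p = norm_p, n = n)
  }
  structure(out, class = "bland_altman_result")
}

#' @export
print.bland_altman_result <- function(x, ...) {
  cat(sprintf("Bland-Altman (%s, n=%d): bias %.1f ms, LoA [%.1f; %.1f] ms\n",
              x$method, x$n, x$bias_ms, x$loa_low_ms, x$loa_high_ms))
  invisible(x)
}

#' Full agreement evaluation of detected beats against a reference
#'
#' Convenience wrapper running [classify_detections()], [sensitivity_ppv()],
#' [pair_ibis_excluding_errors()], and -- when enough IBI pairs survive --
#' [ols_regression_with_ci()] and [bland_altman()].
#'
#' @param detected sorted detected beat times (seconds).
#' @param reference sorted reference beat times (seconds).
#' @param boot_seed passed to [bland_altman()].
#' @param tolerance_s passed to [classify_detections()].
#' @return an `agreement_stats`: list with `match`, `metrics`, `ibi_pairs`,
#'   `regression` (or `NULL`), `bland_altman` (or `NULL`).
#' @export
evaluate_agreement <- function(detected, reference, boot_seed = 20260924L,
                               tolerance_s = NULL) {
  match <- classify_detections(detected, reference,
                               tolerance_s = tolerance_s)
  metrics <- sensitivity_ppv(match)
  pairs <- pair_ibis_excluding_errors(match)
  reg <- if (length(pairs$reference_ms) >= 3 && var(pairs$reference_ms) > 0)
    ols_regression_with_ci(pairs$reference_ms, pairs$detected_ms) else NULL
  ba <- if (length(pairs$reference_ms) >= 10)
    bland_altman(pairs$reference_ms, pairs$detected_ms,
                 boot_seed = boot_seed) else NULL
  structure(list(match = match, metrics = metrics, ibi_pairs = pairs,
                 regression = reg, bland_altman = ba),
            class = "agreement_stats")
}

#' @export
print.agreement_stats <- function(x, ...) {
  print(x$metrics)
  if (!is.null(x$regression))
    cat(sprintf("regression: slope %.3f, intercept %.1f ms, R^2 %.4f (n=%d)\n",
                x$regression$slope, x$regression$intercept_ms,
                x$regression$r_squared, x$regression$n))
  if (!is.null(x$bland_altman)) print(x$bland_altman)
  invisible(x)
}
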