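# Independent reference implementations used as oracles. These deliberately
# use the slowest, most literal formulation of each rule so they share no
# code path with the package.

# Gabor-atom heartbeat kernel, written out directly from the generator's
# documented model (systolic/diastolic atoms; width = +-3 sigma support)
oracle_kernel <- function(t, spec) {
  out <- numeric(length(t))
  for (a in spec) {
    sigma <- a$width_ms / 1000 / 6
    tt <- t - a$latency_ms / 1000
    out <- out + a$amp * exp(-0.5 * (tt / sigma)^2) * cos(2 * pi * a$freq_hz * tt)
  }
  out
}

# brute-force all-vs-all template scoring: explicit double loop of Pearson
# correlations, score = mean / sd over the n-1 off-diagonal values
oracle_template_scores <- function(cands) {
  n <- length(cands)
  vapply(seq_len(n), function(i) {
    r <- numeric(0)
    for (j in seq_len(n)) if (j != i) r <- c(r, cor(cands[[i]], cands[[j]]))
    mean(r) / max(sd(r), 1e-12)
  }, numeric(1))
}

# literal cycle-rule classifier: build each cycle's interval explicitly,
# scan detections, nearest one is TP
oracle_classify <- function(detected, reference) {
  n <- length(reference)
  mids <- (reference[-n] + reference[-1]) / 2
  lo <- c(-Inf, mids)
  hi <- c(mids, Inf)
  tp <- 0L; fp <- 0L; fn <- 0L
  for (i in seq_len(n)) {
    inside <- which(detected >= lo[i] & detected < hi[i])
    if (!length(inside)) { fn <- fn + 1L; next }
    tp <- tp + 1L
    fp <- fp + length(inside) - 1L
  }
  list(tp = tp, fp = fp, fn = fn)
}

# beats of a synthetic record for which a full template placement fits
# inside the record (the detector cannot report beats whose template
# support overruns either end)
reachable_truth <- function(synth, det) {
  fs <- det$fs
  L <- length(det$template$waveform)
  a <- det$template$anchor_offset_samples
  n <- round(length(synth$record$samples[[1]]) * fs / synth$record$fs)
  tb <- synth$truth_beats
  tb[tb >= a / fs & tb <= (n - L + a) / fs]
}
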