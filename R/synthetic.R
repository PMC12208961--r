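#' Parameters for the synthetic cardiomechanical record generator
#'
#' Defines the study conditions emulated by [generate_record()]:
#' quasi-periodic heartbeat wave packets in the 7--30 Hz band riding on
#' respiratory modulation and broadband noise, paired with an ECG channel
#' whose R peaks lead the mechanical beats by a fixed electromechanical
#' delay.
#'
#' @param duration_s record length in seconds.
#' @param fs sampling rate in Hz (512 by default, a device rate in common
#'   use for wearable inertial sensors).
#' @param mean_hr_bpm mean heart rate.
#' @param ibi_sd_ms stationary SD of the AR(1) inter-beat-interval noise;
#'   `NULL` (default) scales it to 5% of the mean IBI, reflecting the usual
#'   cycle-length dependence of heart-rate variability.
#' @param rsa_depth_ms,resp_rate_hz respiratory sinus arrhythmia: IBI
#'   modulation depth (ms) at the respiration rate (Hz).
#' @param kernel_spec list of Gabor atoms (fields `freq_hz`, `width_ms`,
#'   `amp`, `latency_ms`) composing one heartbeat; the default is a systolic
#'   complex (15 Hz, 120 ms) plus a diastolic complex (12 Hz, 80 ms) at
#'   +320 ms with 40% amplitude. The systolic peak is the beat anchor.
#' @param amp_mod_depth respiratory amplitude modulation of the mechanical
#'   channel, in `[0, 1)`.
#' @param snr_db in-band (7--30 Hz) signal-to-noise ratio of the mechanical
#'   channel, in dB; noise is an equal-power mix of white and pink.
#' @param morph_jitter `NULL` for stable morphology, or a list with `amp`
#'   (relative amplitude perturbation, e.g. 0.4 for +-40%) and `latency_ms`
#'   (uniform latency perturbation) applied independently per beat and atom
#'   -- the "pathological" mode emulating unstable beat morphologies.
#' @param n_artifact_bursts broadband artifact bursts to inject after
#'   generation (see [inject_spurious_bursts()]).
#' @param emd_ms electromechanical delay from the ECG R peak to the
#'   mechanical beat anchor.
#' @param with_fcg also synthesize a raw-FCG-like channel (cardiac kernels
#'   riding on a large 0.3 Hz respiration baseline).
#' @param seed RNG seed; generation is fully deterministic given the seed.
#' @param preset `"healthy"` (defaults as given) or `"pathological"`
#'   (morphology jitter +-40% amplitude / +-20 ms latency, IBI SD 60 ms,
#'   SNR 10 dB).
#' @return a `synth_params` list.
#' @export
synth_params <- function(duration_s = 120, fs = 512, mean_hr_bpm = 70,
                         ibi_sd_ms = NULL, rsa_depth_ms = 30,
                         resp_rate_hz = 0.25,
                         kernel_spec = list(
                           list(freq_hz = 15, width_ms = 120, amp = 1,
                                latency_ms = 0),
                           list(freq_hz = 12, width_ms = 80, amp = 0.4,
                                latency_ms = 320)),
                         amp_mod_depth = 0.15, snr_db = 15,
                         morph_jitter = NULL, n_artifact_bursts = 0,
                         emd_ms = 40, with_fcg = FALSE, seed = 1L,
                         preset = c("healthy", "pathological")) {
  preset <- match.arg(preset)
  if (preset == "pathological") {
    if (is.null(morph_jitter))
      morph_jitter <- list(amp = 0.4, latency_ms = 20)
    if (missing(ibi_sd_ms)) ibi_sd_ms <- 60
    if (missing(snr_db)) snr_db <- 10
  }
  if (is.null(ibi_sd_ms)) ibi_sd_ms <- 0.05 * 60000 / mean_hr_bpm
  p <- list(duration_s = duration_s, fs = fs, mean_hr_bpm = mean_hr_bpm,
            ibi_sd_ms = ibi_sd_ms, rsa_depth_ms = rsa_depth_ms,
            resp_rate_hz = resp_rate_hz, kernel_spec = kernel_spec,
            amp_mod_depth = amp_mod_depth, snr_db = snr_db,
            morph_jitter = morph_jitter,
            n_artifact_bursts = n_artifact_bursts, emd_ms = emd_ms,
            with_fcg = with_fcg, seed = as.integer(seed), preset = preset)
  fmax <- max(vapply(kernel_spec, `[[`, numeric(1), "freq_hz"))
  if (fs <= 2 * fmax)
    cm_error("fs must exceed twice the highest kernel frequency",
             "cardiomatch_parameter_error")
  kernel_end <- max(vapply(kernel_spec, function(a)
    a$latency_ms + a$width_ms / 2, numeric(1)))
  if (60000 / mean_hr_bpm <= kernel_end)
    cm_error("mean IBI must exceed the kernel duration",
             "cardiomatch_parameter_error")
  if (!is.finite(snr_db))
    cm_error("snr_db must be finite", "cardiomatch_parameter_error")
  if (amp_mod_depth < 0 || amp_mod_depth >= 1)
    cm_error("amp_mod_depth must lie in [0, 1)",
             "cardiomatch_parameter_error")
  structure(p, class = "synth_params")
}

#' Generate a seeded inter-beat-interval sequence
#'
#' `IBI_i = 60000 / mean_hr + AR(1) noise + RSA`, where the AR(1) process
#' has coefficient 0.4 with innovation SD chosen so its stationary SD equals
#' `ibi_sd_ms`, and the respiratory sinus arrhythmia term is
#' `rsa_depth_ms * sin(2 pi resp_rate_hz t_i)` evaluated at each beat time.
#' IBIs are clamped at 300 ms from below; parameters forcing clamping of
#' more than 5% of beats are rejected.
#'
#' @param params a [synth_params()].
#' @param n_beats number of IBIs to generate.
#' @param seed RNG seed; defaults to `params$seed`.
#' @return numeric vector of `n_beats` IBIs in milliseconds.
#' @export
synth_ibi_sequence <- function(params, n_beats, seed = params$seed) {
  stopifnot(inherits(params, "synth_params"), n_beats >= 1)
  phi <- 0.4
  base <- 60000 / params$mean_hr_bpm
  with_local_seed(seed, {
    innov_sd <- params$ibi_sd_ms * sqrt(1 - phi^2)
    ar <- numeric(n_beats)
    ar[1] <- rnorm(1, 0, params$ibi_sd_ms)
    if (n_beats > 1)
      for (i in 2:n_beats) ar[i] <- phi * ar[i - 1] + rnorm(1, 0, innov_sd)
    ibis <- numeric(n_beats)
    t_i <- 0
    for (i in seq_len(n_beats)) {
      rsa <- params$rsa_depth_ms * sin(2 * pi * params$resp_rate_hz * t_i)
      ibis[i] <- base + ar[i] + rsa
      t_i <- t_i + ibis[i] / 1000
    }
    clamped <- ibis < 300
    if (mean(clamped) > 0.05)
      cm_error("parameters force clamping of more than 5% of IBIs",
               "cardiomatch_parameter_error")
    pmax(ibis, 300)
  })
}

# one heartbeat kernel evaluated at times t (seconds, anchor at 0);
# jitter: optional per-atom list of (amp_factor, latency_shift_s)
eval_kernel <- function(t, kernel_spec, jitter = NULL) {
  out <- numeric(length(t))
  for (k in seq_along(kernel_spec)) {
    a <- kernel_spec[[k]]
    amp <- a$amp
    lat <- a$latency_ms / 1000
    if (!is.null(jitter)) {
      amp <- amp * jitter[[k]]$amp_factor
      lat <- lat + jitter[[k]]$latency_shift_s
    }
    sigma <- a$width_ms / 1000 / 6   # width taken as the +-3 sigma support
    tt <- t - lat
    out <- out + amp * exp(-0.5 * (tt / sigma)^2) * cos(2 * pi * a$freq_hz * tt)
  }
  out
}

# pink (1/f) noise via spectral shaping of white noise; unit variance
pink_noise <- function(n) {
  m <- stats::nextn(n, 2)
  w <- fft(rnorm(m))
  f <- c(1, seq_len(m - 1))
  f <- pmin(f, m - f + 1)            # two-sided frequency index
  shaped <- Re(fft(w / sqrt(f), inverse = TRUE)) / m
  x <- shaped[1:n]
  (x - mean(x)) / sd(x)
}

in_band_power <- function(x, fs, lo = 7, hi = 30) {
  var(butterworth_zero_lag(x, fs, c(lo, hi), order = 4, type = "pass"))
}

#' Generate a paired cardiomechanical + ECG record with ground truth
#'
#' Places one heartbeat kernel per beat on a uniform grid (the systolic peak
#' of each kernel is the ground-truth mechanical beat time), applies
#' respiratory amplitude modulation, and adds a white + pink noise mix
#' scaled so the realized 7--30 Hz in-band SNR matches `snr_db`. The ECG
#' channel is a spike train of QRS-like Ricker wavelets with P and T bumps
#' at `truth_beats - emd_ms`. Generation is bit-reproducible given
#' `params$seed`.
#'
#' @param params a [synth_params()].
#' @return a `synth_record`: list with `record` (a [waveform_record()] with
#'   channels `scg`, `ecg`, and optionally `fcg_raw`), `truth_beats`,
#'   `truth_r_peaks` (seconds), `burst_times` (if artifacts were injected)
#'   and `params`.
#' @export
generate_record <- function(params) {
  stopifnot(inherits(params, "synth_params"))
  fs <- params$fs
  n <- as.integer(round(params$duration_s * fs))
  tgrid <- (seq_len(n) - 1L) / fs

  n_max <- ceiling(params$duration_s * params$mean_hr_bpm / 60 * 1.5) + 5L
  ibis <- synth_ibi_sequence(params, n_max, seed = params$seed)
  beat_times <- ibis[1] / 2000 + cumsum(c(0, ibis[-1] / 1000))
  beat_times <- beat_times[beat_times < params$duration_s]

  res <- with_local_seed(params$seed + 1L, {
    scg <- numeric(n)
    support <- c(-0.15, max(vapply(params$kernel_spec, function(a)
      a$latency_ms / 1000 + a$width_ms / 2000, numeric(1))) + 0.1)
    for (bt in beat_times) {
      jit <- NULL
      if (!is.null(params$morph_jitter)) {
        jit <- lapply(params$kernel_spec, function(a) list(
          amp_factor = 1 + runif(1, -params$morph_jitter$amp,
                                 params$morph_jitter$amp),
          latency_shift_s = runif(1, -params$morph_jitter$latency_ms,
                                  params$morph_jitter$latency_ms) / 1000))
      }
      lo <- max(1L, as.integer(floor((bt + support[1]) * fs)) + 1L)
      hi <- min(n, as.integer(ceiling((bt + support[2]) * fs)) + 1L)
      idx <- lo:hi
      scg[idx] <- scg[idx] +
        eval_kernel(tgrid[idx] - bt, params$kernel_spec, jit)
    }
    scg <- scg * (1 + params$amp_mod_depth *
                    sin(2 * pi * params$resp_rate_hz * tgrid))
    noise <- rnorm(n) + pink_noise(n)
    p_sig <- in_band_power(scg, fs)
    p_noi <- in_band_power(noise, fs)
    noise <- noise * sqrt(p_sig / (p_noi * 10^(params$snr_db / 10)))
    scg_noisy <- scg + noise

    r_times <- beat_times - params$emd_ms / 1000
    r_times <- r_times[r_times > 0.05]
    ecg <- numeric(n)
    for (rt in r_times) {
      lo <- max(1L, as.integer(floor((rt - 0.3) * fs)) + 1L)
      hi <- min(n, as.integer(ceiling((rt + 0.45) * fs)) + 1L)
      tt <- tgrid[lo:hi] - rt
      qrs <- (1 - (tt / 0.012)^2) * exp(-0.5 * (tt / 0.012)^2)
      p_wave <- 0.15 * exp(-0.5 * ((tt + 0.16) / 0.025)^2)
      t_wave <- 0.30 * exp(-0.5 * ((tt - 0.25) / 0.05)^2)
      ecg[lo:hi] <- ecg[lo:hi] + qrs + p_wave + t_wave
    }
    ecg <- ecg + 0.01 * rnorm(n)

    channels <- list(scg = scg_noisy, ecg = ecg)
    roles <- c(scg = "scg", ecg = "ecg")
    if (params$with_fcg) {
      resp <- 5 * sin(2 * pi * 0.3 * tgrid)
      channels$fcg_raw <- 0.8 * scg + resp +
        noise * 0.5 + 0.02 * rnorm(n)
      roles <- c(roles, fcg_raw = "fcg_raw")
    }
    list(channels = channels, roles = roles, r_times = r_times)
  })

  record <- waveform_record(res$channels, fs = fs,
                            channel_roles = res$roles,
                            record_id = sprintf("synth_seed%d", params$seed))
  out <- structure(list(record = record, truth_beats = beat_times,
                        truth_r_peaks = res$r_times,
                        burst_times = numeric(0), params = params),
                   class = "synth_record")
  if (params$n_artifact_bursts > 0)
    out <- inject_spurious_bursts(out, n = params$n_artifact_bursts,
                                  magnitude = 3,
                                  seed = params$seed + 2L)
  out
}

#' Inject broadband artifact bursts into a synthetic record
#'
#' Adds `n` randomly placed 100--300 ms Hann-windowed noise bursts to the
#' mechanical channel. Burst noise is band-passed to the 7--30 Hz analysis
#' band (motion artifacts are only disruptive through their in-band
#' content) and each burst is rescaled so its standard deviation is
#' `magnitude` times the channel RMS. A protected interval can be declared
#' so a clean stretch survives for template selection.
#'
#' @param synth a `synth_record` from [generate_record()].
#' @param n number of bursts.
#' @param magnitude burst amplitude relative to the channel RMS.
#' @param seed RNG seed.
#' @param protect_s optional `c(start, end)` interval (seconds) kept free of
#'   bursts.
#' @param within_s optional `c(start, end)` interval the burst centres are
#'   drawn from (defaults to the whole record).
#' @param channel channel to corrupt (default `"scg"`).
#' @return the modified `synth_record`, with burst centre times appended to
#'   `burst_times`.
#' @export
inject_spurious_bursts <- function(synth, n, magnitude = 3, seed = 1L,
                                   protect_s = NULL, within_s = NULL,
                                   channel = "scg") {
  stopifnot(inherits(synth, "synth_record"), n >= 0)
  if (n == 0) return(synth)
  fs <- synth$record$fs
  x <- synth$record$samples[[channel]]
  dur <- (length(x) - 1) / fs
  if (is.null(within_s)) within_s <- c(0.3, dur - 0.3)
  rms <- sqrt(mean(x^2))
  times <- with_local_seed(seed, {
    got <- numeric(0)
    tries <- 0L
    while (length(got) < n && tries < 1000L) {
      tries <- tries + 1L
      ct <- runif(1, within_s[1], within_s[2])
      if (!is.null(protect_s) && ct >= protect_s[1] && ct <= protect_s[2])
        next
      got <- c(got, ct)
    }
    blens <- runif(length(got), 0.1, 0.3)
    raw <- numeric(length(x))
    spans <- vector("list", length(got))
    for (k in seq_along(got)) {
      half <- blens[k] / 2
      lo <- max(1L, as.integer(round((got[k] - half) * fs)) + 1L)
      hi <- min(length(x), as.integer(round((got[k] + half) * fs)) + 1L)
      m <- hi - lo + 1L
      win <- 0.5 - 0.5 * cos(2 * pi * seq_len(m) / (m + 1))
      raw[lo:hi] <- raw[lo:hi] + win * rnorm(m)
      spans[[k]] <- lo:hi
    }
    inband <- butterworth_zero_lag(raw, fs, c(7, 30), order = 4)
    for (k in seq_along(got)) {
      seg <- inband[spans[[k]]]
      if (sd(seg) > 0)
        x[spans[[k]]] <- x[spans[[k]]] + seg * magnitude * rms / sd(seg)
    }
    sort(got)
  })
  synth$record$samples[[channel]] <- x
  synth$burst_times <- sort(c(synth$burst_times, times))
  synth
}

#' Write a synthetic record's waveform and ground truth to CSV
#'
#' @param synth a `synth_record`.
#' @param dir output directory (created if missing).
#' @return named character vector of the written paths, invisibly.
#' @export
write_synth_record <- function(synth, dir) {
  stopifnot(inherits(synth, "synth_record"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wf <- file.path(dir, "waveform.csv")
  tb <- file.path(dir, "truth_beats.csv")
  rp <- file.path(dir, "truth_rpeaks.csv")
  write_waveform_csv(wf, synth$record)
  write_beat_annotations(tb, beat_annotations(synth$truth_beats,
                                              source = "ground_truth"),
                         synth$record$fs)
  write_beat_annotations(rp, beat_annotations(synth$truth_r_peaks,
                                              source = "ecg_rpeak"),
                         synth$record$fs)
  invisible(c(waveform = wf, truth_beats = tb, truth_r_peaks = rp))
}
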