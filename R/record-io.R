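#' Build a uniformly sampled multi-channel waveform record
#'
#' The basic container passed through the pipeline: one or more equal-length
#' channels sampled at a common rate, each tagged with a role that determines
#' its pre-processing chain. Sample `n` (0-based) occurs at time `n / fs`
#' seconds.
#'
#' @param samples named list of numeric vectors, all the same length.
#' @param fs sampling rate in Hz (positive scalar).
#' @param channel_roles named character vector mapping channel names to roles
#'   among `"scg"`, `"gcg"`, `"fcg_raw"`, `"dhf_fcg"`, `"ecg"`, `"other"`.
#'   Channels without an entry default to `"other"`.
#' @param record_id identifier string carried through outputs.
#' @return an object of class `waveform_record`.
#' @export
waveform_record <- function(samples, fs, channel_roles = NULL,
                            record_id = "record") {
  if (!is.list(samples) || length(samples) == 0L)
    cm_error("`samples` must be a non-empty named list of numeric vectors",
             "cardiomatch_format_error")
  if (is.null(names(samples)) || any(!nzchar(names(samples))))
    names(samples) <- paste0("ch", seq_along(samples))
  lens <- vapply(samples, length, integer(1))
  if (length(unique(lens)) != 1L || lens[1] < 1L)
    cm_error("all channels must have the same length >= 1",
             "cardiomatch_format_error")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    cm_error("`fs` must be a positive finite scalar",
             "cardiomatch_config_error")
  roles <- rep("other", length(samples))
  names(roles) <- names(samples)
  if (!is.null(channel_roles)) {
    bad <- setdiff(channel_roles, CHANNEL_ROLES)
    if (length(bad))
      cm_error(paste0("unknown channel role(s): ", paste(bad, collapse = ", ")),
               "cardiomatch_config_error")
    known <- intersect(names(channel_roles), names(samples))
    roles[known] <- channel_roles[known]
  }
  structure(list(samples = lapply(samples, as.numeric), fs = as.numeric(fs),
                 channel_roles = roles, record_id = as.character(record_id)),
            class = "waveform_record")
}

#' @export
print.waveform_record <- function(x, ...) {
  n <- length(x$samples[[1]])
  cat(sprintf("<waveform_record '%s'>  %d channel(s), %d samples @ %g Hz (%.2f s)\n",
              x$record_id, length(x$samples), n, x$fs, n / x$fs))
  for (ch in names(x$samples))
    cat(sprintf("  %-12s role=%s\n", ch, x$channel_roles[[ch]]))
  invisible(x)
}

#' Record duration in seconds
#' @param record a `waveform_record`.
#' @return duration `(n - 1) / fs` of the sampled grid, in seconds.
#' @export
record_duration <- function(record) {
  (length(record$samples[[1]]) - 1L) / record$fs
}

#' Build a beat-annotation set
#'
#' @param beat_times strictly increasing beat times in seconds.
#' @param source provenance: `"template_matching"`, `"ecg_rpeak"` or
#'   `"ground_truth"`.
#' @param labels optional per-beat labels (e.g. `"TP"`/`"FP"` after
#'   evaluation); recycled `NA` otherwise.
#' @return an object of class `beat_annotations`.
#' @export
beat_annotations <- function(beat_times,
                             source = c("template_matching", "ecg_rpeak",
                                        "ground_truth"),
                             labels = NULL) {
  source <- match.arg(source)
  beat_times <- as.numeric(beat_times)
  if (length(beat_times) && any(diff(beat_times) <= 0))
    cm_error("beat times must be strictly increasing",
             "cardiomatch_format_error")
  if (is.null(labels)) labels <- rep(NA_character_, length(beat_times))
  if (length(labels) != length(beat_times))
    cm_error("`labels` must match `beat_times` in length",
             "cardiomatch_format_error")
  structure(list(beat_times = beat_times, source = source,
                 labels = as.character(labels)),
            class = "beat_annotations")
}

#' Read a waveform from delimited text
#'
#' Expects one header row naming the channels; an optional first column named
#' `time` (seconds) from which the sampling rate is derived after checking
#' grid uniformity.
#'
#' @param path CSV file path.
#' @param fs sampling rate in Hz, or `"from header"` to require a `time`
#'   column.
#' @param roles named character vector of channel roles (see
#'   [waveform_record()]).
#' @param record_id identifier; defaults to the file base name.
#' @return a `waveform_record`.
#' @export
read_waveform_csv <- function(path, fs = "from header", roles = NULL,
                              record_id = NULL) {
  if (!file.exists(path))
    cm_error(paste0("file not found: ", path), "cardiomatch_io_error")
  df <- tryCatch(read.csv(path, check.names = FALSE),
                 error = function(e)
                   cm_error(paste0("cannot parse ", path, ": ",
                                   conditionMessage(e)),
                            "cardiomatch_format_error"))
  if (nrow(df) < 1L || ncol(df) < 1L)
    cm_error("empty waveform file", "cardiomatch_format_error")
  if (!all(vapply(df, is.numeric, logical(1))))
    cm_error("all waveform columns must be numeric",
             "cardiomatch_format_error")
  if (anyNA(df))
    cm_error("ragged or missing values in waveform file",
             "cardiomatch_format_error")
  has_time <- identical(tolower(names(df)[1]), "time")
  if (has_time) {
    tcol <- df[[1]]
    if (nrow(df) < 2L)
      cm_error("time column needs at least two rows to derive fs",
               "cardiomatch_sampling_error")
    dt <- diff(tcol)
    if (any(dt <= 0) || max(abs(dt - dt[1])) > 1e-6 * abs(dt[1]))
      cm_error("time column is not uniformly spaced",
               "cardiomatch_sampling_error")
    fs_derived <- 1 / mean(dt)
    df <- df[, -1, drop = FALSE]
    if (identical(fs, "from header")) fs <- fs_derived
  } else if (identical(fs, "from header")) {
    cm_error("fs = \"from header\" requires a leading `time` column",
             "cardiomatch_config_error")
  }
  if (ncol(df) == 0L)
    cm_error("no signal channels in file", "cardiomatch_format_error")
  if (is.null(record_id))
    record_id <- sub("\\.[^.]*$", "", basename(path))
  waveform_record(as.list(df), fs = fs, channel_roles = roles,
                  record_id = record_id)
}

#' Write a waveform record to delimited text
#'
#' Inverse of [read_waveform_csv()]: writes a `time` column plus one column
#' per channel.
#'
#' @param path output CSV path.
#' @param record a `waveform_record`.
#' @return `path`, invisibly.
#' @export
write_waveform_csv <- function(path, record) {
  n <- length(record$samples[[1]])
  df <- data.frame(time = (seq_len(n) - 1L) / record$fs)
  for (ch in names(record$samples)) df[[ch]] <- record$samples[[ch]]
  ok <- tryCatch({ write.csv(df, path, row.names = FALSE); TRUE },
                 error = function(e) FALSE)
  if (!ok) cm_error(paste0("cannot write ", path), "cardiomatch_io_error")
  invisible(path)
}

#' Write beat annotations to CSV
#'
#' One row per beat: 0-based sample index (nearest integer of `time * fs`),
#' time in seconds with 6 decimals, and label.
#'
#' @param path output CSV path.
#' @param ann a `beat_annotations` object.
#' @param fs sampling rate used to compute sample indices.
#' @return `path`, invisibly.
#' @export
write_beat_annotations <- function(path, ann, fs) {
  stopifnot(inherits(ann, "beat_annotations"))
  df <- data.frame(sample = as.integer(round(ann$beat_times * fs)),
                   time_s = sprintf("%.6f", ann$beat_times),
                   label = ifelse(is.na(ann$labels), "", ann$labels))
  ok <- tryCatch({ write.csv(df, path, row.names = FALSE, quote = FALSE); TRUE },
                 error = function(e) FALSE)
  if (!ok) cm_error(paste0("cannot write ", path), "cardiomatch_io_error")
  invisible(path)
}

#' Read beat annotations written by [write_beat_annotations()]
#'
#' @param path CSV path with columns `sample`, `time_s`, `label`.
#' @param source provenance tag to attach.
#' @return a `beat_annotations` object.
#' @export
read_beat_annotations <- function(path, source = "template_matching") {
  if (!file.exists(path))
    cm_error(paste0("file not found: ", path), "cardiomatch_io_error")
  df <- read.csv(path, colClasses = c(time_s = "numeric"))
  if (!all(c("sample", "time_s") %in% names(df)))
    cm_error("annotation file must have columns sample, time_s",
             "cardiomatch_format_error")
  labels <- if ("label" %in% names(df)) {
    l <- as.character(df$label); l[!nzchar(l) | is.na(l)] <- NA_character_; l
  } else NULL
  beat_annotations(df$time_s, source = source, labels = labels)
}

#' Linearly resample a record onto a new uniform grid
#'
#' Each channel is interpolated onto the grid `0, 1/target_fs, ...` up to the
#' last original sample time. The first sample is preserved exactly; original
#' sample instants that fall on the new grid keep their values.
#'
#' @param record a `waveform_record`.
#' @param target_fs new sampling rate in Hz.
#' @return a resampled `waveform_record`.
#' @export
resample_linear <- function(record, target_fs) {
  stopifnot(inherits(record, "waveform_record"))
  if (!is.numeric(target_fs) || length(target_fs) != 1L ||
      !is.finite(target_fs) || target_fs <= 0)
    cm_error("`target_fs` must be a positive scalar",
             "cardiomatch_config_error")
  n <- length(record$samples[[1]])
  t_old <- (seq_len(n) - 1L) / record$fs
  t_new <- seq(0, t_old[n], by = 1 / target_fs)
  samples <- lapply(record$samples, function(x)
    approx(t_old, x, xout = t_new, method = "linear")$y)
  waveform_record(samples, fs = target_fs,
                  channel_roles = record$channel_roles,
                  record_id = record$record_id)
}
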