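# Reading/writing recordings, band-pass filtering, epoching, and the
# artifact/channel exclusion bookkeeping applied before classification.

#' Band-pass filter a continuous recording
#'
#' Applies a zero-phase 4th-order Butterworth band-pass (forward-backward,
#' so the effective magnitude response is squared and no group delay is
#' introduced) to every channel of a continuous recording. The channel mean
#' is removed before filtering; the output has the same length as the
#' input. Filtering is done on the continuous signal before epoching, the
#' standard offline CSP practice.
#'
#' @param rec A `session_recording`.
#' @param low,high Band edges in Hz; default 8-30 Hz, the mu/beta band used
#'   for spatial filter design.
#' @param order Butterworth order per pass (default 4).
#' @return The recording with filtered signals.
#' @export
bandpass_filter <- function(rec, low = 8, high = 30, order = 4) {
  sr <- rec$sampling_rate
  if (!(low > 0 && low < high && high < sr / 2)) {
    stop_mt("band edges must satisfy 0 < low < high < sampling_rate/2 (got %g-%g Hz at %g Hz)",
            low, high, sr)
  }
  bf <- signal::butter(order, c(low, high) / (sr / 2), type = "pass")
  out <- rec
  for (ch in seq_len(nrow(rec$signals))) {
    x <- rec$signals[ch, ]
    out$signals[ch, ] <- as.numeric(signal::filtfilt(bf, x - mean(x)))
  }
  out
}

empty_exclusions <- function() {
  data.frame(trial_index = integer(0), reason = character(0),
             stringsAsFactors = FALSE)
}

#' Extract labeled trial epochs from a continuous recording
#'
#' Cuts one trial per cue event. Trial-relative times are in seconds,
#' sample indices 0-based, and windows half-open: trial `t`'s sample `k`
#' holds the continuous signal at `event_sample + k` for
#' `k = start*sr, ..., end*sr - 1`.
#'
#' @param rec A `session_recording`.
#' @param window Numeric `(start_s, end_s)` relative to trial onset;
#'   default the full 10-s trial.
#' @return An object of class `epoch_set`: list with `data`
#'   (trials x channels x samples), `labels` (factor over the five tasks),
#'   `day`, `run_index`, `sampling_rate`, `channel_labels`, `window`,
#'   `excluded_trials` (data.frame `trial_index`, `reason`) and
#'   `excluded_channels`.
#' @export
extract_epochs <- function(rec, window = c(0, 10)) {
  sr <- rec$sampling_rate
  n_samp <- round((window[2] - window[1]) * sr)
  ev <- rec$events
  bad <- !ev$task %in% mt_tasks()
  if (any(bad)) {
    stop_mt("unknown task label(s) in events: %s",
            paste(unique(ev$task[bad]), collapse = ", "))
  }
  n_total <- ncol(rec$signals)
  data <- array(0, dim = c(nrow(ev), nrow(rec$signals), n_samp))
  if (nrow(ev) > 0) {
    start0 <- ev$sample + round(window[1] * sr)      # 0-based
    over <- which(start0 < 0 | start0 + n_samp > n_total)
    if (length(over) > 0) {
      stop_mt("trial window [%g, %g) s does not fit the recording for event %d (task %s at sample %d)",
              window[1], window[2], over[1], ev$task[over[1]], ev$sample[over[1]])
    }
    for (i in seq_len(nrow(ev))) {
      data[i, , ] <- rec$signals[, (start0[i] + 1L):(start0[i] + n_samp)]
    }
  }
  structure(list(
    data = data,
    labels = factor(ev$task, levels = mt_tasks()),
    day = rec$day,
    run_index = ev$run,
    sampling_rate = sr,
    channel_labels = rec$channel_labels,
    window = window,
    excluded_trials = empty_exclusions(),
    excluded_channels = character(0)
  ), class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf(
    "<epoch_set> day %s: %d trials x %d channels x %d samples @ %g Hz; window [%g, %g) s; %d trials / %d channels excluded\n",
    x$day %||% NA, dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
    x$sampling_rate, x$window[1], x$window[2],
    nrow(x$excluded_trials), length(x$excluded_channels)))
  invisible(x)
}

#' Number of trials in an epoch set
#' @param epochs An `epoch_set`.
#' @return Integer trial count.
#' @export
n_trials <- function(epochs) dim(epochs$data)[1]

#' Subset an epoch set by trial index or task labels
#'
#' @param epochs An `epoch_set`.
#' @param trials Integer trial indices to keep (default all).
#' @param tasks Optional character vector of tasks to keep.
#' @return The subsetted `epoch_set`.
#' @export
subset_epochs <- function(epochs, trials = NULL, tasks = NULL) {
  keep <- seq_len(n_trials(epochs))
  if (!is.null(tasks)) keep <- keep[epochs$labels[keep] %in% tasks]
  if (!is.null(trials)) keep <- intersect(keep, trials)
  out <- epochs
  out$data <- epochs$data[keep, , , drop = FALSE]
  out$labels <- epochs$labels[keep]
  out$run_index <- epochs$run_index[keep]
  out
}

#' Apply artifact-trial and bad-channel exclusions to a day pair
#'
#' Marked trials are dropped from their respective day. Bad channels are
#' pooled: the union of both days' bad channels is removed from both days,
#' so that single-trial classification uses identical channel information
#' on both days.
#'
#' @param day1,day2 `epoch_set` objects for day 1 and day 2.
#' @param trial_marks Data frame with columns `day`, `trial_index`,
#'   `reason` (e.g. from [marks_as_exclusions()]), or `NULL` for none.
#' @param bad_channels_day1,bad_channels_day2 Character vectors of channel
#'   labels scored as bad on each day.
#' @return List with `day1`, `day2` (cleaned epoch sets) and `report`, an
#'   exclusion report: per-task, per-day counts of removed trials plus the
#'   removed channel labels.
#' @export
apply_exclusions <- function(day1, day2, trial_marks = NULL,
                             bad_channels_day1 = character(0),
                             bad_channels_day2 = character(0)) {
  if (is.null(trial_marks) || nrow(trial_marks) == 0) {
    trial_marks <- data.frame(day = integer(0), trial_index = integer(0),
                              reason = character(0))
  }
  bad_union <- union(bad_channels_day1, bad_channels_day2)
  unknown <- setdiff(bad_union, union(day1$channel_labels, day2$channel_labels))
  if (length(unknown) > 0) {
    stop_mt("unknown channel label(s): %s", paste(unknown, collapse = ", "))
  }

  counts <- matrix(0L, nrow = length(mt_tasks()), ncol = 2,
                   dimnames = list(mt_tasks(), c("day1", "day2")))
  drop_one <- function(epochs, d) {
    marks <- trial_marks[trial_marks$day == d, , drop = FALSE]
    if (any(marks$trial_index < 1 | marks$trial_index > n_trials(epochs))) {
      stop_mt("trial mark index out of range for day %d", d)
    }
    drop <- unique(marks$trial_index)
    if (length(drop) > 0) {
      tab <- table(epochs$labels[drop])
      counts[names(tab), d] <<- counts[names(tab), d] + as.integer(tab)
    }
    keep_ch <- !(epochs$channel_labels %in% bad_union)
    out <- subset_epochs(epochs, trials = setdiff(seq_len(n_trials(epochs)), drop))
    out$data <- out$data[, keep_ch, , drop = FALSE]
    out$channel_labels <- epochs$channel_labels[keep_ch]
    out$excluded_trials <- rbind(
      epochs$excluded_trials,
      data.frame(trial_index = drop,
                 reason = marks$reason[match(drop, marks$trial_index)],
                 stringsAsFactors = FALSE))
    out$excluded_channels <- union(epochs$excluded_channels, bad_union)
    out
  }
  d1 <- drop_one(day1, 1)
  d2 <- drop_one(day2, 2)
  report <- structure(list(
    trial_counts = counts,
    total = colSums(counts),
    channels_excluded = bad_union
  ), class = "exclusion_report")
  list(day1 = d1, day2 = d2, report = report)
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat("<exclusion_report> trials removed (day1/day2):\n")
  print(x$trial_counts)
  cat(sprintf("channels removed from both days: %s\n",
              if (length(x$channels_excluded)) paste(x$channels_excluded, collapse = ", ") else "none"))
  invisible(x)
}

#' Convert simulator artifact marks to exclusion marks
#'
#' @param rec A `session_recording` with ground-truth `artifact_marks`.
#' @return Data frame with columns `day`, `trial_index`, `reason` suitable
#'   for [apply_exclusions()].
#' @export
marks_as_exclusions <- function(rec) {
  m <- rec$artifact_marks
  if (nrow(m) == 0) {
    return(data.frame(day = integer(0), trial_index = integer(0),
                      reason = character(0)))
  }
  data.frame(day = rec$day, trial_index = m$trial_index, reason = m$kind,
             stringsAsFactors = FALSE)
}

#' Read exclusion marks from a delimited text file
#'
#' The file must be tab- or comma-delimited with a header containing at
#' least `day`, `trial_index` and `reason` columns (e.g. from expert visual
#' scoring).
#'
#' @param path Path to the marks file.
#' @return Data frame with columns `day`, `trial_index`, `reason`.
#' @export
read_exclusion_marks <- function(path) {
  marks <- utils::read.delim(path, sep = "", stringsAsFactors = FALSE)
  need <- c("day", "trial_index", "reason")
  if (!all(need %in% names(marks))) {
    stop_mt("marks file must have columns: %s", paste(need, collapse = ", "))
  }
  marks[need]
}

#' Load a continuous recording
#'
#' @param path File path (for the internal format, the path prefix used
#'   when writing).
#' @param format `"internal"` (binary array + JSON sidecar) or `"edf"`.
#' @return A `session_recording`.
#' @export
load_recording <- function(path, format = c("internal", "edf")) {
  format <- match.arg(format)
  rec <- switch(format,
    internal = read_recording_internal(path),
    edf = read_edf(path)
  )
  bad <- !rec$events$task %in% mt_tasks()
  if (any(bad)) {
    stop_mt("unknown task annotation(s): %s",
            paste(unique(rec$events$task[bad]), collapse = ", "))
  }
  rec
}

#' Write a continuous recording
#'
#' @param rec A `session_recording`.
#' @param path Output path (prefix for the internal format).
#' @param format `"internal"` or `"edf"`.
#' @param params Optional `sim_params` written alongside as a provenance
#'   sidecar (`<path>.params.json`).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = c("internal", "edf"),
                            params = NULL) {
  format <- match.arg(format)
  switch(format,
    internal = write_recording_internal(rec, path),
    edf = write_edf(rec, path)
  )
  if (!is.null(params)) write_params(params, paste0(path, ".params.json"))
  invisible(path)
}

# Internal container: little-endian doubles plus a JSON metadata sidecar.
write_recording_internal <- function(rec, path) {
  con <- file(paste0(path, ".bin"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(rec$signals), con, size = 8, endian = "little")
  meta <- list(
    n_channels = nrow(rec$signals),
    n_samples = ncol(rec$signals),
    sampling_rate = rec$sampling_rate,
    channel_labels = rec$channel_labels,
    events = rec$events,
    artifact_marks = rec$artifact_marks,
    day = rec$day
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(path)
}

read_recording_internal <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  n <- meta$n_channels * meta$n_samples
  con <- file(paste0(path, ".bin"), "rb")
  on.exit(close(con))
  signals <- matrix(readBin(con, "numeric", n, size = 8, endian = "little"),
                    meta$n_channels, meta$n_samples)
  rownames(signals) <- meta$channel_labels
  ev <- as.data.frame(meta$events)
  if (nrow(ev) == 0) ev <- data.frame(sample = integer(0), task = character(0), run = integer(0))
  am <- as.data.frame(meta$artifact_marks)
  if (nrow(am) == 0) am <- data.frame(trial_index = integer(0), kind = character(0))
  structure(list(
    signals = signals,
    sampling_rate = meta$sampling_rate,
    channel_labels = meta$channel_labels,
    events = ev,
    artifact_marks = am,
    day = meta$day
  ), class = "session_recording")
}

#' Write an epoch set to an array file with JSON metadata sidecar
#'
#' @param epochs An `epoch_set`.
#' @param path Output path prefix (`<path>.bin` and `<path>.json`).
#' @return `path`, invisibly.
#' @export
write_epochs <- function(epochs, path) {
  con <- file(paste0(path, ".bin"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(epochs$data), con, size = 8, endian = "little")
  meta <- list(
    dim = dim(epochs$data),
    labels = as.character(epochs$labels),
    day = epochs$day,
    run_index = epochs$run_index,
    sampling_rate = epochs$sampling_rate,
    channel_labels = epochs$channel_labels,
    window = epochs$window,
    excluded_trials = epochs$excluded_trials,
    excluded_channels = epochs$excluded_channels
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(path)
}

#' Read an epoch set written by [write_epochs()]
#'
#' @param path Path prefix used when writing.
#' @return An `epoch_set`.
#' @export
read_epochs <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  con <- file(paste0(path, ".bin"), "rb")
  on.exit(close(con))
  data <- array(readBin(con, "numeric", prod(meta$dim), size = 8,
                        endian = "little"), dim = meta$dim)
  excl <- as.data.frame(meta$excluded_trials)
  if (nrow(excl) == 0) excl <- empty_exclusions()
  structure(list(
    data = data,
    labels = factor(meta$labels, levels = mt_tasks()),
    day = meta$day,
    run_index = meta$run_index,
    sampling_rate = meta$sampling_rate,
    channel_labels = meta$channel_labels,
    window = meta$window,
    excluded_trials = excl,
    excluded_channels = as.character(meta$excluded_channels %||% character(0))
  ), class = "epoch_set")
}
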