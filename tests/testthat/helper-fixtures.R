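# Scaled-down simulation parameters and hand-built containers used across
# the unit tests. All fixtures are generated in code.

# A small but structurally complete parameter set: fewer channels/sources,
# shorter sessions, 4-source gain profiles planting a strong SUB/FEET and a
# weak HAND/FEET contrast.
small_params <- function(seed = 1, n_channels = 12, n_sources = 4,
                         runs = 2, cues = 3, artifact_rate = 0,
                         noise = 0.4,
                         drift = list(mixing_perturbation_sd = 0,
                                      channel_offset_sd = 0)) {
  p <- default_params(seed)
  p$n_channels <- as.integer(n_channels)
  p$n_sources <- as.integer(n_sources)
  set.seed(seed + 7777)
  m <- matrix(rnorm(n_channels * n_sources), n_channels, n_sources)
  p$mixing <- sweep(m, 2, sqrt(colSums(m^2)), "/")
  prof <- list(
    WORD = c(0.55, 0.85, 1.00, 1.00),
    SUB  = c(0.85, 0.50, 1.00, 1.00),
    NAV  = c(1.00, 0.80, 0.75, 1.00),
    HAND = c(1.00, 1.00, 0.70, 0.95),
    FEET = c(1.00, 1.00, 0.95, 0.55)
  )
  p$task_profiles <- lapply(prof, function(g) {
    out <- rep(1, n_sources)
    out[seq_len(min(4, n_sources))] <- g[seq_len(min(4, n_sources))]
    out
  })
  p$runs_per_day <- as.integer(runs)
  p$cues_per_task_per_run <- as.integer(cues)
  p$iti <- 1
  p$run_gap <- 1
  p$background_noise_sd <- noise
  p$pink_noise_sd <- noise
  p$artifact_trial_rate <- artifact_rate
  p$day2_drift <- drift
  validate_params(p)
  p
}

# Simulate, band-pass and epoch one session in one call.
epochs_for <- function(params, day = 1, seed = 1) {
  rec <- simulate_session(params, day = day, seed = seed)
  extract_epochs(bandpass_filter(rec))
}

# Build an epoch_set directly from a trials x channels x samples array.
make_epochs <- function(data, labels, sampling_rate = 256,
                        window = c(0, dim(data)[3] / sampling_rate),
                        day = 1) {
  structure(list(
    data = data,
    labels = factor(labels, levels = mt_tasks()),
    day = day,
    run_index = rep(1L, dim(data)[1]),
    sampling_rate = sampling_rate,
    channel_labels = sprintf("CH%02d", seq_len(dim(data)[2])),
    window = window,
    excluded_trials = data.frame(trial_index = integer(0),
                                 reason = character(0)),
    excluded_channels = character(0)
  ), class = "epoch_set")
}

# Epochs of two classes whose planted channel variances differ: class A has
# high variance on the first channel, class B on the second.
planted_epochs <- function(n_per_class = 8, n_channels = 4, n_samples = 128,
                           contrast = 3, seed = 1, tasks = c("SUB", "FEET")) {
  set.seed(seed)
  n <- 2 * n_per_class
  data <- array(rnorm(n * n_channels * n_samples), c(n, n_channels, n_samples))
  labels <- rep(tasks, each = n_per_class)
  for (i in seq_len(n)) {
    if (labels[i] == tasks[1]) {
      data[i, 1, ] <- data[i, 1, ] * contrast
    } else {
      data[i, 2, ] <- data[i, 2, ] * contrast
    }
  }
  make_epochs(data, labels)
}

# A continuous single-trial recording holding the given channel signals.
make_recording <- function(signals, sampling_rate = 256, events = NULL,
                           day = 1) {
  if (is.null(events)) {
    events <- data.frame(sample = integer(0), task = character(0),
                         run = integer(0))
  }
  structure(list(
    signals = signals,
    sampling_rate = sampling_rate,
    channel_labels = rownames(signals) %||%
      sprintf("CH%02d", seq_len(nrow(signals))),
    events = events,
    artifact_marks = data.frame(trial_index = integer(0),
                                kind = character(0)),
    day = day
  ), class = "session_recording")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
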