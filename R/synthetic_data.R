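# Synthetic screening-session generator.
#
# Generative model: band-limited (8-30 Hz) stochastic sources are mixed
# linearly and instantaneously into sensor space. During the imagery period
# of each trial the variance of every source is multiplied by a
# task-specific gain (gain < 1 emulates event-related desynchronization,
# gain > 1 synchronization), ramping in linearly after cue onset. Low
# frequency AR(1) background activity and white sensor noise are added per
# channel. This is the minimal model under which CSP spatial filtering is
# the matched analysis.

mt_montage <- c(
  "AFz", "F7", "F3", "Fz", "F4", "F8", "FC3", "FCz", "FC4", "T3",
  "C3", "Cz", "C4", "T4", "CP3", "CPz", "CP4", "P7", "P5", "P3",
  "P1", "Pz", "P2", "P4", "P6", "P8", "PO3", "PO4", "O1", "O2"
)

mt_channel_labels <- function(n_channels) {
  if (n_channels == length(mt_montage)) {
    mt_montage
  } else {
    sprintf("CH%02d", seq_len(n_channels))
  }
}

default_task_profiles <- function(n_sources) {
  base <- list(
    WORD = c(0.55, 0.80, 1.00, 1.00, 1.00, 1.00, 1.30, 1.00),
    SUB  = c(0.70, 0.60, 1.00, 1.00, 1.00, 1.00, 1.30, 1.00),
    NAV  = c(1.00, 1.00, 0.60, 0.85, 1.00, 1.00, 1.00, 1.20),
    HAND = c(1.00, 1.00, 1.00, 1.00, 0.70, 0.90, 1.00, 1.00),
    FEET = c(1.00, 1.00, 1.00, 1.00, 0.85, 0.65, 1.00, 1.00)
  )
  lapply(base, function(g) {
    out <- rep(1, n_sources)
    k <- min(n_sources, length(g))
    out[seq_len(k)] <- g[seq_len(k)]
    out
  })
}

#' Default simulation parameters for a screening session
#'
#' Returns a fully populated parameter set mirroring the screening paradigm:
#' 30 EEG channels sampled at 256 Hz, 8 runs per day with 5 cues per task
#' per run (40 trials per task per day), 10-s trials with the cue at 3 s,
#' and task-specific 8-30 Hz source-power modulation during the imagery
#' period. The mixing matrix is drawn reproducibly from `seed`; the
#' task-specific gain profiles are fixed defaults chosen so that
#' brain-teaser vs. motor-imagery pairs (e.g. SUB vs. FEET) separate well
#' while the two motor-imagery tasks overlap and separate poorly.
#'
#' @param seed Integer master seed; drives the mixing matrix and, by
#'   default, all downstream simulation randomness.
#' @return An object of class `sim_params`: a list with fields
#'   `n_channels`, `n_sources`, `sampling_rate`, `mixing`
#'   (channels x sources), `task_profiles` (per task, per-source variance
#'   gains during imagery; 1 = no modulation), `source_band`,
#'   `erd_ramp` (s), `background_noise_sd`, `pink_noise_sd`,
#'   `trial_length`, `cue_onset`, `iti`, `run_gap` (all s),
#'   `runs_per_day`, `cues_per_task_per_run`, `artifact_trial_rate`,
#'   `artifact_amplitude`, `day2_drift` (list with
#'   `mixing_perturbation_sd`, `channel_offset_sd`) and `seed`.
#' @export
#' @examples
#' p <- default_params(seed = 1)
#' p$runs_per_day * p$cues_per_task_per_run   # 40 trials per task per day
default_params <- function(seed = 1L) {
  seed <- as.integer(seed)
  n_channels <- 30L
  n_sources <- 8L
  mixing <- with_seed(substream_seed(seed, "mixing"), {
    m <- matrix(stats::rnorm(n_channels * n_sources), n_channels, n_sources)
    sweep(m, 2, sqrt(colSums(m^2)), "/")
  })
  params <- structure(list(
    n_channels = n_channels,
    n_sources = n_sources,
    sampling_rate = 256,
    mixing = mixing,
    task_profiles = default_task_profiles(n_sources),
    source_band = c(8, 30),
    erd_ramp = 0.5,
    background_noise_sd = 0.7,
    pink_noise_sd = 0.9,
    trial_length = 10,
    cue_onset = 3,
    iti = 3,
    run_gap = 4,
    runs_per_day = 8L,
    cues_per_task_per_run = 5L,
    artifact_trial_rate = 0.1,
    artifact_amplitude = 12,
    day2_drift = list(mixing_perturbation_sd = 0.05, channel_offset_sd = 0.15),
    seed = seed
  ), class = "sim_params")
  validate_params(params)
  params
}

#' Validate simulation parameters
#'
#' Checks the structural invariants of a `sim_params` object: positive
#' variance gains, artifact rate in \[0, 1\], full-column-rank mixing, and a
#' cue onset that leaves a non-empty imagery period inside the trial.
#'
#' @param params A `sim_params` list, e.g. from [default_params()].
#' @return `params`, invisibly, if valid; otherwise an error.
#' @export
validate_params <- function(params) {
  p <- params
  if (!all(dim(p$mixing) == c(p$n_channels, p$n_sources))) {
    stop_mt("mixing must be %d x %d", p$n_channels, p$n_sources)
  }
  if (qr(p$mixing)$rank < p$n_sources) {
    stop_mt("mixing matrix must have full column rank")
  }
  gains <- unlist(p$task_profiles)
  if (any(!is.finite(gains)) || any(gains <= 0)) {
    stop_mt("all task-profile variance gains must be positive")
  }
  if (any(lengths(p$task_profiles) != p$n_sources)) {
    stop_mt("each task profile must have one gain per source (%d)", p$n_sources)
  }
  if (p$artifact_trial_rate < 0 || p$artifact_trial_rate > 1) {
    stop_mt("artifact_trial_rate must lie in [0, 1]")
  }
  if (p$background_noise_sd <= 0 || p$pink_noise_sd < 0) {
    stop_mt("noise standard deviations must be positive")
  }
  if (p$cue_onset >= p$trial_length) {
    stop_mt("cue_onset (%g s) must leave an imagery period inside the %g s trial",
            p$cue_onset, p$trial_length)
  }
  if (any(vapply(p$day2_drift, function(x) x < 0, logical(1)))) {
    stop_mt("day2_drift standard deviations must be non-negative")
  }
  invisible(params)
}

# AR(1) low-frequency background noise, scaled to the requested sd.
pink_noise <- function(n, sd, a = 0.95) {
  if (sd == 0) return(numeric(n))
  x <- as.numeric(stats::filter(stats::rnorm(n), a, method = "recursive"))
  x * (sd * sqrt(1 - a^2))
}

#' Simulate one screening session of multichannel EEG
#'
#' Generates a continuous multichannel recording for one day of the
#' paradigm: `runs_per_day` runs, each presenting `cues_per_task_per_run`
#' cues of each of the five tasks in randomized order. Sources are
#' band-limited to `source_band`; during each trial's imagery period
#' (`cue_onset` to `trial_length`) every source's amplitude is scaled by the
#' square root of the cued task's variance gain, ramping in over `erd_ramp`
#' seconds. A fraction `artifact_trial_rate` of trials receives
#' high-amplitude 3-8 Hz half-sine transients on frontal channels, recorded
#' as ground-truth artifact marks (no detection is performed). For day 2,
#' the mixing matrix is perturbed by additive Gaussian entries and each
#' channel receives a multiplicative amplitude drift plus a DC offset,
#' emulating between-day changes in montage and impedance.
#'
#' @param params A `sim_params` object.
#' @param day 1 or 2; day 2 applies the configured `day2_drift`.
#' @param seed Integer seed for this session (defaults to the params seed
#'   combined with the day).
#' @return An object of class `session_recording`: list with `signals`
#'   (channels x samples), `sampling_rate`, `channel_labels`, `events`
#'   (data.frame `sample` (0-based onset), `task`, `run`), `artifact_marks`
#'   (data.frame `trial_index`, `kind`) and `day`.
#' @export
simulate_session <- function(params, day = 1,
                             seed = substream_seed(params$seed, "day", day)) {
  validate_params(params)
  if (!day %in% c(1, 2)) stop_mt("day must be 1 or 2")
  p <- params
  sr <- p$sampling_rate
  tasks <- mt_tasks()
  n_tasks <- length(tasks)
  t_samp <- round(p$trial_length * sr)
  iti_samp <- round(p$iti * sr)
  gap_samp <- round(p$run_gap * sr)
  cues_per_run <- n_tasks * p$cues_per_task_per_run
  run_samp <- gap_samp + cues_per_run * (t_samp + iti_samp)
  n_total <- p$runs_per_day * run_samp

  # cue schedule: randomized order within each run, balanced counts
  schedule <- do.call(rbind, lapply(seq_len(p$runs_per_day), function(r) {
    order_r <- with_seed(substream_seed(seed, "order", r),
                         sample(rep(tasks, p$cues_per_task_per_run)))
    onset <- (r - 1L) * run_samp + gap_samp +
      (seq_len(cues_per_run) - 1L) * (t_samp + iti_samp)
    data.frame(sample = onset, task = order_r, run = r,
               stringsAsFactors = FALSE)
  }))

  # band-limited sources with task-dependent variance envelopes
  sources <- with_seed(substream_seed(seed, "sources"), {
    s <- matrix(stats::rnorm(p$n_sources * n_total), p$n_sources, n_total)
    for (k in seq_len(p$n_sources)) {
      s[k, ] <- band_filter_vector(s[k, ], sr, p$source_band[1], p$source_band[2])
      s[k, ] <- s[k, ] / stats::sd(s[k, ])
    }
    s
  })
  ramp_samp <- max(1L, round(p$erd_ramp * sr))
  cue_samp <- round(p$cue_onset * sr)
  env <- matrix(1, p$n_sources, n_total)
  for (i in seq_len(nrow(schedule))) {
    g <- sqrt(p$task_profiles[[schedule$task[i]]])
    i0 <- schedule$sample[i] + cue_samp            # 0-based imagery start
    i1 <- schedule$sample[i] + t_samp              # 0-based trial end (excl.)
    idx <- (i0 + 1L):i1                            # 1-based columns
    prof <- rep(1, length(idx))
    nr <- min(ramp_samp, length(idx))
    prof[seq_len(nr)] <- seq(0, 1, length.out = nr)
    prof[-seq_len(nr)] <- 1
    for (k in seq_len(p$n_sources)) {
      env[k, idx] <- 1 + prof * (g[k] - 1)
    }
  }

  mixing <- p$mixing
  chan_gain <- rep(1, p$n_channels)
  chan_dc <- rep(0, p$n_channels)
  if (day == 2) {
    drift <- with_seed(substream_seed(seed, "drift"), {
      rms <- sqrt(mean(mixing^2))
      pert <- matrix(stats::rnorm(length(mixing),
                                  sd = p$day2_drift$mixing_perturbation_sd * rms),
                     nrow(mixing), ncol(mixing))
      list(
        mixing = mixing + pert,
        gain = exp(stats::rnorm(p$n_channels, sd = p$day2_drift$channel_offset_sd)),
        dc = stats::rnorm(p$n_channels, sd = p$day2_drift$channel_offset_sd)
      )
    })
    mixing <- drift$mixing
    chan_gain <- drift$gain
    chan_dc <- drift$dc
  }

  signals <- mixing %*% (sources * env)
  signals <- signals + with_seed(substream_seed(seed, "noise"), {
    noise <- matrix(stats::rnorm(p$n_channels * n_total,
                                 sd = p$background_noise_sd),
                    p$n_channels, n_total)
    for (ch in seq_len(p$n_channels)) {
      noise[ch, ] <- noise[ch, ] + pink_noise(n_total, p$pink_noise_sd)
    }
    noise
  })

  labels <- mt_channel_labels(p$n_channels)
  frontal <- which(labels %in% c("AFz", "F7", "F3", "Fz", "F4", "F8"))
  if (length(frontal) == 0) frontal <- seq_len(max(1L, p$n_channels %/% 5L))

  artifact_marks <- data.frame(trial_index = integer(0),
                               kind = character(0), stringsAsFactors = FALSE)
  if (p$artifact_trial_rate > 0) {
    marks <- with_seed(substream_seed(seed, "artifact"), {
      hit <- stats::runif(nrow(schedule)) < p$artifact_trial_rate
      hit_idx <- which(hit)
      kinds <- character(length(hit_idx))
      for (j in seq_along(hit_idx)) {
        i <- hit_idx[j]
        kinds[j] <- sample(c("eye", "muscle"), 1)
        f <- stats::runif(1, 3, 8)
        dur <- round(sr / (2 * f))                 # half period of f
        t0 <- schedule$sample[i] + cue_samp +
          sample.int(t_samp - cue_samp - dur, 1)   # within imagery period
        pulse <- p$artifact_amplitude * sin(pi * seq_len(dur) / dur)
        cols <- (t0 + 1L):(t0 + dur)
        for (ch in frontal) {
          signals[ch, cols] <- signals[ch, cols] + pulse
        }
      }
      list(signals = signals,
           marks = data.frame(trial_index = hit_idx, kind = kinds,
                              stringsAsFactors = FALSE))
    })
    signals <- marks$signals
    artifact_marks <- marks$marks
  }

  if (day == 2) {
    signals <- signals * chan_gain + chan_dc
  }
  rownames(signals) <- labels

  structure(list(
    signals = signals,
    sampling_rate = sr,
    channel_labels = labels,
    events = schedule,
    artifact_marks = artifact_marks,
    day = day
  ), class = "session_recording")
}

#' Simulate a matched day-1 / day-2 session pair
#'
#' Both sessions share the task profiles and mixing matrix of `params`;
#' the day-2 session additionally applies the configured `day2_drift`
#' (mixing perturbation, per-channel amplitude drift and DC offset). With
#' all drift set to zero the two sessions are independent draws from the
#' identical generative process.
#'
#' @param params A `sim_params` object.
#' @param seed Integer seed for the pair.
#' @return List with elements `day1` and `day2`, each a
#'   `session_recording`.
#' @export
simulate_day_pair <- function(params, seed = params$seed) {
  list(
    day1 = simulate_session(params, day = 1, seed = substream_seed(seed, "pair", 1)),
    day2 = simulate_session(params, day = 2, seed = substream_seed(seed, "pair", 2))
  )
}

#' @export
print.session_recording <- function(x, ...) {
  cat(sprintf(
    "<session_recording> day %d: %d channels x %d samples @ %g Hz, %d cues, %d artifact trials\n",
    x$day, nrow(x$signals), ncol(x$signals), x$sampling_rate,
    nrow(x$events), nrow(x$artifact_marks)))
  invisible(x)
}

#' @export
print.sim_params <- function(x, ...) {
  cat(sprintf(
    "<sim_params> %d channels, %d sources @ %g Hz; %d runs x %d cues/task; artifact rate %.2f; seed %d\n",
    x$n_channels, x$n_sources, x$sampling_rate, x$runs_per_day,
    x$cues_per_task_per_run, x$artifact_trial_rate, x$seed))
  invisible(x)
}

#' Write simulation parameters to a text sidecar file
#'
#' Serializes a `sim_params` object to JSON for provenance alongside a
#' written recording.
#'
#' @param params A `sim_params` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_params <- function(params, path) {
  validate_params(params)
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read simulation parameters from a sidecar file
#'
#' @param path Path written by [write_params()].
#' @return A `sim_params` object.
#' @export
read_params <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$mixing <- matrix(unlist(raw$mixing), raw$n_channels, raw$n_sources)
  raw$task_profiles <- lapply(raw$task_profiles, as.numeric)
  raw$n_channels <- as.integer(raw$n_channels)
  raw$n_sources <- as.integer(raw$n_sources)
  raw$runs_per_day <- as.integer(raw$runs_per_day)
  raw$cues_per_task_per_run <- as.integer(raw$cues_per_task_per_run)
  raw$seed <- as.integer(raw$seed)
  params <- structure(raw, class = "sim_params")
  validate_params(params)
  params
}
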