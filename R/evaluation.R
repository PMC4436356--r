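# Segment grids, TPR/TNR/GMAC scoring, repeated stratified within-day
# cross-validation, task-pair ranking, and between-day transfer simulation.

#' Build a grid of 1-s analysis segments
#'
#' Segments are indexed by their end time `t` and span `[t - length, t]`
#' seconds relative to trial onset. Sample ranges are 0-based and
#' half-open, so at 256 Hz a 1-s segment holds exactly 256 samples and
#' adjacent segments share no boundary sample.
#'
#' @param start_t,stop_t First and last segment end time in seconds
#'   (inclusive).
#' @param step Grid step in seconds (default 0.5).
#' @param length Segment length in seconds (default 1).
#' @param sampling_rate Sampling rate in Hz (default 256).
#' @param trial_window Trial window `(start_s, end_s)` the segments must
#'   fit into (default `c(0, 10)`).
#' @return Data frame with one row per segment: `t`, `start_s`, `end_s`,
#'   `start_sample`, `end_sample` (0-based, half-open).
#' @export
#' @examples
#' nrow(build_segment_grid(3, 9))     # 13 between-day training segments
#' nrow(build_segment_grid(3, 9.5))   # 14 within-day segments
build_segment_grid <- function(start_t, stop_t, step = 0.5, length = 1.0,
                               sampling_rate = 256, trial_window = c(0, 10)) {
  if (step <= 0) stop_mt("step must be positive")
  if (stop_t < start_t) stop_mt("stop_t must be >= start_t")
  ts <- start_t + step * (0:floor((stop_t - start_t) / step + 1e-9))
  if (any(ts - length < trial_window[1] - 1e-9) ||
      any(ts > trial_window[2] + 1e-9)) {
    stop_mt("segments [t-%g, t] for t in [%g, %g] extend outside the trial window [%g, %g] s",
            length, start_t, stop_t, trial_window[1], trial_window[2])
  }
  data.frame(
    t = ts,
    start_s = ts - length,
    end_s = ts,
    start_sample = round((ts - length - trial_window[1]) * sampling_rate),
    end_sample = round((ts - trial_window[1]) * sampling_rate)
  )
}

#' Score binary predictions with class-wise rates
#'
#' @param predicted,truth Character vectors of task labels, equal length.
#' @param positive_task Label counted as positive.
#' @return An object of class `rate_summary`: list with `tpr`, `tnr`,
#'   `gmac` (the geometric mean `sqrt(tpr * tnr)`, which penalizes
#'   one-sided classifiers relative to the arithmetic mean), `n_pos`,
#'   `n_neg`.
#' @export
#' @examples
#' score_predictions(c("SUB", "FEET"), c("SUB", "FEET"), "SUB")$gmac  # 1
score_predictions <- function(predicted, truth, positive_task) {
  if (length(predicted) != length(truth)) {
    stop_mt("predicted and truth differ in length (%d vs %d)",
            length(predicted), length(truth))
  }
  pos <- truth == positive_task
  if (!any(pos) || all(pos)) {
    stop_mt("both classes must be present in truth (positive %s: %d of %d)",
            positive_task, sum(pos), length(truth))
  }
  tpr <- mean(predicted[pos] == truth[pos])
  tnr <- mean(predicted[!pos] == truth[!pos])
  structure(list(tpr = tpr, tnr = tnr, gmac = sqrt(tpr * tnr),
                 n_pos = sum(pos), n_neg = sum(!pos)),
            class = "rate_summary")
}

#' @export
print.rate_summary <- function(x, ...) {
  cat(sprintf("<rate_summary> TPR %.3f (n=%d), TNR %.3f (n=%d), GMAC %.3f\n",
              x$tpr, x$n_pos, x$tnr, x$n_neg, x$gmac))
  invisible(x)
}

# Fit CSP + LDA on the given training trials only (the no-leakage unit of
# the cross-validation); cflat is the flat per-trial covariance matrix for
# one segment, labels the per-trial tasks.
fit_pair_model <- function(cflat, labels, train_idx, pair, m) {
  tr_a <- train_idx[labels[train_idx] == pair[1]]
  tr_b <- train_idx[labels[train_idx] == pair[2]]
  csp <- fit_csp(mean_cov_flat(cflat, tr_a), mean_cov_flat(cflat, tr_b), m = m)
  feats_tr <- features_from_flat(csp, cflat, c(tr_a, tr_b))
  lda <- fit_lda(feats_tr[seq_along(tr_a), , drop = FALSE],
                 feats_tr[length(tr_a) + seq_along(tr_b), , drop = FALSE],
                 positive_task = pair[1], negative_task = pair[2])
  list(csp = csp, lda = lda)
}

# Stratified fold assignment: per class, shuffle then deal round-robin.
stratified_folds <- function(labels, pair, folds, seed) {
  fold_of <- integer(length(labels))
  with_seed(seed, {
    for (task in pair) {
      idx <- which(labels == task)
      fold_of[idx] <- sample(rep(seq_len(folds), length.out = length(idx)))
    }
  })
  fold_of
}

#' Within-day cross-validated evaluation of one task pair
#'
#' For every segment of the grid, runs `repetitions` rounds of stratified
#' `folds`-fold cross-validation: per fold, class covariances, CSP filters
#' and the LDA stage are fitted on the training trials only and the
#' held-out trials are classified. TPR/TNR are pooled over all held-out
#' predictions within a repetition, then averaged over repetitions; the
#' segment whose mean GMAC is maximal (earliest segment on ties) is
#' reported as the peak.
#'
#' @param epochs An `epoch_set` (any tasks; the pair is subset internally).
#' @param pair Character vector of two task labels; the first is the
#'   positive class.
#' @param grid Segment grid from [build_segment_grid()]; default the
#'   within-day imagery grid, segment ends `t = 3.0, 3.5, ..., 9.5` s.
#' @param folds,repetitions Cross-validation shape (default 10 x 10).
#' @param m CSP projections kept per spectrum end (default 2).
#' @param seed Integer seed driving the fold shuffles.
#' @return An object of class `within_day_result`: list with `task_pair`,
#'   `day`, `segments` (data frame `t`, `tpr`, `tnr`, `gmac`, `gmac_sd`
#'   over repetitions), `peak` (list `t`, `tpr`, `tnr`, `gmac`), and the
#'   evaluation settings.
#' @export
within_day_cv <- function(epochs, pair, grid = NULL, folds = 10,
                          repetitions = 10, m = 2, seed = 1) {
  ep <- subset_epochs(epochs, tasks = pair)
  if (is.null(grid)) {
    grid <- build_segment_grid(3.0, 9.5, 0.5, 1.0, ep$sampling_rate, ep$window)
  }
  counts <- table(factor(ep$labels, levels = pair))
  if (any(counts < folds)) {
    stop_mt("stratified %d-fold CV needs at least %d trials per class (have %s)",
            folds, folds, paste(sprintf("%s=%d", pair, counts), collapse = ", "))
  }
  labels <- as.character(ep$labels)
  n <- length(labels)
  seg_stats <- vector("list", nrow(grid))
  for (s in seq_len(nrow(grid))) {
    cflat <- trial_segment_cov_flat(ep, c(grid$start_s[s], grid$end_s[s]))
    rep_rates <- matrix(0, repetitions, 3)
    for (r in seq_len(repetitions)) {
      fold_of <- stratified_folds(labels, pair,
                                  folds, substream_seed(seed, "fold", s, r))
      predicted <- character(n)
      for (f in seq_len(folds)) {
        train_idx <- which(fold_of != f)
        test_idx <- which(fold_of == f)
        mod <- fit_pair_model(cflat, labels, train_idx, pair, m)
        feats_te <- features_from_flat(mod$csp, cflat, test_idx)
        predicted[test_idx] <- predict_lda(mod$lda, feats_te)$label
      }
      rs <- score_predictions(predicted, labels, pair[1])
      rep_rates[r, ] <- c(rs$tpr, rs$tnr, rs$gmac)
    }
    seg_stats[[s]] <- c(colMeans(rep_rates), stats::sd(rep_rates[, 3]))
  }
  seg <- do.call(rbind, seg_stats)
  segments <- data.frame(t = grid$t, tpr = seg[, 1], tnr = seg[, 2],
                         gmac = seg[, 3], gmac_sd = seg[, 4])
  pk <- which.max(segments$gmac)
  structure(list(
    task_pair = pair,
    day = ep$day,
    segments = segments,
    peak = list(t = segments$t[pk], tpr = segments$tpr[pk],
                tnr = segments$tnr[pk], gmac = segments$gmac[pk]),
    folds = folds, repetitions = repetitions, m = m, seed = seed
  ), class = "within_day_result")
}

#' @export
print.within_day_result <- function(x, ...) {
  cat(sprintf(
    "<within_day_result> %s vs %s, day %s: peak GMAC %.3f at t = %.1f s (%dx%d CV over %d segments)\n",
    x$task_pair[1], x$task_pair[2], x$day %||% NA, x$peak$gmac, x$peak$t,
    x$repetitions, x$folds, nrow(x$segments)))
  invisible(x)
}

#' Rank task pairs by median peak GMAC across a cohort
#'
#' Computes, per pair, the median peak GMAC over participants for each day
#' (`md`), the overall median over participants and days (`MD`), and the
#' number of participants exceeding 70% GMAC per day (strict inequality).
#' Pairs are sorted by `MD`, descending.
#'
#' @param results Data frame with columns `participant`, `pair`, `day` and
#'   `gmac` (one row per participant x pair x day peak GMAC), e.g. built
#'   with [as_rank_input()].
#' @return Data frame with one row per pair: `pair`, `MD`, `md_day1`,
#'   `n_day1`, `md_day2`, `n_day2`, sorted by `MD` descending.
#' @export
rank_task_pairs <- function(results) {
  if (is.null(results) || nrow(results) == 0) stop_mt("empty ranking input")
  need <- c("participant", "pair", "day", "gmac")
  if (!all(need %in% names(results))) {
    stop_mt("ranking input must have columns: %s", paste(need, collapse = ", "))
  }
  pairs <- unique(results$pair)
  rows <- lapply(pairs, function(p) {
    sub <- results[results$pair == p, , drop = FALSE]
    g1 <- sub$gmac[sub$day == 1]
    g2 <- sub$gmac[sub$day == 2]
    data.frame(
      pair = p,
      MD = stats::median(sub$gmac),
      md_day1 = if (length(g1)) stats::median(g1) else NA_real_,
      n_day1 = sum(g1 > 0.7),
      md_day2 = if (length(g2)) stats::median(g2) else NA_real_,
      n_day2 = sum(g2 > 0.7),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$MD), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assemble a ranking input table from within-day results
#'
#' @param results List of `within_day_result` objects.
#' @param participants Participant identifier per result.
#' @return Data frame with columns `participant`, `pair`, `day`, `gmac`.
#' @export
as_rank_input <- function(results, participants) {
  do.call(rbind, Map(function(res, who) {
    data.frame(participant = who,
               pair = paste(res$task_pair, collapse = "-"),
               day = res$day %||% NA, gmac = res$peak$gmac,
               stringsAsFactors = FALSE)
  }, results, participants))
}

#' Between-day model transfer with bias-only re-adaptation
#'
#' For every training segment of the day-1 grid, CSP filters and the LDA
#' stage are fitted on all non-excluded day-1 trials of the pair; the LDA
#' bias is then re-adapted from the first `n_adapt` day-2 trials of each
#' class (weights and filters unchanged), and the classifier is applied to
#' every 1-s evaluation segment (0.5-s lag) of the remaining day-2 trials.
#' Adaptation trials are excluded from evaluation to avoid leakage. Both
#' the re-biased and the unmodified (day-1 bias) classifier are scored.
#'
#' Two summaries are reported: `oracle_peak`, the best day-2 GMAC over all
#' trained classifiers (the maximum transferable performance), and
#' `day1_selected`, the day-2 GMAC of the classifier whose training
#' segment maximized day-1 cross-validated GMAC (the deployable choice).
#'
#' @param day1,day2 `epoch_set` objects sharing channel lists.
#' @param pair Character vector of two task labels.
#' @param train_grid Day-1 training segment grid; default ends
#'   `t = 3.0, ..., 9.0` s (13 segments).
#' @param eval_grid Day-2 evaluation grid; default equal to `train_grid`.
#' @param n_adapt Adaptation trials per class (default 4).
#' @param m CSP projections per spectrum end (default 2).
#' @param folds,repetitions Shape of the day-1 CV used for segment
#'   selection (default 10 x 10).
#' @param seed Integer seed (drives the day-1 CV fold shuffles).
#' @param day1_cv Optional precomputed `within_day_result` for day 1 on
#'   `train_grid` (avoids recomputation).
#' @return An object of class `transfer_result`: list with `task_pair`,
#'   `curves` (data frame `train_t`, `eval_t`, `tpr`, `tnr`, `gmac`,
#'   `gmac_norebias`), `per_classifier` (peak day-2 rates per training
#'   segment), `oracle_peak`, `oracle_peak_norebias`, `day1_selected`
#'   (incl. `gmac_norebias`), and settings.
#' @export
between_day_transfer <- function(day1, day2, pair, train_grid = NULL,
                                 eval_grid = NULL, n_adapt = 4, m = 2,
                                 folds = 10, repetitions = 10, seed = 1,
                                 day1_cv = NULL) {
  if (!identical(day1$channel_labels, day2$channel_labels)) {
    stop_mt("day 1 and day 2 must share channel lists (apply exclusions first)")
  }
  ep1 <- subset_epochs(day1, tasks = pair)
  ep2 <- subset_epochs(day2, tasks = pair)
  if (is.null(train_grid)) {
    train_grid <- build_segment_grid(3.0, 9.0, 0.5, 1.0, ep1$sampling_rate, ep1$window)
  }
  if (is.null(eval_grid)) eval_grid <- train_grid

  lab2 <- as.character(ep2$labels)
  counts2 <- table(factor(ep2$labels, levels = pair))
  if (any(counts2 <= n_adapt)) {
    stop_mt("day 2 needs more than %d trials per class for adaptation + evaluation (have %s)",
            n_adapt, paste(sprintf("%s=%d", pair, counts2), collapse = ", "))
  }
  adapt_idx <- unlist(lapply(pair, function(task) {
    utils::head(which(lab2 == task), n_adapt)
  }))
  eval_idx <- setdiff(seq_along(lab2), adapt_idx)
  truth <- lab2[eval_idx]

  # day-2 evaluation covariances are train-segment independent: cache them
  eval_covs <- lapply(seq_len(nrow(eval_grid)), function(e) {
    trial_segment_cov_flat(ep2, c(eval_grid$start_s[e], eval_grid$end_s[e]),
                           eval_idx)
  })

  lab1 <- as.character(ep1$labels)
  curves <- list()
  per_cls <- list()
  for (s in seq_len(nrow(train_grid))) {
    tseg <- c(train_grid$start_s[s], train_grid$end_s[s])
    cflat1 <- trial_segment_cov_flat(ep1, tseg)
    mod <- fit_pair_model(cflat1, lab1, seq_along(lab1), pair, m)
    adapt_feats <- features_from_flat(
      mod$csp, trial_segment_cov_flat(ep2, tseg, adapt_idx))
    lda_rb <- rebias_lda(mod$lda,
                         adapt_feats[seq_len(n_adapt), , drop = FALSE],
                         adapt_feats[n_adapt + seq_len(n_adapt), , drop = FALSE],
                         n_adapt = n_adapt)
    seg_rows <- lapply(seq_len(nrow(eval_grid)), function(e) {
      feats <- features_from_flat(mod$csp, eval_covs[[e]])
      pred_rb <- predict_lda(lda_rb, feats)$label
      pred_nb <- predict_lda(mod$lda, feats)$label
      rb <- score_predictions(pred_rb, truth, pair[1])
      nb <- score_predictions(pred_nb, truth, pair[1])
      data.frame(train_t = train_grid$t[s], eval_t = eval_grid$t[e],
                 tpr = rb$tpr, tnr = rb$tnr, gmac = rb$gmac,
                 tpr_norebias = nb$tpr, tnr_norebias = nb$tnr,
                 gmac_norebias = nb$gmac)
    })
    seg_df <- do.call(rbind, seg_rows)
    curves[[s]] <- seg_df
    pk_rb <- which.max(seg_df$gmac)
    pk_nb <- which.max(seg_df$gmac_norebias)
    per_cls[[s]] <- data.frame(
      train_t = train_grid$t[s],
      peak_eval_t = seg_df$eval_t[pk_rb],
      tpr = seg_df$tpr[pk_rb], tnr = seg_df$tnr[pk_rb],
      gmac = seg_df$gmac[pk_rb],
      peak_eval_t_norebias = seg_df$eval_t[pk_nb],
      gmac_norebias = seg_df$gmac_norebias[pk_nb]
    )
  }
  curves <- do.call(rbind, curves)
  per_classifier <- do.call(rbind, per_cls)

  ora <- which.max(per_classifier$gmac)
  ora_nb <- which.max(per_classifier$gmac_norebias)

  if (is.null(day1_cv)) {
    day1_cv <- within_day_cv(day1, pair, grid = train_grid, folds = folds,
                             repetitions = repetitions, m = m,
                             seed = substream_seed(seed, "day1cv"))
  }
  cv_gmac <- day1_cv$segments$gmac[match(train_grid$t, day1_cv$segments$t)]
  if (any(is.na(cv_gmac))) {
    stop_mt("day1_cv does not cover the training grid")
  }
  sel <- which.max(cv_gmac)

  structure(list(
    task_pair = pair,
    curves = curves,
    per_classifier = per_classifier,
    oracle_peak = as.list(per_classifier[ora, c("train_t", "peak_eval_t",
                                                "tpr", "tnr", "gmac")]),
    oracle_peak_norebias = list(
      train_t = per_classifier$train_t[ora_nb],
      gmac = per_classifier$gmac_norebias[ora_nb]),
    day1_selected = list(
      train_t = train_grid$t[sel],
      day1_gmac = cv_gmac[sel],
      peak_eval_t = per_classifier$peak_eval_t[sel],
      gmac = per_classifier$gmac[sel],
      gmac_norebias = per_classifier$gmac_norebias[sel]),
    n_adapt = n_adapt, m = m, seed = seed
  ), class = "transfer_result")
}

#' @export
print.transfer_result <- function(x, ...) {
  cat(sprintf(
    "<transfer_result> %s vs %s: oracle peak GMAC %.3f (train t = %.1f s), day-1-selected GMAC %.3f (vs %.3f without re-bias)\n",
    x$task_pair[1], x$task_pair[2], x$oracle_peak$gmac, x$oracle_peak$train_t,
    x$day1_selected$gmac, x$day1_selected$gmac_norebias))
  invisible(x)
}

#' Cohort-average temporal TPR/TNR curves
#'
#' Averages per-segment true positive and true negative rates over a list
#' of participant results. For within-day results the per-segment CV means
#' are averaged; for transfer results the day-2 evaluation curve of each
#' participant's day-1-selected classifier is averaged.
#'
#' @param results Non-empty list of `within_day_result` or
#'   `transfer_result` objects (one per participant, same grid).
#' @return Data frame with columns `t`, `tpr`, `tnr`, `n` (participants
#'   averaged), with the cue time (3 s) attached as attribute
#'   `"cue_onset"` for plotting.
#' @export
temporal_curves <- function(results) {
  if (length(results) == 0) stop_mt("no results to average")
  one_curve <- function(res) {
    if (inherits(res, "within_day_result")) {
      res$segments[, c("t", "tpr", "tnr")]
    } else if (inherits(res, "transfer_result")) {
      sub <- res$curves[res$curves$train_t == res$day1_selected$train_t, ]
      data.frame(t = sub$eval_t, tpr = sub$tpr, tnr = sub$tnr)
    } else {
      stop_mt("unsupported result type: %s", paste(class(res), collapse = "/"))
    }
  }
  curves <- lapply(results, one_curve)
  ts <- curves[[1]]$t
  if (!all(vapply(curves, function(cv) identical(cv$t, ts), logical(1)))) {
    stop_mt("results use different segment grids")
  }
  out <- data.frame(
    t = ts,
    tpr = rowMeans(vapply(curves, function(cv) cv$tpr, numeric(length(ts)))),
    tnr = rowMeans(vapply(curves, function(cv) cv$tnr, numeric(length(ts)))),
    n = length(curves)
  )
  attr(out, "cue_onset") <- 3
  out
}
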