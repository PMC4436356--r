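test_that("segment grids follow the printed analysis windows", {
  wd <- build_segment_grid(3.0, 9.5)
  expect_equal(nrow(wd), 14)                       # within-day grid
  bd <- build_segment_grid(3.0, 9.0)
  expect_equal(nrow(bd), 13)                       # between-day grid
  expect_equal(bd$t, seq(3, 9, by = 0.5))
  # 1-s windows, 0-based half-open sample ranges: t = 3.0 -> [512, 768)
  expect_equal(bd$start_sample[1], 512)
  expect_equal(bd$end_sample[1], 768)
  expect_true(all(bd$end_sample - bd$start_sample == 256))

  single <- build_segment_grid(3.0, 3.0)
  expect_equal(nrow(single), 1)
  expect_equal(c(single$start_s, single$end_s), c(2, 3))

  expect_error(build_segment_grid(0.5, 9), "outside")
  expect_error(build_segment_grid(3, 11), "outside")
  expect_error(build_segment_grid(3, 9, step = 0), "step")
})

test_that("rate summaries implement the geometric mean accuracy", {
  truth <- rep(c("SUB", "FEET"), each = 100)
  perfect <- score_predictions(truth, truth, "SUB")
  expect_equal(c(perfect$tpr, perfect$tnr, perfect$gmac), c(1, 1, 1))

  # TPR 0.81, TNR 0.64 -> GMAC sqrt(0.5184) = 0.72
  pred <- truth
  pred[1:19] <- "FEET"
  pred[101:136] <- "SUB"
  rs <- score_predictions(pred, truth, "SUB")
  expect_equal(rs$tpr, 0.81)
  expect_equal(rs$tnr, 0.64)
  expect_equal(rs$gmac, 0.72)

  # degenerate one-sided classifier is fully penalized
  all_pos <- score_predictions(rep("SUB", 200), truth, "SUB")
  expect_equal(c(all_pos$tpr, all_pos$tnr, all_pos$gmac), c(1, 0, 0))

  expect_error(score_predictions(rep("SUB", 5), rep("SUB", 5), "SUB"),
               "both classes")
  expect_error(score_predictions("SUB", c("SUB", "FEET"), "SUB"), "length")

  # AM-GM: GMAC never exceeds arithmetic mean accuracy
  set.seed(11)
  for (i in 1:20) {
    pred <- sample(c("SUB", "FEET"), 40, replace = TRUE)
    rs <- score_predictions(pred, truth[c(1:20, 101:120)], "SUB")
    expect_lte(rs$gmac, (rs$tpr + rs$tnr) / 2 + 1e-12)
  }
})

test_that("within-day CV is deterministic, leakage-free and finds planted structure", {
  p <- small_params(runs = 4, cues = 3, noise = 0.25)
  ep <- epochs_for(p, 1, seed = 51)
  grid <- build_segment_grid(3.5, 6.5)
  res <- within_day_cv(ep, c("SUB", "FEET"), grid = grid, folds = 4,
                       repetitions = 2, seed = 5)
  res2 <- within_day_cv(ep, c("SUB", "FEET"), grid = grid, folds = 4,
                        repetitions = 2, seed = 5)
  expect_identical(res, res2)
  expect_equal(nrow(res$segments), nrow(grid))
  expect_equal(res$peak$gmac, max(res$segments$gmac))
  expect_true(all(res$segments$gmac >= 0 & res$segments$gmac <= 1))
  # the planted SUB/FEET contrast is detectable well above chance
  expect_gt(res$peak$gmac, 0.75)

  expect_error(within_day_cv(ep, c("SUB", "FEET"), grid = grid, folds = 40),
               "at least 40")
})

test_that("fold models never see held-out trials", {
  ep <- planted_epochs(n_per_class = 8, seed = 21)
  cflat <- mtscreen:::trial_segment_cov_flat(ep, c(0, 0.5))
  labels <- as.character(ep$labels)
  train_idx <- c(1:6, 9:14)
  held_out <- c(7, 8, 15, 16)
  mod1 <- mtscreen:::fit_pair_model(cflat, labels, train_idx,
                                    c("SUB", "FEET"), m = 1)
  # corrupt the held-out trials' covariances: the trained model must not move
  cflat2 <- cflat
  cflat2[, held_out] <- cflat[, rev(held_out)] * 0.5 + 0.1
  attr(cflat2, "n_channels") <- attr(cflat, "n_channels")
  mod2 <- mtscreen:::fit_pair_model(cflat2, labels, train_idx,
                                    c("SUB", "FEET"), m = 1)
  expect_identical(mod1$csp$filters, mod2$csp$filters)
  expect_identical(mod1$lda$weights, mod2$lda$weights)
  expect_identical(mod1$lda$bias, mod2$lda$bias)
})

test_that("task-pair ranking computes medians and >70% counts", {
  one <- data.frame(participant = "A", pair = "SUB-FEET", day = 1, gmac = 0.8)
  r1 <- rank_task_pairs(one)
  expect_equal(r1$MD, 0.8)
  expect_equal(r1$md_day1, 0.8)

  cohort <- data.frame(
    participant = rep(c("A", "B", "C"), 2),
    pair = rep(c("SUB-FEET", "HAND-FEET"), each = 3),
    day = 1,
    gmac = c(0.83, 0.77, 0.70, 0.60, 0.65, 0.71))
  rk <- rank_task_pairs(cohort)
  expect_equal(rk$pair[1], "SUB-FEET")
  expect_equal(rk$md_day1[rk$pair == "SUB-FEET"], 0.77)
  # strict inequality: 0.70 does not count as exceeding 70%
  expect_equal(rk$n_day1[rk$pair == "SUB-FEET"], 2)
  expect_equal(rk$n_day1[rk$pair == "HAND-FEET"], 1)

  expect_error(rank_task_pairs(data.frame()), "empty")
})

test_that("between-day transfer reports curves, oracle and day-1-selected peaks", {
  p <- small_params(runs = 4, cues = 3, noise = 0.25)
  pair_rec <- simulate_day_pair(p, seed = 77)
  d1 <- extract_epochs(bandpass_filter(pair_rec$day1))
  d2 <- extract_epochs(bandpass_filter(pair_rec$day2))
  grid <- build_segment_grid(3.5, 6.0)
  tr <- between_day_transfer(d1, d2, c("SUB", "FEET"), train_grid = grid,
                             n_adapt = 4, folds = 4, repetitions = 2,
                             seed = 3)
  expect_equal(nrow(tr$curves), nrow(grid)^2)
  expect_lte(tr$day1_selected$gmac, tr$oracle_peak$gmac)
  expect_lte(tr$day1_selected$gmac_norebias, tr$oracle_peak_norebias$gmac)
  expect_equal(tr$oracle_peak$gmac, max(tr$per_classifier$gmac))
  expect_true(tr$day1_selected$train_t %in% grid$t)
  # determinism
  tr2 <- between_day_transfer(d1, d2, c("SUB", "FEET"), train_grid = grid,
                              n_adapt = 4, folds = 4, repetitions = 2,
                              seed = 3)
  expect_identical(tr$curves, tr2$curves)

  # channel lists must agree across days
  d2_dropped <- d2
  d2_dropped$data <- d2$data[, -1, , drop = FALSE]
  d2_dropped$channel_labels <- d2$channel_labels[-1]
  expect_error(between_day_transfer(d1, d2_dropped, c("SUB", "FEET")),
               "channel lists")
  # adaptation demands enough day-2 trials
  few <- subset_epochs(d2, trials = which(d2$labels %in% c("SUB", "FEET"))[1:8])
  expect_error(
    between_day_transfer(d1, few, c("SUB", "FEET"), train_grid = grid,
                         n_adapt = 4),
    "more than 4")
})

test_that("temporal curves average participants per segment", {
  p <- small_params(runs = 4, cues = 3, noise = 0.25)
  grid <- build_segment_grid(3.5, 5.0)
  res <- lapply(c(61, 62), function(s) {
    within_day_cv(epochs_for(p, 1, seed = s), c("SUB", "FEET"), grid = grid,
                  folds = 4, repetitions = 2, seed = s)
  })
  one <- temporal_curves(res[1])
  expect_equal(one$tpr, res[[1]]$segments$tpr)
  both <- temporal_curves(res)
  expect_equal(both$tpr,
               (res[[1]]$segments$tpr + res[[2]]$segments$tpr) / 2)
  expect_equal(attr(both, "cue_onset"), 3)
  expect_error(temporal_curves(list()), "no results")
})
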