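# Fisher linear discriminant: training, scoring, and bias-only
# re-adaptation for between-day model transfer.

#' Fit Fisher's linear discriminant
#'
#' The weight vector is proportional to `S_w^{-1} (mu_A - mu_B)` with
#' `S_w` the pooled within-class scatter (ridge-stabilized by
#' `1e-8 tr(S_w)/d I`); the bias places the decision threshold at the
#' midpoint of the projected class means, i.e.
#' `bias = -w . (mu_A + mu_B)/2`. Scores `w . x + bias > 0` vote for the
#' positive (class-A) task. Equal class priors are assumed (the paradigm is
#' balanced).
#'
#' @param features_A,features_B Numeric matrices (trials x features) of the
#'   two classes, e.g. from [extract_features()].
#' @param positive_task,negative_task Task labels attached to the model
#'   (defaults `"A"`/`"B"`).
#' @param trained_on Optional provenance list (day, segment, pair).
#' @return An object of class `lda_model`: list with `weights`, `bias`,
#'   `label_map` (named `positive`/`negative`) and `trained_on`.
#' @export
fit_lda <- function(features_A, features_B,
                    positive_task = "A", negative_task = "B",
                    trained_on = NULL) {
  xa <- as.matrix(features_A)
  xb <- as.matrix(features_B)
  if (ncol(xa) != ncol(xb)) stop_mt("feature dimensions differ between classes")
  if (nrow(xa) < 2 || nrow(xb) < 2) {
    stop_mt("need at least 2 feature vectors per class (got %d and %d)",
            nrow(xa), nrow(xb))
  }
  mu_a <- colMeans(xa)
  mu_b <- colMeans(xb)
  ca <- sweep(xa, 2, mu_a)
  cb <- sweep(xb, 2, mu_b)
  sw <- (crossprod(ca) + crossprod(cb)) / (nrow(xa) + nrow(xb) - 2)
  d <- ncol(xa)
  sw <- sw + 1e-8 * (sum(diag(sw)) / d + .Machine$double.eps) * diag(d)
  w <- tryCatch(solve(sw, mu_a - mu_b), error = function(e) {
    stop_mt("within-class scatter is singular after ridge: %s", conditionMessage(e))
  })
  if (all(w == 0)) stop_mt("degenerate discriminant: class means coincide")
  structure(list(
    weights = as.numeric(w),
    bias = -sum(w * (mu_a + mu_b)) / 2,
    label_map = c(positive = positive_task, negative = negative_task),
    trained_on = trained_on
  ), class = "lda_model")
}

#' @export
print.lda_model <- function(x, ...) {
  cat(sprintf("<lda_model> %s (+) vs %s (-): %d weights, bias %.4g\n",
              x$label_map["positive"], x$label_map["negative"],
              length(x$weights), x$bias))
  invisible(x)
}

#' Classify feature vectors with a fitted discriminant
#'
#' @param model An `lda_model`.
#' @param features Numeric matrix (trials x features) or a single vector.
#' @return Data frame with one row per trial: `label` (positive task iff
#'   `score > 0`; a score of exactly 0 resolves to the negative task) and
#'   `score`.
#' @export
predict_lda <- function(model, features) {
  x <- if (is.null(dim(features))) matrix(features, nrow = 1) else as.matrix(features)
  if (ncol(x) != length(model$weights)) {
    stop_mt("feature dimension %d does not match model dimension %d",
            ncol(x), length(model$weights))
  }
  score <- as.numeric(x %*% model$weights + model$bias)
  data.frame(
    label = ifelse(score > 0, model$label_map[["positive"]],
                   model$label_map[["negative"]]),
    score = score,
    stringsAsFactors = FALSE
  )
}

#' Re-adapt only the classifier bias from a few new-session trials
#'
#' Between-day feature-mean drift (e.g. from montage and impedance changes)
#' shifts the LDA scores by an approximately constant offset. This update
#' recomputes the bias as the midpoint of the adaptation-trial class means,
#' leaving the weight vector untouched, from exactly `n_adapt` feature
#' vectors per class (the first chronologically occurring non-excluded
#' trials of the new session).
#'
#' @param model An `lda_model`.
#' @param adapt_A,adapt_B Numeric matrices (`n_adapt` x features) of
#'   adaptation trials for the positive and negative task.
#' @param n_adapt Required number of adaptation trials per class
#'   (default 4).
#' @return The model with an updated `bias`; `weights` are unchanged.
#' @export
rebias_lda <- function(model, adapt_A, adapt_B, n_adapt = 4) {
  xa <- as.matrix(adapt_A)
  xb <- as.matrix(adapt_B)
  if (nrow(xa) != n_adapt || nrow(xb) != n_adapt) {
    stop_mt("bias adaptation requires exactly %d trials per class (got %d and %d)",
            n_adapt, nrow(xa), nrow(xb))
  }
  if (ncol(xa) != length(model$weights) || ncol(xb) != length(model$weights)) {
    stop_mt("adaptation feature dimension does not match model dimension")
  }
  out <- model
  out$bias <- -sum(model$weights * (colMeans(xa) + colMeans(xb))) / 2
  out
}
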