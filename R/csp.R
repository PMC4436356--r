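# Common spatial patterns by two-step whitening + rotation.
#
# Given class covariance matrices S_A and S_B, the composite S_A + S_B is
# whitened (eigendecomposition with inverse square-root scaling); in the
# whitened space the class-A covariance is rotated onto the coordinate axes.
# The composite transform simultaneously diagonalizes both classes with
# per-component class-A and class-B variances summing to one, so the
# projections with the largest / smallest class-A eigenvalues carry the
# highest variance contrast between the classes.

# 0-based, half-open sample range of a trial-relative segment in seconds.
segment_samples <- function(segment, sampling_rate, window) {
  start <- round((segment[1] - window[1]) * sampling_rate)
  stop <- round((segment[2] - window[1]) * sampling_rate)
  if (start < 0 || stop > round((window[2] - window[1]) * sampling_rate)) {
    stop_mt("segment [%g, %g] s lies outside the epoch window [%g, %g] s",
            segment[1], segment[2], window[1], window[2])
  }
  if (stop <= start) stop_mt("segment must have positive length")
  c(start, stop)
}

# Per-trial centered channel covariances for one segment, each normalized
# to unit trace, stored column-flattened (channels^2 x trials) for fast
# fold averaging. Trace normalization is harmless for features, which are
# variance ratios.
trial_segment_cov_flat <- function(epochs, segment,
                                   trials = seq_len(n_trials(epochs))) {
  rng <- segment_samples(segment, epochs$sampling_rate, epochs$window)
  cols <- (rng[1] + 1L):rng[2]
  nch <- dim(epochs$data)[2]
  out <- matrix(0, nch * nch, length(trials))
  for (j in seq_along(trials)) {
    x <- epochs$data[trials[j], , cols, drop = TRUE]
    x <- x - rowMeans(x)
    cmat <- tcrossprod(x) / (length(cols) - 1)
    tr <- sum(diag(cmat))
    if (tr <= 0) {
      stop_mt("trial %d has zero variance in segment [%g, %g] s",
              trials[j], segment[1], segment[2])
    }
    out[, j] <- cmat / tr
  }
  attr(out, "n_channels") <- nch
  out
}

# Same covariances as a channels x channels x trials array (public paths).
trial_segment_cov <- function(epochs, segment,
                              trials = seq_len(n_trials(epochs))) {
  flat <- trial_segment_cov_flat(epochs, segment, trials)
  nch <- attr(flat, "n_channels")
  array(flat, dim = c(nch, nch, length(trials)))
}

mean_cov_flat <- function(cflat, idx) {
  nch <- attr(cflat, "n_channels")
  m <- matrix(rowMeans(cflat[, idx, drop = FALSE]), nch, nch)
  (m + t(m)) / 2
}

# Rank-1 expansion of the filter rows: row i is vec(w_i w_i'), so that
# projection variances for all trials come from one matrix product.
filter_quadratic_map <- function(filters) {
  t(vapply(seq_len(nrow(filters)),
           function(i) as.vector(tcrossprod(filters[i, ])),
           numeric(ncol(filters)^2)))
}

# Log-normalized variance features (trials x 2m) from flat covariances.
features_from_flat <- function(model, cflat, idx = seq_len(ncol(cflat))) {
  v <- filter_quadratic_map(model$filters) %*% cflat[, idx, drop = FALSE]
  feats <- t(log(sweep(v, 2, colSums(v), "/")))
  colnames(feats) <- sprintf("csp%d", seq_len(ncol(feats)))
  feats
}

#' Estimate a class covariance matrix for one time segment
#'
#' Computes, for every non-excluded trial of the given task, the channel
#' covariance of the segment's samples, normalizes each trial's covariance
#' to unit trace (robustness against trial-wise amplitude drift), and
#' averages over trials.
#'
#' @param epochs An `epoch_set`.
#' @param task Task label whose trials enter the estimate.
#' @param segment Numeric `(start_s, end_s)` relative to trial onset.
#' @return An object of class `csp_cov`: list with `matrix`
#'   (channels x channels, symmetric, unit trace), `n_trials`, `task` and
#'   `segment`.
#' @export
estimate_class_covariance <- function(epochs, task, segment) {
  trials <- which(epochs$labels == task)
  if (length(trials) < 2) {
    stop_mt("need at least 2 trials of task %s (found %d)", task, length(trials))
  }
  cflat <- trial_segment_cov_flat(epochs, segment, trials)
  m <- mean_cov_flat(cflat, seq_along(trials))
  structure(list(matrix = m, n_trials = length(trials), task = task,
                 segment = segment), class = "csp_cov")
}

as_cov_matrix <- function(x) {
  if (inherits(x, "csp_cov")) x$matrix else as.matrix(x)
}

#' Fit a CSP filter bank from two class covariances
#'
#' Two-step construction: (1) whiten the composite covariance
#' `S_A + S_B` via its eigendecomposition with inverse-square-root scaling,
#' rejecting components with eigenvalue below `1e-10` times the maximum;
#' (2) rotate the whitened class-A covariance onto the coordinate axes.
#' Both class covariances are ridge-regularized with
#' `(1-gamma) S + gamma (tr(S)/channels) I` beforehand. The resulting
#' transform diagonalizes both classes simultaneously, with the class-A
#' diagonal (the eigenvalues, in \[0, 1\], sorted descending) and class-B
#' diagonal summing to one per component. The filter bank keeps the `m`
#' rows with the largest and the `m` rows with the smallest eigenvalues.
#' Each filter row's sign is fixed so its largest-magnitude coefficient is
#' positive.
#'
#' @param cov_A,cov_B `csp_cov` objects (or plain symmetric matrices) of
#'   equal dimension.
#' @param m Number of projections kept from each end of the eigenvalue
#'   spectrum (default 2, i.e. 4 projections).
#' @param gamma Ridge regularization weight (default `1e-6`).
#' @return An object of class `csp_model`: list with `filters`
#'   (`2m` x channels; the `m` largest-eigenvalue rows first),
#'   `full_transform` (components x channels), `eigenvalues` (descending),
#'   `m`, `task_pair`, `band`, `train_segment` and `channel_labels`.
#' @export
fit_csp <- function(cov_A, cov_B, m = 2, gamma = 1e-6) {
  sa <- as_cov_matrix(cov_A)
  sb <- as_cov_matrix(cov_B)
  if (!all(dim(sa) == dim(sb))) stop_mt("class covariances differ in dimension")
  nch <- nrow(sa)
  if (2 * m > nch) stop_mt("2m = %d projections exceed %d channels", 2 * m, nch)
  ridge <- function(s) (1 - gamma) * s + gamma * (sum(diag(s)) / nch) * diag(nch)
  sa <- ridge(sa)
  sb <- ridge(sb)
  comp <- sa + sb
  eg <- eigen((comp + t(comp)) / 2, symmetric = TRUE)
  keep <- eg$values > 1e-10 * max(eg$values)
  if (sum(keep) < 2 * m) {
    stop_mt("composite covariance is rank %d (< 2m = %d) after regularization; reduce channels or m",
            sum(keep), 2 * m)
  }
  white <- diag(1 / sqrt(eg$values[keep]), sum(keep)) %*% t(eg$vectors[, keep, drop = FALSE])
  sa_w <- white %*% sa %*% t(white)
  rot <- eigen((sa_w + t(sa_w)) / 2, symmetric = TRUE)
  full <- t(rot$vectors) %*% white          # components x channels
  lambda <- pmin(pmax(rot$values, 0), 1)    # class-A share per component

  # deterministic sign: largest-|coefficient| of each row positive
  fix_sign <- function(w) {
    for (i in seq_len(nrow(w))) {
      j <- which.max(abs(w[i, ]))
      if (w[i, j] < 0) w[i, ] <- -w[i, ]
    }
    w
  }
  full <- fix_sign(full)
  sel <- c(seq_len(m), seq(nrow(full) - m + 1, nrow(full)))
  seg <- if (inherits(cov_A, "csp_cov")) cov_A$segment else NULL
  pair <- c(if (inherits(cov_A, "csp_cov")) cov_A$task else "A",
            if (inherits(cov_B, "csp_cov")) cov_B$task else "B")
  structure(list(
    filters = full[sel, , drop = FALSE],
    full_transform = full,
    eigenvalues = lambda,
    m = m,
    task_pair = pair,
    band = c(8, 30),
    train_segment = seg,
    channel_labels = colnames(sa)
  ), class = "csp_model")
}

#' @export
print.csp_model <- function(x, ...) {
  cat(sprintf(
    "<csp_model> %s vs %s: %d filters over %d channels; eigenvalue range [%.3f, %.3f]\n",
    x$task_pair[1], x$task_pair[2], nrow(x$filters), ncol(x$filters),
    min(x$eigenvalues), max(x$eigenvalues)))
  invisible(x)
}

#' Extract log-normalized variance features
#'
#' Projects each trial's segment through the `2m` CSP filters, computes the
#' variance of each projection over the segment, normalizes by the sum of
#' the `2m` variances, and takes the natural logarithm. By construction the
#' exponentials of each trial's feature vector sum to one.
#'
#' @param model A `csp_model`.
#' @param epochs An `epoch_set` whose channels match the model's training
#'   channels in count and order.
#' @param segment Numeric `(start_s, end_s)` relative to trial onset;
#'   defaults to the model's training segment.
#' @return Numeric matrix (trials x `2m`) of features; row names are trial
#'   indices, with the segment attached as attribute `"segment"`.
#' @export
extract_features <- function(model, epochs, segment = model$train_segment) {
  if (is.null(segment)) stop_mt("no segment given and model has no training segment")
  if (!is.null(model$channel_labels) &&
      !identical(as.character(model$channel_labels),
                 as.character(epochs$channel_labels))) {
    stop_mt("channel mismatch: model trained on [%s], epochs have [%s]",
            paste(model$channel_labels, collapse = ","),
            paste(epochs$channel_labels, collapse = ","))
  }
  if (ncol(model$filters) != dim(epochs$data)[2]) {
    stop_mt("channel count mismatch: model expects %d, epochs have %d",
            ncol(model$filters), dim(epochs$data)[2])
  }
  cflat <- trial_segment_cov_flat(epochs, segment)
  feats <- features_from_flat(model, cflat)
  rownames(feats) <- seq_len(nrow(feats))
  attr(feats, "segment") <- segment
  feats
}

#' Serialize a CSP model (with optional LDA stage) to a JSON artifact
#'
#' @param model A `csp_model`.
#' @param path Output path.
#' @param lda Optional `lda_model` stored alongside.
#' @return `path`, invisibly.
#' @export
write_csp_model <- function(model, path, lda = NULL) {
  obj <- list(
    filters = model$filters,
    full_transform = model$full_transform,
    eigenvalues = model$eigenvalues,
    m = model$m,
    task_pair = model$task_pair,
    band = model$band,
    train_segment = model$train_segment,
    channel_labels = model$channel_labels
  )
  if (!is.null(lda)) {
    obj$lda <- list(weights = lda$weights, bias = lda$bias,
                    label_map = lda$label_map, trained_on = lda$trained_on)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a serialized CSP (+ LDA) model artifact
#'
#' @param path Path written by [write_csp_model()].
#' @return A `csp_model`; if an LDA stage was stored it is attached as
#'   element `lda` (class `lda_model`).
#' @export
read_csp_model <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- structure(list(
    filters = as.matrix(raw$filters),
    full_transform = as.matrix(raw$full_transform),
    eigenvalues = as.numeric(raw$eigenvalues),
    m = as.integer(raw$m),
    task_pair = raw$task_pair,
    band = as.numeric(raw$band),
    train_segment = raw$train_segment,
    channel_labels = raw$channel_labels
  ), class = "csp_model")
  dimnames(model$filters) <- NULL
  dimnames(model$full_transform) <- NULL
  if (!is.null(raw$lda)) {
    model$lda <- structure(list(
      weights = as.numeric(raw$lda$weights),
      bias = as.numeric(raw$lda$bias),
      label_map = unlist(raw$lda$label_map),
      trained_on = raw$lda$trained_on
    ), class = "lda_model")
  }
  model
}
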