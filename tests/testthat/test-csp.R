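random_spd <- function(d) {
  a <- matrix(rnorm(d * d), d)
  crossprod(a) + 0.1 * diag(d)
}

test_that("class covariance estimates are unit-trace trial averages", {
  # channel-wise white noise: covariance approaches I / channels
  set.seed(1)
  nch <- 4
  data <- array(rnorm(60 * nch * 256), c(60, nch, 256))
  ep <- make_epochs(data, rep("SUB", 60))
  cov <- estimate_class_covariance(ep, "SUB", c(0, 1))
  expect_equal(cov$matrix, diag(nch) / nch, tolerance = 0.05)
  expect_equal(sum(diag(cov$matrix)), 1, tolerance = 1e-12)
  expect_equal(cov$n_trials, 60)

  # one common source on two channels with equal gain: rank-1, unit trace
  s <- rnorm(256)
  data2 <- array(0, c(2, 2, 256))
  data2[1, 1, ] <- s; data2[1, 2, ] <- s
  data2[2, 1, ] <- s; data2[2, 2, ] <- s
  ep2 <- make_epochs(data2, c("SUB", "SUB"))
  cov2 <- estimate_class_covariance(ep2, "SUB", c(0, 1))
  expect_equal(cov2$matrix, matrix(0.5, 2, 2), tolerance = 1e-10)

  # duplicating an identical trial leaves the average unchanged
  one_trial_cov <- {
    x <- data2[1, , ] - rowMeans(data2[1, , ])
    cm <- tcrossprod(x) / 255
    cm / sum(diag(cm))
  }
  expect_equal(cov2$matrix, one_trial_cov, tolerance = 1e-12)

  expect_error(estimate_class_covariance(ep2, "NAV", c(0, 1)), "at least 2")
  data3 <- data2
  data3[2, , ] <- 0
  ep3 <- make_epochs(data3, c("SUB", "SUB"))
  expect_error(estimate_class_covariance(ep3, "SUB", c(0, 1)), "zero variance")
  expect_error(estimate_class_covariance(ep2, "SUB", c(0, 2)), "outside")
})

test_that("already-diagonal covariances give the closed-form CSP solution", {
  model <- fit_csp(diag(c(0.8, 0.2)), diag(c(0.2, 0.8)), m = 1)
  expect_equal(model$eigenvalues, c(0.8, 0.2), tolerance = 1e-4)
  # filter rows select channel 1 then channel 2, up to sign/scale
  expect_gt(abs(model$filters[1, 1]) / abs(model$filters[1, 2]), 1e3)
  expect_gt(abs(model$filters[2, 2]) / abs(model$filters[2, 1]), 1e3)

  same <- fit_csp(diag(2) / 2, diag(2) / 2, m = 1)
  expect_equal(same$eigenvalues, c(0.5, 0.5), tolerance = 1e-6)

  expect_error(fit_csp(diag(2), diag(3)), "dimension")
  expect_error(fit_csp(diag(2), diag(2), m = 2), "exceed")
})

test_that("two-step whitening + rotation matches the generalized-eigen oracle", {
  set.seed(42)
  for (rep in 1:25) {
    d <- sample(2:10, 1)
    m <- sample(seq_len(d %/% 2), 1)
    sa <- random_spd(d)
    sb <- random_spd(d)
    model <- fit_csp(sa, sb, m = m)
    # regularization inside fit_csp is 1e-6-weighted: compare against the
    # oracle on the same regularized matrices
    ridge <- function(s) (1 - 1e-6) * s + 1e-6 * (sum(diag(s)) / d) * diag(d)
    ora <- geigen_csp_oracle(ridge(sa), ridge(sb))
    expect_equal(model$eigenvalues, ora$values, tolerance = 1e-8)
    sel <- c(seq_len(m), seq(d - m + 1, d))
    ang <- principal_angles(model$filters, ora$vectors[, sel, drop = FALSE])
    expect_lt(max(ang), 1e-6)
  }
})

test_that("the full transform simultaneously diagonalizes both classes", {
  set.seed(7)
  for (rep in 1:10) {
    d <- sample(3:8, 1)
    # the fitted transform diagonalizes the ridge-regularized covariances
    ridge <- function(s) (1 - 1e-6) * s + 1e-6 * (sum(diag(s)) / d) * diag(d)
    sa <- ridge(random_spd(d))
    sb <- ridge(random_spd(d))
    model <- fit_csp(sa, sb, m = 1, gamma = 0)
    w <- model$full_transform
    da <- w %*% sa %*% t(w)
    db <- w %*% sb %*% t(w)
    expect_lt(max(abs(da + db - diag(d))), 1e-8)
    expect_lt(max(abs(da - diag(diag(da)))), 1e-8)
    # eigenvalue pairing: class-A and class-B diagonals sum to one
    expect_equal(diag(da) + diag(db), rep(1, d), tolerance = 1e-8)
    expect_true(all(diff(model$eigenvalues) <= 1e-12))
    expect_true(all(model$eigenvalues >= 0 & model$eigenvalues <= 1))
  }
})

test_that("label swap reverses the eigenvalue spectrum, same subspace", {
  set.seed(3)
  sa <- random_spd(6)
  sb <- random_spd(6)
  ab <- fit_csp(sa, sb, m = 2)
  ba <- fit_csp(sb, sa, m = 2)
  expect_equal(ba$eigenvalues, rev(1 - ab$eigenvalues), tolerance = 1e-8)
  expect_lt(max(principal_angles(ab$filters, t(ba$filters))), 1e-6)
})

test_that("features are scale invariant and trial covariances drive CV equivalently", {
  ep <- planted_epochs(n_per_class = 6, seed = 4)
  ca <- estimate_class_covariance(ep, "SUB", c(0, 0.5))
  cb <- estimate_class_covariance(ep, "FEET", c(0, 0.5))
  model <- fit_csp(ca, cb, m = 2)
  f1 <- extract_features(model, ep, c(0, 0.5))

  ep_scaled <- ep
  ep_scaled$data <- ep$data * 3.7
  ca2 <- estimate_class_covariance(ep_scaled, "SUB", c(0, 0.5))
  model2 <- fit_csp(ca2, estimate_class_covariance(ep_scaled, "FEET", c(0, 0.5)), m = 2)
  expect_equal(model2$eigenvalues, model$eigenvalues, tolerance = 1e-10)
  f2 <- extract_features(model, ep_scaled, c(0, 0.5))
  expect_equal(f2, f1, tolerance = 1e-10)
})

test_that("log-variance features are normalized and match hand arithmetic", {
  ep <- planted_epochs(n_per_class = 4, seed = 9)
  ca <- estimate_class_covariance(ep, "SUB", c(0, 0.5))
  cb <- estimate_class_covariance(ep, "FEET", c(0, 0.5))
  model <- fit_csp(ca, cb, m = 2)
  feats <- extract_features(model, ep, c(0, 0.5))
  expect_equal(unname(rowSums(exp(feats))), rep(1, nrow(feats)),
               tolerance = 1e-10)

  # printed toy fixture: 2 channels x 4 samples, identity filters, m = 1
  toy <- array(0, c(1, 2, 4))
  toy[1, 1, ] <- c(1, 2, 3, 4)
  toy[1, 2, ] <- c(1, 1, 2, 2)
  ep_toy <- make_epochs(toy, "SUB", sampling_rate = 4, window = c(0, 1))
  id_model <- structure(list(filters = diag(2), m = 1,
                             channel_labels = NULL), class = "csp_model")
  v1 <- var(c(1, 2, 3, 4))             # 5/3
  v2 <- var(c(1, 1, 2, 2))             # 1/3
  got <- extract_features(id_model, ep_toy, c(0, 1))
  expect_equal(as.numeric(got),
               log(c(v1, v2) / (v1 + v2)), tolerance = 1e-12)

  # equal projection variances, m = 2: every feature is log(1/4)
  eq <- array(0, c(1, 4, 8))
  for (ch in 1:4) eq[1, ch, ] <- c(1, -1, 1, -1, 1, -1, 1, -1) * ch / ch
  ep_eq <- make_epochs(eq, "SUB", sampling_rate = 8, window = c(0, 1))
  id4 <- structure(list(filters = diag(4), m = 2,
                        channel_labels = NULL), class = "csp_model")
  f_eq <- extract_features(id4, ep_eq, c(0, 1))
  expect_equal(as.numeric(f_eq), rep(log(1 / 4), 4), tolerance = 1e-12)

  # channel mismatch is rejected with labels named
  ep_bad <- planted_epochs(n_per_class = 4, n_channels = 3, seed = 9)
  expect_error(extract_features(model, ep_bad, c(0, 0.5)), "mismatch")
})

test_that("model artifacts round-trip through serialization", {
  set.seed(10)
  model <- fit_csp(random_spd(5), random_spd(5), m = 2)
  model$channel_labels <- sprintf("CH%02d", 1:5)
  lda <- fit_lda(matrix(rnorm(20), 5), matrix(rnorm(20) + 2, 5),
                 positive_task = "SUB", negative_task = "FEET")
  path <- tempfile(fileext = ".json")
  write_csp_model(model, path, lda = lda)
  back <- read_csp_model(path)
  expect_equal(back$filters, model$filters, tolerance = 1e-12)
  expect_equal(back$eigenvalues, model$eigenvalues, tolerance = 1e-12)
  expect_equal(back$m, model$m)
  expect_equal(back$channel_labels, model$channel_labels)
  expect_equal(back$lda$weights, lda$weights, tolerance = 1e-12)
  expect_equal(back$lda$bias, lda$bias, tolerance = 1e-12)
})
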