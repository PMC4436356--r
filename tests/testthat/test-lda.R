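test_that("closed-form toys recover the Fisher discriminant", {
  # 1-D toy: A = {1, 2}, B = {-2, -1}: positive weight, zero bias
  model <- fit_lda(matrix(c(1, 2)), matrix(c(-2, -1)))
  expect_gt(model$weights, 0)
  expect_equal(model$bias, 0, tolerance = 1e-9)
  pred <- predict_lda(model, matrix(c(1, 2, -2, -1)))
  expect_equal(pred$label, c("A", "A", "B", "B"))

  # symmetric 2-D classes with means (+-1, 0): boundary through the origin
  xa <- rbind(c(1, 0.5), c(1, -0.5), c(1.5, 0), c(0.5, 0))
  xb <- -xa
  m2 <- fit_lda(xa, xb, positive_task = "SUB", negative_task = "FEET")
  expect_equal(m2$weights[2] / m2$weights[1], 0, tolerance = 1e-9)
  expect_gt(m2$weights[1], 0)
  expect_equal(m2$bias, 0, tolerance = 1e-9)

  expect_error(fit_lda(matrix(1), matrix(c(-1, -2))), "at least 2")
  expect_error(fit_lda(matrix(c(1, 2)), matrix(c(-1, -2), 1)), "dimensions differ")
})

test_that("fitted direction matches dense Fisher-criterion search within 1 degree", {
  set.seed(5)
  for (rep in 1:25) {
    na <- sample(3:5, 1)
    nb <- sample(3:5, 1)
    xa <- matrix(rnorm(2 * na), na) + matrix(c(1.5, 0.5), na, 2, byrow = TRUE)
    xb <- matrix(rnorm(2 * nb), nb)
    model <- fit_lda(xa, xb)
    ora <- fisher_direction_oracle(xa, xb)
    expect_lt(direction_angle_deg(model$weights, ora), 1)
  }
})

test_that("prediction thresholds scores at zero with negative ties", {
  model <- structure(list(weights = c(1, 0), bias = -0.5,
                          label_map = c(positive = "SUB", negative = "FEET")),
                     class = "lda_model")
  p <- predict_lda(model, c(0.4, 9.9))
  expect_equal(p$label, "FEET")
  expect_equal(p$score, -0.1, tolerance = 1e-12)
  # score exactly zero resolves to the negative class
  expect_equal(predict_lda(model, c(0.5, 0))$label, "FEET")
  expect_equal(predict_lda(model, c(0.6, 0))$label, "SUB")
  expect_error(predict_lda(model, c(1, 2, 3)), "dimension")
})

test_that("affine feature shifts move only the bias", {
  set.seed(6)
  xa <- matrix(rnorm(12), 6) + 2
  xb <- matrix(rnorm(12), 6)
  shift <- c(3.2, -1.4)
  base <- fit_lda(xa, xb)
  shifted <- fit_lda(sweep(xa, 2, -shift), sweep(xb, 2, -shift))
  expect_equal(shifted$weights, base$weights, tolerance = 1e-9)
  expect_equal(shifted$bias, base$bias - sum(base$weights * shift),
               tolerance = 1e-9)
  test_x <- matrix(rnorm(10), 5)
  expect_equal(predict_lda(shifted, sweep(test_x, 2, -shift))$label,
               predict_lda(base, test_x)$label)
})

test_that("bias re-adaptation changes the bias only and compensates mean drift", {
  set.seed(8)
  xa <- matrix(rnorm(8), 4) + 2
  xb <- matrix(rnorm(8), 4)
  model <- fit_lda(xa, xb)

  # idempotence: re-adapting on the training vectors restores the bias
  re0 <- rebias_lda(model, xa, xb, n_adapt = 4)
  expect_identical(re0$weights, model$weights)
  expect_equal(re0$bias, model$bias, tolerance = 1e-12)

  # constant day-2 shift: re-biased predictions on shifted data equal the
  # original predictions on unshifted data
  shift <- c(-0.8, 1.7)
  re <- rebias_lda(model, sweep(xa, 2, -shift), sweep(xb, 2, -shift),
                   n_adapt = 4)
  expect_identical(re$weights, model$weights)
  test_x <- matrix(rnorm(20), 10)
  p_orig <- predict_lda(model, test_x)
  p_re <- predict_lda(re, sweep(test_x, 2, -shift))
  expect_identical(p_re$label, p_orig$label)
  expect_equal(p_re$score, p_orig$score, tolerance = 1e-9)

  expect_error(rebias_lda(model, xa[1:3, ], xb, n_adapt = 4), "exactly 4")
  expect_error(rebias_lda(model, xa[, 1, drop = FALSE], xb[, 1, drop = FALSE],
                          n_adapt = 4), "dimension")
})

test_that("swapping class roles negates the discriminant and flips labels", {
  set.seed(9)
  xa <- matrix(rnorm(10), 5) + 1
  xb <- matrix(rnorm(10), 5)
  ab <- fit_lda(xa, xb, positive_task = "SUB", negative_task = "FEET")
  ba <- fit_lda(xb, xa, positive_task = "FEET", negative_task = "SUB")
  expect_equal(ba$weights, -ab$weights, tolerance = 1e-9)
  expect_equal(ba$bias, -ab$bias, tolerance = 1e-9)
  x <- matrix(rnorm(8), 4)
  pa <- predict_lda(ab, x)
  pb <- predict_lda(ba, x)
  # scores negate and the positive/negative roles flip, so the predicted
  # task is unchanged away from the decision boundary
  expect_equal(pb$score, -pa$score, tolerance = 1e-9)
  off_boundary <- abs(pa$score) > 1e-9
  expect_true(all((pa$label == pb$label)[off_boundary]))
})
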