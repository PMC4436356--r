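# Independent oracles: these re-derive the core quantities by a different
# algorithmic route than the package implementation.

# CSP oracle: generalized eigenproblem S_A v = lambda (S_A + S_B) v solved
# by Cholesky reduction of the composite (the implementation uses two-step
# eigendecomposition whitening + rotation instead).
geigen_csp_oracle <- function(sa, sb) {
  comp <- sa + sb
  u <- chol(comp)
  ui <- backsolve(u, diag(nrow(u)))
  s <- t(ui) %*% sa %*% ui
  eg <- eigen((s + t(s)) / 2, symmetric = TRUE)
  list(values = eg$values, vectors = ui %*% eg$vectors)
}

# Principal angles (radians) between the row space of f1 and the column
# space of v2.
principal_angles <- function(f1, v2) {
  q1 <- qr.Q(qr(t(f1)))
  q2 <- qr.Q(qr(v2))
  sv <- svd(crossprod(q1, q2))$d
  acos(pmin(pmax(sv, -1), 1))
}

# Fisher LDA oracle: dense search of the Fisher criterion
# J(w) = (w . (mu_A - mu_B))^2 / (w' S_w w) over directions on the unit
# circle (2-D feature spaces only), 0.05 degree resolution.
fisher_direction_oracle <- function(xa, xb) {
  mu_a <- colMeans(xa)
  mu_b <- colMeans(xb)
  sw <- crossprod(sweep(xa, 2, mu_a)) + crossprod(sweep(xb, 2, mu_b))
  angles <- seq(0, pi, by = 0.05 * pi / 180)
  j <- vapply(angles, function(a) {
    w <- c(cos(a), sin(a))
    (sum(w * (mu_a - mu_b)))^2 / drop(w %*% sw %*% w)
  }, 0)
  angles[which.max(j)]
}

# Angle (degrees) between two directions in the plane, sign/180-ambiguity
# removed.
direction_angle_deg <- function(w, angle) {
  a <- atan2(w[2], w[1]) %% pi
  d <- abs(a - (angle %% pi))
  min(d, pi - d) * 180 / pi
}

# Exact two-sided Wilcoxon signed-rank p by full enumeration of the 2^n
# sign assignments (no zeros/ties expected in the fixtures that use it).
wilcoxon_exact_oracle <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  stopifnot(n <= 14)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ws <- vapply(0:(2^n - 1), function(mask) {
    sum(r[bitwAnd(bitwShiftR(mask, 0:(n - 1)), 1L) == 1L])
  }, 0)
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-12)
}

# Permutation null for the Friedman statistic: permute each row
# independently, recompute the chi-square.
friedman_permutation_p <- function(perf, n_perm = 2000, seed = 1) {
  obs <- friedman_test(perf)$chi2
  set.seed(seed)
  ge <- 0
  for (b in seq_len(n_perm)) {
    shuf <- t(apply(perf, 1, sample))
    if (friedman_test(shuf)$chi2 >= obs - 1e-12) ge <- ge + 1
  }
  (ge + 1) / (n_perm + 1)
}
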