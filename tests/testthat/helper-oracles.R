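# Dense/brute-force oracles used across test files. These deliberately take
# the slow, obvious route (dense matrices, exhaustive enumeration) so they
# stay independent of the operator/solver code paths they check.

# Dense (n-1) x n first-difference matrix.
dense_D <- function(n) {
  D <- matrix(0, n - 1, n)
  for (i in seq_len(n - 1)) {
    D[i, i] <- 1
    D[i, i + 1] <- -1
  }
  D
}

# Dense band convolution matrix L for a peak-shape kernel.
dense_L <- function(n, shape) {
  k <- shape$kernel
  c0 <- shape$radius + 1L
  L <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_along(k)) {
      idx <- i - j + c0
      if (idx >= 1 && idx <= n) L[i, idx] <- k[j]
    }
  }
  L
}

# Dense B_mu (or boundary-corrected variant) from a baseline_operator.
dense_B <- function(op) jointdecon:::dense_baseline_matrix(op)

# Dense A_mu = I - B^{-1}.
dense_A <- function(op) diag(op$n) - solve(dense_B(op))

# Exhaustive active-set solver for min 1/2 x'Qx + q'x, x >= 0 (small n).
# Enumerates every subset of components pinned at zero, solves the reduced
# equality system, and keeps the feasible KKT point.
activeset_qp_nonneg <- function(Q, q) {
  n <- length(q)
  best <- NULL
  for (mask in 0:(2^n - 1)) {
    zero <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    free <- setdiff(seq_len(n), zero)
    x <- numeric(n)
    if (length(free) > 0) {
      xf <- tryCatch(solve(Q[free, free, drop = FALSE], -q[free]),
                     error = function(e) NULL)
      if (is.null(xf)) next
      x[free] <- xf
    }
    if (any(x[free] < -1e-12)) next            # primal feasibility
    g <- Q %*% x + q
    if (length(zero) > 0 && any(g[zero] < -1e-9)) next  # dual feasibility
    val <- 0.5 * sum(x * (Q %*% x)) + sum(q * x)
    if (is.null(best) || val < best$val) best <- list(x = x, val = val)
  }
  best$x
}

# Random symmetric positive-definite matrix.
random_spd <- function(n) {
  M <- matrix(stats::rnorm(n * n), n)
  crossprod(M) + diag(n) * 0.5
}

# Full joint objective of the additive model, evaluated densely.
dense_joint_objective <- function(y, x_b, x_p, shape, mu, lambda1, lambda2) {
  L <- dense_L(length(y), shape)
  0.5 * sum((y - x_b - L %*% x_p)^2) +
    0.5 * mu * sum((dense_D(length(y)) %*% x_b)^2) +
    lambda1 * sum(abs(x_p)) + 0.5 * lambda2 * sum(x_p^2)
}
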