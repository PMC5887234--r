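test_that("D'D bands match the printed stencil and the dense product D'D", {
  b3 <- build_dtd(3)
  expect_equal(b3$d, c(1, 2, 1))
  expect_equal(b3$dl, c(0, -1, -1))
  expect_equal(b3$du, c(-1, -1, 0))

  b2 <- build_dtd(2)
  expect_equal(b2$d, c(1, 1))
  expect_equal(b2$du, c(-1, 0))

  for (n in c(4, 7, 12)) {
    ref <- crossprod(dense_D(n))
    b <- build_dtd(n)
    M <- diag(b$d)
    for (i in seq_len(n - 1)) {
      M[i, i + 1] <- b$du[i]
      M[i + 1, i] <- b$dl[i + 1]
    }
    expect_equal(M, unname(ref))
  }
  expect_error(build_dtd(1), "n")
})

test_that("Thomas solve agrees with dense solve and B_0 is the identity", {
  expect_equal(solve_b(baseline_operator(0, n = 8), 1:8), as.numeric(1:8))
  set.seed(11)
  for (rep in 1:10) {
    n <- sample(3:50, 1)
    mu <- stats::runif(1, 0, 100)
    op <- baseline_operator(mu, n = n)
    rhs <- stats::rnorm(n)
    x <- solve_b(op, rhs)
    xd <- solve(dense_B(op), rhs)
    expect_lt(max(abs(x - xd)) / max(abs(xd)), 1e-10)
  }
  expect_error(solve_b(baseline_operator(1, n = 3), c(1, NA, 2)), "finite")
})

test_that("A_mu limits: zero at mu = 0, mean-centering as mu -> Inf, D'D slope", {
  set.seed(21)
  v <- stats::rnorm(500)
  expect_equal(apply_a(baseline_operator(0, n = 500), v), numeric(500))
  # infinite-smoothness limit removes exactly the mean
  lim <- apply_a(baseline_operator(1e12, n = 500), v)
  expect_lt(max(abs(lim - (v - mean(v)))), 1e-4)
  # small-mu Taylor expansion A_mu = mu D'D + o(mu): remainder is O(mu^2)
  DtDv <- as.numeric(crossprod(dense_D(500)) %*% v)
  for (mu in c(1e-6, 1e-5)) {
    err <- max(abs(apply_a(baseline_operator(mu, n = 500), v) - mu * DtDv))
    expect_lt(err, 100 * mu^2 * max(abs(v)))
  }
})

test_that("A_mu is symmetric with spectrum in [0, 1) and a constant null space", {
  set.seed(31)
  for (mu in c(0.5, 10, 1e4)) {
    op <- baseline_operator(mu, n = 15)
    u <- stats::rnorm(15); v <- stats::rnorm(15)
    expect_equal(sum(u * apply_a(op, v)), sum(v * apply_a(op, u)),
                 tolerance = 1e-10)
    ev <- eigen(dense_A(op), symmetric = TRUE, only.values = TRUE)$values
    expect_true(all(ev >= -1e-12 & ev < 1))
    expect_equal(sum(abs(ev) < 1e-9), 1)           # single zero eigenvalue
    expect_equal(apply_a(op, rep(3, 15)), numeric(15), tolerance = 1e-12)
  }
})

test_that("convolution matches the dense band matrix and is linear", {
  set.seed(41)
  sh <- peak_shape(sigma = 2.5)
  n <- 40
  L <- dense_L(n, sh)
  a <- stats::rnorm(n); b <- stats::rnorm(n)
  expect_equal(convolve_peaks(a, sh), as.numeric(L %*% a))
  expect_equal(convolve_peaks(a, sh, adjoint = TRUE), as.numeric(t(L) %*% a))
  expect_equal(convolve_peaks(a + b, sh),
               convolve_peaks(a, sh) + convolve_peaks(b, sh),
               tolerance = 1e-12)
  # unit impulse reproduces the kernel with peak value 1
  imp <- numeric(n); imp[20] <- 1
  out <- convolve_peaks(imp, sh)
  expect_equal(out[20], 1)
  expect_equal(max(out), 1)
  expect_error(convolve_peaks(1:3, peak_shape(kernel = rep(1, 9))), "kernel")
})

test_that("convolved benchmark peak list matches the analytic Gaussian sum", {
  x_p <- truth_peaks(500)
  sh <- peak_shape(sigma = 10)
  out <- convolve_peaks(x_p, sh)
  centers <- which(x_p > 0)
  i <- 1:500
  analytic <- rowSums(sapply(centers, function(m)
    x_p[m] * exp(-0.5 * ((i - m) / 10)^2)))
  # agreement up to kernel truncation at 4 sigma
  expect_lt(max(abs(out - analytic)), 3 * exp(-8) * max(x_p))
})

test_that("Gaussian kernels are unit-amplitude, symmetric, truncated at 4 sigma", {
  sh <- peak_shape(sigma = 10)
  expect_equal(sh$radius, 40L)
  expect_equal(max(sh$kernel), 1)
  expect_equal(sh$kernel, rev(sh$kernel), tolerance = 1e-12)
  # sigma in axis units is converted through the axis step
  sh2 <- peak_shape(sigma = 5, step = 0.5)
  expect_equal(sh2$radius, 40L)
})

test_that("boundary-corrected operator has the printed structure", {
  y <- c(4, 5, 6, 7, 8)
  op <- build_boundary_corrected(2, y, 1, 2)
  expect_equal(op$d, c(3, 5, 5, 5, 3))
  expect_equal(op$du[1], 0)           # zero at (1, 2)
  expect_equal(op$dl[5], 0)           # zero at (5, 4)
  expect_equal(op$du[2:3], c(-2, -2))
  expect_equal(op$y_tilde, c(3 * 1, 5 + 2 * 1, 6, 7 + 2 * 2, 3 * 2))
  # zero boundary values keep the interior of y and zero the ends
  op0 <- build_boundary_corrected(7, y, 0, 0)
  expect_equal(op0$y_tilde[2:4], c(y[2], y[3], y[4]))
  expect_equal(op0$y_tilde[c(1, 5)], c(0, 0))
  expect_error(build_boundary_corrected(2, y, NaN, 1), "finite")
})

test_that("constrained solve pins the baseline ends to the imposed values", {
  set.seed(51)
  y <- stats::rnorm(30) + 10
  for (mu in c(10, 1000, 1e6)) {
    op <- build_boundary_corrected(mu, y, 3.5, -1.25)
    xb <- solve_b(op, op$y_tilde)   # no peaks: x_b = B~^{-1} y~
    expect_equal(xb[1], 3.5, tolerance = 1e-9)
    expect_equal(xb[30], -1.25, tolerance = 1e-9)
  }
})

test_that("spectra validate axis spacing and finiteness", {
  expect_error(mass_spectrum(c(1, 2, 4), 1:3), "uniform")
  expect_error(mass_spectrum(c(2, 1, 3), 1:3), "increasing")
  expect_error(mass_spectrum(1:3, c(1, Inf, 3)), "finite")
  s <- mass_spectrum(seq(100, 200, by = 0.5), rep(1, 201))
  expect_equal(s$step, 0.5)
})
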