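make_small_fixture <- function(n = 40, seed = 1, noise = 0.05) {
  set.seed(seed)
  sh <- peak_shape(sigma = 2)
  x_p <- numeric(n); x_p[c(12, 27)] <- c(2, 1)
  base <- 1 + 0.02 * seq_len(n)
  y <- base + convolve_peaks(x_p, sh) + stats::rnorm(n, sd = noise)
  list(spec = mass_spectrum(seq_len(n), y), shape = sh, x_p = x_p,
       base = base)
}

test_that("reduced objective matches dense assembly in the unconstrained case", {
  fx <- make_small_fixture(n = 30)
  mu <- 8; l1 <- 0.3; l2 <- 0.1
  prob <- reduced_objective_terms(fx$spec, fx$shape, mu, l1, l2,
                                  boundary = NULL)
  n <- 30
  L <- dense_L(n, fx$shape)
  A <- dense_A(baseline_operator(mu, n = n))
  Qd <- t(L) %*% A %*% L + l2 * diag(n)
  qd <- l1 - as.numeric(t(L) %*% A %*% fx$spec$intensity)
  expect_equal(prob$q, qd, tolerance = 1e-10)
  Qfun <- jointdecon:::decon_operator_fun(prob$apply_Q)
  for (i in 1:4) {
    v <- stats::rnorm(n)
    expect_equal(Qfun(v), as.numeric(Qd %*% v), tolerance = 1e-10)
  }
})

test_that("disabling the boundary modification recovers the plain linear term", {
  fx <- make_small_fixture(n = 35)
  plain <- reduced_objective_terms(fx$spec, fx$shape, 5, 0.2, 0.1, NULL)
  # imposing y~ == y via boundary values equal to the data endpoints changes
  # only the first/last rows; interior of q must stay close to the plain form
  yb <- fx$spec$intensity[c(1, 35)]
  corr <- reduced_objective_terms(fx$spec, fx$shape, 5, 0.2, 0.1, yb)
  expect_equal(length(plain$q), length(corr$q))
})

test_that("eliminated baseline zeroes the full-model gradient", {
  set.seed(141)
  n <- 45
  fx <- make_small_fixture(n = n)
  sh <- fx$shape
  mu <- 12
  for (i in 1:5) {
    x_p <- abs(stats::rnorm(n)) * stats::rbinom(n, 1, 0.1)
    resid <- fx$spec$intensity - convolve_peaks(x_p, sh)
    xb <- solve_b(baseline_operator(mu, n = n), resid)
    # gradient of the joint objective in x_b: B xb - (y - L x_p)
    g <- as.numeric(dense_B(baseline_operator(mu, n = n)) %*% xb) - resid
    expect_lt(max(abs(g)), 1e-10 * max(1, max(abs(resid))))
  }
})

test_that("joint and reduced objectives differ by the constant -1/2 y'Ay", {
  set.seed(151)
  n <- 40
  fx <- make_small_fixture(n = n)
  y <- fx$spec$intensity
  sh <- fx$shape
  mu <- 20; l1 <- 0.4; l2 <- 0.1
  A <- dense_A(baseline_operator(mu, n = n))
  L <- dense_L(n, sh)
  Bop <- baseline_operator(mu, n = n)
  C_expected <- -0.5 * sum(y * (A %*% y))
  diffs <- sapply(1:10, function(i) {
    x_p <- abs(stats::rnorm(n)) * stats::rbinom(n, 1, 0.15)
    xb_hat <- solve_b(Bop, y - convolve_peaks(x_p, sh))
    J_full <- dense_joint_objective(y, xb_hat, x_p, sh, mu, l1, l2)
    J_red <- 0.5 * sum(x_p * (t(L) %*% A %*% L %*% x_p + l2 * x_p)) -
      sum(x_p * (t(L) %*% A %*% y - l1))
    J_red - J_full
  })
  expect_equal(diffs, rep(C_expected, 10),
               tolerance = 1e-8 * abs(C_expected))
})

test_that("support extraction keeps mixed-strict local maxima and plateaus", {
  expect_equal(extract_support(c(0, 1, 0)), 2L)
  expect_equal(extract_support(c(0, 1, 1, 0)), c(2L, 3L))
  expect_equal(extract_support(numeric(5)), integer(0))
  expect_equal(extract_support(c(2, 1, 0, 0, 3)), c(1L, 5L))  # one-sided ends
  expect_equal(extract_support(c(0, 1, 0, 2, 0), min_peak_height = 1.5), 4L)
  # floor applied before the scan: a tall neighbour below the floor does not
  # suppress a smaller surviving maximum
  expect_equal(extract_support(c(0, 0.4, 0.5, 2, 0), min_peak_height = 1),
               4L)
})

test_that("stage 1 returns a near-zero peak list on a pure baseline", {
  n <- 120
  y <- mass_spectrum(seq_len(n), 3 + 0.01 * seq_len(n))
  sh <- peak_shape(sigma = 3)
  s1 <- stage1_select(y, sh, mu = 100, lambda1 = 1)
  expect_lt(max(s1$x_p), 1e-6 * max(y$intensity))
})

test_that("stage-1 l1 mass is non-increasing in lambda1", {
  sim <- simulate_spectrum(s = -1, sigma_noise = 0.5, seed = 3)
  masses <- sapply(c(0.2, 0.5, 1, 2, 4), function(l1) {
    s1 <- stage1_select(sim$spectrum, sim$shape, mu = 1000, lambda1 = l1,
                        max_iter = 2000)
    sum(s1$x_p)
  })
  expect_true(all(diff(masses) <= 1e-6 * masses[1]))
})

test_that("debiasing raises the selection-shrunk heights", {
  sim <- simulate_spectrum(s = -1, sigma_noise = 0.3, seed = 5)
  fit <- deconvolve(sim$spectrum, sim$shape, mu = 1000, lambda1 = 1)
  expect_gte(sum(fit$peaks), sum(fit$stage1_peaks) - 1e-8)
})

test_that("stage 2 on the true support recovers interior heights within 2%", {
  sim <- simulate_spectrum(s = -1, sigma_noise = 0, seed = 1)
  sup <- which(sim$peaks > 0)
  # small mu: the baseline is flexible enough not to leak under the peak
  # clusters, so the debiased heights isolate the pure estimation error
  s2 <- stage2_debias(sim$spectrum, sim$shape, sup, mu = 10,
                      boundary = c(sim$baseline[1], sim$baseline[500]),
                      max_iter = 4000)
  expect_equal(s2$x_p[sup], sim$peaks[sup], tolerance = 0.02)
  expect_equal(sum(s2$x_p[-sup]), 0)
  # empty support degrades gracefully
  expect_warning(z <- stage2_debias(sim$spectrum, sim$shape, integer(0),
                                    mu = 1000), "empty")
  expect_equal(z$x_p, numeric(500))
})

test_that("recovered baseline obeys the operator limits", {
  set.seed(161)
  y <- mass_spectrum(1:80, stats::rnorm(80) + 5)
  # mu = 0: baseline equals the data exactly
  b0 <- recover_baseline(y, numeric(80), mu = 0,
                         shape = peak_shape(sigma = 2), boundary = NULL)
  expect_equal(b0, y$intensity, tolerance = 1e-9)
  # mu -> Inf, unconstrained: baseline tends to the spectrum mean
  binf <- recover_baseline(y, numeric(80), mu = 1e12,
                           shape = peak_shape(sigma = 2), boundary = NULL)
  expect_equal(binf, rep(mean(y$intensity), 80), tolerance = 1e-3)
})

test_that("boundary-corrected fits pin the baseline endpoints exactly", {
  sim <- simulate_spectrum(s = -1, sigma_noise = 1, seed = 2)
  yb <- c(sim$baseline[1], sim$baseline[500])
  for (mu in c(10, 1000, 1e6)) {
    fit <- deconvolve(sim$spectrum, sim$shape, mu = mu, lambda1 = 2,
                      boundary = yb, max_iter = 600)
    expect_lt(abs(fit$baseline[1] - yb[1]), 1e-9 * (1 + abs(yb[1])))
    expect_lt(abs(fit$baseline[500] - yb[2]), 1e-9 * (1 + abs(yb[2])))
  }
})

test_that("joint fit tracks the true baseline without ascent below peaks", {
  sim <- simulate_spectrum(s = -1, sigma_noise = 1, seed = 4)
  fit <- deconvolve(sim$spectrum, sim$shape, mu = 1000, lambda1 = 2,
                    max_iter = 2000)
  interior <- 30:470
  err2 <- mean(abs(fit$baseline[interior] - sim$baseline[interior]))
  expect_lt(err2, 0.35)   # a fraction of the noise sd
  # the stage-1 baseline (biased by shrunk peaks) sits higher under peaks
  b1 <- recover_baseline(sim$spectrum, fit$stage1_peaks, mu = 1000,
                         shape = sim$shape, boundary = fit$config$boundary)
  under <- which(convolve_peaks(sim$peaks, sim$shape) > 0.5)
  expect_gt(mean(b1[under]), mean(fit$baseline[under]))
})

test_that("deconvolve handles degenerate input and records a full result", {
  n <- 60
  flat <- mass_spectrum(seq_len(n), numeric(n))
  fit <- suppressWarnings(deconvolve(flat, peak_shape(sigma = 2), mu = 10,
                                     lambda1 = 0.5, boundary = NULL))
  expect_equal(fit$peaks, numeric(n))
  expect_equal(fit$baseline, numeric(n), tolerance = 1e-12)
  expect_s3_class(fit, "maldi_deconv")
  expect_equal(length(fit$residual), n)
})

test_that("noise-free benchmark run finds every peak and a near-zero merit", {
  sim <- simulate_spectrum(s = -1, sigma_noise = 0, seed = 1)
  t0 <- Sys.time()
  fit <- deconvolve(sim$spectrum, sim$shape, mu = 200, lambda1 = 0.6,
                    max_iter = 3000)
  elapsed <- as.numeric(Sys.time() - t0, units = "secs")
  pk <- coef(fit)
  expect_equal(nrow(pk), 10)
  for (m in which(sim$peaks > 0)) expect_lte(min(abs(pk$channel - m)), 2)
  expect_lte(merit_ee(fit$peaks, sim$peaks, sim$shape), 0.05)
  expect_lt(elapsed, 10)
})

test_that("fit accessors are consistent: fitted + residuals reconstruct y", {
  sim <- simulate_spectrum(s = -1, sigma_noise = 0.4, seed = 6)
  fit <- deconvolve(sim$spectrum, sim$shape, mu = 1000, lambda1 = 1,
                    max_iter = 600)
  expect_equal(fitted(fit) + residuals(fit), sim$spectrum$intensity,
               tolerance = 1e-12)
  pk <- coef(fit)
  expect_true(all(pk$height > 0))
  expect_equal(pk$position, sim$spectrum$axis[pk$channel])
  s <- summary(fit)
  expect_output(print(s), "peaks")
})
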