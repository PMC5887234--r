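#' Savitzky-Golay smoothing
#'
#' Moving least-squares smoother: each sample is replaced by the value at
#' its own position of a degree-`degree` polynomial fitted to the
#' surrounding `window` samples. Interior samples use a precomputed
#' convolution stencil; near the edges the polynomial is refitted on the
#' truncated window.
#'
#' @param y Numeric vector.
#' @param window Odd window length (> `degree`).
#' @param degree Polynomial degree.
#' @return Smoothed vector of the same length.
#' @export
savitzky_golay <- function(y, window = 39, degree = 3) {
  y <- as.numeric(y)
  n <- length(y)
  window <- as.integer(window)
  if (window %% 2 == 0) stop("`window` must be odd")
  if (window <= degree) stop("`window` must exceed `degree`")
  if (window > n) stop("`window` must not exceed the signal length")
  h <- (window - 1L) %/% 2L

  # interior stencil: first row of (X'X)^{-1} X' at offset 0
  X <- outer(-h:h, 0:degree, "^")
  w <- solve(crossprod(X), t(X))[1, ]
  out <- numeric(n)
  mid <- (h + 1):(n - h)
  out[mid] <- vapply(mid, function(i) sum(w * y[(i - h):(i + h)]), 0)

  for (i in seq_len(h)) {                    # truncated-window edges
    for (side in c("left", "right")) {
      j <- if (side == "left") i else n - i + 1L
      lo <- max(1L, j - h); hi <- min(n, j + h)
      off <- (lo:hi) - j
      d <- min(degree, length(off) - 1L)
      Xe <- outer(off, 0:d, "^")
      out[j] <- qr.solve(Xe, y[lo:hi])[1]
    }
  }
  out
}

#' SNIP baseline estimation
#'
#' Statistics-sensitive nonlinear iterative peak clipping: for window
#' half-widths `m = 1, ..., m_snip`, each interior point is replaced by the
#' minimum of itself and the average of its two neighbours at distance `m`.
#' The result is a lower envelope of the (previously smoothed) spectrum;
#' the single parameter `m_snip` should exceed the peak half-width.
#'
#' @param y_smooth Smoothed spectrum vector.
#' @param m_snip Number of clipping iterations (max half-width); must be
#'   below `length(y_smooth) / 2`.
#' @return Baseline vector, pointwise `<= y_smooth`.
#' @export
snip_baseline <- function(y_smooth, m_snip) {
  b <- as.numeric(y_smooth)
  n <- length(b)
  m_snip <- as.integer(m_snip)
  if (m_snip < 1) stop("`m_snip` must be >= 1")
  if (m_snip >= n / 2) stop("`m_snip` must be below n / 2")
  for (m in seq_len(m_snip)) {
    i <- (m + 1):(n - m)
    b[i] <- pmin(b[i], 0.5 * (b[i - m] + b[i + m]))
  }
  b
}

#' Classical sparse deconvolution of a baseline-corrected spectrum
#'
#' The usual sparse nonnegative deconvolution
#' `argmin_{x_p >= 0} 1/2 ||y - L x_p||^2 + lambda1 ||x_p||_1 +
#' lambda2/2 ||x_p||^2`, solved with the same projected Barzilai-Borwein
#' solver and the same two-pass scheme as the joint method: selection with
#' a strong `lambda1`, then support-restricted debiasing with the penalty
#' removed.
#'
#' @param y_corrected Baseline-subtracted intensity vector.
#' @param shape A [peak_shape()].
#' @param lambda1 Sparsity weight of the selection pass.
#' @param lambda2 Ridge weight (default 0.1).
#' @param tol,max_iter Solver controls.
#' @param min_peak_height Support floor; default `1e-8 * max(|y|)`.
#' @return A list with `peaks` (debiased), `stage1_peaks`, `support` and
#'   `reports`.
#' @export
classic_deconvolve <- function(y_corrected, shape, lambda1, lambda2 = 0.1,
                               tol = NULL, max_iter = 5000,
                               min_peak_height = NULL) {
  yv <- as.numeric(y_corrected)
  stopifnot(inherits(shape, "peak_shape"))
  n <- length(yv)
  if (is.null(min_peak_height)) min_peak_height <- 1e-8 * max(abs(yv))

  Lty <- convolve_peaks(yv, shape, adjoint = TRUE)
  p1 <- qp_problem(decon_operator(shape$kernel, lambda2),
                   q = lambda1 - Lty, lower = 0, upper = Inf)
  rep1 <- solve_pbb(p1, tol = tol, max_iter = max_iter)
  support <- extract_support(rep1$solution, min_peak_height)

  if (length(support) == 0) {
    warning("empty peak support; returning a zero peak vector")
    return(list(peaks = numeric(n), stage1_peaks = rep1$solution,
                support = support, reports = list(stage1 = rep1,
                                                  stage2 = NULL)))
  }
  upper <- numeric(n); upper[support] <- Inf
  p2 <- qp_problem(decon_operator(shape$kernel, 0),
                   q = -Lty, lower = 0, upper = upper)
  x0 <- numeric(n); x0[support] <- rep1$solution[support]
  rep2 <- solve_pbb(p2, x0 = x0, tol = tol, max_iter = max_iter)
  list(peaks = rep2$solution, stage1_peaks = rep1$solution,
       support = support, reports = list(stage1 = rep1, stage2 = rep2))
}

#' Sequential pipeline: smooth, clip the baseline, deconvolve
#'
#' The classical chained procedure used as the comparison method:
#' Savitzky-Golay smoothing, SNIP baseline estimation on the smoothed
#' spectrum, subtraction of that baseline from the original spectrum, then
#' sparse nonnegative deconvolution ([classic_deconvolve()]) with the same
#' two-pass debiasing as the joint method. Negative values left by the
#' subtraction are kept; the nonnegativity constraint on the peak list
#' handles them.
#'
#' @inheritParams deconvolve
#' @param m_snip SNIP window parameter (clipping iterations).
#' @param m_sg Savitzky-Golay window (default 39).
#' @param sg_degree Savitzky-Golay polynomial degree (default 3).
#' @return An object of class `"maldi_deconv"` (`method = "sequential"`)
#'   whose `baseline` is the SNIP estimate; extra fields `smoothed` (the
#'   SG-filtered spectrum).
#' @export
deconvolve_sequential <- function(y, shape, m_snip, lambda1, lambda2 = 0.1,
                                  m_sg = 39, sg_degree = 3, tol = NULL,
                                  max_iter = 5000, min_peak_height = NULL) {
  y <- as_mass_spectrum(y)
  yv <- y$intensity
  smoothed <- savitzky_golay(yv, window = m_sg, degree = sg_degree)
  baseline <- snip_baseline(smoothed, m_snip)
  corrected <- yv - baseline
  fit <- classic_deconvolve(corrected, shape, lambda1 = lambda1,
                            lambda2 = lambda2, tol = tol,
                            max_iter = max_iter,
                            min_peak_height = min_peak_height)
  residual <- yv - baseline - convolve_peaks(fit$peaks, shape)
  structure(list(
    peaks = fit$peaks, baseline = baseline, support = fit$support,
    stage1_peaks = fit$stage1_peaks, reports = fit$reports,
    residual = residual, spectrum = y, shape = shape, smoothed = smoothed,
    method = "sequential",
    config = list(m_snip = m_snip, lambda1 = lambda1, lambda2 = lambda2,
                  m_sg = m_sg, sg_degree = sg_degree),
    call = match.call()), class = "maldi_deconv")
}
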