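#' Reduced quadratic objective of the joint model
#'
#' Eliminating the baseline in closed form from the joint fit leaves a
#' bound-constrained quadratic in the peak list alone:
#' `Q = lambda2 I + L' A_mu L` and
#' `q = lambda1 1 - L' A_mu y` (plain form), or, with imposed baseline
#' boundary values, the boundary-corrected
#' `q = lambda1 1 - L' A~_mu y~ - L' (y - y~)` built from the modified
#' operator `A~_mu` and modified data `y~`. `Q` is returned as an implicit
#' operator (convolution, tridiagonal solve, adjoint convolution).
#'
#' @param y A [mass_spectrum()] (or anything [mass_spectrum()] accepts).
#' @param shape A [peak_shape()].
#' @param mu Baseline smoothness weight (> 0).
#' @param lambda1 Sparsity weight (>= 0).
#' @param lambda2 Ridge weight (>= 0).
#' @param boundary `NULL` for the plain form, or `c(ybar1, ybarn)`.
#' @return A [qp_problem()] with bounds `[0, Inf)` and, attached as
#'   attribute `"baseline_op"`, the [baseline_operator()] used.
#' @export
reduced_objective_terms <- function(y, shape, mu, lambda1, lambda2,
                                    boundary = NULL) {
  y <- as_mass_spectrum(y)
  stopifnot(inherits(shape, "peak_shape"))
  if (!is.finite(mu) || mu <= 0) stop("`mu` must be > 0")
  if (lambda1 < 0 || lambda2 < 0) stop("penalty weights must be >= 0")
  yv <- y$intensity
  n <- y$n
  op <- baseline_operator(mu, y = yv, boundary = boundary)
  Ay <- apply_a(op, op$y_tilde)
  q <- lambda1 - convolve_peaks(Ay, shape, adjoint = TRUE)
  if (op$constrained) {
    # extra linear term from the data modification; nonzero only near edges
    q <- q - convolve_peaks(yv - op$y_tilde, shape, adjoint = TRUE)
  }
  prob <- qp_problem(decon_operator(shape$kernel, lambda2, op),
                     q = q, lower = 0, upper = Inf)
  attr(prob, "baseline_op") <- op
  prob
}

#' First pass: sparse peak-support selection
#'
#' Solves the reduced QP under nonnegativity with a strong l1 penalty. The
#' solution is sparse and its heights are biased low; it is used only to
#' locate the peak support, which the second pass then re-fits.
#'
#' @inheritParams reduced_objective_terms
#' @param tol,max_iter Solver controls passed to [solve_pbb()].
#' @param x0 Starting point (default: the zero vector).
#' @return A list with `x_p` (the stage-1 peak vector) and `report` (the
#'   [solve_pbb()] fit).
#' @export
stage1_select <- function(y, shape, mu, lambda1, lambda2 = 0.1,
                          boundary = NULL, tol = NULL, max_iter = 5000,
                          x0 = NULL) {
  prob <- reduced_objective_terms(y, shape, mu, lambda1, lambda2, boundary)
  rep1 <- solve_pbb(prob, x0 = x0, tol = tol, max_iter = max_iter)
  list(x_p = rep1$solution, report = rep1)
}

#' Extract the peak support as local maxima
#'
#' A channel belongs to the support when its stage-1 height reaches
#' `min_peak_height` and it is a local maximum in the mixed
#' strict/non-strict sense: strictly above one neighbour and at least equal
#' to the other (so both ends of a two-sample plateau are kept). The floor
#' is applied before the scan; boundary channels use the one available
#' neighbour with a strict comparison.
#'
#' @param x_p_hat Stage-1 peak vector.
#' @param min_peak_height Height floor (absolute units).
#' @return Integer vector of support channel indices (possibly empty).
#' @export
extract_support <- function(x_p_hat, min_peak_height = 0) {
  x <- as.numeric(x_p_hat)
  n <- length(x)
  x[x < min_peak_height] <- 0
  if (n == 1) return(if (x >= min_peak_height && x > 0) 1L else integer(0))
  keep <- logical(n)
  if (n > 2) {
    i <- 2:(n - 1)
    left <- x[i - 1]; mid <- x[i]; right <- x[i + 1]
    keep[i] <- (mid > left & mid >= right) | (mid >= left & mid > right)
  }
  keep[1] <- x[1] > x[2]
  keep[n] <- x[n] > x[n - 1]
  which(keep & x >= min_peak_height & x > 0)
}

#' Second pass: support-restricted height debiasing
#'
#' Re-solves the reduced fit with the l1 penalty removed (`lambda1 = 0`,
#' and no ridge either), constraining the peak vector to zero off the
#' support (`l = u = 0`) and to `[0, Inf)` on it. This corrects the height
#' shrinkage induced by the stage-1 penalty.
#'
#' @inheritParams reduced_objective_terms
#' @param support Integer vector of support channels from
#'   [extract_support()].
#' @param tol,max_iter Solver controls.
#' @param x0 Starting point (default: zero off support).
#' @return A list with `x_p` and `report`. An empty support returns a zero
#'   vector with a warning.
#' @export
stage2_debias <- function(y, shape, support, mu, boundary = NULL,
                          tol = NULL, max_iter = 5000, x0 = NULL) {
  y <- as_mass_spectrum(y)
  if (length(support) == 0) {
    warning("empty peak support; returning a zero peak vector")
    return(list(x_p = numeric(y$n), report = NULL))
  }
  prob <- reduced_objective_terms(y, shape, mu, lambda1 = 0, lambda2 = 0,
                                  boundary = boundary)
  upper <- numeric(y$n)          # pinned to zero off the support
  upper[support] <- Inf
  prob$upper <- upper
  rep2 <- solve_pbb(prob, x0 = x0, tol = tol, max_iter = max_iter)
  list(x_p = rep2$solution, report = rep2)
}

#' Recover the baseline from a fitted peak list
#'
#' One tridiagonal solve of the closed-form baseline equation
#' `x_b = B_mu^{-1} (y - L x_p)`. With imposed boundary values the
#' equality-constraint modification is applied to the full residual
#' `y - L x_p` before the boundary-corrected solve, so the recovered
#' baseline endpoints equal the imposed values exactly (to floating point)
#' whatever the peak vector.
#'
#' @inheritParams reduced_objective_terms
#' @param x_p_hat Fitted peak vector.
#' @return The baseline vector.
#' @export
recover_baseline <- function(y, x_p_hat, mu, shape, boundary = NULL) {
  y <- as_mass_spectrum(y)
  rhs <- y$intensity - convolve_peaks(x_p_hat, shape)
  op <- baseline_operator(mu, y = rhs, boundary = boundary)
  solve_b(op, op$y_tilde)
}

resolve_boundary <- function(boundary, yv) {
  if (is.null(boundary)) return(NULL)
  if (is.character(boundary)) {
    if (identical(boundary, "auto")) {
      k <- min(10L, length(yv))
      return(c(stats::median(utils::head(yv, k)),
               stats::median(utils::tail(yv, k))))
    }
    if (identical(boundary, "off")) return(NULL)
    stop("`boundary` must be \"auto\", \"off\", NULL or a numeric pair")
  }
  as.numeric(boundary)
}

#' Joint baseline removal and sparse peak deconvolution
#'
#' Fits the additive model `y = x_b + L x_p + e`: a smooth baseline plus a
#' nonnegative sparse peak list blurred by a known peak shape, under
#' Gaussian noise. The baseline is eliminated in closed form through the
#' tridiagonal operator `B_mu = I + mu D'D`, leaving a box-constrained QP
#' in the peak list that is solved twice: a selection pass with the l1
#' penalty to locate peak centres, then a debiasing pass restricted to the
#' detected support with the penalty removed. The baseline is recovered
#' from the debiased peaks by one more tridiagonal solve.
#'
#' @param y A [mass_spectrum()], two-column data frame/matrix
#'   (axis, intensity), or bare numeric vector (channel axis assumed).
#' @param shape A [peak_shape()] describing the blur kernel.
#' @param mu Baseline smoothness weight (> 0). Larger values give stiffer
#'   baselines; as `mu -> Inf` the baseline tends to a constant.
#' @param lambda1 Sparsity weight of the selection pass; a strong value is
#'   recommended, heights are corrected afterwards.
#' @param lambda2 Small ridge weight (default 0.1) that improves solver
#'   conditioning with negligible effect on the solution.
#' @param boundary Baseline boundary handling: `"auto"` (default; imposes
#'   the medians of the first and last 10 intensities), a numeric pair
#'   `c(ybar1, ybarn)`, or `"off"` / `NULL` for the uncorrected operator.
#' @param tol Solver tolerance on the KKT violation (default
#'   `1e-6 * max(1, max(abs(q)))` per stage).
#' @param max_iter Iteration cap per stage (default 5000).
#' @param min_peak_height Support floor applied before the local-maximum
#'   scan; default `1e-8 * max(y)`.
#' @return An object of class `"maldi_deconv"`; see [coef.maldi_deconv()],
#'   [fitted.maldi_deconv()], [plot.maldi_deconv()]. Fields include
#'   `peaks` (debiased sparse peak vector), `baseline`, `support`,
#'   `stage1_peaks`, `reports` (one [solve_pbb()] report per stage) and
#'   `residual`.
#' @examples
#' sim <- simulate_spectrum(s = -1, sigma_noise = 0.5, seed = 1)
#' fit <- deconvolve(sim$spectrum, peak_shape(sigma = 10),
#'                   mu = 1000, lambda1 = 1)
#' coef(fit)
#' @export
deconvolve <- function(y, shape, mu, lambda1, lambda2 = 0.1,
                       boundary = "auto", tol = NULL, max_iter = 5000,
                       min_peak_height = NULL) {
  y <- as_mass_spectrum(y)
  stopifnot(inherits(shape, "peak_shape"))
  yv <- y$intensity
  bvals <- resolve_boundary(boundary, yv)
  if (is.null(min_peak_height)) min_peak_height <- 1e-8 * max(abs(yv))

  s1 <- stage1_select(y, shape, mu = mu, lambda1 = lambda1,
                      lambda2 = lambda2, boundary = bvals,
                      tol = tol, max_iter = max_iter)
  support <- extract_support(s1$x_p, min_peak_height)
  if (length(support) > 0) {
    x0 <- numeric(y$n)
    x0[support] <- s1$x_p[support]
    s2 <- stage2_debias(y, shape, support, mu = mu, boundary = bvals,
                        tol = tol, max_iter = max_iter, x0 = x0)
  } else {
    s2 <- list(x_p = numeric(y$n), report = NULL)
  }
  baseline <- recover_baseline(y, s2$x_p, mu = mu, shape = shape,
                               boundary = bvals)
  residual <- yv - baseline - convolve_peaks(s2$x_p, shape)

  structure(list(
    peaks = s2$x_p, baseline = baseline, support = support,
    stage1_peaks = s1$x_p,
    reports = list(stage1 = s1$report, stage2 = s2$report),
    residual = residual, spectrum = y, shape = shape,
    method = "joint",
    config = list(mu = mu, lambda1 = lambda1, lambda2 = lambda2,
                  boundary = bvals, min_peak_height = min_peak_height),
    call = match.call()), class = "maldi_deconv")
}
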