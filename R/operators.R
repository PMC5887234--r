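#' Bands of the second-difference penalty matrix D'D
#'
#' `D` is the (n-1) x n first-order finite-difference matrix; the penalty on
#' baseline roughness uses the tridiagonal `D'D` with diagonal
#' `(1, 2, ..., 2, 1)` and off-diagonals `-1`.
#'
#' @param n Dimension (at least 2).
#' @return A list with numeric vectors `dl`, `d`, `du` of length `n`: the
#'   sub-, main and super-diagonal (first element of `dl` and last of `du`
#'   are padding zeros).
#' @export
build_dtd <- function(n) {
  n <- as.integer(n)
  if (is.na(n) || n < 2) stop("`n` must be an integer >= 2")
  list(dl = c(0, rep(-1, n - 1)),
       d  = c(1, rep(2, max(n - 2, 0)), 1),
       du = c(rep(-1, n - 1), 0))
}

#' Baseline smoothing operator B_mu (and its boundary-corrected variant)
#'
#' The closed-form baseline estimate is `B_mu^{-1} (y - L x_p)` with
#' `B_mu = I + mu D'D`, a symmetric strictly diagonally dominant tridiagonal
#' matrix. With imposed boundary values `(ybar1, ybarn)` the first and last
#' rows are replaced by `(1 + mu, 0, ...)` / `(..., 0, 1 + mu)` and the data
#' vector is modified accordingly, so that the recovered baseline hits the
#' imposed values exactly.
#'
#' @param mu Nonnegative smoothness weight.
#' @param n Dimension; inferred from `y` when omitted.
#' @param y Data vector (required for the boundary-corrected form, where it
#'   is turned into the modified vector `y_tilde`).
#' @param boundary `NULL` for the plain operator, or a numeric pair
#'   `c(ybar1, ybarn)` of imposed baseline endpoint values.
#' @return An object of class `"baseline_operator"`: bands `dl`, `d`, `du`,
#'   the flag `constrained`, the imposed `boundary` values and `y_tilde`
#'   (equal to `y` when unconstrained, `NULL` when `y` is not given).
#' @seealso [solve_b()], [apply_a()], [build_boundary_corrected()]
#' @export
baseline_operator <- function(mu, n = NULL, y = NULL, boundary = NULL) {
  if (!is.finite(mu) || mu < 0) stop("`mu` must be a finite nonnegative number")
  if (is.null(n)) {
    if (is.null(y)) stop("give `n` or `y`")
    n <- length(y)
  }
  n <- as.integer(n)
  if (n < 2) stop("`n` must be >= 2")
  if (!is.null(y) && length(y) != n) stop("`y` has wrong length")

  if (is.null(boundary)) {
    dtd <- build_dtd(n)
    op <- list(mu = mu, n = n,
               dl = mu * dtd$dl, d = 1 + mu * dtd$d, du = mu * dtd$du,
               constrained = FALSE, boundary = NULL,
               y_tilde = y)
  } else {
    boundary <- as.numeric(boundary)
    if (length(boundary) != 2 || !all(is.finite(boundary)))
      stop("`boundary` must be two finite values c(ybar1, ybarn)")
    if (n < 3) stop("boundary correction needs n >= 3")
    d <- c(1 + mu, rep(1 + 2 * mu, n - 2), 1 + mu)
    du <- c(0, rep(-mu, max(n - 3, 0)), 0, 0)
    dl <- c(0, 0, rep(-mu, max(n - 3, 0)), 0)
    y_tilde <- NULL
    if (!is.null(y)) {
      y_tilde <- y
      y_tilde[1] <- (1 + mu) * boundary[1]
      y_tilde[2] <- y[2] + mu * boundary[1]
      y_tilde[n - 1] <- y[n - 1] + mu * boundary[2]
      y_tilde[n] <- (1 + mu) * boundary[2]
    }
    op <- list(mu = mu, n = n, dl = dl, d = d, du = du,
               constrained = TRUE, boundary = boundary, y_tilde = y_tilde)
  }
  structure(op, class = "baseline_operator")
}

#' Boundary-corrected baseline operator from data and endpoint values
#'
#' Convenience wrapper building the modified operator and modified data
#' vector in one step.
#'
#' @param mu Smoothness weight.
#' @param y Data vector (length at least 3).
#' @param ybar1,ybarn Imposed baseline values at the first and last channel.
#' @return A `"baseline_operator"` with `constrained = TRUE` and `y_tilde`
#'   filled in.
#' @export
build_boundary_corrected <- function(mu, y, ybar1, ybarn) {
  if (length(y) < 3) stop("`y` must have length >= 3")
  baseline_operator(mu, y = as.numeric(y), boundary = c(ybar1, ybarn))
}

#' Solve a tridiagonal baseline system
#'
#' Computes `B_mu^{-1} rhs` (or the boundary-corrected solve) by Thomas
#' elimination in O(n).
#'
#' @param op A [baseline_operator()].
#' @param rhs Numeric right-hand side of length `op$n`.
#' @return The solution vector.
#' @export
solve_b <- function(op, rhs) {
  stopifnot(inherits(op, "baseline_operator"))
  rhs <- as.numeric(rhs)
  if (length(rhs) != op$n) stop("`rhs` has wrong length")
  if (!all(is.finite(rhs))) stop("`rhs` must be finite")
  cpp_tridiag_solve(op$dl, op$d, op$du, rhs)
}

#' Apply the baseline-complement operator A_mu
#'
#' `A_mu = I - B_mu^{-1}` acts as a regularized second derivative for small
#' `mu` and as mean-centering in the limit `mu -> Inf`. It is applied as an
#' operator (one tridiagonal solve plus a subtraction), never formed densely.
#'
#' @param op A [baseline_operator()].
#' @param v Numeric vector of length `op$n`.
#' @return `v - solve_b(op, v)`.
#' @export
apply_a <- function(op, v) {
  stopifnot(inherits(op, "baseline_operator"))
  v <- as.numeric(v)
  if (length(v) != op$n) stop("`v` has wrong length")
  if (!all(is.finite(v))) stop("`v` must be finite")
  cpp_apply_A(op$dl, op$d, op$du, v)
}

# Dense matrix form, for small-n tests and verification only.
dense_baseline_matrix <- function(op) {
  n <- op$n
  B <- diag(op$d)
  for (i in seq_len(n - 1)) {
    B[i, i + 1] <- op$du[i]
    B[i + 1, i] <- op$dl[i + 1]
  }
  B
}
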