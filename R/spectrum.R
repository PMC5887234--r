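#' Construct a mass spectrum
#'
#' A spectrum is a uniformly sampled intensity vector with axis metadata
#' (m/z values or plain channel indices). All model operators work on the
#' channel grid, so the axis must be uniformly spaced.
#'
#' @param axis Strictly increasing numeric vector of axis positions.
#' @param intensity Numeric vector of intensities, same length as `axis`.
#' @return An object of class `"mass_spectrum"`: a list with elements
#'   `axis`, `intensity`, `n` and `step` (the constant axis spacing).
#' @examples
#' s <- mass_spectrum(1:100, sin(1:100 / 10) + 2)
#' s$step
#' @export
mass_spectrum <- function(axis, intensity) {
  axis <- as.numeric(axis)
  intensity <- as.numeric(intensity)
  if (length(axis) != length(intensity))
    stop("`axis` and `intensity` must have the same length")
  if (length(axis) < 2)
    stop("a spectrum needs at least 2 samples")
  if (!all(is.finite(axis)) || !all(is.finite(intensity)))
    stop("spectrum values must be finite")
  d <- diff(axis)
  if (any(d <= 0))
    stop("`axis` must be strictly increasing")
  step <- mean(d)
  if (max(abs(d - step)) > 1e-6 * abs(step))
    stop("`axis` must be uniformly spaced (relative tolerance 1e-6)")
  structure(list(axis = axis, intensity = intensity,
                 n = length(axis), step = step),
            class = "mass_spectrum")
}

as_mass_spectrum <- function(x) {
  if (inherits(x, "mass_spectrum")) return(x)
  if (is.matrix(x) || is.data.frame(x)) {
    if (ncol(x) < 2) stop("need two columns (axis, intensity)")
    return(mass_spectrum(x[[1]], x[[2]]))
  }
  if (is.numeric(x)) return(mass_spectrum(seq_along(x), x))
  stop("cannot interpret `x` as a spectrum")
}

#' @export
print.mass_spectrum <- function(x, ...) {
  cat(sprintf("Mass spectrum: %d channels, axis %g .. %g (step %g)\n",
              x$n, x$axis[1], x$axis[x$n], x$step))
  invisible(x)
}

#' Discrete peak-shape kernel
#'
#' The peak shape is the known point-spread function by which the sparse
#' peak list is blurred. For a Gaussian shape the kernel is unit amplitude,
#' `exp(-((i - c) / sigma_ch)^2 / 2)`, truncated at `ceiling(4 * sigma_ch)`
#' channels on each side, where `sigma_ch = sigma / step` is the width in
#' channels. A discrete kernel may be supplied instead; it must have odd
#' length, nonnegative entries and its maximum at the central element.
#'
#' @param sigma Gaussian width in axis units (ignored when `kernel` given).
#' @param step Axis spacing used to convert `sigma` to channels (default 1,
#'   i.e. `sigma` is already in channels).
#' @param kernel Optional user-supplied discrete kernel.
#' @return An object of class `"peak_shape"` with elements `kernel`,
#'   `radius` (half-width in channels) and `sigma` (in channels, `NA` for a
#'   user kernel).
#' @examples
#' p <- peak_shape(sigma = 10)
#' length(p$kernel)  # 2 * ceiling(40) + 1
#' @export
peak_shape <- function(sigma = NULL, step = 1, kernel = NULL) {
  if (is.null(kernel)) {
    if (is.null(sigma) || !is.finite(sigma) || sigma <= 0)
      stop("`sigma` must be a positive number when no kernel is supplied")
    sigma_ch <- sigma / step
    r <- as.integer(ceiling(4 * sigma_ch))
    kernel <- exp(-0.5 * ((-r:r) / sigma_ch)^2)
  } else {
    kernel <- as.numeric(kernel)
    if (length(kernel) %% 2 == 0) stop("`kernel` must have odd length")
    if (any(kernel < 0)) stop("`kernel` must be nonnegative")
    r <- (length(kernel) - 1L) / 2L
    if (which.max(kernel) != r + 1L)
      stop("`kernel` must attain its maximum at the central element")
    sigma_ch <- NA_real_
  }
  structure(list(kernel = kernel, radius = as.integer(r), sigma = sigma_ch),
            class = "peak_shape")
}

#' @export
print.peak_shape <- function(x, ...) {
  cat(sprintf("Peak shape: %d-tap kernel (radius %d)%s\n",
              length(x$kernel), x$radius,
              if (is.na(x$sigma)) "" else sprintf(", Gaussian sigma %g channels",
                                                  x$sigma)))
  invisible(x)
}

#' Convolve a peak list with the peak shape
#'
#' Applies the band convolution operator `L` (or its adjoint) to a vector:
#' same-size zero-padded discrete convolution with the peak-shape kernel.
#' Peaks closer to an edge than the truncation radius lose the clipped mass.
#'
#' @param x Numeric vector (a sparse peak list, or any vector).
#' @param shape A [peak_shape()].
#' @param adjoint Apply the transpose operator `L^t` instead.
#' @return Numeric vector of the same length as `x`.
#' @export
convolve_peaks <- function(x, shape, adjoint = FALSE) {
  stopifnot(inherits(shape, "peak_shape"))
  x <- as.numeric(x)
  n <- length(x)
  if (length(shape$kernel) > 2 * n + 1)
    stop("kernel is longer than 2n + 1; shorten the kernel or supply more channels")
  cpp_conv(x, shape$kernel, isTRUE(adjoint))
}
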