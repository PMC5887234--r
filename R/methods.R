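#' @export
print.maldi_deconv <- function(x, ...) {
  cat(sprintf("Deconvolved spectrum (%s method): %d channels, %d peaks\n",
              x$method, x$spectrum$n, length(x$support)))
  cfg <- x$config
  pars <- paste(names(cfg)[!vapply(cfg, is.null, TRUE)],
                vapply(cfg[!vapply(cfg, is.null, TRUE)],
                       function(v) paste(signif(unlist(v), 4), collapse = ","),
                       ""), sep = "=", collapse = ", ")
  cat("  parameters:", pars, "\n")
  conv <- vapply(x$reports, function(r) is.null(r) || isTRUE(r$converged), TRUE)
  if (!all(conv)) cat("  WARNING: solver did not converge in some stage\n")
  invisible(x)
}

#' Peak table of a deconvolution fit
#'
#' @param object A `"maldi_deconv"` fit.
#' @param ... Unused.
#' @return A data frame with columns `position` (axis units), `channel`
#'   (index) and `height`, one row per detected peak, sorted by position.
#' @export
coef.maldi_deconv <- function(object, ...) {
  idx <- object$support
  idx <- idx[object$peaks[idx] > 0]
  data.frame(position = object$spectrum$axis[idx],
             channel = idx,
             height = object$peaks[idx])
}

#' @export
summary.maldi_deconv <- function(object, ...) {
  out <- list(method = object$method, n = object$spectrum$n,
              peaks = coef(object),
              rss = sum(object$residual^2),
              reports = object$reports, config = object$config)
  class(out) <- "summary.maldi_deconv"
  out
}

#' @export
print.summary.maldi_deconv <- function(x, ...) {
  cat(sprintf("Joint/sequential deconvolution summary (%s method)\n", x$method))
  cat(sprintf("  channels: %d   residual sum of squares: %.6g\n", x$n, x$rss))
  for (nm in names(x$reports)) {
    r <- x$reports[[nm]]
    if (is.null(r)) next
    cat(sprintf("  %s: %d iterations, KKT residual %.3g (%s)\n", nm,
                r$iterations, r$kkt_residual,
                if (r$converged) "converged" else "not converged"))
  }
  cat(sprintf("  %d peaks:\n", nrow(x$peaks)))
  print(x$peaks, row.names = FALSE)
  invisible(x)
}

#' Fitted values of a deconvolution fit
#'
#' @param object A `"maldi_deconv"` fit.
#' @param ... Unused.
#' @return `baseline + L peaks`, the model reconstruction of the spectrum.
#' @export
fitted.maldi_deconv <- function(object, ...) {
  object$baseline + convolve_peaks(object$peaks, object$shape)
}

#' @export
residuals.maldi_deconv <- function(object, ...) object$residual

#' Plot a deconvolution fit
#'
#' Draws the raw spectrum, the recovered baseline and vertical stems at the
#' detected peaks (baseline + height, so stems are in spectrum units).
#'
#' @param x A `"maldi_deconv"` fit.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.maldi_deconv <- function(x, ...) {
  sp <- x$spectrum
  graphics::plot(sp$axis, sp$intensity, type = "l", col = "grey40",
                 xlab = "m/z", ylab = "intensity", ...)
  graphics::lines(sp$axis, x$baseline, col = "blue", lwd = 2)
  pk <- coef(x)
  if (nrow(pk) > 0)
    graphics::segments(pk$position, x$baseline[pk$channel],
                       pk$position, x$baseline[pk$channel] + pk$height,
                       col = "red", lwd = 2)
  invisible(x)
}
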