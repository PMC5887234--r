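#' Read a spectrum from a two-column CSV file
#'
#' Expects comma-separated rows with two numeric columns (axis, intensity)
#' and an optional single header line, auto-detected by a non-numeric first
#' row. The axis must be strictly increasing and uniformly spaced.
#'
#' @param path Path to the CSV file.
#' @return A [mass_spectrum()].
#' @export
read_spectrum_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2) stop("need at least 2 data rows in ", path)
  first <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  has_header <- any(is.na(suppressWarnings(as.numeric(first))))
  start <- if (has_header) 2L else 1L
  if (length(lines) - start + 1L < 2) stop("need at least 2 data rows in ", path)
  axis <- intensity <- numeric(length(lines) - start + 1L)
  for (k in seq.int(start, length(lines))) {
    cells <- strsplit(lines[k], ",", fixed = TRUE)[[1]]
    if (length(cells) != 2)
      stop(sprintf("parse error at line %d of %s: expected 2 columns, got %d",
                   k, path, length(cells)))
    vals <- suppressWarnings(as.numeric(cells))
    if (any(is.na(vals)))
      stop(sprintf("parse error at line %d of %s: non-numeric cell", k, path))
    axis[k - start + 1L] <- vals[1]
    intensity[k - start + 1L] <- vals[2]
  }
  mass_spectrum(axis, intensity)
}

#' Write a spectrum to CSV
#'
#' Mirrors the input format of [read_spectrum_csv()]: a header line
#' `axis,intensity` followed by full-precision numeric rows.
#'
#' @param spectrum A [mass_spectrum()] (or coercible), or a plain numeric
#'   vector paired with `axis`.
#' @param path Output path.
#' @param axis Optional axis override (e.g. to write a baseline vector on
#'   the axis of its parent spectrum).
#' @return Invisibly, the path.
#' @export
write_spectrum_csv <- function(spectrum, path, axis = NULL) {
  if (is.numeric(spectrum) && !is.null(axis)) {
    spectrum <- mass_spectrum(axis, spectrum)
  } else {
    spectrum <- as_mass_spectrum(spectrum)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("axis,intensity", con)
  writeLines(sprintf("%.17g,%.17g", spectrum$axis, spectrum$intensity), con)
  invisible(path)
}

#' Write a peak table to CSV
#'
#' Columns `position` (axis units), `channel` (index) and `height`, sorted
#' by position, serialized with 12 significant digits. An empty peak list
#' yields a header-only file.
#'
#' @param fit A `"maldi_deconv"` object (see [deconvolve()]).
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_peaks_csv <- function(fit, path) {
  stopifnot(inherits(fit, "maldi_deconv"))
  pk <- coef(fit)
  pk <- pk[order(pk$position), , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("position,channel,height", con)
  if (nrow(pk) > 0)
    writeLines(sprintf("%.12g,%d,%.12g", pk$position, as.integer(pk$channel),
                       pk$height), con)
  invisible(path)
}
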