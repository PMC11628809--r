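#' One-dimensional NMR spectrum
#'
#' Container for a 1D lineshape: a strictly increasing frequency (or chemical
#' shift) axis and an intensity array of the same length. Used for both
#' simulated and measured deuterium quadrupolar powder spectra (axis in kHz)
#' and phosphorus-31 chemical-shift-anisotropy lineshapes (axis in ppm).
#'
#' @param axis numeric, strictly increasing; kHz for `nucleus = "2H"`, ppm for
#'   `nucleus = "31P"`.
#' @param intensity numeric, same length as `axis`, arbitrary units.
#' @param axis_unit `"kHz"` or `"ppm"`.
#' @param nucleus `"2H"` or `"31P"`.
#' @param meta named list of free-form metadata (temperature, sample label,
#'   simulation ground truth, processing notes).
#' @return An object of class `spectrum1d`: a list with elements `axis`,
#'   `intensity`, `axis_unit`, `nucleus`, `meta`.
#' @examples
#' s <- spectrum1d(seq(-50, 50, length.out = 64), dnorm(seq(-50, 50, length.out = 64), sd = 5))
#' s
#' @export
spectrum1d <- function(axis, intensity, axis_unit = c("kHz", "ppm"),
                       nucleus = c("2H", "31P"), meta = list()) {
  axis_unit <- match.arg(axis_unit)
  nucleus <- match.arg(nucleus)
  axis <- as.numeric(axis)
  intensity <- as.numeric(intensity)
  if (length(axis) != length(intensity)) {
    stop("axis and intensity must have the same length", call. = FALSE)
  }
  if (length(axis) < 16L) {
    stop("spectrum needs at least 16 points", call. = FALSE)
  }
  if (!all(is.finite(axis)) || !all(is.finite(intensity))) {
    stop("axis and intensity must be finite", call. = FALSE)
  }
  if (any(diff(axis) <= 0)) {
    stop("axis must be strictly increasing", call. = FALSE)
  }
  structure(list(axis = axis, intensity = intensity, axis_unit = axis_unit,
                 nucleus = nucleus, meta = meta),
            class = "spectrum1d")
}

#' @export
print.spectrum1d <- function(x, ...) {
  cat(sprintf("<spectrum1d> %s spectrum, %d points, axis %.4g..%.4g %s\n",
              x$nucleus, length(x$axis), min(x$axis), max(x$axis), x$axis_unit))
  cat(sprintf("  integral: %.6g; max intensity at %.4g %s\n",
              spectrum_integral(x), x$axis[which.max(x$intensity)], x$axis_unit))
  if (length(x$meta)) {
    cat("  meta:", paste(names(x$meta), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
plot.spectrum1d <- function(x, ..., type = "l",
                            xlab = sprintf("%s (%s)",
                                           if (x$nucleus == "2H") "frequency" else "chemical shift",
                                           x$axis_unit),
                            ylab = "intensity (a.u.)") {
  graphics::plot(x$axis, x$intensity, type = type, xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Trapezoidal integral of a spectrum
#' @param x a [spectrum1d()] object.
#' @return numeric scalar.
#' @export
spectrum_integral <- function(x) {
  stopifnot(inherits(x, "spectrum1d"))
  sum(diff(x$axis) * (utils::head(x$intensity, -1) + utils::tail(x$intensity, -1)) / 2)
}

# Resample to a uniform grid (linear interpolation), preserving metadata.
# All inversion-type processing assumes equal spacing.
resample_uniform <- function(x, n = length(x$axis)) {
  grid <- seq(min(x$axis), max(x$axis), length.out = n)
  y <- stats::approx(x$axis, x$intensity, xout = grid)$y
  spectrum1d(grid, y, axis_unit = x$axis_unit, nucleus = x$nucleus, meta = x$meta)
}

# Relative asymmetry about zero of a spectrum interpolated on a mirrored grid.
symmetry_residual <- function(x) {
  vmax <- min(abs(min(x$axis)), abs(max(x$axis)))
  grid <- seq(0, vmax, length.out = 256L)
  ip <- stats::approx(x$axis, x$intensity, xout = grid)$y
  im <- stats::approx(x$axis, x$intensity, xout = -grid)$y
  sum(abs(ip - im)) / max(sum(abs(ip + im) / 2), .Machine$double.eps)
}

#' Read a spectrum from a two-column delimited text file
#'
#' Expects two numeric columns (axis, intensity), optionally comma- or
#' whitespace-separated, with `#`-prefixed header lines carrying metadata as
#' `# key: value` pairs. Recognised keys: `nucleus`, `axis_unit`, `sample`;
#' other keys are kept in `meta`.
#'
#' @param path file path.
#' @return a [spectrum1d()] object.
#' @export
read_spectrum <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^\\s*#", lines, value = TRUE)
  body <- grep("^\\s*#", lines, value = TRUE, invert = TRUE)
  body <- body[nzchar(trimws(body))]
  meta <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^\\s*#\\s*([^:]+):\\s*(.*)$", h))[[1]]
    if (length(m) == 3L) {
      v <- trimws(m[3])
      num <- suppressWarnings(as.numeric(v))
      meta[[trimws(m[2])]] <- if (!is.na(num) && !trimws(m[2]) %in%
                                  c("nucleus", "axis_unit", "sample")) num else v
    }
  }
  sep <- if (any(grepl(",", body[1]))) "," else ""
  tab <- utils::read.table(text = body, sep = sep, header = FALSE,
                           col.names = c("axis", "intensity"),
                           colClasses = "numeric")
  nucleus <- meta$nucleus %||% "2H"
  axis_unit <- meta$axis_unit %||% if (nucleus == "31P") "ppm" else "kHz"
  meta$nucleus <- NULL
  meta$axis_unit <- NULL
  spectrum1d(tab$axis, tab$intensity, axis_unit = axis_unit, nucleus = nucleus,
             meta = meta)
}

#' Write a spectrum to a two-column CSV with metadata header
#'
#' @param x a [spectrum1d()] object.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(x, path) {
  stopifnot(inherits(x, "spectrum1d"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# nucleus: %s", x$nucleus), con)
  writeLines(sprintf("# axis_unit: %s", x$axis_unit), con)
  for (k in names(x$meta)) {
    v <- x$meta[[k]]
    if (is.character(v) || is.numeric(v)) {
      writeLines(sprintf("# %s: %s", k, paste(format(v), collapse = " ")), con)
    }
  }
  utils::write.table(data.frame(x$axis, x$intensity), con, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Gaussian line broadening by discrete convolution on a uniform grid.
# sigma in axis units; kernel normalised to unit sum so the integral is kept.
gaussian_blur <- function(y, dx, sigma) {
  if (sigma <= 0) return(y)
  half <- max(1L, ceiling(4 * sigma / dx))
  k <- stats::dnorm(seq(-half, half) * dx, sd = sigma)
  k <- k / sum(k)
  n <- length(y)
  ypad <- c(rep(0, half), y, rep(0, half))
  out <- stats::filter(ypad, k, sides = 2)
  as.numeric(out[(half + 1L):(half + n)])
}
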