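#' FRET cleavage progress curve
#'
#' Time course of EDANS fluorescence during protease cleavage of a
#' FRET-quenched transmembrane substrate. Cleavage separates donor and
#' quencher, so the signal rises toward a plateau.
#'
#' @param time seconds, strictly increasing, >= 8 points.
#' @param intensity fluorescence, arbitrary units.
#' @param sample_meta named list: lipid species, cholesterol mol %, protease
#'   flag, replicate id, ...
#' @return An object of class `progress_curve`.
#' @export
progress_curve <- function(time, intensity, sample_meta = list()) {
  time <- as.numeric(time)
  intensity <- as.numeric(intensity)
  if (length(time) != length(intensity) || length(time) < 8L) {
    stop("need >= 8 (time, intensity) points", call. = FALSE)
  }
  if (any(diff(time) <= 0)) stop("time must be strictly increasing", call. = FALSE)
  if (!all(is.finite(intensity))) stop("intensities must be finite", call. = FALSE)
  structure(list(time = time, intensity = intensity, sample_meta = sample_meta),
            class = "progress_curve")
}

#' @export
print.progress_curve <- function(x, ...) {
  cat(sprintf("<progress_curve> %d points over %.4g..%.4g s", length(x$time),
              min(x$time), max(x$time)))
  if (!is.null(x$sample_meta$label)) cat(" [", x$sample_meta$label, "]", sep = "")
  cat("\n")
  invisible(x)
}

#' Read a progress curve from CSV
#'
#' Two columns (time in seconds, intensity) with optional `# key: value`
#' metadata header lines.
#' @param path file path.
#' @return a [progress_curve()].
#' @export
read_progress_curve <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^\\s*#", lines, value = TRUE)
  body <- grep("^\\s*#", lines, value = TRUE, invert = TRUE)
  body <- body[nzchar(trimws(body))]
  meta <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^\\s*#\\s*([^:]+):\\s*(.*)$", h))[[1]]
    if (length(m) == 3L) meta[[trimws(m[2])]] <- trimws(m[3])
  }
  if (grepl("^[a-zA-Z]", body[1])) body <- body[-1] # header row
  sep <- if (any(grepl(",", body[1]))) "," else ""
  tab <- utils::read.table(text = body, sep = sep, header = FALSE,
                           col.names = c("time", "intensity"),
                           colClasses = "numeric")
  progress_curve(tab$time, tab$intensity, sample_meta = meta)
}

#' Fit the single-exponential cleavage model
#'
#' Fits `I(t) = I_max - I_0 * exp(-t / tau)` to a progress curve by
#' Levenberg-Marquardt least squares on unweighted residuals. Starting
#' values come from a log-linearised tail: with a provisional plateau
#' slightly above the observed maximum, `log(I_max - I)` is regressed on `t`
#' to seed `tau` and `I_0`. Curves without a rising trend (Spearman
#' rho < 0.2 between time and intensity) are rejected as carrying no
#' cleavage signal; a fitted `tau` beyond 100x the observation window is
#' flagged unreliable.
#'
#' @param curve a [progress_curve()].
#' @return An object of class `kinetics_fit`: `i_max`, `i_0`, `tau` (s),
#'   `tau_se`, `r_squared`, `unreliable` flag, `sample_meta`, and the
#'   residual vector.
#' @export
fit_single_exponential <- function(curve) {
  stopifnot(inherits(curve, "progress_curve"))
  t <- curve$time
  y <- curve$intensity
  if (diff(range(y)) <= 0) stop("no cleavage signal: constant intensity", call. = FALSE)
  rho <- stats::cor(t, y, method = "spearman")
  if (!is.finite(rho) || rho < 0.2) {
    stop(sprintf("no cleavage signal: Spearman rho = %.2f < 0.2", rho), call. = FALSE)
  }
  # log-linearised tail initialisation
  imax0 <- max(y) + 0.05 * diff(range(y))
  z <- log(pmax(imax0 - y, 1e-12 * diff(range(y))))
  lfit <- stats::lm(z ~ t)
  tau0 <- -1 / unname(stats::coef(lfit)[2])
  if (!is.finite(tau0) || tau0 <= 0) tau0 <- diff(range(t)) / 2
  i00 <- exp(unname(stats::coef(lfit)[1]))
  par0 <- c(i_max = imax0, i_0 = i00, tau = tau0)
  fit <- minpack.lm::nls.lm(
    par = par0,
    fn = function(p) y - (p[1] - p[2] * exp(-t / p[3])),
    lower = c(-Inf, 0, 1e-9 * diff(range(t))),
    control = minpack.lm::nls.lm.control(maxiter = 500L))
  p <- fit$par
  resid <- y - (p[1] - p[2] * exp(-t / p[3]))
  dof <- length(y) - 3L
  covm <- tryCatch(sum(resid^2) / dof * solve(fit$hessian), error = function(e) NULL)
  tau_se <- if (!is.null(covm) && covm[3, 3] > 0) sqrt(covm[3, 3]) else NA_real_
  window <- diff(range(t))
  structure(list(i_max = unname(p[1]), i_0 = unname(p[2]), tau = unname(p[3]),
                 tau_se = tau_se,
                 r_squared = 1 - sum(resid^2) / sum((y - mean(y))^2),
                 unreliable = unname(p[3]) > 100 * window,
                 sample_meta = curve$sample_meta,
                 residuals = resid),
            class = "kinetics_fit")
}

#' @export
print.kinetics_fit <- function(x, ...) {
  cat(sprintf("<kinetics_fit> tau = %.4g s (se %.3g), I_max = %.4g, I_0 = %.4g, r^2 = %.4f%s\n",
              x$tau, x$tau_se, x$i_max, x$i_0, x$r_squared,
              if (x$unreliable) " [UNRELIABLE: tau >> window]" else ""))
  invisible(x)
}

#' @export
coef.kinetics_fit <- function(object, ...) {
  c(i_max = object$i_max, i_0 = object$i_0, tau = object$tau)
}

#' @export
predict.kinetics_fit <- function(object, time, ...) {
  object$i_max - object$i_0 * exp(-as.numeric(time) / object$tau)
}

#' Normalise cleavage time constants to a reference sample
#'
#' Builds the tau/tau0 table: every fitted time constant is divided by the
#' reference sample's (conventionally the protease in the thinnest,
#' cholesterol-free membrane). Standard errors propagate to the ratio at
#' first order, `se(r)^2 = r^2 * (se_tau^2/tau^2 + se_tau0^2/tau0^2)`; the
#' reference row is exactly 1 with zero propagated error (its ratio is
#' self-correlated).
#'
#' @param fits named list of [fit_single_exponential()] results (names are
#'   sample labels), or a list whose elements carry `sample_meta$label`.
#' @param reference_label label of the reference sample; must occur exactly
#'   once.
#' @return data frame with columns `label`, `tau`, `tau_se`, `tau_ratio`,
#'   `tau_ratio_se`.
#' @export
normalize_tau <- function(fits, reference_label) {
  labels <- names(fits)
  if (is.null(labels) || any(!nzchar(labels))) {
    labels <- vapply(fits, function(f) f$sample_meta$label %||% "", character(1))
  }
  hits <- which(labels == reference_label)
  if (length(hits) != 1L) {
    stop(sprintf("reference label '%s' occurs %d times; need exactly 1",
                 reference_label, length(hits)), call. = FALSE)
  }
  tau <- vapply(fits, `[[`, numeric(1), "tau")
  se <- vapply(fits, `[[`, numeric(1), "tau_se")
  tau0 <- tau[hits]
  se0 <- se[hits]
  ratio <- tau / tau0
  ratio_se <- abs(ratio) * sqrt((se / tau)^2 + (se0 / tau0)^2)
  ratio[hits] <- 1
  ratio_se[hits] <- 0
  data.frame(label = labels, tau = tau, tau_se = se,
             tau_ratio = ratio, tau_ratio_se = ratio_se,
             row.names = NULL)
}

#' Linear and exponential trends of tau/tau0 versus leaflet thickness
#'
#' Fits both trend models to a (thickness, rate-ratio) table:
#' a straight line and a single-exponential decay
#' `y = A * exp(-(x - min(x)) / d)`. Point exclusions are explicit caller
#' masks (never automatic outlier rejection) and are recorded in the output.
#'
#' @param l_c leaflet thickness (projected chain length), angstrom.
#' @param tau_ratio normalised time constants tau/tau0.
#' @param mask logical vector: `TRUE` keeps a point. Default keeps all.
#' @return list with elements `linear` (slope, intercept, r_squared),
#'   `exponential` (amplitude, decay, r_squared), `mask`, `n_used`.
#' @export
trend_fits <- function(l_c, tau_ratio, mask = rep(TRUE, length(l_c))) {
  stopifnot(length(l_c) == length(tau_ratio), length(mask) == length(l_c))
  x <- l_c[mask]
  y <- tau_ratio[mask]
  if (length(x) < 3L) stop("need >= 3 points after masking", call. = FALSE)
  lin <- stats::lm(y ~ x)
  linear <- list(slope = unname(stats::coef(lin)[2]),
                 intercept = unname(stats::coef(lin)[1]),
                 r_squared = 1 - sum(stats::residuals(lin)^2) /
                   sum((y - mean(y))^2))
  x0 <- min(x)
  lz <- stats::lm(log(pmax(y, 1e-12)) ~ I(x - x0))
  d0 <- -1 / unname(stats::coef(lz)[2])
  if (!is.finite(d0) || d0 <= 0) d0 <- diff(range(x))
  a0 <- exp(unname(stats::coef(lz)[1]))
  efit <- minpack.lm::nls.lm(
    par = c(A = a0, d = d0),
    fn = function(p) y - p[1] * exp(-(x - x0) / p[2]),
    control = minpack.lm::nls.lm.control(maxiter = 500L))
  er <- y - efit$par[1] * exp(-(x - x0) / efit$par[2])
  exponential <- list(amplitude = unname(efit$par[1]),
                      decay = unname(efit$par[2]),
                      x0 = x0,
                      r_squared = 1 - sum(er^2) / sum((y - mean(y))^2))
  list(linear = linear, exponential = exponential,
       mask = mask, n_used = length(x))
}
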