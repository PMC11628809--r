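#' Gridded membrane midplane height field
#'
#' Bins the reference atoms (default: phosphorus) of each leaflet onto a
#' `grid_n x grid_n` lateral grid, takes the mean z per cell and leaflet
#' (empty cells are filled by periodic nearest-neighbour averaging), and
#' returns the mean-subtracted midplane surface, the average of the two
#' leaflet surfaces. Leaflets are split about the instantaneous mean z of
#' the reference atoms.
#'
#' @param frame a [membrane_frame()].
#' @param reference_selector selector for the reference atoms (default atom
#'   name `P`).
#' @param grid_n lateral grid size.
#' @return matrix `grid_n x grid_n` of heights (angstrom, zero mean), with
#'   attributes `box_xy` (angstrom) and `grid_n`.
#' @export
membrane_height_field <- function(frame, reference_selector = list(atomname = "P"),
                                  grid_n = 8L) {
  stopifnot(inherits(frame, "membrane_frame"))
  grid_n <- as.integer(grid_n)
  sel <- resolve_selection(frame, reference_selector)
  if (!any(sel)) stop("empty reference selection", call. = FALSE)
  xyz <- frame$coords[sel, , drop = FALSE]
  mid <- mean(xyz[, 3])
  upper <- xyz[, 3] >= mid
  if (!any(upper) || all(upper)) stop("empty leaflet", call. = FALSE)
  if (sum(upper) < grid_n^2 / 4 || sum(!upper) < grid_n^2 / 4) {
    stop(sprintf("need >= %d reference atoms per leaflet for grid_n = %d",
                 ceiling(grid_n^2 / 4), grid_n), call. = FALSE)
  }
  leaflet_surface <- function(pts) {
    ix <- (floor(pts[, 1] / frame$box[1] * grid_n) %% grid_n) + 1L
    iy <- (floor(pts[, 2] / frame$box[2] * grid_n) %% grid_n) + 1L
    s <- matrix(NA_real_, grid_n, grid_n)
    cell <- (iy - 1L) * grid_n + ix
    means <- tapply(pts[, 3], cell, mean)
    s[as.integer(names(means))] <- means
    # periodic nearest-neighbour fill for empty cells
    while (anyNA(s)) {
      up <- s[c(grid_n, seq_len(grid_n - 1L)), ]
      dn <- s[c(seq_len(grid_n - 1L) + 1L, 1L), ]
      lf <- s[, c(grid_n, seq_len(grid_n - 1L))]
      rt <- s[, c(seq_len(grid_n - 1L) + 1L, 1L)]
      nb <- array(c(up, dn, lf, rt), dim = c(grid_n, grid_n, 4L))
      fill <- apply(nb, c(1, 2), mean, na.rm = TRUE)
      na <- is.na(s)
      s[na] <- fill[na]
      if (all(is.nan(s[na]))) stop("cannot fill empty leaflet grid", call. = FALSE)
      s[is.nan(s)] <- NA_real_
    }
    s
  }
  up_s <- leaflet_surface(xyz[upper, , drop = FALSE])
  lo_s <- leaflet_surface(xyz[!upper, , drop = FALSE])
  h <- (up_s + lo_s) / 2
  h <- h - mean(h)
  attr(h, "box_xy") <- frame$box[1:2]
  attr(h, "grid_n") <- grid_n
  h
}

#' Height-fluctuation (undulation) power spectrum
#'
#' Per frame, the midplane height field is Fourier transformed and the
#' squared mode amplitudes are averaged; the spectrum is
#' `Su(q) = A <|h_q|^2>` with `h_q = FFT(h) / N^2` and `A` the mean
#' projected box area, so that for thermally undulating surfaces the
#' Helfrich-Canham prediction `Su(q) = kB T / (kc q^4 + gamma q^2)` holds
#' with `kc` in units of `kB T` when lengths are in nm. Modes are radially
#' binned by exact magnitude (each bin averages only modes of identical
#' `|q|`, which avoids the shallow-slope bias of fixed-width annular bins);
#' the q = 0 mode is excluded and magnitudes beyond the axis Nyquist
#' wavenumber are dropped.
#'
#' @param x a `surface_stack` from [gen_helfrich_surfaces()] (heights in
#'   nm), or a [membrane_trajectory()] whose frames' phosphorus positions
#'   define the midplane (coordinates in angstrom, converted to nm).
#' @param grid_n grid size used when `x` is a trajectory.
#' @param reference_selector reference-atom selector for the trajectory
#'   route.
#' @return An object of class `undulation_spectrum`: list with `q` (nm^-1),
#'   `su` (nm^4), `n_modes` per bin, `area` (nm^2), `n_frames`.
#' @export
undulation_spectrum <- function(x, grid_n = 8L,
                                reference_selector = list(atomname = "P")) {
  if (inherits(x, "surface_stack")) {
    hs <- x$surfaces
    lx <- x$box_l
    ly <- x$box_l
  } else {
    traj <- as_trajectory(x)
    if (length(traj$frames) < 10L) {
      stop("need >= 10 frames for an undulation spectrum", call. = FALSE)
    }
    boxes <- vapply(traj$frames, function(fr) fr$box[1:2], numeric(2))
    drift <- apply(boxes, 1, function(b) diff(range(b)) / mean(b))
    if (any(drift > 0.1)) stop("box x/y drift exceeds 10%", call. = FALSE)
    hs <- lapply(traj$frames, function(fr) {
      membrane_height_field(fr, reference_selector, grid_n) / 10 # A -> nm
    })
    lx <- mean(boxes[1, ]) / 10
    ly <- mean(boxes[2, ]) / 10
  }
  n <- nrow(hs[[1]])
  if (length(hs) < 10L) stop("need >= 10 frames for an undulation spectrum", call. = FALSE)
  area <- lx * ly
  acc <- matrix(0, n, n)
  for (h in hs) {
    hq <- stats::fft(h) / n^2
    acc <- acc + Mod(hq)^2
  }
  acc <- acc / length(hs)
  k <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
  if (n %% 2 == 0) k <- c(0:(n %/% 2 - 1), -(n %/% 2):-1)
  qx <- 2 * pi * k / lx
  qy <- 2 * pi * k / ly
  qmag <- sqrt(outer(qx^2, qy^2, "+"))
  dq <- 2 * pi / max(lx, ly)
  q_nyq <- dq * (n %/% 2)
  # bin by exact mode magnitude so every bin averages modes of identical |q|
  key <- signif(qmag, 8)
  keep <- qmag > 0 & qmag <= q_nyq
  su_bin <- tapply(acc[keep], key[keep], mean) * area
  n_bin <- tapply(acc[keep], key[keep], length)
  q_bin <- as.numeric(names(su_bin))
  ord <- order(q_bin)
  su_bin <- su_bin[ord]; n_bin <- n_bin[ord]; q_bin <- q_bin[ord]
  structure(list(q = q_bin, su = as.numeric(su_bin),
                 n_modes = as.integer(n_bin) * length(hs),
                 area = area, n_frames = length(hs)),
            class = "undulation_spectrum")
}

#' @export
print.undulation_spectrum <- function(x, ...) {
  cat(sprintf("<undulation_spectrum> %d q-bins (%.3g..%.3g nm^-1), %d frames, area %.4g nm^2\n",
              length(x$q), min(x$q), max(x$q), x$n_frames, x$area))
  invisible(x)
}

#' @export
plot.undulation_spectrum <- function(x, ..., log = "xy",
                                     xlab = expression(q ~ (nm^-1)),
                                     ylab = expression(S[u](q) ~ (nm^4))) {
  graphics::plot(x$q, x$su, log = log, xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Fit the Helfrich-Canham bending modulus
#'
#' Weighted least squares of the undulation spectrum against
#' `Su(q) = kB T / (kc q^4 + gamma q^2)` (`mode = "with_tension"`) or the
#' tension-free form `Su(q) = kB T / (kc q^4)` (`gamma` fixed at 0). In
#' `kB T = 1` working units both forms are linear in the inverse spectrum,
#' `1/Su = kc q^4 + gamma q^2`, and are fitted by weighted linear regression
#' with weights `n_modes * su^2` (the inverse-variance weight under a
#' constant relative mode error). The long-wavelength Helfrich regime is
#' selected with `q_window`; the default keeps the 4 smallest non-zero bins.
#'
#' @param spectrum an [undulation_spectrum()].
#' @param q_window `c(qmin, qmax)` in nm^-1, or `NULL` for the default
#'   window.
#' @param mode `"tension_free"` or `"with_tension"`.
#' @param temperature absolute temperature in K (for the SI conversion of
#'   `kc` only).
#' @return An object of class `bending_fit`: `kc` (kB T units), `kc_si`
#'   (J), `gamma` (kB T / nm^2; 0 in tension-free mode), `q_range`,
#'   `r_squared`, `mode`, `temperature`.
#' @export
fit_bending_modulus <- function(spectrum, q_window = NULL,
                                mode = c("tension_free", "with_tension"),
                                temperature = 310) {
  stopifnot(inherits(spectrum, "undulation_spectrum"))
  mode <- match.arg(mode)
  q <- spectrum$q
  su <- spectrum$su
  nm <- spectrum$n_modes
  if (is.null(q_window)) {
    q_window <- c(0, sort(q)[min(4L, length(q))] * (1 + 1e-9))
  }
  keep <- q >= q_window[1] & q <= q_window[2] & su > 0
  if (sum(keep) < 3L) stop("need >= 3 q-bins inside q_window", call. = FALSE)
  q <- q[keep]; su <- su[keep]; nm <- nm[keep]
  y <- 1 / su
  w <- nm * su^2
  if (mode == "tension_free") {
    fit <- stats::lm(y ~ 0 + I(q^4), weights = w)
    kc <- unname(stats::coef(fit)[1])
    gam <- 0
  } else {
    fit <- stats::lm(y ~ 0 + I(q^4) + I(q^2), weights = w)
    kc <- unname(stats::coef(fit)[1])
    gam <- unname(stats::coef(fit)[2])
  }
  if (!is.finite(kc) || kc <= 0) {
    stop("unphysical rigidity; check q_window", call. = FALSE)
  }
  su_hat <- 1 / (kc * q^4 + gam * q^2)
  r2 <- 1 - sum((su - su_hat)^2) / sum((su - mean(su))^2)
  kb <- 1.380649e-23
  structure(list(kc = kc, kc_si = kc * kb * temperature, gamma = gam,
                 q_range = range(q), r_squared = r2, mode = mode,
                 temperature = temperature,
                 n_bins = length(q)),
            class = "bending_fit")
}

#' @export
print.bending_fit <- function(x, ...) {
  cat(sprintf("<bending_fit> kc = %.3g kBT (%.3g J at %g K), gamma = %.3g kBT/nm^2 [%s]\n",
              x$kc, x$kc_si, x$temperature, x$gamma, x$mode))
  cat(sprintf("  q in [%.3g, %.3g] nm^-1 over %d bins, r^2 = %.4f\n",
              x$q_range[1], x$q_range[2], x$n_bins, x$r_squared))
  invisible(x)
}

#' Log-log slope of an undulation spectrum
#'
#' Convenience check of the Helfrich regime: the slope of `log Su` versus
#' `log q` over a q-window (about -4 for tension-free thermal undulations).
#' @param spectrum an [undulation_spectrum()].
#' @param q_window `c(qmin, qmax)` or `NULL` for the default 4 lowest bins.
#' @return slope (dimensionless).
#' @export
undulation_loglog_slope <- function(spectrum, q_window = NULL) {
  q <- spectrum$q; su <- spectrum$su
  if (is.null(q_window)) q_window <- c(0, sort(q)[min(4L, length(q))] * (1 + 1e-9))
  keep <- q >= q_window[1] & q <= q_window[2] & su > 0
  if (sum(keep) < 2L) stop("need >= 2 bins for a slope", call. = FALSE)
  unname(stats::coef(stats::lm(log(su[keep]) ~ log(q[keep])))[2])
}
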