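#' Axially symmetric CSA powder component
#'
#' One component of a ³¹P lineshape: either an axially symmetric
#' chemical-shift-anisotropy powder pattern (fast axial reorientation) or an
#' isotropic line. For lamellar phospholipids under fast axial rotation the
#' span `delta_sigma = sigma_par - sigma_perp` is negative; reports quote the
#' magnitude `|delta_sigma|` as the CSA span.
#'
#' @param delta_sigma CSA span, ppm (ignored for `kind = "isotropic"`).
#' @param sigma_iso isotropic shift, ppm.
#' @param fraction mole fraction of the total integral, in `[0, 1]`.
#' @param broadening Gaussian broadening (sd), ppm.
#' @param kind `"powder"` or `"isotropic"`.
#' @return An object of class `csa_component` (a named list).
#' @export
csa_component <- function(delta_sigma = 0, sigma_iso = 0, fraction = 1,
                          broadening = 1, kind = c("powder", "isotropic")) {
  kind <- match.arg(kind)
  if (!is.finite(fraction) || fraction < 0 || fraction > 1) {
    stop("fraction must lie in [0, 1]", call. = FALSE)
  }
  if (broadening < 0) stop("broadening must be >= 0", call. = FALSE)
  if (kind == "isotropic") delta_sigma <- 0
  structure(list(delta_sigma = delta_sigma, sigma_iso = sigma_iso,
                 fraction = fraction, broadening = broadening, kind = kind),
            class = "csa_component")
}

#' @export
print.csa_component <- function(x, ...) {
  if (x$kind == "powder") {
    cat(sprintf("<csa_component> powder |dsigma| = %.2f ppm, iso %.2f ppm, fraction %.3f, broadening %.2f ppm\n",
                abs(x$delta_sigma), x$sigma_iso, x$fraction, x$broadening))
  } else {
    cat(sprintf("<csa_component> isotropic at %.2f ppm, fraction %.3f, broadening %.2f ppm\n",
                x$sigma_iso, x$fraction, x$broadening))
  }
  invisible(x)
}

#' Simulate an axially symmetric ³¹P powder lineshape
#'
#' The anisotropic shift is `v(theta) = sigma_iso + (delta_sigma/3) *
#' (3 cos^2 theta - 1)`, giving tensor edges at `sigma_iso + 2 delta_sigma/3`
#' (theta = 0) and `sigma_iso - delta_sigma/3` (theta = 90, the intensity
#' maximum under the sin(theta) orientation weight). The lineshape is
#' convolved with a Gaussian and normalised to unit integral. For
#' `kind = "isotropic"` (or zero span) a broadened line at `sigma_iso` is
#' returned.
#'
#' @param component a [csa_component()].
#' @param axis ppm grid, uniform, spanning both tensor edges.
#' @return a [spectrum1d()] (unit integral).
#' @export
simulate_csa_powder <- function(component,
                                axis = seq(-60, 40, length.out = 1001L)) {
  stopifnot(inherits(component, "csa_component"))
  check_uniform_axis(axis)
  ds <- component$delta_sigma
  iso <- component$sigma_iso
  dx <- axis[2] - axis[1]
  edges_grid <- c(axis - dx / 2, axis[length(axis)] + dx / 2)
  if (component$kind == "isotropic" || ds == 0) {
    mass <- diff(as.numeric(edges_grid >= iso))
  } else {
    e0 <- iso + 2 * ds / 3
    e90 <- iso - ds / 3
    if (min(axis) > min(e0, e90) || max(axis) < max(e0, e90)) {
      stop(sprintf("axis must span the tensor edges [%.1f, %.1f] ppm",
                   min(e0, e90), max(e0, e90)), call. = FALSE)
    }
    mass <- diff(csa_branch_cdf(edges_grid, iso, ds))
  }
  y <- mass / dx
  y <- gaussian_blur(y, dx, component$broadening)
  out <- spectrum1d(axis, y, axis_unit = "ppm", nucleus = "31P",
                    meta = list(component = component))
  out$intensity <- out$intensity / spectrum_integral(out)
  out
}

# orientation CDF in shift: v = iso + (ds/3)(3x^2 - 1), x = cos(theta)
# uniform in [0,1]; returns fraction of orientations with shift <= v.
csa_branch_cdf <- function(v, iso, ds) {
  x2 <- ((v - iso) * 3 / ds + 1) / 3
  x2[x2 < 0] <- 0
  x2[x2 > 1] <- 1
  x <- sqrt(x2)
  if (ds > 0) x else 1 - x
}

#' Compose a multi-component ³¹P spectrum
#'
#' Fraction-weighted superposition of CSA powder components plus optional
#' i.i.d. Gaussian noise; the generator for decomposition round-trip tests.
#'
#' @param components list of [csa_component()]; fractions must sum to 1
#'   within 1e-6.
#' @param axis ppm grid.
#' @param noise_sd Gaussian noise standard deviation (intensity units).
#' @param seed integer seed (used only when `noise_sd > 0`).
#' @return a [spectrum1d()] with generating components in `meta$truth_components`.
#' @export
compose_spectrum <- function(components, axis = seq(-60, 40, length.out = 1001L),
                             noise_sd = 0, seed = 1L) {
  stopifnot(length(components) >= 1L)
  fr <- vapply(components, `[[`, numeric(1), "fraction")
  if (abs(sum(fr) - 1) > 1e-6) {
    stop(sprintf("component fractions sum to %.8f, not 1", sum(fr)), call. = FALSE)
  }
  y <- numeric(length(axis))
  for (cmp in components) {
    y <- y + cmp$fraction * simulate_csa_powder(cmp, axis)$intensity
  }
  if (noise_sd > 0) {
    y <- y + with_seed(seed, stats::rnorm(length(axis), sd = noise_sd))
  }
  spectrum1d(axis, y, axis_unit = "ppm", nucleus = "31P",
             meta = list(truth_components = components, noise_sd = noise_sd,
                         seed = seed))
}

#' Decompose a ³¹P spectrum into CSA powder components
#'
#' Nonlinear least squares of the observed lineshape against a superposition
#' of `n_powder` axially symmetric powder patterns plus an optional isotropic
#' line. Free parameters per powder component: span, isotropic shift and
#' Gaussian broadening; fractions live on the probability simplex via a
#' stick-breaking reparameterisation (n-1 free fractions in [0,1]), so the
#' simplex constraint is hard. Optimisation uses Levenberg-Marquardt with
#' box bounds ([minpack.lm::nls.lm]); the result is deterministic for a given
#' spectrum and initialisation.
#'
#' @param spectrum a ³¹P [spectrum1d()].
#' @param n_powder number of powder components, 1 or 2.
#' @param has_isotropic include an isotropic line.
#' @param init optional list of [csa_component()] giving starting values
#'   (powder components first, isotropic last). Defaults to a generic
#'   lamellar-phase start.
#' @param max_iter Levenberg-Marquardt iteration cap.
#' @return An object of class `csa_fit`: list with `components` (sorted by
#'   span magnitude, descending; fractions also given as percentages),
#'   `residual_norm`, `r_squared`, `degenerate` flag (two powder spans within
#'   1 ppm), and `convergence` info.
#' @export
fit_multicomponent <- function(spectrum, n_powder = 2L, has_isotropic = TRUE,
                               init = NULL, max_iter = 500L) {
  stopifnot(inherits(spectrum, "spectrum1d"))
  if (!n_powder %in% c(1L, 2L)) stop("n_powder must be 1 or 2", call. = FALSE)
  axis <- spectrum$axis
  y <- spectrum$intensity
  span_axis <- diff(range(axis))
  n_comp <- n_powder + as.integer(has_isotropic)
  if (is.null(init)) {
    init <- default_csa_init(n_powder, has_isotropic)
  }
  if (length(init) != n_comp) {
    stop("init must supply one component per fitted component", call. = FALSE)
  }
  ok_span <- vapply(init, function(cmp) {
    cmp$kind == "isotropic" ||
      (abs(cmp$delta_sigma) < span_axis &&
         cmp$sigma_iso > min(axis) && cmp$sigma_iso < max(axis))
  }, logical(1))
  if (!all(ok_span)) stop("init components must lie within the axis span", call. = FALSE)

  # parameter vector: per powder comp (ds<0, iso, log broadening), isotropic
  # (iso, log broadening), then n_comp-1 stick-breaking fractions in [0,1]
  pack <- function(components) {
    th <- c()
    for (cmp in components) {
      if (cmp$kind == "powder") {
        th <- c(th, -abs(cmp$delta_sigma), cmp$sigma_iso, log(max(cmp$broadening, 1e-3)))
      } else {
        th <- c(th, cmp$sigma_iso, log(max(cmp$broadening, 1e-3)))
      }
    }
    fr <- vapply(components, `[[`, numeric(1), "fraction")
    fr <- fr / sum(fr)
    u <- numeric(n_comp - 1L)
    rem <- 1
    for (k in seq_len(n_comp - 1L)) {
      u[k] <- if (rem > 1e-12) fr[k] / rem else 0
      rem <- rem - fr[k]
    }
    c(th, pmin(pmax(u, 1e-6), 1 - 1e-6))
  }
  unpack <- function(theta) {
    comps <- vector("list", n_comp)
    i <- 1L
    for (k in seq_len(n_comp)) {
      if (k <= n_powder) {
        comps[[k]] <- csa_component(delta_sigma = theta[i], sigma_iso = theta[i + 1],
                                    broadening = exp(theta[i + 2]), kind = "powder")
        i <- i + 3L
      } else {
        comps[[k]] <- csa_component(sigma_iso = theta[i], broadening = exp(theta[i + 1]),
                                    kind = "isotropic")
        i <- i + 2L
      }
    }
    fr <- numeric(n_comp)
    rem <- 1
    if (n_comp > 1L) {
      u <- theta[i:(i + n_comp - 2L)]
      for (k in seq_len(n_comp - 1L)) {
        fr[k] <- rem * u[k]
        rem <- rem - fr[k]
      }
    }
    fr[n_comp] <- rem
    for (k in seq_len(n_comp)) comps[[k]]$fraction <- fr[k]
    comps
  }
  model_y <- function(theta) {
    comps <- unpack(theta)
    ym <- numeric(length(axis))
    for (cmp in comps) {
      ym <- ym + cmp$fraction * simulate_csa_powder(cmp, axis)$intensity
    }
    ym
  }
  theta0 <- pack(init)
  np <- length(theta0)
  lower <- rep(-Inf, np); upper <- rep(Inf, np)
  i <- 1L
  for (k in seq_len(n_comp)) {
    if (k <= n_powder) {
      lower[i] <- -span_axis; upper[i] <- -0.1          # span: negative, bounded
      lower[i + 1] <- min(axis); upper[i + 1] <- max(axis)
      lower[i + 2] <- log(1e-3); upper[i + 2] <- log(span_axis / 4)
      i <- i + 3L
    } else {
      lower[i] <- min(axis); upper[i] <- max(axis)
      lower[i + 1] <- log(1e-3); upper[i + 1] <- log(span_axis / 4)
      i <- i + 2L
    }
  }
  if (n_comp > 1L) {
    lower[i:np] <- 1e-6; upper[i:np] <- 1 - 1e-6
  }
  fit <- minpack.lm::nls.lm(par = theta0,
                            fn = function(th) y - model_y(th),
                            lower = lower, upper = upper,
                            control = minpack.lm::nls.lm.control(maxiter = max_iter))
  if (fit$info == 0 || fit$info == 9) {
    stop(sprintf("CSA fit did not converge within %d iterations (residual norm %.3g)",
                 max_iter, sqrt(fit$deviance)), call. = FALSE)
  }
  comps <- unpack(fit$par)
  spans <- vapply(comps, function(cmp) abs(cmp$delta_sigma), numeric(1))
  ord <- order(vapply(comps, function(cmp) cmp$kind == "isotropic", logical(1)),
               -spans)
  comps <- comps[ord]
  pow_spans <- spans[ord][seq_len(n_powder)]
  degenerate <- n_powder == 2L && abs(diff(pow_spans)) < 1
  if (degenerate) {
    warning("two powder components collapse within 1 ppm of each other", call. = FALSE)
  }
  resid <- y - model_y(fit$par)
  structure(list(components = comps,
                 fractions_pct = 100 * vapply(comps, `[[`, numeric(1), "fraction"),
                 residual_norm = sqrt(sum(resid^2)),
                 r_squared = 1 - sum(resid^2) / sum((y - mean(y))^2),
                 degenerate = degenerate,
                 convergence = list(info = fit$info, message = fit$message,
                                    niter = fit$niter)),
            class = "csa_fit")
}

default_csa_init <- function(n_powder, has_isotropic) {
  init <- list(csa_component(delta_sigma = -45, sigma_iso = 0, fraction = 0.85,
                             broadening = 1.5))
  if (n_powder == 2L) {
    init[[1]]$fraction <- 0.7
    init <- c(init, list(csa_component(delta_sigma = -30, sigma_iso = 0,
                                       fraction = 0.25, broadening = 1.5)))
  }
  if (has_isotropic) {
    used <- sum(vapply(init, `[[`, numeric(1), "fraction"))
    init <- c(init, list(csa_component(sigma_iso = 0, fraction = 1 - used,
                                       broadening = 1, kind = "isotropic")))
  } else {
    tot <- sum(vapply(init, `[[`, numeric(1), "fraction"))
    for (k in seq_along(init)) init[[k]]$fraction <- init[[k]]$fraction / tot
  }
  init
}

#' @export
print.csa_fit <- function(x, ...) {
  cat(sprintf("<csa_fit> %d component(s), residual norm %.4g, r^2 = %.5f\n",
              length(x$components), x$residual_norm, x$r_squared))
  for (k in seq_along(x$components)) {
    cmp <- x$components[[k]]
    if (cmp$kind == "powder") {
      cat(sprintf("  powder: |dsigma| = %6.2f ppm, iso %6.2f ppm, %5.1f%%, broadening %.2f ppm\n",
                  abs(cmp$delta_sigma), cmp$sigma_iso, 100 * cmp$fraction, cmp$broadening))
    } else {
      cat(sprintf("  isotropic: at %6.2f ppm, %5.1f%%, broadening %.2f ppm\n",
                  cmp$sigma_iso, 100 * cmp$fraction, cmp$broadening))
    }
  }
  invisible(x)
}
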