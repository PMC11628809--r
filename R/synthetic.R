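#' Generate a monotone acyl-chain order profile
#'
#' Builds the canonical fluid-phase profile shape: a plateau over the upper
#' chain followed by a smooth taper to the disordered methyl end. A uniform
#' scaling knob emulates the cholesterol condensation effect (order grows
#' roughly linearly with cholesterol content); values are capped at the
#' physical bound 0.5 with a warning.
#'
#' @param n_carbons chain length (carbons C2..Cn carry deuterons).
#' @param plateau_s plateau order-parameter magnitude, in (0, 0.5].
#' @param methyl_s magnitude at the terminal methyl (chain-referenced).
#' @param plateau_end last carbon of the plateau (default C8).
#' @param taper_model `"linear"` or `"quadratic"` decay from plateau end to
#'   methyl.
#' @param scale uniform multiplier on all magnitudes (cholesterol knob).
#' @param jitter_sd optional Gaussian jitter (applied under `seed`, then
#'   re-monotonised) emulating profile scatter.
#' @param seed integer seed.
#' @return an [order_profile()] with generator parameters in `meta$truth`.
#' @export
gen_order_profile <- function(n_carbons = 12L, plateau_s = 0.21,
                              methyl_s = 0.05, plateau_end = 8L,
                              taper_model = c("linear", "quadratic"),
                              scale = 1, jitter_sd = 0, seed = 1L) {
  taper_model <- match.arg(taper_model)
  if (plateau_s <= 0 || plateau_s > 0.5) stop("plateau_s must be in (0, 0.5]", call. = FALSE)
  if (methyl_s > plateau_s) stop("taper must not exceed the plateau", call. = FALSE)
  carbons <- 2:n_carbons
  s <- numeric(length(carbons))
  s[carbons <= plateau_end] <- plateau_s
  tail_idx <- which(carbons > plateau_end)
  if (length(tail_idx)) {
    frac <- seq_along(tail_idx) / length(tail_idx)
    if (taper_model == "quadratic") frac <- frac^2
    s[tail_idx] <- plateau_s + (methyl_s - plateau_s) * frac
  }
  s <- s * scale
  if (any(s > 0.5)) {
    warning("scaled order parameters capped at 0.5", call. = FALSE)
    s <- pmin(s, 0.5)
  }
  if (jitter_sd > 0) {
    s <- with_seed(seed, s + stats::rnorm(length(s), sd = jitter_sd))
    s <- pmin(pmax(s, 1e-3), 0.5)
    s <- pava_nonincreasing(s, rep(1, length(s)))
  }
  order_profile(carbons, s,
                meta = list(truth = list(plateau_s = plateau_s,
                                         methyl_s = methyl_s,
                                         plateau_end = plateau_end,
                                         taper_model = taper_model,
                                         scale = scale, seed = seed)))
}

#' Generate a noisy deuterium powder spectrum
#'
#' Forward-simulates the Pake superposition of a profile and adds Gaussian
#' noise at a stated peak signal-to-noise ratio. The generating profile is
#' attached to the output metadata, making the spectrum a ground-truthed
#' fixture for dePakeing and profile-extraction recovery tests.
#'
#' @param profile an [order_profile()].
#' @param chi_q static quadrupolar coupling, kHz.
#' @param broadening Gaussian broadening, kHz.
#' @param snr peak amplitude / noise sd; `Inf` for noiseless.
#' @param axis frequency grid, kHz.
#' @param seed integer seed.
#' @return a [spectrum1d()] with `meta$truth_profile`, `meta$snr`.
#' @export
gen_2h_spectrum <- function(profile, chi_q = 167, broadening = 0.5, snr = 50,
                            axis = seq(-60, 60, length.out = 1025L), seed = 1L) {
  if (!is.finite(snr) && snr > 0) {
    s <- simulate_quadrupolar_powder(profile, chi_q, broadening, axis)
    s$meta$snr <- Inf
    return(s)
  }
  if (snr <= 0) stop("snr must be > 0", call. = FALSE)
  s <- simulate_quadrupolar_powder(profile, chi_q, broadening, axis)
  sd_noise <- max(s$intensity) / snr
  s$intensity <- s$intensity + with_seed(seed, stats::rnorm(length(axis), sd = sd_noise))
  s$meta$snr <- snr
  s$meta$noise_sd <- sd_noise
  s$meta$seed <- seed
  s
}

#' Generate a single-exponential cleavage progress curve
#'
#' Samples `I(t) = i_max - i_0 * exp(-t / tau)` on a uniform time grid over
#' the observation window and adds Gaussian noise scaled to the signal
#' range. The generating parameters are attached as ground truth.
#'
#' @param i_max plateau fluorescence, a.u.
#' @param i_0 pre-exponential amplitude, a.u.
#' @param tau characteristic time constant, s; > 0.
#' @param window observation window length, s; > 0.
#' @param n_points number of samples (>= 8).
#' @param noise_frac noise sd as a fraction of the modelled signal range.
#' @param seed integer seed.
#' @param sample_meta metadata stored on the curve.
#' @return a [progress_curve()] with `sample_meta$truth`.
#' @export
gen_progress_curve <- function(i_max = 1000, i_0 = 800, tau = 600,
                               window = 1800, n_points = 60L,
                               noise_frac = 0.02, seed = 1L,
                               sample_meta = list()) {
  if (tau <= 0) stop("tau must be > 0", call. = FALSE)
  if (window <= 0) stop("window must be > 0", call. = FALSE)
  if (n_points < 8L) stop("need n_points >= 8", call. = FALSE)
  t <- seq(0, window, length.out = n_points)
  y <- i_max - i_0 * exp(-t / tau)
  if (noise_frac > 0) {
    rng <- diff(range(y))
    y <- y + with_seed(seed, stats::rnorm(n_points, sd = noise_frac * rng))
  }
  sample_meta$truth <- list(i_max = i_max, i_0 = i_0, tau = tau,
                            noise_frac = noise_frac, seed = seed)
  progress_curve(t, y, sample_meta = sample_meta)
}

#' Sample thermally undulating Helfrich surfaces
#'
#' Draws independent membrane height fields from the stationary
#' Helfrich-Canham distribution: Fourier modes are complex Gaussian with
#' `<|h_q|^2> = kB T / (A (kc q^4 + gamma q^2))` (in `kB T = 1` units with
#' lengths in nm), Hermitian-symmetrised and inverse-transformed, so the
#' surfaces are exactly real and their ensemble spectrum equals the
#' Helfrich prediction by construction.
#'
#' @param box_l lateral box length, nm (square box).
#' @param grid_n grid size per side, a power of two, >= 8.
#' @param kc bending rigidity, kB T units; > 0.
#' @param gamma surface tension, kB T / nm^2.
#' @param n_frames number of independent surfaces.
#' @param seed integer seed.
#' @return An object of class `surface_stack`: list with `surfaces` (list of
#'   `grid_n x grid_n` matrices, nm), `box_l`, `truth` (kc, gamma).
#' @export
gen_helfrich_surfaces <- function(box_l = 25, grid_n = 64L, kc = 20,
                                  gamma = 0, n_frames = 500L, seed = 1L) {
  grid_n <- as.integer(grid_n)
  if (grid_n < 8L) stop("grid_n must be >= 8", call. = FALSE)
  if (bitwAnd(grid_n, grid_n - 1L) != 0L) stop("grid_n must be a power of two", call. = FALSE)
  if (kc <= 0) stop("kc must be > 0", call. = FALSE)
  n <- grid_n
  area <- box_l^2
  k <- c(0:(n %/% 2 - 1), -(n %/% 2):-1)
  q2 <- outer((2 * pi * k / box_l)^2, (2 * pi * k / box_l)^2, "+")
  var_q <- 1 / (area * (kc * q2^2 + gamma * q2))
  var_q[1, 1] <- 0
  conj_idx <- function(i) ((n - (i - 1L)) %% n) + 1L
  ci <- conj_idx(seq_len(n))
  surfaces <- with_seed(seed, {
    lapply(seq_len(n_frames), function(f) {
      zre <- matrix(stats::rnorm(n * n), n, n)
      zim <- matrix(stats::rnorm(n * n), n, n)
      z <- complex(real = zre, imaginary = zim) * sqrt(var_q / 2)
      dim(z) <- c(n, n)
      hsym <- (z + Conj(z[ci, ci])) / sqrt(2)
      Re(stats::fft(hsym, inverse = TRUE))
    })
  })
  structure(list(surfaces = surfaces, box_l = box_l,
                 truth = list(kc = kc, gamma = gamma, seed = seed)),
            class = "surface_stack")
}

#' @export
print.surface_stack <- function(x, ...) {
  cat(sprintf("<surface_stack> %d surfaces, %d x %d grid over %.3g x %.3g nm\n",
              length(x$surfaces), nrow(x$surfaces[[1]]), ncol(x$surfaces[[1]]),
              x$box_l, x$box_l))
  invisible(x)
}

#' Generate an ideal alpha-helix backbone
#'
#' Canonical helix (rise 1.5 angstrom per residue, 100 degrees per residue,
#' CA radius 2.3 angstrom) with N and C backbone atoms offset around each
#' CA, built along +z and then rotated about the x axis to the requested
#' tilt. A fixture for helix-axis and tilt-angle estimators.
#'
#' @param n_res number of residues, >= 6.
#' @param tilt_deg rotation about x applied to the helix, degrees.
#' @param seed unused randomness hook (the fixture is deterministic); kept
#'   so generator calls are uniform.
#' @return a [membrane_frame()] with resname `ALA`, atom names N/CA/C.
#' @export
gen_ideal_helix <- function(n_res = 18L, tilt_deg = 0, seed = 1L) {
  if (n_res < 6L) stop("need n_res >= 6", call. = FALSE)
  rise <- 1.5
  twist <- 100 * pi / 180
  r_ca <- 2.3
  rows <- list()
  xyz <- list()
  for (i in seq_len(n_res)) {
    phi <- (i - 1) * twist
    z <- (i - 1) * rise
    ca <- c(r_ca * cos(phi), r_ca * sin(phi), z)
    # N and C at the CA z level: offsetting them along z in step with the
    # azimuth would correlate height with phase and lean the principal axis
    nn <- c(1.9 * cos(phi - 0.45), 1.9 * sin(phi - 0.45), z)
    cc <- c(1.9 * cos(phi + 0.45), 1.9 * sin(phi + 0.45), z)
    xyz <- c(xyz, list(nn, ca, cc))
    rows[[i]] <- data.frame(resname = "ALA", resid = i,
                            atomname = c("N", "CA", "C"))
  }
  coords <- do.call(rbind, xyz)
  coords <- sweep(coords, 2, colMeans(coords))
  th <- tilt_deg * pi / 180
  rot_x <- matrix(c(1, 0, 0,
                    0, cos(th), -sin(th),
                    0, sin(th), cos(th)), 3, 3, byrow = TRUE)
  coords <- coords %*% t(rot_x)
  coords <- sweep(coords, 2, c(50, 50, 50), "+")
  membrane_frame(coords, do.call(rbind, rows), box = c(100, 100, 100))
}

# closed-form expected S_CD for a methylene whose chain director wobbles
# about +z with a von Mises-Fisher distribution of concentration kappa:
# C-H bonds are perpendicular to the director, so
#   E S_CD = -1/2 * E P2(cos beta),  E P2 = 1 - 3 L(kappa)/kappa,
# with L(kappa) = coth(kappa) - 1/kappa the Langevin function.
#' Expected methylene order parameter of the wobble generator
#' @param kappa von Mises-Fisher concentration, > 0 (may be `Inf`).
#' @return expected S_CD (negative).
#' @export
scd_expected_vmf <- function(kappa) {
  if (is.infinite(kappa)) return(-0.5)
  if (kappa <= 0) stop("kappa must be > 0", call. = FALSE)
  lang <- 1 / tanh(kappa) - 1 / kappa
  -0.5 * (1 - 3 * lang / kappa)
}

# sample cos(beta) from the von Mises-Fisher polar distribution
sample_vmf_cos <- function(n, kappa) {
  if (is.infinite(kappa)) return(rep(1, n))
  u <- stats::runif(n)
  1 + log(u + (1 - u) * exp(-2 * kappa)) / kappa
}
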