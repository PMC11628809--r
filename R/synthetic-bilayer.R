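#' Generate toy two-leaflet bilayer frames
#'
#' Desk-scale geometric stand-in for an atomistic bilayer trajectory. Each
#' leaflet is a jittered square lattice of phosphocholine lipids; every PC
#' lipid carries an explicit-hydrogen all-trans acyl chain whose director
#' wobbles about the bilayer normal with a von Mises-Fisher distribution of
#' concentration `kappa` (the expected methylene order parameter then has
#' the closed form [scd_expected_vmf()]), plus P and N headgroup
#' pseudo-atoms with a configurable P-to-N polar angle. A fraction of
#' lattice sites hold cholesterol placeholder residues; an optional rigid
#' cylinder of protein pseudo-atoms sits at the box centre, and an optional
#' radial depletion rule keeps cholesterol away from it. These frames are
#' geometric fixtures, not physical lipids: every consumer analysis is a
#' geometric functional, so ideal tetrahedral geometry and placeholder
#' residues are sufficient to give each estimator a known ground truth.
#'
#' @param n_lipids_per_leaflet lipids per leaflet (rounded up to a square
#'   lattice).
#' @param chol_fraction fraction of lattice sites holding cholesterol, in
#'   `[0, 1)`.
#' @param wobble_kappa chain-director concentration; `Inf` = no wobble
#'   (all-trans chains along the normal).
#' @param protein `NULL`, or `list(radius = r)` for a rigid cylinder of
#'   heavy pseudo-atoms (resname `GLPG`) at the box centre.
#' @param depletion_radius `NULL`, or a lateral distance (angstrom) from the
#'   box centre within which no cholesterol is placed.
#' @param n_frames number of frames (lipid orientations and jitter are
#'   redrawn each frame; lattice sites persist).
#' @param n_carbons acyl chain length (carbons C2..Cn; Cn is the methyl).
#' @param spacing lattice constant, angstrom.
#' @param pn_polar_deg polar angle of the P-to-N vector from the outward
#'   normal, degrees (90 = in-plane); drawn azimuths are uniform.
#' @param pn_polar_sd Gaussian spread of the polar angle, degrees.
#' @param jitter_sd lateral lattice jitter, angstrom.
#' @param seed integer seed.
#' @return a [membrane_trajectory()]; `meta$truth` records all generator
#'   parameters, the expected methylene S_CD, and the realised global
#'   cholesterol fraction.
#' @export
gen_bilayer_frames <- function(n_lipids_per_leaflet = 64L, chol_fraction = 0,
                               wobble_kappa = Inf, protein = NULL,
                               depletion_radius = NULL, n_frames = 5L,
                               n_carbons = 12L, spacing = 8,
                               pn_polar_deg = 90, pn_polar_sd = 0,
                               jitter_sd = 0.5, seed = 1L) {
  if (n_lipids_per_leaflet <= 0) stop("need at least one lipid per leaflet", call. = FALSE)
  if (chol_fraction < 0 || chol_fraction >= 1) {
    stop("chol_fraction must lie in [0, 1)", call. = FALSE)
  }
  nside <- ceiling(sqrt(n_lipids_per_leaflet))
  n_sites <- nside^2
  box_xy <- nside * spacing
  z_head <- 19
  box <- c(box_xy, box_xy, 2 * (z_head + 6))
  if (spacing < 5) {
    stop("box too small for the requested lipid count at minimum spacing", call. = FALSE)
  }
  grid_xy <- as.matrix(expand.grid(x = (seq_len(nside) - 0.5) * spacing,
                                   y = (seq_len(nside) - 0.5) * spacing))
  centre <- c(box_xy, box_xy) / 2

  frames_and_truth <- with_seed(seed, {
    # site species assignment (persistent across frames)
    assign_species <- function() {
      species <- rep("PC", n_sites)
      n_chol <- round(chol_fraction * n_sites)
      if (n_chol > 0) {
        eligible <- seq_len(n_sites)
        if (!is.null(depletion_radius)) {
          r_lat <- sqrt((grid_xy[, 1] - centre[1])^2 + (grid_xy[, 2] - centre[2])^2)
          eligible <- which(r_lat > depletion_radius)
          if (length(eligible) < n_chol) {
            stop("depletion rule leaves too few sites for the requested cholesterol",
                 call. = FALSE)
          }
        }
        species[sample(eligible, n_chol)] <- "CHOL"
      }
      species
    }
    species_up <- assign_species()
    species_lo <- assign_species()

    build_lipid <- function(x0, y0, leaflet, resid) {
      sgn <- if (leaflet == "upper") 1 else -1
      p <- c(x0, y0, sgn * z_head)
      polar <- (pn_polar_deg + if (pn_polar_sd > 0) stats::rnorm(1, sd = pn_polar_sd) else 0) * pi / 180
      az <- stats::runif(1, 0, 2 * pi)
      # polar angle measured from the outward normal of the leaflet
      pn_dir <- c(sin(polar) * cos(az), sin(polar) * sin(az), sgn * cos(polar))
      nn <- p + 3 * pn_dir
      cosb <- sample_vmf_cos(1, wobble_kappa)
      sinb <- sqrt(max(0, 1 - cosb^2))
      caz <- stats::runif(1, 0, 2 * pi)
      d <- c(sinb * cos(caz), sinb * sin(caz), -sgn * cosb) # chain points inward
      u <- c(-sin(caz), cos(caz), 0)                        # unit, perpendicular to d
      v <- c(d[2] * u[3] - d[3] * u[2],
             d[3] * u[1] - d[1] * u[3],
             d[1] * u[2] - d[2] * u[1])
      start <- p + c(0, 0, -sgn * 2.5)
      carbons <- 2:n_carbons
      coords <- list(p, nn)
      names_v <- c("P", "N")
      for (k in seq_along(carbons)) {
        ck <- start + d * 1.27 * (k - 1)
        coords <- c(coords, list(ck))
        names_v <- c(names_v, sprintf("C%d", carbons[k]))
        is_methyl <- k == length(carbons)
        haz <- stats::runif(1, 0, 2 * pi)
        if (!is_methyl) {
          # two H per methylene, both perpendicular to the director and
          # separated azimuthally by the tetrahedral H-C-H angle
          h1 <- cos(haz) * u + sin(haz) * v
          h2 <- cos(haz + 1.9106) * u + sin(haz + 1.9106) * v
          coords <- c(coords, list(ck + 1.09 * h1, ck + 1.09 * h2))
          names_v <- c(names_v, sprintf("H%dA", carbons[k]), sprintf("H%dB", carbons[k]))
        } else {
          # methyl: three H at the tetrahedral angle from the director
          ct <- -1 / 3 # cos(109.47 deg) relative to -d, i.e. 70.53 deg from d
          st <- sqrt(1 - ct^2)
          for (m in 0:2) {
            am <- haz + 2 * pi * m / 3
            hdir <- st * (cos(am) * u + sin(am) * v) - ct * d
            coords <- c(coords, list(ck + 1.09 * hdir))
            names_v <- c(names_v, sprintf("H%d%s", carbons[k], LETTERS[m + 1]))
          }
        }
      }
      list(coords = do.call(rbind, coords),
           atoms = data.frame(resname = "DLPC", resid = resid, atomname = names_v))
    }
    build_chol <- function(x0, y0, leaflet, resid) {
      sgn <- if (leaflet == "upper") 1 else -1
      z0 <- sgn * (z_head - 3)
      zs <- z0 - sgn * c(0, 2.5, 5, 7.5)
      list(coords = cbind(x0, y0, zs),
           atoms = data.frame(resname = "CHOL", resid = resid,
                              atomname = paste0("C", 1:4)))
    }
    protein_atoms <- NULL
    if (!is.null(protein)) {
      r <- protein$radius
      ang <- seq(0, 2 * pi, length.out = 13L)[-13L]
      zs <- seq(-z_head, z_head, length.out = 8L)
      pc <- do.call(rbind, lapply(zs, function(z) {
        cbind(centre[1] + r * cos(ang), centre[2] + r * sin(ang), z)
      }))
      protein_atoms <- list(coords = pc,
                            atoms = data.frame(resname = "GLPG", resid = 99999L,
                                               atomname = rep("CA", nrow(pc))))
    }
    frames <- lapply(seq_len(n_frames), function(f) {
      parts <- list()
      resid <- 0L
      for (leaflet in c("upper", "lower")) {
        species <- if (leaflet == "upper") species_up else species_lo
        for (s in seq_len(n_sites)) {
          resid <- resid + 1L
          xy <- grid_xy[s, ] + stats::rnorm(2, sd = jitter_sd)
          xy <- xy %% box_xy
          if (species[s] == "PC") {
            parts[[resid]] <- build_lipid(xy[1], xy[2], leaflet, resid)
          } else {
            parts[[resid]] <- build_chol(xy[1], xy[2], leaflet, resid)
          }
        }
      }
      if (!is.null(protein_atoms)) parts <- c(parts, list(protein_atoms))
      coords <- do.call(rbind, lapply(parts, `[[`, "coords"))
      coords[, 3] <- coords[, 3] + box[3] / 2 # shift midplane to box centre
      atoms <- do.call(rbind, lapply(parts, `[[`, "atoms"))
      membrane_frame(coords, atoms, box)
    })
    list(frames = frames,
         chol_realised = (sum(species_up == "CHOL") + sum(species_lo == "CHOL")) /
           (2 * n_sites))
  })
  membrane_trajectory(
    frames_and_truth$frames,
    meta = list(truth = list(
      n_lipids_per_leaflet = n_sites, chol_fraction = chol_fraction,
      chol_fraction_realised = frames_and_truth$chol_realised,
      wobble_kappa = wobble_kappa,
      expected_scd_methylene = scd_expected_vmf(if (wobble_kappa > 0) wobble_kappa else Inf),
      protein = protein, depletion_radius = depletion_radius,
      n_carbons = n_carbons, spacing = spacing,
      pn_polar_deg = pn_polar_deg, pn_polar_sd = pn_polar_sd,
      seed = seed)))
}

# chain selector matching the synthetic bilayer naming scheme
#' Chain selector for the synthetic bilayer generator
#' @param n_carbons chain length used in [gen_bilayer_frames()].
#' @return list usable as `chain_selector` in [acyl_order_parameters()].
#' @export
synthetic_chain_selector <- function(n_carbons = 12L) {
  list(resnames = "DLPC", carbons = 2:n_carbons,
       carbon_fmt = "C%d", h_fmts = c("H%dA", "H%dB", "H%dC"))
}
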