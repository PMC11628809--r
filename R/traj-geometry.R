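#' Headgroup P-N vector angle histogram
#'
#' For each phosphocholine lipid the phosphorus-to-nitrogen vector reports
#' the headgroup orientation. The angle to the +z bilayer normal is
#' histogrammed over molecules and frames; lipids in the lower leaflet
#' (phosphorus below the instantaneous midplane of the selected phosphorus
#' atoms) have their vectors reflected so both leaflets share one
#' convention. The histogram is normalised to unit area (density per
#' degree).
#'
#' @param traj a [membrane_trajectory()] (or single frame).
#' @param lipid_selector selector for the lipid residues (default: residues
#'   owning both a `P` and an `N` atom).
#' @param bins number of bins over `[0, 180]` degrees.
#' @param p_name,n_name atom names of the phosphorus and nitrogen.
#' @param resid_subset optional residue ids (annular/bulk stratification).
#' @return list: `breaks`, `mids`, `density` (per degree, unit area),
#'   `counts`, `angles` (all pooled angles, degrees).
#' @export
pn_angle_histogram <- function(traj, lipid_selector = NULL, bins = 36L,
                               p_name = "P", n_name = "N",
                               resid_subset = NULL) {
  traj <- as_trajectory(traj)
  angles <- c()
  for (fr in traj$frames) {
    a <- fr$atoms
    keep <- if (is.null(lipid_selector)) rep(TRUE, nrow(a)) else resolve_selection(fr, lipid_selector)
    if (!is.null(resid_subset)) keep <- keep & a$resid %in% resid_subset
    p_rows <- which(keep & a$atomname == p_name)
    if (!length(p_rows)) next
    n_rows <- match(paste(a$resid[p_rows], n_name, sep = "|"),
                    paste(a$resid, a$atomname, sep = "|"))
    if (anyNA(n_rows)) {
      bad <- a$resid[p_rows][is.na(n_rows)]
      stop(sprintf("residue(s) missing %s atom: %s", n_name,
                   paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
    }
    v <- fr$coords[n_rows, , drop = FALSE] - fr$coords[p_rows, , drop = FALSE]
    # wrap intramolecular vectors split across the periodic boundary
    for (k in 1:3) v[, k] <- v[, k] - fr$box[k] * round(v[, k] / fr$box[k])
    mid <- mean(fr$coords[p_rows, 3])
    lower <- fr$coords[p_rows, 3] < mid
    v[lower, 3] <- -v[lower, 3]
    angles <- c(angles, angle_to_z_deg(v))
  }
  if (!length(angles)) stop("no P atoms found in selection", call. = FALSE)
  breaks <- seq(0, 180, length.out = bins + 1L)
  h <- graphics::hist(angles, breaks = breaks, plot = FALSE)
  width <- diff(breaks)[1]
  list(breaks = breaks, mids = h$mids,
       density = h$counts / (sum(h$counts) * width),
       counts = h$counts, angles = angles)
}

#' Transmembrane helix tilt angles
#'
#' The helix axis is the principal axis (largest-variance direction) of the
#' per-residue backbone centroids after a one-helical-turn (3.6 residue)
#' moving average — the smoothing cancels the phase-height coupling of the
#' helical winding, which would otherwise lean a raw principal axis by a
#' degree or two. The axis sign is chosen toward increasing residue index;
#' the tilt is the angle between the axis and +z, folded to `[0, 90]`
#' degrees so the result is invariant to the axis sign and to a 180-degree
#' flip of the helix.
#'
#' @param traj a [membrane_trajectory()] (or single frame).
#' @param helix_residue_ranges named list of `c(first, last)` residue id
#'   ranges, each covering >= 6 residues.
#' @param backbone_atoms backbone atom names used for the axis.
#' @return list: `per_frame` (data frame helix x frame x tilt_deg),
#'   `summary` (helix, mean_tilt_deg, sd_tilt_deg, n_frames).
#' @export
helix_tilt <- function(traj, helix_residue_ranges,
                       backbone_atoms = c("N", "CA", "C")) {
  traj <- as_trajectory(traj)
  if (is.null(names(helix_residue_ranges))) {
    names(helix_residue_ranges) <- paste0("helix", seq_along(helix_residue_ranges))
  }
  rows <- list()
  for (hx in names(helix_residue_ranges)) {
    rg <- helix_residue_ranges[[hx]]
    if (diff(rg) + 1 < 6) {
      stop(sprintf("helix '%s' spans %d residues; need >= 6", hx, diff(rg) + 1),
           call. = FALSE)
    }
    for (i in seq_along(traj$frames)) {
      fr <- traj$frames[[i]]
      sel <- fr$atoms$resid >= rg[1] & fr$atoms$resid <= rg[2] &
        fr$atoms$atomname %in% backbone_atoms
      if (sum(sel) < 3 * 6) {
        stop(sprintf("helix '%s': backbone atoms missing in frame %d", hx, i),
             call. = FALSE)
      }
      xyz <- fr$coords[sel, , drop = FALSE]
      resid <- fr$atoms$resid[sel]
      rid <- sort(unique(resid))
      cent <- t(vapply(rid, function(r) colMeans(xyz[resid == r, , drop = FALSE]),
                       numeric(3)))
      # one-turn (3.6 residue) moving average of residue centroids
      wts <- c(1, 1, 1, 0.6) / 3.6
      nres <- nrow(cent)
      sm <- t(vapply(seq_len(nres - 3L), function(j) {
        colSums(cent[j:(j + 3L), , drop = FALSE] * wts)
      }, numeric(3)))
      ctr <- sweep(sm, 2, colMeans(sm))
      ax <- svd(ctr, nu = 0, nv = 1)$v[, 1]
      direction <- sm[nrow(sm), ] - sm[1, ]
      if (sum(ax * direction) < 0) ax <- -ax
      tilt <- acos(min(1, abs(ax[3]))) * 180 / pi
      rows[[length(rows) + 1L]] <- data.frame(helix = hx, frame = i,
                                              tilt_deg = tilt)
    }
  }
  per_frame <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(per_frame, per_frame$helix), function(d) {
    data.frame(helix = d$helix[1], mean_tilt_deg = mean(d$tilt_deg),
               sd_tilt_deg = stats::sd(d$tilt_deg), n_frames = nrow(d))
  }))
  rownames(agg) <- NULL
  list(per_frame = per_frame, summary = agg)
}

#' Radial distribution function between two atom selections
#'
#' Standard cross-pair g(r): minimum-image distances between the two
#' selections are histogrammed in half-open bins `[r, r + dr)` and
#' normalised by the ideal-gas shell volume and the mean pair density,
#' averaged over frames. For a residue-pair use case (e.g. the catalytic
#' serine against its partner histidine) pass the two residues' side-chain
#' atoms as selections.
#'
#' @param traj a [membrane_trajectory()] (or single frame).
#' @param sel_a,sel_b atom selectors (see [select_atoms()]).
#' @param r_max maximum distance, angstrom; must be below half the smallest
#'   box length.
#' @param bin_width bin width, angstrom.
#' @return data frame with columns `r_lo`, `r_mid`, `g`, `counts`; attribute
#'   `n_pairs`.
#' @export
residue_pair_rdf <- function(traj, sel_a, sel_b, r_max = 12, bin_width = 0.2) {
  traj <- as_trajectory(traj)
  box0 <- traj$frames[[1]]$box
  if (r_max >= min(box0) / 2) {
    stop(sprintf("r_max (%.1f A) must be below half the smallest box length (%.1f A)",
                 r_max, min(box0) / 2), call. = FALSE)
  }
  edges <- seq(0, r_max, by = bin_width)
  if (utils::tail(edges, 1) < r_max) edges <- c(edges, utils::tail(edges, 1) + bin_width)
  counts <- numeric(length(edges) - 1L)
  norm_acc <- 0
  for (fr in traj$frames) {
    ia <- which(resolve_selection(fr, sel_a))
    ib <- which(resolve_selection(fr, sel_b))
    if (!length(ia) || !length(ib)) stop("empty selection", call. = FALSE)
    d2 <- min_image_dist2(fr$coords[ia, , drop = FALSE],
                          fr$coords[ib, , drop = FALSE], fr$box)
    same <- outer(ia, ib, "==")
    d <- sqrt(d2[!same])
    d <- d[d < r_max]
    idx <- findInterval(d, edges, left.open = FALSE, rightmost.closed = FALSE)
    tab <- tabulate(idx, nbins = length(counts))
    counts <- counts + tab
    n_pairs <- length(ia) * length(ib) - sum(same)
    v <- prod(fr$box)
    norm_acc <- norm_acc + n_pairs / v
  }
  shell <- 4 / 3 * pi * (edges[-1]^3 - edges[-length(edges)]^3)
  g <- counts / (shell * norm_acc)
  out <- data.frame(r_lo = edges[-length(edges)],
                    r_mid = (edges[-1] + edges[-length(edges)]) / 2,
                    g = g, counts = counts)
  attr(out, "n_frames") <- length(traj$frames)
  out
}
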