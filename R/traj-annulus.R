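#' Classify lipids as annular or bulk
#'
#' A lipid is annular when its minimum heavy-atom distance to any protein
#' heavy atom is at most `cutoff`, under orthorhombic periodic boundary
#' conditions (minimum-image). With no protein selection every lipid is
#' bulk. The cutoff is a first-shell contact criterion; it is recorded in
#' the output so downstream reports always carry the provenance.
#'
#' @param frame a [membrane_frame()].
#' @param protein_selector selector for protein atoms (see
#'   [select_atoms()]); `NULL` means no protein present.
#' @param cutoff contact distance, angstrom, > 0.
#' @param lipid_selector selector for lipid atoms; defaults to every atom
#'   outside the protein selection.
#' @return data frame with one row per lipid residue: `resid`, `resname`,
#'   `label` (`"annular"` or `"bulk"`), `min_dist`; attribute `cutoff`.
#' @export
classify_annular <- function(frame, protein_selector, cutoff = 6,
                             lipid_selector = NULL) {
  stopifnot(inherits(frame, "membrane_frame"))
  if (!is.finite(cutoff) || cutoff <= 0) stop("cutoff must be > 0", call. = FALSE)
  prot <- resolve_selection(frame, protein_selector)
  lip <- if (is.null(lipid_selector)) !prot else resolve_selection(frame, lipid_selector)
  heavy <- !grepl("^H", frame$atoms$atomname)
  lip <- lip & heavy
  prot <- prot & heavy
  if (!any(lip)) stop("no lipid atoms selected", call. = FALSE)
  lip_resid <- frame$atoms$resid[lip]
  resids <- unique(lip_resid)
  resname <- frame$atoms$resname[lip][match(resids, lip_resid)]
  if (!any(prot)) {
    out <- data.frame(resid = resids, resname = resname, label = "bulk",
                      min_dist = Inf)
  } else {
    d2 <- min_image_dist2(frame$coords[lip, , drop = FALSE],
                          frame$coords[prot, , drop = FALSE], frame$box)
    dmin_atom <- sqrt(apply(d2, 1, min))
    dmin <- vapply(resids, function(r) min(dmin_atom[lip_resid == r]), numeric(1))
    out <- data.frame(resid = resids, resname = resname,
                      label = ifelse(dmin <= cutoff, "annular", "bulk"),
                      min_dist = dmin)
  }
  attr(out, "cutoff") <- cutoff
  out
}

#' Annulus composition statistics over a trajectory
#'
#' Classifies every lipid in every frame with [classify_annular()] and
#' reports cholesterol content in the annular shell versus the bulk, both as
#' the mean of per-frame percentages and as pooled-lipid percentages, plus
#' the histogram of annular lipid counts per frame. Counts conserve the
#' total lipid number in every frame. Because the stated annular cutoff is a
#' modelling choice, a sensitivity table over several cutoffs is included.
#'
#' @param traj a [membrane_trajectory()] (or single frame).
#' @param protein_selector,cutoff,lipid_selector as in [classify_annular()].
#' @param chol_resnames residue names counted as cholesterol.
#' @param sensitivity_cutoffs cutoffs (angstrom) for the sensitivity report.
#' @return list: `per_frame` (frame, n_annular, n_bulk, n_chol_annular,
#'   n_chol_bulk), `annular_chol_pct` / `bulk_chol_pct` (per-frame means),
#'   `pooled` (same, pooled over lipid-frames), `annular_count_histogram`
#'   (table), `cutoff`, `sensitivity` (cutoff vs mean annular count and
#'   annular cholesterol %).
#' @export
annulus_composition <- function(traj, protein_selector, cutoff = 6,
                                lipid_selector = NULL,
                                chol_resnames = "CHOL",
                                sensitivity_cutoffs = c(5, 6, 7)) {
  traj <- as_trajectory(traj)
  one_pass <- function(co) {
    pf <- lapply(seq_along(traj$frames), function(i) {
      cl <- classify_annular(traj$frames[[i]], protein_selector, co, lipid_selector)
      ann <- cl$label == "annular"
      chol <- cl$resname %in% chol_resnames
      data.frame(frame = i,
                 n_lipids = nrow(cl),
                 n_annular = sum(ann), n_bulk = sum(!ann),
                 n_chol_annular = sum(ann & chol),
                 n_chol_bulk = sum(!ann & chol))
    })
    do.call(rbind, pf)
  }
  pf <- one_pass(cutoff)
  frame_ann_pct <- ifelse(pf$n_annular > 0, 100 * pf$n_chol_annular / pf$n_annular, NA)
  frame_blk_pct <- ifelse(pf$n_bulk > 0, 100 * pf$n_chol_bulk / pf$n_bulk, NA)
  sens <- do.call(rbind, lapply(sensitivity_cutoffs, function(co) {
    s <- one_pass(co)
    data.frame(cutoff = co,
               mean_annular_count = mean(s$n_annular),
               annular_chol_pct = if (sum(s$n_annular) > 0)
                 100 * sum(s$n_chol_annular) / sum(s$n_annular) else NA_real_)
  }))
  list(per_frame = pf,
       annular_chol_pct = mean(frame_ann_pct, na.rm = TRUE),
       bulk_chol_pct = mean(frame_blk_pct, na.rm = TRUE),
       pooled = list(
         annular_chol_pct = if (sum(pf$n_annular) > 0)
           100 * sum(pf$n_chol_annular) / sum(pf$n_annular) else NA_real_,
         bulk_chol_pct = if (sum(pf$n_bulk) > 0)
           100 * sum(pf$n_chol_bulk) / sum(pf$n_bulk) else NA_real_),
       annular_count_histogram = table(pf$n_annular),
       cutoff = cutoff,
       sensitivity = sens)
}
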