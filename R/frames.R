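#' Membrane trajectory snapshot
#'
#' One frame of labelled particle coordinates in an orthorhombic box with the
#' bilayer normal along z. Coordinates are in angstrom.
#'
#' @param coords numeric N x 3 matrix of coordinates, angstrom.
#' @param atoms data frame with one row per atom: `resname`, `resid`,
#'   `atomname` (character/integer columns).
#' @param box orthorhombic box lengths `c(lx, ly, lz)`, angstrom.
#' @return An object of class `membrane_frame`.
#' @export
membrane_frame <- function(coords, atoms, box) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L || nrow(coords) != nrow(atoms)) {
    stop("coords must be N x 3 and match atoms rows", call. = FALSE)
  }
  if (!all(is.finite(coords))) stop("coordinates must be finite", call. = FALSE)
  box <- as.numeric(box)
  if (length(box) != 3L || any(!is.finite(box)) || any(box <= 0)) {
    stop("box must be three positive lengths", call. = FALSE)
  }
  need <- c("resname", "resid", "atomname")
  if (!all(need %in% names(atoms))) {
    stop("atoms needs columns resname, resid, atomname", call. = FALSE)
  }
  structure(list(coords = coords,
                 atoms = as.data.frame(atoms)[need],
                 box = box),
            class = "membrane_frame")
}

#' @export
print.membrane_frame <- function(x, ...) {
  cat(sprintf("<membrane_frame> %d atoms, %d residues, box %.1f x %.1f x %.1f A\n",
              nrow(x$coords), length(unique(x$atoms$resid)),
              x$box[1], x$box[2], x$box[3]))
  invisible(x)
}

#' Membrane trajectory
#'
#' An ordered collection of [membrane_frame()] snapshots.
#' @param frames list of [membrane_frame()] objects.
#' @param meta named list of metadata (generator truth, source files, ...).
#' @return An object of class `membrane_trajectory`.
#' @export
membrane_trajectory <- function(frames, meta = list()) {
  if (inherits(frames, "membrane_frame")) frames <- list(frames)
  stopifnot(length(frames) >= 1L,
            all(vapply(frames, inherits, logical(1), "membrane_frame")))
  structure(list(frames = frames, meta = meta), class = "membrane_trajectory")
}

#' @export
print.membrane_trajectory <- function(x, ...) {
  cat(sprintf("<membrane_trajectory> %d frame(s), %d atoms each\n",
              length(x$frames), nrow(x$frames[[1]]$coords)))
  invisible(x)
}

#' @export
length.membrane_trajectory <- function(x) length(x$frames)

as_trajectory <- function(x) {
  if (inherits(x, "membrane_trajectory")) x else membrane_trajectory(x)
}

#' Select atoms of a frame
#'
#' @param frame a [membrane_frame()].
#' @param resname,atomname,resid optional vectors restricting the selection.
#' @param atom_pattern optional regular expression on atom names.
#' @param heavy if `TRUE`, drop hydrogens (atom names starting with H).
#' @return logical vector over atoms.
#' @export
select_atoms <- function(frame, resname = NULL, atomname = NULL, resid = NULL,
                         atom_pattern = NULL, heavy = FALSE) {
  a <- frame$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(resname)) keep <- keep & a$resname %in% resname
  if (!is.null(atomname)) keep <- keep & a$atomname %in% atomname
  if (!is.null(resid)) keep <- keep & a$resid %in% resid
  if (!is.null(atom_pattern)) keep <- keep & grepl(atom_pattern, a$atomname)
  if (heavy) keep <- keep & !grepl("^H", a$atomname)
  keep
}

# resolve a selector (logical vector, function(atoms)->logical, list of
# select_atoms() arguments, or character resname vector) to a logical mask
resolve_selection <- function(frame, sel) {
  if (is.null(sel)) return(rep(FALSE, nrow(frame$atoms)))
  if (is.logical(sel)) {
    stopifnot(length(sel) == nrow(frame$atoms))
    return(sel)
  }
  if (is.function(sel)) return(as.logical(sel(frame$atoms)))
  if (is.character(sel)) return(frame$atoms$resname %in% sel)
  if (is.list(sel)) return(do.call(select_atoms, c(list(frame), sel)))
  stop("cannot interpret atom selector", call. = FALSE)
}

# squared minimum-image distances between two coordinate sets (orthorhombic)
min_image_dist2 <- function(xa, xb, box) {
  d2 <- matrix(0, nrow(xa), nrow(xb))
  for (k in 1:3) {
    d <- outer(xa[, k], xb[, k], "-")
    d <- d - box[k] * round(d / box[k])
    d2 <- d2 + d * d
  }
  d2
}

#' Write a trajectory as a multi-frame PDB file
#'
#' MODEL/ENDMDL-delimited ATOM records with a CRYST1 box line per model.
#' @param traj a [membrane_trajectory()] or single frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_frames_pdb <- function(traj, path) {
  traj <- as_trajectory(traj)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(traj$frames)) {
    fr <- traj$frames[[i]]
    writeLines(sprintf("MODEL     %4d", i), con)
    writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f  90.00  90.00  90.00 P 1           1",
                       fr$box[1], fr$box[2], fr$box[3]), con)
    a <- fr$atoms
    serial <- ((seq_len(nrow(a)) - 1L) %% 99999L) + 1L
    writeLines(sprintf("ATOM  %5d %-4s %-4s%5d    %8.3f%8.3f%8.3f  1.00  0.00",
                       serial, substr(a$atomname, 1, 4), substr(a$resname, 1, 4),
                       a$resid %% 100000L,
                       fr$coords[, 1], fr$coords[, 2], fr$coords[, 3]), con)
    writeLines("ENDMDL", con)
  }
  invisible(path)
}

#' Read a multi-frame PDB file as a trajectory
#'
#' Minimal fixed-column reader for MODEL/ATOM/CRYST1 records as written by
#' [write_frames_pdb()] (or any conforming PDB). For single-structure PDB and
#' DCD trajectories from simulation packages, read with the bio3d package and
#' convert via [membrane_frame()].
#' @param path PDB file.
#' @return a [membrane_trajectory()].
#' @export
read_frames_pdb <- function(path) {
  lines <- readLines(path)
  is_atom <- startsWith(lines, "ATOM")
  is_model <- startsWith(lines, "MODEL")
  is_cryst <- startsWith(lines, "CRYST1")
  if (!any(is_atom)) stop("no ATOM records found", call. = FALSE)
  model_id <- cumsum(is_model)
  if (all(model_id[is_atom] == 0)) model_id <- model_id + 1L
  frames <- list()
  for (m in unique(model_id[is_atom])) {
    sel <- is_atom & model_id == m
    rec <- lines[sel]
    atoms <- data.frame(
      resname = trimws(substr(rec, 18, 21)),
      resid = as.integer(substr(rec, 23, 26)),
      atomname = trimws(substr(rec, 13, 16)))
    coords <- cbind(as.numeric(substr(rec, 31, 38)),
                    as.numeric(substr(rec, 39, 46)),
                    as.numeric(substr(rec, 47, 54)))
    crysts <- lines[is_cryst & model_id == m]
    box <- if (length(crysts)) {
      as.numeric(c(substr(crysts[1], 7, 15), substr(crysts[1], 16, 24),
                   substr(crysts[1], 25, 33)))
    } else {
      apply(coords, 2, function(v) diff(range(v)) + 2)
    }
    frames[[length(frames) + 1L]] <- membrane_frame(coords, atoms, box)
  }
  membrane_trajectory(frames, meta = list(source = path))
}
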