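#' Trajectory ensemble container
#'
#' An ordered set of conformations (frames) of the same atom set, the
#' basic object consumed by the flexibility, essential-dynamics and
#' landscape stages. Coordinates are stored internally in nanometres as a
#' frames-by-(3N) matrix in x1,y1,z1,x2,... order; PDB readers and
#' writers convert from/to angstroms.
#'
#' @param xyz numeric matrix, `T` frames by `3N` coordinates (nm).
#' @param atoms data frame with one row per atom and columns `resno`
#'   (1-based residue index), `resid` (three-letter residue name),
#'   `elety` (atom name, e.g. `"CA"`) and `mass` (amu).
#' @param dt time between consecutive frames within a replica (ps).
#' @param labels per-frame replica identifier (integer or character);
#'   recycled if length 1.
#' @return An object of class `trajectory_ensemble`.
#' @examples
#' tr <- trajectory_ensemble(matrix(rnorm(12), 2, 6),
#'   atoms = data.frame(resno = 1:2, resid = "GLY", elety = "CA", mass = 1),
#'   dt = 5)
#' n_frames(tr)
#' @export
trajectory_ensemble <- function(xyz, atoms, dt = 1, labels = 1L) {
  xyz <- as.matrix(xyz)
  atoms <- as_tibble(atoms)
  if (is.null(atoms$mass)) atoms$mass <- 1
  if (ncol(xyz) != 3 * nrow(atoms)) {
    abort(sprintf(
      "coordinate width %d does not match 3 x %d atoms",
      ncol(xyz), nrow(atoms)
    ))
  }
  if (any(atoms$mass <= 0)) abort("atom masses must be positive")
  if (length(labels) == 1) labels <- rep(labels, nrow(xyz))
  if (length(labels) != nrow(xyz)) {
    abort("labels must have one entry per frame")
  }
  structure(
    list(xyz = xyz, atoms = atoms, dt = dt, labels = labels),
    class = "trajectory_ensemble"
  )
}

#' @rdname trajectory_ensemble
#' @param traj a `trajectory_ensemble`.
#' @export
n_frames <- function(traj) nrow(traj$xyz)

#' @rdname trajectory_ensemble
#' @export
n_atoms <- function(traj) nrow(traj$atoms)

#' @export
print.trajectory_ensemble <- function(x, ...) {
  cat(sprintf(
    "<trajectory_ensemble> %d frames x %d atoms, dt = %g ps, %d replica(s)\n",
    n_frames(x), n_atoms(x), x$dt, length(unique(x$labels))
  ))
  invisible(x)
}

## frame coordinates as an N x 3 matrix
frame_coords <- function(traj, t) {
  matrix(traj$xyz[t, ], ncol = 3, byrow = TRUE)
}

## flatten an N x 3 matrix into the xyz row layout
flatten_coords <- function(m) as.numeric(t(m))

## subset frames, keeping metadata
subset_frames <- function(traj, idx) {
  trajectory_ensemble(traj$xyz[idx, , drop = FALSE], traj$atoms,
    dt = traj$dt, labels = traj$labels[idx]
  )
}

#' Read a trajectory from multi-model PDB files
#'
#' Reads one or more multi-model PDB files (MODEL/ENDMDL blocks) and
#' concatenates their frames in path order. Atom ordering must be
#' identical across files; each file contributes one replica label.
#' Coordinates are converted from angstroms to nanometres. Atom masses
#' are assigned from the atom element via [bio3d::atom2mass()], with
#' unknown elements falling back to 1 amu.
#'
#' @param paths character vector of PDB file paths.
#' @param dt frame spacing in picoseconds.
#' @param masses optional numeric vector overriding per-atom masses (amu).
#' @return A [trajectory_ensemble()]; the per-file frame counts are kept
#'   in the `"load_report"` attribute.
#' @export
read_trajectory <- function(paths, dt = 1, masses = NULL) {
  if (length(paths) < 1) abort("at least one trajectory file is required")
  frames <- list()
  labels <- integer(0)
  atoms <- NULL
  counts <- integer(length(paths))
  for (k in seq_along(paths)) {
    pdb <- bio3d::read.pdb(paths[k], multi = TRUE, verbose = FALSE)
    xyz <- pdb$xyz
    if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
    meta <- tibble(
      resno = pdb$atom$resno,
      resid = pdb$atom$resid,
      elety = pdb$atom$elety
    )
    if (is.null(atoms)) {
      atoms <- meta
    } else if (ncol(xyz) != 3 * nrow(atoms)) {
      abort(sprintf(
        "atom-count mismatch at frame %d (file %s): %d atoms, expected %d",
        length(labels) + 1, paths[k], ncol(xyz) / 3, nrow(atoms)
      ))
    }
    frames[[k]] <- xyz / 10 # angstrom -> nm
    labels <- c(labels, rep(k, nrow(xyz)))
    counts[k] <- nrow(xyz)
  }
  if (is.null(masses)) {
    masses <- tryCatch(
      suppressWarnings(bio3d::atom2mass(atoms$elety, rescue = TRUE)),
      error = function(e) rep(1, nrow(atoms))
    )
    masses[!is.finite(masses) | masses <= 0] <- 1
  }
  atoms$mass <- masses
  out <- trajectory_ensemble(do.call(rbind, frames), atoms,
    dt = dt, labels = labels
  )
  attr(out, "load_report") <- tibble(path = paths, n_frames = counts)
  out
}

#' Write a trajectory as a multi-model PDB file
#'
#' Each frame becomes one MODEL block; coordinates are converted from
#' nanometres to angstroms (PDB precision, 0.001 A).
#'
#' @param traj a [trajectory_ensemble()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory_pdb <- function(traj, path) {
  bio3d::write.pdb(
    file = path,
    xyz = traj$xyz * 10,
    resno = traj$atoms$resno,
    resid = traj$atoms$resid,
    elety = traj$atoms$elety,
    chain = rep("A", n_atoms(traj))
  )
  invisible(path)
}

#' Drop equilibration frames from each replica
#'
#' Removes the first `t_discard` picoseconds of every replica (as
#' identified by the per-frame labels) and re-concatenates the remainder
#' in the original replica order. Used to strip the initial relaxation of
#' a simulation before any statistics are computed.
#'
#' @param traj a [trajectory_ensemble()].
#' @param t_discard time to discard per replica (ps); must be
#'   non-negative and shorter than every replica.
#' @return A [trajectory_ensemble()] with the remaining frames.
#' @examples
#' tr <- trajectory_ensemble(matrix(0, 20, 3),
#'   atoms = data.frame(resno = 1, resid = "GLY", elety = "CA", mass = 1),
#'   dt = 5)
#' n_frames(discard_equilibration(tr, 25)) # 20 - 25/5
#' @export
discard_equilibration <- function(traj, t_discard) {
  if (t_discard < 0) abort("t_discard must be non-negative")
  n_drop <- floor(t_discard / traj$dt + 1e-9)
  keep <- logical(n_frames(traj))
  for (lab in unique(traj$labels)) {
    idx <- which(traj$labels == lab)
    if (n_drop >= length(idx)) {
      abort(sprintf(
        "t_discard = %g ps exceeds the %g ps span of replica '%s'",
        t_discard, length(idx) * traj$dt, lab
      ))
    }
    keep[idx[seq_len(length(idx) - n_drop) + n_drop]] <- TRUE
  }
  subset_frames(traj, which(keep))
}

#' Read a reference structure from a single-model PDB file
#'
#' Loads per-atom heavy-atom coordinates with their residue numbering,
#' for structural checks such as sector contiguity. Coordinates are kept
#' in angstroms (the unit of the contact cutoff); hydrogens are dropped.
#'
#' @param path PDB file.
#' @return An object of class `reference_structure`: a tibble of atoms
#'   (`resno`, `resid`, `elety`, `x`, `y`, `z`) with a `units` attribute.
#' @export
read_reference_structure <- function(path) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  heavy <- !grepl("^H", trimws(at$elety))
  out <- tibble(
    resno = at$resno[heavy], resid = at$resid[heavy],
    elety = at$elety[heavy],
    x = at$x[heavy], y = at$y[heavy], z = at$z[heavy]
  )
  structure(out, units = "angstrom", class = c("reference_structure", class(out)))
}

## build a reference_structure from an atom tibble (angstrom coordinates)
reference_structure <- function(atoms) {
  structure(as_tibble(atoms),
    units = "angstrom",
    class = c("reference_structure", class(as_tibble(atoms)))
  )
}
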