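#' Coordinate trajectory
#'
#' A trajectory binds a [topology()] to a stack of frames. Coordinates are in
#' angstroms, times in nanoseconds, and frames must be uniformly spaced (the
#' downstream analysis windows are expressed in time).
#'
#' @param topology A [topology()].
#' @param coords An `F x N x 3` array of coordinates, or an `N x 3` matrix
#'   for a single frame.
#' @param times Optional numeric vector of frame times (ns), strictly
#'   increasing and equally spaced.
#' @param frame_spacing Optional frame spacing (ns) used to synthesise
#'   `times` when they are not given; defaults to 1e-3 ns.
#' @return An object of class `mltsa_trajectory` with fields `topology`,
#'   `coords`, `times`, `frame_spacing`.
#' @export
trajectory <- function(topology, coords, times = NULL, frame_spacing = NULL) {
  if (is.matrix(coords)) {
    coords <- array(coords, dim = c(1, nrow(coords), ncol(coords)))
  }
  if (length(dim(coords)) != 3 || dim(coords)[3] != 3) {
    abort("coords must be an F x N x 3 array")
  }
  if (dim(coords)[2] != nrow(topology)) {
    abort(sprintf("coords have %d atoms but topology has %d",
                  dim(coords)[2], nrow(topology)))
  }
  if (!all(is.finite(coords))) abort("coordinates must be finite")
  nf <- dim(coords)[1]
  if (is.null(times)) {
    if (is.null(frame_spacing)) frame_spacing <- 1e-3
    times <- frame_spacing * seq_len(nf)
  }
  if (length(times) != nf) abort("length(times) must equal the frame count")
  if (nf > 1) {
    dt <- diff(times)
    if (any(dt <= 0) || max(abs(dt - dt[1])) > 1e-9) {
      abort("frame times must be strictly increasing and equally spaced")
    }
    frame_spacing <- dt[1]
  } else if (is.null(frame_spacing)) {
    frame_spacing <- 1e-3
  }
  structure(
    list(topology = topology, coords = coords, times = as.numeric(times),
         frame_spacing = frame_spacing),
    class = "mltsa_trajectory"
  )
}

#' @export
print.mltsa_trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d frames x %d atoms, %.4g ns/frame, span %.4g ns\n",
              n_frames(x), n_atoms(x), x$frame_spacing,
              x$times[length(x$times)] - x$times[1]))
  invisible(x)
}

#' @rdname trajectory
#' @param traj A trajectory.
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' @rdname trajectory
#' @export
n_atoms <- function(traj) dim(traj$coords)[2]

#' Extract one frame's coordinates as an `N x 3` matrix
#' @param traj A [trajectory()].
#' @param i Frame index (1-based).
#' @export
frame_coords <- function(traj, i) {
  if (i < 1 || i > n_frames(traj)) abort(sprintf("frame index %d out of range", i))
  matrix(traj$coords[i, , ], ncol = 3)
}

#' Keep a subset of frames
#' @param traj A [trajectory()].
#' @param idx Frame indices to keep (must stay equally spaced).
#' @export
subset_frames <- function(traj, idx) {
  trajectory(traj$topology, traj$coords[idx, , , drop = FALSE],
             times = traj$times[idx])
}

# ---- DCD I/O -----------------------------------------------------------

#' Read a DCD trajectory
#'
#' Reads a CHARMM/X-PLOR DCD file (via bio3d) against a known topology.
#' DCD headers do not reliably carry a time base, so frame times are
#' synthesised from `frame_spacing`.
#'
#' @param path Path to a DCD file.
#' @param topology The [topology()] the frames belong to; the frame atom
#'   count must match.
#' @param frame_spacing Frame spacing in ns.
#' @return A [trajectory()].
#' @export
read_trajectory <- function(path, topology, frame_spacing = 1e-3) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  xyz <- tryCatch(
    suppressWarnings(bio3d::read.dcd(path, verbose = FALSE)),
    error = function(e) abort(paste0("failed to read DCD '", path, "': ",
                                     conditionMessage(e)))
  )
  nat <- ncol(xyz) / 3
  if (nat != nrow(topology)) {
    abort(sprintf("DCD has %d atoms per frame but topology has %d",
                  nat, nrow(topology)))
  }
  nf <- nrow(xyz)
  coords <- array(0, dim = c(nf, nat, 3))
  coords[, , 1] <- xyz[, seq(1, 3 * nat, by = 3), drop = FALSE]
  coords[, , 2] <- xyz[, seq(2, 3 * nat, by = 3), drop = FALSE]
  coords[, , 3] <- xyz[, seq(3, 3 * nat, by = 3), drop = FALSE]
  trajectory(topology, coords, frame_spacing = frame_spacing)
}

#' Write a DCD trajectory
#'
#' Minimal single-precision CHARMM-format DCD writer used to produce fixture
#' trajectories (no unit cell, one title line). Round-trips through
#' [read_trajectory()] to within float precision.
#'
#' @param traj A [trajectory()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  con <- tryCatch(file(path, "wb"),
                  error = function(e) abort(paste0("cannot write '", path, "'")))
  on.exit(close(con))
  nf <- n_frames(traj)
  nat <- n_atoms(traj)
  icntrl <- integer(20)
  icntrl[1] <- nf          # number of frames
  icntrl[2] <- 1L          # first step
  icntrl[3] <- 1L          # step interval
  icntrl[4] <- nf          # total steps
  icntrl[20] <- 24L        # CHARMM version flag
  writeBin(84L, con, size = 4)
  writeChar("CORD", con, nchars = 4, eos = NULL)
  writeBin(icntrl[1:9], con, size = 4)
  writeBin(1.0, con, size = 4)            # timestep slot (AKMA), float
  writeBin(icntrl[11:20], con, size = 4)
  writeBin(84L, con, size = 4)
  title <- formatC("fixture trajectory written by mltsa", width = -80)
  writeBin(84L, con, size = 4)
  writeBin(1L, con, size = 4)
  writeChar(substr(title, 1, 80), con, nchars = 80, eos = NULL)
  writeBin(84L, con, size = 4)
  writeBin(4L, con, size = 4)
  writeBin(as.integer(nat), con, size = 4)
  writeBin(4L, con, size = 4)
  reclen <- as.integer(4 * nat)
  for (f in seq_len(nf)) {
    for (ax in 1:3) {
      writeBin(reclen, con, size = 4)
      writeBin(as.numeric(traj$coords[f, , ax]), con, size = 4)
      writeBin(reclen, con, size = 4)
    }
  }
  invisible(path)
}

# ---- superposition and RMSD -------------------------------------------

# Kabsch least-squares fit: rotation+translation taking `mobile` onto `ref`,
# minimising the RMSD of the atoms in `idx`. Returns the transformed N x 3
# matrix for all atoms.
.kabsch_transform <- function(mobile, ref, idx) {
  xm <- colMeans(mobile[idx, , drop = FALSE])
  ym <- colMeans(ref[idx, , drop = FALSE])
  xc <- sweep(mobile[idx, , drop = FALSE], 2, xm)
  yc <- sweep(ref[idx, , drop = FALSE], 2, ym)
  a <- crossprod(xc, yc)            # 3 x 3
  s <- svd(a)
  d <- sign(det(s$u %*% t(s$v)))
  q <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  sweep(sweep(mobile, 2, xm) %*% q, 2, ym, `+`)
}

#' Superpose all frames onto a reference frame
#'
#' Rigid-body (least-squares/Kabsch) superposition of every frame onto the
#' reference, fitting on a selection and applying the transform to all atoms
#' of the frame. Needed before Cartesian PCA and RMSD.
#'
#' @param traj A [trajectory()].
#' @param reference Reference frame index within `traj` (default 1), or a
#'   one-frame [trajectory()] sharing the topology.
#' @param role,heavy_only,residue_range Fitting selection, as in
#'   [select_atoms()]; default protein heavy atoms.
#' @return The superposed trajectory.
#' @export
superpose_frames <- function(traj, reference = 1, role = "protein",
                             heavy_only = TRUE, residue_range = NULL) {
  idx <- select_atoms(traj$topology, role = role, heavy_only = heavy_only,
                      residue_range = residue_range)
  if (length(idx) < 3) abort("superposition needs at least 3 fitting atoms")
  ref <- if (inherits(reference, "mltsa_trajectory")) {
    frame_coords(reference, 1)
  } else {
    frame_coords(traj, reference)
  }
  refc <- sweep(ref[idx, , drop = FALSE], 2, colMeans(ref[idx, , drop = FALSE]))
  if (svd(refc)$d[2] < 1e-8) abort("fitting atoms are collinear")
  out <- traj$coords
  for (f in seq_len(n_frames(traj))) {
    out[f, , ] <- .kabsch_transform(frame_coords(traj, f), ref, idx)
  }
  trajectory(traj$topology, out, times = traj$times)
}

# plain RMSD over a fixed atom set, no fitting
.rmsd <- function(x, y, idx) {
  d <- x[idx, , drop = FALSE] - y[idx, , drop = FALSE]
  sqrt(mean(rowSums(d^2)))
}

#' Ligand heavy-atom RMSD between two frames
#'
#' Measures how far the ligand has moved relative to the receptor: the two
#' frames are first superposed on the protein heavy atoms, then the RMSD is
#' taken over the ligand heavy atoms with no further fitting.
#'
#' @param traj A [trajectory()].
#' @param frame_a,frame_b Frame indices.
#' @return RMSD in angstroms.
#' @export
ligand_rmsd <- function(traj, frame_a, frame_b) {
  lig <- select_atoms(traj$topology, role = "ligand", heavy_only = TRUE,
                      allow_empty = TRUE)
  if (length(lig) == 0) abort("trajectory has no ligand heavy atoms")
  prot <- select_atoms(traj$topology, role = "protein", heavy_only = TRUE)
  a <- frame_coords(traj, frame_a)
  b <- .kabsch_transform(frame_coords(traj, frame_b), frame_coords(traj, frame_a), prot)
  .rmsd(a, b, lig)
}
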