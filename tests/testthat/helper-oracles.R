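# Brute-force oracles and fixture builders shared across the suite.
# Oracles are deliberately naive (explicit loops) and independent of the
# package's vectorised implementations.

oracle_pair_distances <- function(traj, pairs) {
  ids <- traj$topology$atom_id
  out <- matrix(0, n_frames(traj), nrow(pairs))
  for (f in seq_len(n_frames(traj))) {
    xyz <- frame_coords(traj, f)
    for (p in seq_len(nrow(pairs))) {
      a <- xyz[match(pairs$atom_a[p], ids), ]
      b <- xyz[match(pairs$atom_b[p], ids), ]
      out[f, p] <- sqrt(sum((a - b)^2))
    }
  }
  out
}

# exhaustive recount of interacting pairs over all ligand x protein heavy pairs
oracle_detect <- function(traj, config) {
  top <- traj$topology
  lig <- which(top$role == "ligand" & !top$is_hydrogen)
  prot <- which(top$role == "protein" & !top$is_hydrogen)
  frames <- lapply(seq_len(n_frames(traj)), function(f) frame_coords(traj, f))
  res <- NULL
  for (li in lig) {
    for (pi in prot) {
      n_close <- 0L
      for (xyz in frames) {
        if (sqrt(sum((xyz[li, ] - xyz[pi, ])^2)) < config$d_interact) {
          n_close <- n_close + 1L
        }
      }
      occ <- n_close / length(frames)
      if (occ > config$occ_threshold) {
        res <- rbind(res, data.frame(ligand_atom_id = top$atom_id[li],
                                     protein_atom_id = top$atom_id[pi],
                                     occupancy = occ))
      }
    }
  }
  if (is.null(res)) {
    return(data.frame(ligand_atom_id = integer(), protein_atom_id = integer(),
                      occupancy = numeric()))
  }
  res[order(res$ligand_atom_id, res$protein_atom_id), , drop = FALSE]
}

# build a trajectory directly from a list of F coordinate matrices
make_custom_traj <- function(coord_frames, roles, residue_id = NULL,
                             is_hydrogen = NULL, frame_spacing = 0.001,
                             residue_name = NULL) {
  n <- nrow(coord_frames[[1]])
  if (is.null(residue_id)) residue_id <- seq_len(n)
  if (is.null(is_hydrogen)) is_hydrogen <- rep(FALSE, n)
  if (is.null(residue_name)) {
    residue_name <- ifelse(roles == "protein", "GLY",
                           ifelse(roles == "ligand", "LIG",
                                  ifelse(roles == "water", "HOH", "UNK")))
  }
  top <- topology(tibble::tibble(
    atom_id = seq_len(n),
    name = ifelse(is_hydrogen, "H", "CA"),
    element = ifelse(is_hydrogen, "H", "C"),
    is_hydrogen = is_hydrogen,
    residue_id = residue_id,
    residue_name = residue_name,
    role = roles
  ))
  co <- array(0, dim = c(length(coord_frames), n, 3))
  for (f in seq_along(coord_frames)) co[f, , ] <- coord_frames[[f]]
  trajectory(top, co, frame_spacing = frame_spacing)
}

# write a small PDB fixture by hand, optionally without the element column;
# returns the path and the hydrogen count for independent verification
write_pdb_fixture <- function(path, n_atoms = 100, n_hydrogens = 12,
                              with_element = TRUE) {
  set.seed(4)
  lines <- character(n_atoms)
  is_h <- rep(FALSE, n_atoms)
  is_h[sample(n_atoms, n_hydrogens)] <- TRUE
  for (i in seq_len(n_atoms)) {
    resno <- (i - 1) %/% 10 + 1
    resid <- if (resno <= 8) "ALA" else if (resno == 9) "LIG" else "HOH"
    rectype <- if (resid == "ALA") "ATOM" else "HETATM"
    name <- if (is_h[i]) sprintf("H%d", i %% 100) else sprintf("C%d", i %% 100)
    el <- if (!with_element) "" else if (is_h[i]) " H" else " C"
    lines[i] <- sprintf(
      "%-6s%5d  %-3s %3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      rectype, i, name, resid, resno,
      runif(1, -20, 20), runif(1, -20, 20), runif(1, -20, 20), 1, 0, el)
  }
  writeLines(c(lines, "END"), path)
  list(path = path, n_hydrogens = n_hydrogens)
}

# small labeled downhill ensemble reused by ML tests (kept cheap)
small_downhill <- function(seed = 11, n_traj = 40, n_features = 12,
                           n_frames = 150) {
  spec <- toy_system_spec(seed = seed, n_features = n_features,
                          informative_ids = 1:2)
  make_downhill_ensemble(spec, n_traj = n_traj, n_frames = n_frames)
}
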