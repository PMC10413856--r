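#' Ensemble of downhill trajectories
#'
#' Bundles trajectories that share a topology and frame times with their
#' IN/OUT outcome labels; the substrate of the feature builders. UNDECIDED
#' trajectories must be dropped before featurization.
#'
#' @param trajectories List of [trajectory()] objects.
#' @param labels Factor of outcome labels, one per trajectory.
#' @export
trajectory_ensemble <- function(trajectories, labels) {
  if (length(trajectories) == 0) abort("ensemble needs at least one trajectory")
  labels <- droplevels(factor(labels))
  if (length(labels) != length(trajectories)) {
    abort("one label per trajectory required")
  }
  if (any(labels == "UNDECIDED")) {
    abort("drop UNDECIDED trajectories before building an ensemble")
  }
  t0 <- trajectories[[1]]
  for (tr in trajectories[-1]) {
    if (n_atoms(tr) != n_atoms(t0) ||
        n_frames(tr) != n_frames(t0) ||
        max(abs(tr$times - t0$times)) > 1e-9) {
      abort("ensemble trajectories must share topology size and frame times")
    }
  }
  structure(list(trajectories = trajectories, labels = labels,
                 topology = t0$topology, times = t0$times),
            class = "trajectory_ensemble")
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  cat(sprintf("<ensemble> %d trajectories x %d frames x %d atoms\n",
              length(x$trajectories), n_frames(x$trajectories[[1]]),
              n_atoms(x$trajectories[[1]])))
  print(table(x$labels))
  invisible(x)
}

# minimum distance from each atom in `idx` to any atom in `ref_idx`, one frame
.min_dist_to_set <- function(xyz, idx, ref_idx) {
  a <- xyz[idx, , drop = FALSE]
  b <- xyz[ref_idx, , drop = FALSE]
  d2 <- outer(rowSums(a^2), rep(1, nrow(b))) +
    outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * a %*% t(b)
  sqrt(pmax(apply(d2, 1, min), 0))
}

.pair_descriptors <- function(top, pairs) {
  pm <- match(pairs$protein_atom_id, top$atom_id)
  tibble(
    feature = paste0("d_", pairs$ligand_atom_id, "_", pairs$protein_atom_id),
    kind = "pair_distance",
    ligand_atom_id = pairs$ligand_atom_id,
    protein_atom_id = pairs$protein_atom_id,
    residue_id = top$residue_id[pm],
    residue_name = top$residue_name[pm],
    water_molecule_id = NA_integer_,
    component_index = NA_integer_
  )
}

#' Ligand--protein pair-distance features from a distance shell
#'
#' Selects the protein heavy atoms whose minimum distance to any ligand
#' heavy atom at the reference (transition-state) structure is below
#' `cutoff`, optionally augments the selection with all heavy atoms of a
#' residue range regardless of distance, and builds one feature per
#' (ligand heavy atom x selected protein atom) pair, evaluated on every
#' frame of every trajectory. With `semantics = "strict"` only the pairs
#' themselves closer than `cutoff` at the reference are kept.
#'
#' @param ensemble A [trajectory_ensemble()].
#' @param reference A one-frame [trajectory()]: the shared starting
#'   (TS) structure.
#' @param cutoff Shell cutoff (angstrom), e.g. 3 or 6.
#' @param augment_residue_range Optional inclusive residue-id range
#'   `c(first, last)` whose heavy atoms are always included.
#' @param semantics `"shell"` (default; atoms within `cutoff` of the
#'   ligand, all ligand pairs to them) or `"strict"` (only pairs closer
#'   than `cutoff`).
#' @return A [feature_matrix()].
#' @export
shell_pair_features <- function(ensemble, reference, cutoff = 3,
                                augment_residue_range = NULL,
                                semantics = c("shell", "strict")) {
  semantics <- match.arg(semantics)
  top <- ensemble$topology
  lig <- select_atoms(top, role = "ligand", heavy_only = TRUE)
  prot <- select_atoms(top, role = "protein", heavy_only = TRUE)
  xyz <- frame_coords(reference, 1)
  mind <- .min_dist_to_set(xyz, prot, lig)
  sel <- prot[mind < cutoff]
  if (!is.null(augment_residue_range)) {
    extra <- select_atoms(top, role = "protein", heavy_only = TRUE,
                          residue_range = augment_residue_range)
    sel <- sort(union(sel, extra))
  }
  if (length(sel) == 0) abort("shell selection is empty; increase the cutoff")
  pairs <- tidyr::expand_grid(
    ligand_atom_id = top$atom_id[lig],
    protein_atom_id = top$atom_id[sel]
  )
  if (semantics == "strict") {
    li <- match(pairs$ligand_atom_id, top$atom_id)
    pi <- match(pairs$protein_atom_id, top$atom_id)
    dref <- sqrt(rowSums((xyz[li, , drop = FALSE] - xyz[pi, , drop = FALSE])^2))
    aug <- if (is.null(augment_residue_range)) rep(FALSE, nrow(pairs)) else {
      top$residue_id[pi] >= augment_residue_range[1] &
        top$residue_id[pi] <= augment_residue_range[2]
    }
    pairs <- pairs[dref < cutoff | aug, , drop = FALSE]
    if (nrow(pairs) == 0) abort("strict shell selection is empty")
  }
  s <- length(ensemble$trajectories)
  values <- array(0, dim = c(s, length(ensemble$times), nrow(pairs)))
  for (i in seq_len(s)) {
    values[i, , ] <- interatomic_distances(ensemble$trajectories[[i]], pairs)
  }
  feature_matrix(values, .pair_descriptors(top, pairs),
                 ensemble$labels, ensemble$times)
}

#' Closest residue--ligand distance features
#'
#' One feature per protein residue: the minimum heavy-atom distance between
#' that residue and the ligand, recomputed on every frame (so the closest
#' atom may change identity frame to frame).
#'
#' @param ensemble A [trajectory_ensemble()].
#' @return A [feature_matrix()] with `residue_min_distance` descriptors.
#' @export
residue_min_features <- function(ensemble) {
  top <- ensemble$topology
  lig <- select_atoms(top, role = "ligand", heavy_only = TRUE)
  prot <- select_atoms(top, role = "protein", heavy_only = TRUE)
  res_ids <- unique(top$residue_id[prot])
  res_of <- split(prot, top$residue_id[prot])[as.character(res_ids)]
  s <- length(ensemble$trajectories)
  nt <- length(ensemble$times)
  values <- array(0, dim = c(s, nt, length(res_ids)))
  for (i in seq_len(s)) {
    tr <- ensemble$trajectories[[i]]
    for (f in seq_len(nt)) {
      xyz <- frame_coords(tr, f)
      md <- .min_dist_to_set(xyz, prot, lig)
      values[i, f, ] <- vapply(seq_along(res_ids), function(r) {
        min(md[match(res_of[[r]], prot)])
      }, numeric(1))
    }
  }
  descriptors <- tibble(
    feature = paste0("res_", res_ids),
    kind = "residue_min_distance",
    ligand_atom_id = NA_integer_, protein_atom_id = NA_integer_,
    residue_id = res_ids,
    residue_name = top$residue_name[match(res_ids, top$residue_id)],
    water_molecule_id = NA_integer_, component_index = NA_integer_
  )
  feature_matrix(values, descriptors, ensemble$labels, ensemble$times)
}

#' Closest-water distance features
#'
#' Ranks water molecules by their minimum heavy-atom distance to the ligand
#' at the reference structure, keeps the closest `n_waters`, and tracks
#' those molecules by identity across all frames (their feature grows if
#' they drift away; the selection never re-ranks). `track = "per_frame"`
#' instead reports the k-th smallest water--ligand distance each frame.
#'
#' @param ensemble A [trajectory_ensemble()].
#' @param reference A one-frame [trajectory()] (the TS structure).
#' @param n_waters Number of waters tracked, default 8.
#' @param base Optional [feature_matrix()] the water features are appended
#'   to.
#' @param track `"reference"` (fixed identity, default) or `"per_frame"`.
#' @return A [feature_matrix()].
#' @export
water_features <- function(ensemble, reference, n_waters = 8, base = NULL,
                           track = c("reference", "per_frame")) {
  track <- match.arg(track)
  top <- ensemble$topology
  lig <- select_atoms(top, role = "ligand", heavy_only = TRUE)
  wat <- select_atoms(top, role = "water", heavy_only = TRUE, allow_empty = TRUE)
  mol_ids <- unique(top$residue_id[wat])
  if (length(mol_ids) < n_waters) {
    abort(sprintf("need %d water molecules but only %d are present",
                  n_waters, length(mol_ids)))
  }
  atoms_of <- split(wat, top$residue_id[wat])

  mol_min <- function(xyz, ids) {
    vapply(as.character(ids), function(m) {
      min(.min_dist_to_set(xyz, atoms_of[[m]], lig))
    }, numeric(1))
  }
  ref_d <- mol_min(frame_coords(reference, 1), mol_ids)
  keep <- mol_ids[order(ref_d)][seq_len(n_waters)]

  s <- length(ensemble$trajectories)
  nt <- length(ensemble$times)
  values <- array(0, dim = c(s, nt, n_waters))
  for (i in seq_len(s)) {
    tr <- ensemble$trajectories[[i]]
    for (f in seq_len(nt)) {
      xyz <- frame_coords(tr, f)
      values[i, f, ] <- if (track == "reference") {
        mol_min(xyz, keep)
      } else {
        sort(mol_min(xyz, mol_ids))[seq_len(n_waters)]
      }
    }
  }
  descriptors <- tibble(
    feature = if (track == "reference") paste0("wat_", keep)
              else paste0("wat_rank", seq_len(n_waters)),
    kind = "water_distance",
    ligand_atom_id = NA_integer_, protein_atom_id = NA_integer_,
    residue_id = NA_integer_, residue_name = NA_character_,
    water_molecule_id = if (track == "reference") as.integer(keep)
                        else NA_integer_,
    component_index = NA_integer_
  )
  fm <- feature_matrix(values, descriptors, ensemble$labels, ensemble$times)
  if (is.null(base)) fm else bind_features(base, fm)
}

#' Cartesian-coordinate PCA features
#'
#' Superposes every frame on the reference (protein heavy atoms), flattens
#' the protein heavy-atom coordinates, fits a PCA on the pooled in-window
#' frames of the whole ensemble, and uses the projections on the top
#' components as features.
#'
#' @param ensemble A [trajectory_ensemble()].
#' @param reference A one-frame [trajectory()] for the superposition.
#' @param n_components Number of components kept, default 100; truncated
#'   with a warning when it exceeds the rank of the pooled data.
#' @param window Optional `c(t_start, t_end)` (ns) restricting the pooled
#'   frames (and the returned features) to the analysis window.
#' @return A list: `features` (a [feature_matrix()]) and `model` (class
#'   `pca_model`: `mean`, `rotation`, `sdev`, `atom_ids`).
#' @export
xyz_pca_features <- function(ensemble, reference, n_components = 100,
                             window = NULL) {
  top <- ensemble$topology
  prot <- select_atoms(top, role = "protein", heavy_only = TRUE)
  idx_t <- if (is.null(window)) seq_along(ensemble$times) else {
    which(ensemble$times > window[1] & ensemble$times <= window[2])
  }
  if (length(idx_t) == 0) abort("no frames fall inside the window")
  s <- length(ensemble$trajectories)
  nt <- length(idx_t)
  x <- matrix(0, s * nt, 3 * length(prot))
  for (i in seq_len(s)) {
    fitted <- superpose_frames(ensemble$trajectories[[i]], reference)
    for (k in seq_len(nt)) {
      x[(i - 1L) * nt + k, ] <- t(frame_coords(fitted, idx_t[k])[prot, , drop = FALSE])
    }
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  rank <- sum(pc$sdev > max(pc$sdev) * 1e-10)
  if (n_components > rank) {
    warn(sprintf("n_components truncated from %d to the data rank %d",
                 n_components, rank))
    n_components <- rank
  }
  proj <- pc$x[, seq_len(n_components), drop = FALSE]
  values <- array(0, dim = c(s, nt, n_components))
  for (i in seq_len(s)) {
    values[i, , ] <- proj[(i - 1L) * nt + seq_len(nt), , drop = FALSE]
  }
  descriptors <- tibble(
    feature = paste0("PC", seq_len(n_components)),
    kind = "pca_component",
    ligand_atom_id = NA_integer_, protein_atom_id = NA_integer_,
    residue_id = NA_integer_, residue_name = NA_character_,
    water_molecule_id = NA_integer_,
    component_index = seq_len(n_components)
  )
  model <- structure(
    list(mean = pc$center,
         rotation = pc$rotation[, seq_len(n_components), drop = FALSE],
         sdev = pc$sdev, atom_ids = top$atom_id[prot]),
    class = "pca_model"
  )
  list(
    features = feature_matrix(values, descriptors, ensemble$labels,
                              ensemble$times[idx_t]),
    model = model
  )
}

#' Per-residue contributions to PCA components
#'
#' The contribution of residue r to component c is the sum of squared
#' loadings of r's atom coordinates in c; since each component's loading
#' vector has unit norm, contributions sum to 1 per component.
#'
#' @param model A `pca_model` from [xyz_pca_features()].
#' @param topology The [topology()] the model was fitted on.
#' @return A tibble: `component`, `residue_id`, `residue_name`,
#'   `contribution`.
#' @export
pca_residue_contributions <- function(model, topology) {
  if (3 * length(model$atom_ids) != nrow(model$rotation)) {
    abort("model rotation does not match its atom count")
  }
  pos <- match(model$atom_ids, topology$atom_id)
  if (anyNA(pos)) abort("model atoms are not all present in the topology")
  res <- topology$residue_id[pos]
  res_rows <- rep(res, each = 3)
  purrr::map_dfr(seq_len(ncol(model$rotation)), function(cc) {
    load2 <- model$rotation[, cc]^2
    contrib <- tapply(load2, res_rows, sum)
    tibble(
      component = cc,
      residue_id = as.integer(names(contrib)),
      residue_name = topology$residue_name[match(as.integer(names(contrib)),
                                                 topology$residue_id)],
      contribution = as.numeric(contrib)
    )
  })
}

#' Water occupancy of an H-bonding site
#'
#' Occupancy is the fraction of frames in which at least one water oxygen
#' (water heavy atom) lies within `cutoff` of the site atom; the returned
#' residence segments are the lengths (in frames) of each water molecule's
#' maximal runs of continuous occupancy, for comparing how easily waters
#' swap places.
#'
#' @param traj A [trajectory()] containing waters.
#' @param site_atom_id Atom id of the protein donor/acceptor heavy atom.
#' @param cutoff Distance criterion (angstrom), default 3.5.
#' @return A list: `occupancy` (fraction) and `segments` (tibble
#'   `water_molecule_id`, `length_frames`).
#' @export
water_site_occupancy <- function(traj, site_atom_id, cutoff = 3.5) {
  top <- traj$topology
  site <- match(site_atom_id, top$atom_id)
  if (is.na(site)) abort(sprintf("no atom with id %s", site_atom_id))
  wat <- select_atoms(top, role = "water", heavy_only = TRUE, allow_empty = TRUE)
  if (length(wat) == 0) abort("trajectory has no waters")
  pairs <- tibble(atom_a = rep(top$atom_id[site], length(wat)),
                  atom_b = top$atom_id[wat])
  d <- interatomic_distances(traj, pairs)          # F x n_wat
  inside <- d < cutoff
  occupancy <- mean(apply(inside, 1, any))
  mol <- top$residue_id[wat]
  segments <- purrr::map_dfr(unique(mol), function(m) {
    occ <- apply(inside[, mol == m, drop = FALSE], 1, any)
    r <- rle(occ)
    len <- r$lengths[r$values]
    if (length(len) == 0) return(tibble())
    tibble(water_molecule_id = m, length_frames = as.integer(len))
  })
  list(occupancy = occupancy, segments = segments)
}
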