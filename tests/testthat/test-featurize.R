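make_shell_fixture <- function() {
  # 3 ligand atoms at the origin region; protein atoms at 2.5, 2.8 (inside
  # a 3 A shell), 5 (inside 6 A), 20 (outside both); two frames
  base <- rbind(
    c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),        # ligand
    c(2.9, 0, 0), c(0, 2.8, 0), c(5, 0, 0), c(20, 0, 0))
  f2 <- base
  f2[4, ] <- c(2.6, 0, 0)
  make_custom_traj(list(base, f2),
                   roles = c(rep("ligand", 3), rep("protein", 4)),
                   residue_id = c(1, 1, 1, 2, 3, 4, 5))
}

test_that("shell selection sizes, nesting, and strict semantics behave", {
  tr <- make_shell_fixture()
  ens <- trajectory_ensemble(list(tr, tr), factor(c("IN", "OUT")))
  ref <- subset_frames(tr, 1)
  f3 <- shell_pair_features(ens, ref, cutoff = 3)
  # 2 protein atoms inside 3 A of a ligand atom x 3 ligand atoms
  expect_equal(mltsa::n_features(f3), 6)
  f6 <- shell_pair_features(ens, ref, cutoff = 6)
  expect_equal(mltsa::n_features(f6), 9)
  key <- function(fm) paste(fm$descriptors$ligand_atom_id,
                            fm$descriptors$protein_atom_id)
  expect_true(all(key(f3) %in% key(f6)))

  # strict pair semantics keeps only pairs themselves under the cutoff
  fs <- shell_pair_features(ens, ref, cutoff = 3, semantics = "strict")
  expect_lt(mltsa::n_features(fs), mltsa::n_features(f3))
  d_ref <- interatomic_distances(ref, tibble::tibble(
    atom_a = fs$descriptors$ligand_atom_id, atom_b = fs$descriptors$protein_atom_id))
  expect_true(all(d_ref < 3))

  # residue-range augmentation pulls in atoms regardless of distance
  fa <- shell_pair_features(ens, ref, cutoff = 3, augment_residue_range = c(5, 5))
  expect_equal(mltsa::n_features(fa), 9)
  expect_true(5L %in% fa$descriptors$residue_id)
})

test_that("a wide 6 A shell reproduces the expected feature count exactly", {
  # sized so ligand atoms x selected protein atoms is ~5000 features
  spec <- receptor_spec(seed = 19, n_protein_atoms = 1667, n_ligand_atoms = 3,
                        n_waters = 0, pair_mean = 4, pair_sd = 0.2)
  tr <- make_toy_receptor_trajectory(spec, 2)
  ens <- trajectory_ensemble(list(tr), factor("IN", levels = c("IN", "OUT")))
  ref <- subset_frames(tr, 1)
  fm <- shell_pair_features(ens, ref, cutoff = 6)
  # independent enumeration of the selection at the reference frame
  xyz <- frame_coords(ref, 1)
  lig <- which(tr$topology$role == "ligand")
  prot <- which(tr$topology$role == "protein")
  n_sel <- 0L
  for (p in prot) {
    if (min(sqrt(colSums((t(xyz[lig, , drop = FALSE]) - xyz[p, ])^2))) < 6) {
      n_sel <- n_sel + 1L
    }
  }
  expect_equal(mltsa::n_features(fm), 3L * n_sel)
  expect_gt(mltsa::n_features(fm), 4000)
})

test_that("per-residue minimum distances track the closest atom each frame", {
  tr <- make_shell_fixture()
  ens <- trajectory_ensemble(list(tr), factor("IN", levels = c("IN", "OUT")))
  fm <- residue_min_features(ens)
  expect_equal(mltsa::n_features(fm), 4)
  # residue 2's atom sits 1.9 A then 1.6 A from the nearest ligand atom
  j <- which(fm$descriptors$residue_id == 2)
  expect_equal(fm$values[1, , j], c(1.9, 1.6))

  # identity of the closest atom may switch between frames
  frames <- list(
    rbind(c(0, 0, 0), c(4, 0, 0), c(0, 6, 0)),
    rbind(c(0, 0, 0), c(7, 0, 0), c(0, 6, 0)))
  tr2 <- make_custom_traj(frames, roles = c("ligand", "protein", "protein"),
                          residue_id = c(1, 2, 2))
  ens2 <- trajectory_ensemble(list(tr2), factor("OUT", levels = c("IN", "OUT")))
  fm2 <- residue_min_features(ens2)
  expect_equal(fm2$values[1, , 1], c(4, 6))
})

test_that("residue minima agree with brute force and bound the pair features", {
  spec <- receptor_spec(seed = 23, n_protein_atoms = 12, n_ligand_atoms = 2,
                        n_waters = 0, pair_mean = seq(2.5, 5, length.out = 12))
  tr <- make_toy_receptor_trajectory(spec, 8)
  ens <- trajectory_ensemble(list(tr), factor("IN", levels = c("IN", "OUT")))
  fm <- residue_min_features(ens)
  top <- tr$topology
  for (f in seq_len(8)) {
    xyz <- frame_coords(tr, f)
    for (j in seq_len(mltsa::n_features(fm))) {
      rid <- fm$descriptors$residue_id[j]
      ats <- which(top$residue_id == rid & top$role == "protein")
      ligs <- which(top$role == "ligand")
      best <- Inf
      for (a in ats) for (l in ligs) {
        best <- min(best, sqrt(sum((xyz[a, ] - xyz[l, ])^2)))
      }
      expect_equal(fm$values[1, f, j], best, tolerance = 1e-12)
    }
  }
  # frame-wise lower bound on every pair feature of the same residue
  f6 <- shell_pair_features(ens, subset_frames(tr, 1), cutoff = 20)
  for (j in seq_len(mltsa::n_features(f6))) {
    rid <- f6$descriptors$residue_id[j]
    k <- which(fm$descriptors$residue_id == rid)
    expect_true(all(fm$values[1, , k] <= f6$values[1, , j] + 1e-12))
  }
})

test_that("water features fix molecule identity at the reference frame", {
  spec <- receptor_spec(seed = 29, n_waters = 10, water_shell_radius = 8)
  tr <- make_toy_receptor_trajectory(spec, 6)
  ens <- trajectory_ensemble(list(tr), factor("IN", levels = c("IN", "OUT")))
  ref <- subset_frames(tr, 1)
  fm <- water_features(ens, ref, n_waters = 8)
  expect_equal(mltsa::n_features(fm), 8)

  # selected identities are the 8 nearest molecules at the reference
  top <- tr$topology
  wat <- which(top$role == "water")
  xyz <- frame_coords(ref, 1)
  lig <- which(top$role == "ligand")
  d_ref <- vapply(wat, function(w) {
    min(sqrt(colSums((t(xyz[lig, , drop = FALSE]) - xyz[w, ])^2)))
  }, numeric(1))
  nearest <- top$residue_id[wat][order(d_ref)][1:8]
  expect_setequal(fm$descriptors$water_molecule_id, nearest)

  # per-frame values equal a brute-force recomputation
  for (f in 1:6) {
    xyzf <- frame_coords(tr, f)
    for (j in 1:8) {
      w <- which(top$residue_id == fm$descriptors$water_molecule_id[j] &
                   top$role == "water")
      expect_equal(fm$values[1, f, j],
                   min(sqrt(colSums((t(xyzf[lig, , drop = FALSE]) - xyzf[w, ])^2))),
                   tolerance = 1e-12)
    }
  }
  expect_error(water_features(ens, ref, n_waters = 11), "only 10")
})

test_that("a tracked water that drifts away keeps its identity", {
  # water 1 starts closest then leaves; water 2 stays put
  frames <- lapply(0:4, function(k) {
    rbind(c(0, 0, 0), c(2 + 3 * k, 0, 0), c(0, 4, 0))
  })
  tr <- make_custom_traj(frames, roles = c("ligand", "water", "water"),
                         residue_id = c(1, 2, 3))
  ens <- trajectory_ensemble(list(tr), factor("IN", levels = c("IN", "OUT")))
  fm <- water_features(ens, subset_frames(tr, 1), n_waters = 1)
  expect_equal(fm$descriptors$water_molecule_id, 2L)
  expect_equal(fm$values[1, , 1], c(2, 5, 8, 11, 14))
  # per-frame re-ranking switches to the nearer molecule instead
  fm2 <- water_features(ens, subset_frames(tr, 1), n_waters = 1,
                        track = "per_frame")
  expect_equal(fm2$values[1, , 1], c(2, 4, 4, 4, 4))
})

make_pca_ensemble <- function(amp1 = 2, amp2 = 0, n_frames = 40, seed = 77) {
  # residues 1 and 2 move coherently along x with amplitudes amp1/amp2;
  # the remaining residues are static scaffold
  set.seed(seed)
  n_res <- 11
  base <- matrix(rnorm(3 * n_res * 3, sd = 6), ncol = 3)
  z <- sin(seq(0, 6 * pi, length.out = n_frames))
  frames <- lapply(seq_len(n_frames), function(f) {
    x <- base
    x[1:3, 1] <- x[1:3, 1] + amp1 * z[f]
    x[4:6, 1] <- x[4:6, 1] + amp2 * z[f]
    x
  })
  tr <- make_custom_traj(frames, roles = rep("protein", 3 * n_res),
                         residue_id = rep(seq_len(n_res), each = 3))
  trajectory_ensemble(list(tr), factor("IN", levels = c("IN", "OUT")))
}

test_that("Cartesian PCA matches an SVD oracle with orthonormal components", {
  ens <- make_pca_ensemble(amp1 = 2, amp2 = 1)
  ref <- subset_frames(ens$trajectories[[1]], 1)
  expect_warning(res <- xyz_pca_features(ens, ref, n_components = 50),
                 "truncated")
  rot <- res$model$rotation
  gram <- crossprod(rot)
  expect_lt(max(abs(gram - diag(ncol(rot)))), 1e-8)
  expect_true(all(diff(res$model$sdev) <= 1e-8))

  # projections equal the SVD of the pooled centered matrix up to sign
  sup <- superpose_frames(ens$trajectories[[1]], ref)
  prot <- select_atoms(ens$topology, "protein", heavy_only = TRUE)
  x <- t(vapply(seq_len(n_frames(sup)), function(f) {
    as.numeric(t(frame_coords(sup, f)[prot, ]))
  }, numeric(3 * length(prot))))
  xc <- scale(x, center = TRUE, scale = FALSE)
  sv <- svd(xc)
  proj_oracle <- sv$u %*% diag(sv$d)
  for (k in seq_len(ncol(rot))) {
    got <- res$features$values[1, , k]
    expect_lt(min(max(abs(got - proj_oracle[, k])),
                  max(abs(got + proj_oracle[, k]))), 1e-6)
  }

  # total explained variance equals total coordinate variance
  expect_equal(sum(res$model$sdev^2), sum(apply(xc, 2, stats::var)),
               tolerance = 1e-6)
})

test_that("PCA rank collapses when motion is confined to a plane", {
  ens <- make_pca_ensemble(amp1 = 2, amp2 = 1)
  ref <- subset_frames(ens$trajectories[[1]], 1)
  suppressWarnings(res <- xyz_pca_features(ens, ref, n_components = 10))
  ev <- res$model$sdev^2
  # one coherent degree of freedom plus superposition residue: the spectrum
  # beyond the leading component is negligible
  expect_lt(sum(ev[-1]) / sum(ev), 0.05)
})

test_that("residue contributions normalise and recover planted ratios", {
  # constructed loadings: residue 1 carries 0.8, residue 2 carries 0.2
  rot <- matrix(0, 12, 2)
  rot[1:6, 1] <- sqrt(0.8 / 6)
  rot[7:12, 1] <- sqrt(0.2 / 6)
  rot[1:6, 2] <- sqrt(0.2 / 6)
  rot[7:12, 2] <- -sqrt(0.8 / 6)
  model <- structure(list(mean = rep(0, 12), rotation = rot, sdev = c(2, 1),
                          atom_ids = 1:4), class = "pca_model")
  top <- topology(tibble::tibble(
    atom_id = 1:4, name = "CA", element = "C", is_hydrogen = FALSE,
    residue_id = c(1, 1, 2, 2), residue_name = "GLY", role = "protein"))
  contrib <- pca_residue_contributions(model, top)
  sums <- tapply(contrib$contribution, contrib$component, sum)
  expect_equal(as.numeric(sums), c(1, 1), tolerance = 1e-8)
  c1 <- contrib$contribution[contrib$component == 1]
  expect_equal(c1[1] / c1[2], 4, tolerance = 1e-8)

  # end to end: motion confined to one residue dominates component 1
  ens <- make_pca_ensemble(amp1 = 2, amp2 = 0)
  ref <- subset_frames(ens$trajectories[[1]], 1)
  suppressWarnings(res <- xyz_pca_features(ens, ref, n_components = 5))
  contrib <- pca_residue_contributions(res$model, ens$topology)
  c1 <- contrib[contrib$component == 1, ]
  expect_gt(c1$contribution[c1$residue_id == 1], 0.8)
  expect_equal(sum(c1$contribution), 1, tolerance = 1e-8)
})

test_that("water-site occupancy counts frames and residence segments exactly", {
  # water A inside for frames 1-60 and 81-100; water B inside 61-73
  frames <- lapply(1:100, function(f) {
    da <- if (f <= 60 || f > 80) 2.5 else 9
    db <- if (f > 60 && f <= 73) 3.0 else 12
    rbind(c(0, 0, 0), c(da, 0, 0), c(0, db, 0))
  })
  tr <- make_custom_traj(frames, roles = c("protein", "water", "water"),
                         residue_id = c(1, 2, 3))
  res <- water_site_occupancy(tr, site_atom_id = 1, cutoff = 3.5)
  expect_equal(res$occupancy, 0.93)
  expect_equal(sort(res$segments$length_frames[res$segments$water_molecule_id == 2]),
               c(20, 60))
  expect_equal(res$segments$length_frames[res$segments$water_molecule_id == 3], 13)

  always <- make_custom_traj(list(rbind(c(0, 0, 0), c(2, 0, 0)),
                                  rbind(c(0, 0, 0), c(2, 0, 0))),
                             roles = c("protein", "water"), residue_id = c(1, 2))
  expect_equal(water_site_occupancy(always, 1)$occupancy, 1)
  never <- make_custom_traj(list(rbind(c(0, 0, 0), c(9, 0, 0)),
                                 rbind(c(0, 0, 0), c(9, 0, 0))),
                            roles = c("protein", "water"), residue_id = c(1, 2))
  expect_equal(water_site_occupancy(never, 1)$occupancy, 0)
  expect_error(water_site_occupancy(never, 99), "no atom")
})

test_that("permuting feature columns with their descriptors leaves rankings intact", {
  ens <- small_downhill(seed = 71, n_traj = 30, n_features = 8, n_frames = 60)
  fm <- ens$features
  set.seed(5)
  perm <- sample(mltsa::n_features(fm))
  fm_perm <- feature_matrix(fm$values[, , perm, drop = FALSE],
                            fm$descriptors[perm, ], fm$labels, fm$times)
  cfg <- ensemble_config("gbdt", n_models = 5, base_seed = 3,
                         window = c(0.04, 0.2))
  top_by_name <- function(f) {
    prof <- tidy(rfi_importance(train_ensemble(f, cfg)))
    prof$feature[order(-prof$mean)][1:2]
  }
  expect_setequal(top_by_name(fm), top_by_name(fm_perm))
})
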