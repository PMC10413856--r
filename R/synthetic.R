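# kT at 310.15 K in kcal/mol, used to convert restraint force constants
# (kcal mol^-1 A^-2) into reduced units for the toy propagators
.kt_kcal <- 0.0019872041 * 310.15

# run code under a fixed seed without clobbering the caller's RNG stream
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Specification of a pseudo-atom receptor/ligand/water system
#'
#' Describes a toy system in which every protein atom is tethered to one
#' ligand atom and their distance follows a stationary Ornstein--Uhlenbeck
#' process: mean `pair_mean`, stationary standard deviation `pair_sd`,
#' relaxation time `pair_tau`. Waters are single-site (oxygen-only)
#' pseudo-molecules placed on a shell around the complex. Used to exercise
#' pair detection, featurization and water analyses against exact
#' bookkeeping.
#'
#' @param n_protein_atoms,n_ligand_atoms,n_waters Atom/molecule counts.
#' @param pair_mean Mean pair distance(s), angstrom; recycled to the number
#'   of protein atoms.
#' @param pair_sd Stationary standard deviation of the distance process.
#' @param pair_tau Relaxation time (ns).
#' @param atoms_per_residue Protein atoms grouped into residues of this size.
#' @param water_shell_radius Radius of the water shell (angstrom).
#' @param frame_spacing Frame spacing (ns).
#' @param seed Seed making the generated trajectory deterministic.
#' @export
receptor_spec <- function(n_protein_atoms = 20, n_ligand_atoms = 3,
                          n_waters = 10, pair_mean = 4, pair_sd = 0.3,
                          pair_tau = 0.05, atoms_per_residue = 4,
                          water_shell_radius = 12, frame_spacing = 0.001,
                          seed = 1L) {
  if (n_protein_atoms < 1 || n_ligand_atoms < 1 || n_waters < 0) {
    abort("counts must be positive")
  }
  if (any(pair_mean <= 0)) abort("pair means must be positive")
  if (pair_sd <= 0 || pair_tau <= 0) abort("pair_sd and pair_tau must be positive")
  structure(
    list(n_protein_atoms = as.integer(n_protein_atoms),
         n_ligand_atoms = as.integer(n_ligand_atoms),
         n_waters = as.integer(n_waters),
         pair_mean = rep_len(pair_mean, n_protein_atoms),
         pair_sd = pair_sd, pair_tau = pair_tau,
         atoms_per_residue = as.integer(atoms_per_residue),
         water_shell_radius = water_shell_radius,
         frame_spacing = frame_spacing, seed = as.integer(seed)),
    class = "receptor_spec"
  )
}

#' Generate a pseudo-atom receptor--ligand--water trajectory
#'
#' Ligand atoms sit at fixed positions near the origin; protein atom `i` is
#' placed along a fixed random direction from its partner ligand atom at a
#' distance following the spec's OU process, so designated pair distances
#' have known stationary statistics. Waters are static single-oxygen sites
#' on an outer shell (with small positional jitter).
#'
#' @param spec A [receptor_spec()].
#' @param n_frames Number of frames (>= 2).
#' @return A [trajectory()]; the designated pairs are recoverable as
#'   protein atom `i` vs ligand atom `(i - 1) %% n_ligand + 1`.
#' @export
make_toy_receptor_trajectory <- function(spec, n_frames) {
  if (!inherits(spec, "receptor_spec")) abort("spec must be a receptor_spec")
  if (n_frames < 2) abort("n_frames must be >= 2")
  np <- spec$n_protein_atoms
  nl <- spec$n_ligand_atoms
  nw <- spec$n_waters

  top <- topology(tibble(
    atom_id = seq_len(np + nl + nw),
    name = c(rep("CA", np), paste0("C", seq_len(nl)), rep("OH2", max(nw, 0))[seq_len(nw)]),
    element = c(rep("C", np + nl), rep("O", nw)),
    is_hydrogen = FALSE,
    residue_id = c((seq_len(np) - 1L) %/% spec$atoms_per_residue + 1L,
                   rep(ceiling(np / spec$atoms_per_residue) + 1L, nl),
                   ceiling(np / spec$atoms_per_residue) + 1L + seq_len(nw)),
    residue_name = c(rep("GLY", np), rep("LIG", nl), rep("HOH", nw)),
    role = c(rep("protein", np), rep("ligand", nl), rep("water", nw))
  ))

  .with_seed(spec$seed, {
    # fixed ligand geometry near the origin
    lig <- matrix(rnorm(nl * 3, sd = 0.6), ncol = 3)
    # fixed unit direction for each protein atom
    u <- matrix(rnorm(np * 3), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    partner <- (seq_len(np) - 1L) %% nl + 1L

    # exact OU updates for the pair-distance processes
    rho <- exp(-spec$frame_spacing / spec$pair_tau)
    innov_sd <- spec$pair_sd * sqrt(1 - rho^2)
    d <- matrix(0, n_frames, np)
    d[1, ] <- spec$pair_mean + rnorm(np, sd = spec$pair_sd)
    if (n_frames > 1) {
      for (f in 2:n_frames) {
        d[f, ] <- spec$pair_mean + rho * (d[f - 1, ] - spec$pair_mean) +
          rnorm(np, sd = innov_sd)
      }
    }
    d[d < 0.5] <- 0.5    # atoms cannot overlap

    # waters: fixed shell positions with tiny jitter per frame
    wdir <- matrix(rnorm(max(nw, 1) * 3), ncol = 3)
    wdir <- wdir / sqrt(rowSums(wdir^2))
    wbase <- wdir * spec$water_shell_radius

    coords <- array(0, dim = c(n_frames, np + nl + nw, 3))
    for (f in seq_len(n_frames)) {
      coords[f, np + seq_len(nl), ] <- lig
      coords[f, seq_len(np), ] <- lig[partner, , drop = FALSE] + u * d[f, ]
      if (nw > 0) {
        coords[f, np + nl + seq_len(nw), ] <-
          wbase[seq_len(nw), , drop = FALSE] + matrix(rnorm(nw * 3, sd = 0.05), ncol = 3)
      }
    }
    trajectory(top, coords, frame_spacing = spec$frame_spacing)
  })
}

#' Designated pairs of a toy receptor system
#'
#' @param spec A [receptor_spec()].
#' @return Tibble with `ligand_atom_id`, `protein_atom_id`, `pair_mean`.
#' @export
receptor_designated_pairs <- function(spec) {
  np <- spec$n_protein_atoms
  nl <- spec$n_ligand_atoms
  tibble(
    ligand_atom_id = np + ((seq_len(np) - 1L) %% nl + 1L),
    protein_atom_id = seq_len(np),
    pair_mean = spec$pair_mean
  )
}

# ---- funnel system for the unbinding protocol --------------------------

#' Bundled funnel system with a Brownian-dynamics propagator
#'
#' A minimal binding funnel for end-to-end protocol runs: a rigid three-atom
#' ligand bound in a six-atom pocket ring at the funnel mouth, a line of
#' channel atoms along the exit axis that the ligand contacts on its way
#' out (so new interacting pairs appear, as in a real vestibule), harmonic
#' funnel walls confining lateral motion, and a Gaussian binding well. The
#' returned propagator moves the ligand as a rigid body with overdamped
#' (Brownian) dynamics under the funnel potential plus, when given, the
#' harmonic restraint on the distance-sum CV.
#'
#' @param seed Seed for the propagator's noise (per-segment seeds are passed
#'   by the protocol driver).
#' @param well_depth Binding-well depth (kT), default 3.
#' @param well_width Binding-well width (angstrom), default 1.5.
#' @param wall_k Lateral wall stiffness (kT/A^2), default 2.
#' @param diffusion Ligand diffusion coefficient (A^2/ns), default 10.
#' @param dt Integration time step (ns), default 2e-6.
#' @param stride Steps per recorded frame, default 50.
#' @return A list: `structure` (one-frame [trajectory()]) and `propagator`,
#'   a function `(structure, restraint, n_frames, seed)` satisfying the
#'   protocol's propagator contract.
#' @export
make_funnel_system <- function(seed = 1L, well_depth = 3, well_width = 1.5,
                               wall_k = 2, diffusion = 10, dt = 2e-6,
                               stride = 50L) {
  ring_ang <- seq(0, 300, by = 60) * pi / 180
  pocket <- cbind(3.0 * cos(ring_ang), 3.0 * sin(ring_ang), 0)
  chan_z <- c(2.5, 5, 7.5, 10, 12.5)
  chan_ang <- c(0, 180, 90, 270, 45) * pi / 180
  channel <- cbind(3.0 * cos(chan_ang), 3.0 * sin(chan_ang), chan_z)
  lig_ang <- c(90, 210, 330) * pi / 180
  lig <- cbind(0.9 * cos(lig_ang), 0.9 * sin(lig_ang), 0)

  np <- nrow(pocket) + nrow(channel)
  nl <- nrow(lig)
  top <- topology(tibble(
    atom_id = seq_len(np + nl),
    name = c(rep("CA", np), paste0("C", seq_len(nl))),
    element = "C",
    is_hydrogen = FALSE,
    residue_id = c(seq_len(np), rep(np + 1L, nl)),
    residue_name = c(rep("GLY", np), rep("LIG", nl)),
    role = c(rep("protein", np), rep("ligand", nl))
  ))
  coords0 <- rbind(pocket, channel, lig)
  structure0 <- trajectory(top, coords0, frame_spacing = dt * stride)

  prot_xyz <- coords0[seq_len(np), , drop = FALSE]
  lig_rel <- sweep(lig, 2, colMeans(lig))   # rigid internal geometry
  lig_rows <- np + seq_len(nl)

  propagator <- function(structure, restraint, n_frames, seed) {
    x0 <- frame_coords(structure, 1)
    cen <- colMeans(x0[lig_rows, , drop = FALSE])
    pr <- NULL
    if (!is.null(restraint) && nrow(restraint$pairs) > 0) {
      pr <- list(
        li = match(restraint$pairs$ligand_atom_id, top$atom_id) - np,
        pi = match(restraint$pairs$protein_atom_id, top$atom_id),
        k = restraint$force_constant / .kt_kcal,
        center = restraint$center
      )
    }
    out <- array(0, dim = c(n_frames, np + nl, 3))
    step_sd <- sqrt(2 * diffusion * dt)
    .with_seed(seed, {
      for (f in seq_len(n_frames)) {
        for (s in seq_len(stride)) {
          force <- c(0, 0, 0)
          # binding well (Gaussian, depth in kT)
          r2 <- sum(cen^2)
          force <- force - well_depth * exp(-r2 / (2 * well_width^2)) *
            cen / well_width^2
          # funnel walls confine x,y around the exit axis
          force <- force - wall_k * c(cen[1], cen[2], 0)
          # harmonic restraint on the distance-sum CV
          if (!is.null(pr)) {
            lx <- sweep(lig_rel[pr$li, , drop = FALSE], 2, cen, `+`)
            dvec <- lx - prot_xyz[pr$pi, , drop = FALSE]
            dd <- sqrt(rowSums(dvec^2))
            cv <- sum(dd)
            grad <- colSums(dvec / dd)   # d(cv)/d(centroid)
            force <- force - pr$k * (cv - pr$center) * grad
          }
          cen <- cen + diffusion * force * dt + rnorm(3, sd = step_sd)
        }
        out[f, seq_len(np), ] <- prot_xyz
        out[f, lig_rows, ] <- sweep(lig_rel, 2, cen, `+`)
      }
    })
    trajectory(top, out, frame_spacing = dt * stride)
  }

  list(structure = structure0, propagator = propagator)
}

# ---- double-well downhill ensembles ------------------------------------

#' Specification of the toy committor system
#'
#' A one-dimensional double well `U(x) = B ((x/a)^2 - 1)^2` (barrier `B` at
#' the saddle `x = 0`, minima at `x = -a` [IN] and `x = +a` [OUT], with
#' `a = basin_separation / 2`) propagated by overdamped Langevin dynamics
#' with diffusion coefficient `D = temperature_factor / friction`.
#' Trajectories started at the saddle commit to a basin; recorded features
#' are either informative (`gain * x` plus noise) or pure noise, which
#' gives the ML stage a planted ground truth to recover.
#'
#' @param barrier_height Barrier height in kT, default 6.
#' @param basin_separation Distance between the two minima (angstrom),
#'   default 2.
#' @param friction Friction (kT ns / A^2), default 0.1 (so D = 10 A^2/ns).
#' @param temperature_factor Thermal energy in kT units, default 1.
#' @param dt Integration step (ns), default 2e-4.
#' @param n_features Number of recorded features, default 50.
#' @param informative_ids Indices (1-based) of the informative features,
#'   default 1:3.
#' @param informative_gain Slope of informative features on x, default 1.
#' @param noise_sigma Additive feature noise SD, default 0.5.
#' @param record_stride Integration steps per recorded frame, default 20
#'   (frame spacing `dt * record_stride` = 0.004 ns).
#' @param seed Seed.
#' @export
toy_system_spec <- function(barrier_height = 6, basin_separation = 2,
                            friction = 0.1, temperature_factor = 1,
                            dt = 2e-4, n_features = 50,
                            informative_ids = 1:3, informative_gain = 1,
                            noise_sigma = 0.5, record_stride = 20L,
                            seed = 1L) {
  if (barrier_height <= 0) abort("barrier_height must be positive")
  if (noise_sigma <= 0 || informative_gain <= 0) {
    abort("informative_gain and noise_sigma must be positive")
  }
  if (length(informative_ids) > 0 &&
      (min(informative_ids) < 1 || max(informative_ids) > n_features)) {
    abort("informative_ids must lie in [1, n_features]")
  }
  structure(
    list(barrier_height = barrier_height, basin_separation = basin_separation,
         friction = friction, temperature_factor = temperature_factor,
         dt = dt, n_features = as.integer(n_features),
         informative_ids = as.integer(informative_ids),
         informative_gain = informative_gain, noise_sigma = noise_sigma,
         record_stride = as.integer(record_stride), seed = as.integer(seed)),
    class = "toy_system_spec"
  )
}

# one overdamped step for a vector of walkers
.dw_step <- function(x, spec) {
  a <- spec$basin_separation / 2
  beta_b <- spec$barrier_height / spec$temperature_factor
  d <- spec$temperature_factor / spec$friction
  grad <- beta_b * 4 * x * (x^2 - a^2) / a^4
  x - d * grad * spec$dt + rnorm(length(x), sd = sqrt(2 * d * spec$dt))
}

#' Exact committor of the toy double well
#'
#' Probability that a walker started at `x0` reaches the OUT basin (`+a`)
#' before the IN basin (`-a`): the classical quadrature
#' `q(x0) = int_{-a}^{x0} exp(U/kT) dx / int_{-a}^{a} exp(U/kT) dx`.
#'
#' @param spec A [toy_system_spec()].
#' @param x0 Starting position(s).
#' @return Committor value(s) in `[0, 1]`.
#' @export
committor_exact <- function(spec, x0) {
  a <- spec$basin_separation / 2
  beta_b <- spec$barrier_height / spec$temperature_factor
  f <- function(x) exp(beta_b * ((x / a)^2 - 1)^2)
  denom <- stats::integrate(f, -a, a, rel.tol = 1e-10)$value
  vapply(x0, function(x) {
    if (x <= -a) return(0)
    if (x >= a) return(1)
    stats::integrate(f, -a, x, rel.tol = 1e-10)$value / denom
  }, numeric(1))
}

#' Generate a labeled downhill ensemble with planted informative features
#'
#' Propagates `n_traj` independent walkers on the double well from
#' `start_x` (the saddle by default), records `n_frames` feature frames at
#' spacing `dt * record_stride`, and labels each trajectory IN or OUT by
#' the basin it commits to first (first crossing of `x = -a` / `x = +a`,
#' checked at every integration step). Walkers that never commit within the
#' run are labeled UNDECIDED and excluded from the returned feature matrix.
#'
#' @param spec A [toy_system_spec()].
#' @param n_traj Number of trajectories (>= 10), default 150.
#' @param n_frames Recorded frames per trajectory, default 1250 (5 ns at the
#'   default spacing).
#' @param start_x Starting position, default 0 (the saddle).
#' @return A list: `features` (a [feature_matrix()] of decided
#'   trajectories), `labels` (factor over all trajectories, including
#'   UNDECIDED), `ground_truth` (informative ids, exact start committor,
#'   basin rule), `paths` (matrix of recorded reaction-coordinate values).
#' @export
make_downhill_ensemble <- function(spec, n_traj = 150, n_frames = 1250,
                                   start_x = 0) {
  if (!inherits(spec, "toy_system_spec")) abort("spec must be a toy_system_spec")
  if (n_traj < 10) abort("n_traj must be >= 10")
  a <- spec$basin_separation / 2
  .with_seed(spec$seed, {
    x <- rep(start_x, n_traj)
    committed <- integer(n_traj)   # 0 = open, -1 = IN, +1 = OUT
    xs <- matrix(0, n_traj, n_frames)
    for (f in seq_len(n_frames)) {
      for (s in seq_len(spec$record_stride)) {
        x <- .dw_step(x, spec)
        open <- committed == 0L
        committed[open & x <= -a] <- -1L
        committed[open & x >= a] <- 1L
      }
      xs[, f] <- x
    }
    labels <- factor(
      c("IN", "UNDECIDED", "OUT")[committed + 2L],
      levels = c("IN", "OUT", "UNDECIDED")
    )
    if (all(labels == "UNDECIDED")) {
      abort("no trajectory committed; increase n_frames or lower the barrier")
    }
    decided <- which(labels != "UNDECIDED")

    d <- spec$n_features
    noise <- array(rnorm(length(decided) * n_frames * d, sd = spec$noise_sigma),
                   dim = c(length(decided), n_frames, d))
    values <- noise + 5
    for (j in spec$informative_ids) {
      values[, , j] <- values[, , j] + spec$informative_gain * xs[decided, ]
    }
    times <- spec$dt * spec$record_stride * seq_len(n_frames)
    descriptors <- tibble(
      feature = paste0("f", seq_len(d)),
      kind = "synthetic",
      ligand_atom_id = NA_integer_, protein_atom_id = NA_integer_,
      residue_id = NA_integer_, residue_name = NA_character_,
      water_molecule_id = NA_integer_, component_index = NA_integer_
    )
    fm <- feature_matrix(values, descriptors,
                         labels = droplevels(labels[decided]), times = times)
    list(
      features = fm,
      labels = labels,
      ground_truth = list(
        informative_ids = spec$informative_ids,
        start_committor = committor_exact(spec, start_x),
        basin_rule = "IN: first crossing of x = -a; OUT: first crossing of x = +a"
      ),
      paths = xs
    )
  })
}

#' Monte-Carlo committor shots from a given start point
#'
#' Runs independent walkers from `x0` until first commitment and returns
#' their outcomes; the brute-force counterpart of [committor_exact()] and
#' the shot generator for candidate transition-state windows.
#'
#' @param spec A [toy_system_spec()].
#' @param x0 Start position.
#' @param n_shots Number of walkers.
#' @param seed Seed.
#' @param max_steps Integration-step budget per walker.
#' @return Factor of outcomes (`IN`/`OUT`/`UNDECIDED`).
#' @export
simulate_committor_shots <- function(spec, x0, n_shots, seed = 1L,
                                     max_steps = 50000L) {
  a <- spec$basin_separation / 2
  .with_seed(seed, {
    x <- rep(x0, n_shots)
    committed <- integer(n_shots)
    step <- 0L
    while (any(committed == 0L) && step < max_steps) {
      open <- committed == 0L
      x[open] <- .dw_step(x[open], spec)
      committed[open & x <= -a] <- -1L
      committed[open & x >= a] <- 1L
      step <- step + 1L
    }
    factor(c("IN", "UNDECIDED", "OUT")[committed + 2L],
           levels = c("IN", "OUT", "UNDECIDED"))
  })
}

#' Simulate candidate transition-state windows along the toy path
#'
#' Emulates the protocol step in which several path windows around the
#' presumed bottleneck each spawn a set of unbiased downhill shots: every
#' shot is propagated to a fixed length, scored (offset + reaction
#' coordinate, so IN means a low score), and labeled through
#' [label_outcome()] with a symmetric [labeling_rule()].
#'
#' @param spec A [toy_system_spec()].
#' @param offsets Window start positions (reaction-coordinate units),
#'   path-ordered; default `c(-0.2, -0.1, 0, 0.1, 0.2)`.
#' @param n_shots Shots per window, default 50.
#' @param n_frames Recorded frames per shot, default 125 (0.5 ns).
#' @param seed Seed.
#' @return A tibble of shots: `window_id`, `x0`, `shot`, `label`.
#' @export
simulate_candidate_windows <- function(spec, offsets = c(-0.2, -0.1, 0, 0.1, 0.2),
                                       n_shots = 50, n_frames = 125, seed = 1L) {
  a <- spec$basin_separation / 2
  rule <- labeling_rule(s_in = 10 - a / 2, s_out = 10 + a / 2,
                        terminal_fraction = 0.1)
  purrr::map_dfr(seq_along(offsets), function(w) {
    scores <- .with_seed(seed + 1000L * w, {
      x <- rep(offsets[w], n_shots)
      xs <- matrix(0, n_shots, n_frames)
      for (f in seq_len(n_frames)) {
        for (s in seq_len(spec$record_stride)) x <- .dw_step(x, spec)
        xs[, f] <- x
      }
      xs + 10
    })
    tibble(
      window_id = w, x0 = offsets[w], shot = seq_len(n_shots),
      label = label_outcome(scores, rule)
    )
  })
}

#' Permute outcome labels (null-model control)
#'
#' @param labels Factor (or character) of labels with at least two classes.
#' @param seed Seed; the same seed gives the same permutation.
#' @return Labels permuted; the class multiset is preserved exactly.
#' @export
make_null_labels <- function(labels, seed = 1L) {
  if (length(unique(as.character(labels))) < 2) {
    abort("make_null_labels needs at least two classes")
  }
  .with_seed(seed, labels[sample(length(labels))])
}
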