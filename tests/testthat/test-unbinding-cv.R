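test_that("interatomic distances match geometry and a brute-force loop", {
  f1 <- rbind(c(0, 0, 0), c(3, 4, 0), c(0, 0, 0))
  tr <- make_custom_traj(list(f1), roles = c("ligand", "protein", "protein"))
  d <- interatomic_distances(tr, tibble::tibble(atom_a = 1L, atom_b = 2L))
  expect_equal(d[1, 1], 5)
  expect_equal(
    interatomic_distances(tr, tibble::tibble(atom_a = 1L, atom_b = 3L))[1, 1], 0)
  expect_error(interatomic_distances(tr, tibble::tibble(atom_a = 1L, atom_b = 99L)),
               "unknown atom")

  spec <- receptor_spec(seed = 14, n_protein_atoms = 25, n_waters = 5)
  tr2 <- make_toy_receptor_trajectory(spec, 40)
  set.seed(2)
  pairs <- tibble::tibble(atom_a = sample(n_atoms(tr2), 50, replace = TRUE),
                          atom_b = sample(n_atoms(tr2), 50, replace = TRUE))
  expect_equal(interatomic_distances(tr2, pairs),
               oracle_pair_distances(tr2, pairs), tolerance = 1e-12)
})

test_that("pair detection honors the strict more-than-half occupancy rule", {
  cfg <- protocol_config()
  # constant 3.0 A contact: occupancy 1, interacting
  frames <- replicate(10, rbind(c(0, 0, 0), c(3, 0, 0)), simplify = FALSE)
  tr <- make_custom_traj(frames, roles = c("ligand", "protein"))
  det <- detect_interacting_pairs(tr, cfg)
  expect_equal(nrow(det), 1)
  expect_equal(det$occupancy, 1)

  # below the cutoff in exactly 5 of 10 frames: occupancy 0.5 is NOT interacting
  frames <- lapply(1:10, function(f) {
    rbind(c(0, 0, 0), c(if (f <= 5) 3.4 else 6.0, 0, 0))
  })
  tr <- make_custom_traj(frames, roles = c("ligand", "protein"))
  expect_equal(nrow(detect_interacting_pairs(tr, cfg)), 0)
  # one more close frame tips it over
  frames[[6]] <- rbind(c(0, 0, 0), c(3.4, 0, 0))
  tr <- make_custom_traj(frames, roles = c("ligand", "protein"))
  det <- detect_interacting_pairs(tr, cfg)
  expect_equal(det$occupancy, 0.6)
})

test_that("pair detection equals an exhaustive brute-force recount", {
  cfg <- protocol_config()
  spec <- receptor_spec(seed = 27, n_protein_atoms = 15, n_ligand_atoms = 2,
                        n_waters = 3, pair_mean = seq(3, 4.5, length.out = 15),
                        pair_sd = 0.4)
  tr <- make_toy_receptor_trajectory(spec, 60)
  det <- detect_interacting_pairs(tr, cfg)
  ora <- oracle_detect(tr, cfg)
  expect_equal(nrow(det), nrow(ora))
  expect_equal(det$ligand_atom_id, ora$ligand_atom_id)
  expect_equal(det$protein_atom_id, ora$protein_atom_id)
  expect_equal(det$occupancy, ora$occupancy, tolerance = 1e-15)
})

test_that("the CV is the additive sum of its member distances", {
  f1 <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 3, 0), c(0, 0, 4.5))
  tr <- make_custom_traj(list(f1), roles = c("ligand", rep("protein", 3)))
  cvp <- tibble::tibble(ligand_atom_id = 1L, protein_atom_id = 2:4,
                        iteration_added = 0L, status = "active")
  expect_equal(cv_value(tr, unbinding_cv(cvp)), 9.5)
  expect_equal(cv_value(tr, cvp[0, ]), 0)

  spec <- receptor_spec(seed = 4, n_protein_atoms = 30, n_ligand_atoms = 3,
                        n_waters = 0)
  tr2 <- make_toy_receptor_trajectory(spec, 20)
  pairs <- receptor_designated_pairs(spec)
  pairs$iteration_added <- 0L
  pairs$status <- "active"
  total <- cv_value(tr2, pairs)
  expect_equal(total, rowSums(oracle_pair_distances(
    tr2, tibble::tibble(atom_a = pairs$ligand_atom_id, atom_b = pairs$protein_atom_id))),
    tolerance = 1e-12)
  # additivity over a disjoint split, within 1e-9
  a <- pairs[1:10, ]
  b <- pairs[11:30, ]
  expect_equal(cv_value(tr2, a) + cv_value(tr2, b), total, tolerance = 1e-9)
})

test_that("ledger updates discard far pairs, add new ones, and re-admit", {
  cfg <- protocol_config()
  # pair 1 stays at 3 A, pair 2 drifts to 12 A
  frames <- lapply(1:10, function(f) {
    rbind(c(0, 0, 0), c(3, 0, 0), c(0, if (f <= 2) 3 else 14, 0))
  })
  tr <- make_custom_traj(frames, roles = c("ligand", "protein", "protein"))
  start <- tibble::tibble(ligand_atom_id = 1L, protein_atom_id = 2:3,
                          occupancy = 1, iteration_added = 0L,
                          status = "active", discard_iteration = NA_integer_)
  state <- protocol_state(start)
  state$iteration <- 1L
  state <- update_cv_pairs(state, tr, cfg)
  expect_equal(state$ledger$status, c("active", "discarded"))
  expect_equal(state$ledger$discard_iteration, c(NA_integer_, 1L))
  # no active pair retains a segment-mean distance above d_discard
  act <- state$ledger[state$ledger$status == "active", ]
  expect_true(all(colMeans(interatomic_distances(tr, act)) <= cfg$d_discard))

  # the discarded pair re-qualifies when it comes back
  back <- replicate(10, rbind(c(0, 0, 0), c(3, 0, 0), c(0, 3, 0)),
                    simplify = FALSE)
  tr_back <- make_custom_traj(back, roles = c("ligand", "protein", "protein"))
  state$iteration <- 2L
  state <- update_cv_pairs(state, tr_back, cfg)
  expect_equal(state$ledger$status, c("active", "active"))
  expect_true(any(state$events$event == "readmitted"))

  # a brand-new contact enters the ledger at the current iteration
  wide <- replicate(10, rbind(c(0, 0, 0), c(3, 0, 0), c(0, 3, 0), c(0, 0, 3)),
                    simplify = FALSE)
  tr_wide <- make_custom_traj(wide, roles = c("ligand", rep("protein", 3)))
  state$iteration <- 3L
  state <- update_cv_pairs(state, tr_wide, cfg)
  new_row <- state$ledger[state$ledger$protein_atom_id == 4L, ]
  expect_equal(new_row$iteration_added, 3L)
  expect_equal(new_row$status, "active")
})

test_that("restraint centers are clamped to a non-decreasing schedule", {
  cfg <- protocol_config(delta_per_pair = 0.1)
  pairs <- tibble::tibble(ligand_atom_id = 1L, protein_atom_id = 2:6,
                          occupancy = 1, iteration_added = 0L,
                          status = "active", discard_iteration = NA_integer_)
  state <- protocol_state(pairs)
  state$centers <- 10.0
  # candidate 9 + 0.1*5 = 9.5 is clamped to the previous center
  state <- next_center(state, 9.0, cfg)
  expect_equal(state$centers, c(10.0, 10.0))
  # candidate 12 + 0.5 = 12.5 advances
  state <- next_center(state, 12.0, cfg)
  expect_equal(state$centers, c(10.0, 10.0, 12.5))
  state$ledger$status <- "discarded"
  expect_error(next_center(state, 1, cfg), "empty CV")
})

test_that("a frozen propagator leaves a well-formed, bounded protocol run", {
  sys <- make_funnel_system()
  cfg <- protocol_config(max_iterations = 5, initial_detection_frames = 10,
                         iteration_frames = 10)
  frozen <- function(structure, restraint, n_frames, seed) {
    co <- array(rep(structure$coords[1, , ], each = n_frames),
                dim = c(n_frames, n_atoms(structure), 3))
    trajectory(structure$topology, co, frame_spacing = structure$frame_spacing)
  }
  init <- frozen(sys$structure, NULL, 10, 1)
  res <- run_unbinding_protocol(init, frozen, cfg)
  expect_equal(res$status, "max_iterations")
  expect_equal(res$iterations, 5)
  expect_true(all(diff(res$state$centers) >= 0))
})

test_that("protocol bookkeeping replays deterministically", {
  sys <- make_funnel_system()
  cfg <- protocol_config(max_iterations = 4, initial_detection_frames = 30,
                         iteration_frames = 30, seed = 7)
  init <- sys$propagator(sys$structure, NULL, cfg$initial_detection_frames, cfg$seed)
  r1 <- run_unbinding_protocol(init, sys$propagator, cfg)
  r2 <- run_unbinding_protocol(init, sys$propagator, cfg)
  expect_identical(r1$state$ledger, r2$state$ledger)
  expect_identical(r1$state$centers, r2$state$centers)
  expect_identical(r1$state$events, r2$state$events)
  expect_equal(r1$displacement, r2$displacement)
})

test_that("colvars export round-trips and serialises the default constants", {
  pairs <- tibble::tibble(ligand_atom_id = c(101L, 102L),
                          protein_atom_id = c(7L, 9L))
  spec <- restraint_spec(pairs, center = 7.5)
  path <- withr::local_tempfile(fileext = ".colvars")
  export_colvars(spec, path)
  txt <- readLines(path)
  expect_equal(sum(grepl("group1", txt)), 2)
  expect_true(any(grepl("forceConstant 10$", txt)))
  back <- read_colvars(path)
  expect_equal(back$pairs, spec$pairs)
  expect_equal(back$center, spec$center)
  expect_equal(back$force_constant, spec$force_constant)

  # a 52-pair restraint (the scale of a full adaptive CV) emits 52 blocks
  big <- restraint_spec(tibble::tibble(ligand_atom_id = 200L + 1:52,
                                       protein_atom_id = 1:52), center = 150)
  export_colvars(big, path)
  expect_equal(sum(grepl("group1", readLines(path))), 52)
  expect_equal(nrow(read_colvars(path)$pairs), 52)
})

test_that("discarding contacts too early strands the ligand in the pocket", {
  # with the discard distance barely above the interaction cutoff the CV
  # keeps losing its members and the ligand falls back instead of leaving
  seeds <- 1:3
  run_with <- function(cfg_d_discard, seed) {
    sys <- make_funnel_system()
    cfg <- protocol_config(d_discard = cfg_d_discard, seed = seed,
                           initial_detection_frames = 50, iteration_frames = 50)
    init <- sys$propagator(sys$structure, NULL, cfg$initial_detection_frames,
                           cfg$seed)
    run_unbinding_protocol(init, sys$propagator, cfg)$status == "displaced"
  }
  ok_default <- vapply(seeds, function(s) run_with(11, s), logical(1))
  ok_short <- vapply(seeds, function(s) run_with(3.6, s), logical(1))
  expect_gt(sum(ok_default), sum(ok_short))
})
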