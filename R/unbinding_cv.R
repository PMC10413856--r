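#' Protocol configuration for adaptive-CV unbinding
#'
#' Holds the thresholds and schedule of the iterative unbinding protocol:
#' a ligand--protein heavy-atom pair is "interacting" when its distance is
#' below `d_interact` for strictly more than `occ_threshold` of the frames;
#' the CV is the sum of the interacting distances, restrained harmonically
#' with `force_constant`, its center only ever increased; pairs whose
#' segment-mean distance exceeds `d_discard` are dropped from the CV.
#'
#' @param d_interact Interaction distance cutoff (angstrom), default 3.5.
#' @param occ_threshold Occupancy threshold (fraction, strict `>`), default 0.5.
#' @param d_discard Discard distance (angstrom), default 11.
#' @param force_constant Harmonic force constant (kcal mol^-1 A^-2), default 10.
#' @param max_iterations Iteration budget, default 25.
#' @param delta_per_pair Restraint-center increment per active pair
#'   (angstrom), default 0.5, chosen so that 25 iterations move the ligand
#'   by the ~10-12 A the protocol is expected to produce.
#' @param initial_detection_frames Frames of the unrestrained production
#'   segment used for the first pair detection.
#' @param iteration_frames Frames per restrained iteration segment.
#' @param stop_displacement Ligand-centroid displacement (angstrom) at which
#'   the ligand counts as displaced out of the receptor, default 10.
#' @param seed Base seed forwarded to the propagator.
#' @return A list of class `protocol_config`.
#' @export
protocol_config <- function(d_interact = 3.5, occ_threshold = 0.5,
                            d_discard = 11, force_constant = 10,
                            max_iterations = 25, delta_per_pair = 0.5,
                            initial_detection_frames = 200,
                            iteration_frames = 100,
                            stop_displacement = 10, seed = 1L) {
  if (d_interact <= 0 || d_discard <= d_interact) {
    abort("need 0 < d_interact < d_discard")
  }
  if (occ_threshold <= 0 || occ_threshold >= 1) abort("occ_threshold must be in (0,1)")
  if (force_constant <= 0) abort("force_constant must be positive")
  if (max_iterations < 1) abort("max_iterations must be >= 1")
  structure(
    list(d_interact = d_interact, occ_threshold = occ_threshold,
         d_discard = d_discard, force_constant = force_constant,
         max_iterations = as.integer(max_iterations),
         delta_per_pair = delta_per_pair,
         initial_detection_frames = as.integer(initial_detection_frames),
         iteration_frames = as.integer(iteration_frames),
         stop_displacement = stop_displacement, seed = as.integer(seed)),
    class = "protocol_config"
  )
}

#' Per-frame inter-atomic distances for a list of pairs
#'
#' @param traj A [trajectory()].
#' @param pairs A data frame with integer columns `atom_a` and `atom_b`
#'   (atom ids), or columns `ligand_atom_id`/`protein_atom_id`.
#' @return An `F x P` matrix of Euclidean distances (angstrom).
#' @export
interatomic_distances <- function(traj, pairs) {
  pairs <- .normalise_pairs(pairs)
  ids <- traj$topology$atom_id
  ia <- match(pairs$atom_a, ids)
  ib <- match(pairs$atom_b, ids)
  if (anyNA(ia) || anyNA(ib)) abort("pair refers to an unknown atom id")
  dx <- traj$coords[, ia, 1, drop = FALSE] - traj$coords[, ib, 1, drop = FALSE]
  dy <- traj$coords[, ia, 2, drop = FALSE] - traj$coords[, ib, 2, drop = FALSE]
  dz <- traj$coords[, ia, 3, drop = FALSE] - traj$coords[, ib, 3, drop = FALSE]
  d <- sqrt(dx^2 + dy^2 + dz^2)
  matrix(d, nrow = n_frames(traj), ncol = nrow(pairs))
}

.normalise_pairs <- function(pairs) {
  pairs <- as_tibble(pairs)
  if (all(c("ligand_atom_id", "protein_atom_id") %in% names(pairs))) {
    tibble(atom_a = as.integer(pairs$ligand_atom_id),
           atom_b = as.integer(pairs$protein_atom_id))
  } else if (all(c("atom_a", "atom_b") %in% names(pairs))) {
    tibble(atom_a = as.integer(pairs$atom_a), atom_b = as.integer(pairs$atom_b))
  } else {
    abort("pairs need columns atom_a/atom_b or ligand_atom_id/protein_atom_id")
  }
}

#' Detect interacting ligand--protein heavy-atom pairs
#'
#' Scans all ligand-heavy x protein-heavy atom pairs of a trajectory segment
#' and keeps those whose distance is below `d_interact` in strictly more
#' than `occ_threshold` of the frames.
#'
#' @param traj A [trajectory()] segment with ligand and protein heavy atoms.
#' @param config A [protocol_config()].
#' @return A tibble with columns `ligand_atom_id`, `protein_atom_id`,
#'   `occupancy`, `iteration_added`, `status`, `discard_iteration`, ordered
#'   by atom ids.
#' @export
detect_interacting_pairs <- function(traj, config = protocol_config()) {
  if (n_frames(traj) < 2) abort("pair detection needs at least 2 frames")
  top <- traj$topology
  lig <- select_atoms(top, role = "ligand", heavy_only = TRUE, allow_empty = TRUE)
  prot <- select_atoms(top, role = "protein", heavy_only = TRUE, allow_empty = TRUE)
  if (length(lig) == 0 || length(prot) == 0) {
    abort("trajectory needs ligand and protein heavy atoms")
  }
  grid <- expand.grid(li = lig, pi = prot)
  pairs <- tibble(atom_a = top$atom_id[grid$li], atom_b = top$atom_id[grid$pi])
  d <- interatomic_distances(traj, pairs)
  occ <- colMeans(d < config$d_interact)
  keep <- occ > config$occ_threshold
  tibble(
    ligand_atom_id = pairs$atom_a[keep],
    protein_atom_id = pairs$atom_b[keep],
    occupancy = occ[keep],
    iteration_added = 0L,
    status = "active",
    discard_iteration = NA_integer_
  ) %>%
    arrange(.data$ligand_atom_id, .data$protein_atom_id)
}

#' Sum-of-distances collective variable
#'
#' The unbinding CV is the plain (equal-weight) sum of the active
#' interacting-pair distances. `unbinding_cv()` extracts and orders the
#' active pairs of a ledger; `cv_value()` evaluates the CV on frames.
#'
#' @param ledger A pair ledger as returned by [detect_interacting_pairs()]
#'   or carried by a protocol state.
#' @return For `unbinding_cv()`, a tibble of active pairs ordered by
#'   `iteration_added` then atom ids, of class `unbinding_cv`.
#' @export
unbinding_cv <- function(ledger) {
  active <- ledger %>%
    filter(.data$status == "active") %>%
    arrange(.data$iteration_added, .data$ligand_atom_id, .data$protein_atom_id)
  if (anyDuplicated(active[, c("ligand_atom_id", "protein_atom_id")]) > 0) {
    abort("duplicate pairs in CV")
  }
  class(active) <- c("unbinding_cv", class(active))
  active
}

#' @rdname unbinding_cv
#' @param traj A [trajectory()].
#' @param cv An `unbinding_cv` (or any pair table); may be empty.
#' @return For `cv_value()`, a numeric vector of per-frame CV values
#'   (angstrom); 0 for an empty CV.
#' @export
cv_value <- function(traj, cv) {
  if (is.null(cv) || nrow(cv) == 0) return(rep(0, n_frames(traj)))
  rowSums(interatomic_distances(traj, cv))
}

#' Harmonic restraint specification
#'
#' The exported bias is `0.5 * k * (CV - center)^2` with the CV the
#' distance sum over `pairs`.
#'
#' @param pairs Pair table (`ligand_atom_id`, `protein_atom_id`).
#' @param center Restraint center (angstrom).
#' @param force_constant Force constant (kcal mol^-1 A^-2).
#' @export
restraint_spec <- function(pairs, center, force_constant = 10) {
  pairs <- as_tibble(pairs)[, c("ligand_atom_id", "protein_atom_id")]
  pairs$ligand_atom_id <- as.integer(pairs$ligand_atom_id)
  pairs$protein_atom_id <- as.integer(pairs$protein_atom_id)
  structure(list(pairs = pairs, center = as.numeric(center),
                 force_constant = as.numeric(force_constant)),
            class = "restraint_spec")
}

#' @export
print.restraint_spec <- function(x, ...) {
  cat(sprintf("<restraint> %d pairs, center %.3f A, k = %.3g kcal/mol/A^2\n",
              nrow(x$pairs), x$center, x$force_constant))
  invisible(x)
}

# ---- protocol state ----------------------------------------------------

#' Create a protocol state from an initial pair detection
#'
#' @param pairs Initial pair table from [detect_interacting_pairs()].
#' @return A list of class `protocol_state`: `iteration`, `centers`
#'   (history, non-decreasing), `ledger` (all pairs ever seen), `events`
#'   (one row per add/discard/readmit event).
#' @export
protocol_state <- function(pairs) {
  if (nrow(pairs) == 0) abort("zero interacting pairs at protocol start")
  events <- pairs %>%
    mutate(iteration = 0L, event = "added") %>%
    select("iteration", "event", "ligand_atom_id", "protein_atom_id", "occupancy")
  structure(list(iteration = 0L, centers = numeric(0), ledger = pairs,
                 events = events),
            class = "protocol_state")
}

#' @export
print.protocol_state <- function(x, ...) {
  cat(sprintf(
    "<protocol state> iteration %d, %d/%d pairs active, center %.3f A\n",
    x$iteration, sum(x$ledger$status == "active"), nrow(x$ledger),
    if (length(x$centers)) x$centers[length(x$centers)] else NA_real_))
  invisible(x)
}

#' Update the CV pair ledger after an iteration segment
#'
#' Applies the protocol's adaptive rules to a freshly propagated segment:
#' newly interacting pairs are added to the CV, active pairs whose
#' segment-mean distance exceeds `d_discard` are discarded (with the
#' iteration recorded), and previously discarded pairs that re-qualify are
#' re-admitted.
#'
#' @param state A [protocol_state()].
#' @param segment The trajectory segment propagated under the current
#'   restraint.
#' @param config A [protocol_config()].
#' @return The updated state.
#' @export
update_cv_pairs <- function(state, segment, config = protocol_config()) {
  if (is.null(segment) || n_frames(segment) < 2) {
    abort("update_cv_pairs needs a non-empty segment")
  }
  it <- state$iteration
  ledger <- state$ledger

  # discard active pairs whose mean distance over the segment is too large
  active <- ledger$status == "active"
  if (any(active)) {
    d <- interatomic_distances(segment, ledger[active, ])
    too_far <- colMeans(d) > config$d_discard
    if (any(too_far)) {
      idx <- which(active)[too_far]
      ledger$status[idx] <- "discarded"
      ledger$discard_iteration[idx] <- it
      state$events <- dplyr::bind_rows(state$events, tibble(
        iteration = it, event = "discarded",
        ligand_atom_id = ledger$ligand_atom_id[idx],
        protein_atom_id = ledger$protein_atom_id[idx],
        occupancy = NA_real_
      ))
    }
  }

  detected <- detect_interacting_pairs(segment, config)
  key <- function(df) paste(df$ligand_atom_id, df$protein_atom_id)
  known <- match(key(detected), key(ledger))

  # brand-new pairs
  new <- detected[is.na(known), , drop = FALSE]
  if (nrow(new) > 0) {
    new$iteration_added <- it
    ledger <- dplyr::bind_rows(ledger, new)
    state$events <- dplyr::bind_rows(state$events, tibble(
      iteration = it, event = "added",
      ligand_atom_id = new$ligand_atom_id,
      protein_atom_id = new$protein_atom_id,
      occupancy = new$occupancy
    ))
  }

  # re-admit discarded pairs that qualify again
  readmit <- which(!is.na(known) & ledger$status[known] == "discarded")
  if (length(readmit) > 0) {
    idx <- known[readmit]
    ledger$status[idx] <- "active"
    ledger$occupancy[idx] <- detected$occupancy[readmit]
    state$events <- dplyr::bind_rows(state$events, tibble(
      iteration = it, event = "readmitted",
      ligand_atom_id = ledger$ligand_atom_id[idx],
      protein_atom_id = ledger$protein_atom_id[idx],
      occupancy = detected$occupancy[readmit]
    ))
  }

  state$ledger <- ledger
  state
}

#' Schedule the next restraint center
#'
#' The candidate center is the current CV value plus `delta_per_pair` per
#' active pair; the returned center is clamped so the history never
#' decreases, and is appended to the state's center history.
#'
#' @param state A [protocol_state()].
#' @param current_cv The CV value on the current frame (angstrom).
#' @param config A [protocol_config()].
#' @return The updated state; the new center is
#'   `state$centers[length(state$centers)]`.
#' @export
next_center <- function(state, current_cv, config = protocol_config()) {
  n_active <- sum(state$ledger$status == "active")
  if (n_active == 0) abort("cannot schedule a center for an empty CV")
  candidate <- current_cv + config$delta_per_pair * n_active
  prev <- if (length(state$centers)) state$centers[length(state$centers)] else -Inf
  state$centers <- c(state$centers, max(prev, candidate))
  state
}

#' Run the adaptive unbinding protocol
#'
#' Iterates detect/update pairs, schedule a monotone restraint center,
#' export the harmonic restraint, and propagate, until the ligand centroid
#' has moved by more than `stop_displacement` from its starting position or
#' the iteration budget is exhausted. If every pair has been discarded the
#' segment is propagated unrestrained (the ligand has lost all tracked
#' contacts).
#'
#' @param initial An unrestrained production segment used for the first
#'   pair detection; its last frame seeds the propagation.
#' @param propagator A function `(structure, restraint, n_frames, seed)`
#'   returning a trajectory segment, where `structure` is a one-frame
#'   [trajectory()] and `restraint` a [restraint_spec()] or `NULL`.
#' @param config A [protocol_config()].
#' @return A list: `state` (ledger, centers, events), `segments` (list of
#'   per-iteration trajectories), `status` (`"displaced"` or
#'   `"max_iterations"`), `displacement` (final ligand-centroid displacement,
#'   angstrom), `iterations` (number performed).
#' @export
run_unbinding_protocol <- function(initial, propagator,
                                   config = protocol_config()) {
  pairs <- detect_interacting_pairs(initial, config)
  if (nrow(pairs) == 0) abort("zero interacting pairs at protocol start")
  state <- protocol_state(pairs)

  lig <- select_atoms(initial$topology, role = "ligand", heavy_only = TRUE)
  centroid <- function(tr, f) colMeans(frame_coords(tr, f)[lig, , drop = FALSE])
  origin <- centroid(initial, 1)

  current <- subset_frames(initial, n_frames(initial))
  segments <- list()
  status <- "max_iterations"
  displacement <- sqrt(sum((centroid(current, 1) - origin)^2))

  for (it in seq_len(config$max_iterations)) {
    state$iteration <- it
    cvp <- unbinding_cv(state$ledger)
    restraint <- NULL
    if (nrow(cvp) > 0) {
      cvnow <- cv_value(current, cvp)[1]
      state <- next_center(state, cvnow, config)
      restraint <- restraint_spec(cvp, state$centers[length(state$centers)],
                                  config$force_constant)
    }
    seg <- tryCatch(
      propagator(current, restraint, config$iteration_frames,
                 config$seed + it),
      error = function(e) abort(sprintf("propagator failed at iteration %d: %s",
                                        it, conditionMessage(e)))
    )
    state <- update_cv_pairs(state, seg, config)
    segments[[it]] <- seg
    current <- subset_frames(seg, n_frames(seg))
    displacement <- sqrt(sum((centroid(current, 1) - origin)^2))
    if (displacement > config$stop_displacement) {
      status <- "displaced"
      break
    }
  }
  list(state = state, segments = segments, status = status,
       displacement = displacement, iterations = state$iteration)
}

# ---- colvars export ----------------------------------------------------

#' Export / read a harmonic distance-sum restraint in colvars dialect
#'
#' Writes a colvars configuration defining one collective variable as the
#' sum of the pair distances and one harmonic bias at the spec's center and
#' force constant; `read_colvars()` parses it back to an equal
#' [restraint_spec()].
#'
#' @param spec A [restraint_spec()].
#' @param path Output (input) path.
#' @return `export_colvars()` returns `path` invisibly; `read_colvars()`
#'   returns a [restraint_spec()].
#' @export
export_colvars <- function(spec, path) {
  lines <- c("colvar {", "  name unbinding_cv")
  for (i in seq_len(nrow(spec$pairs))) {
    lines <- c(lines,
               "  distance {",
               sprintf("    group1 { atomNumbers %d }", spec$pairs$ligand_atom_id[i]),
               sprintf("    group2 { atomNumbers %d }", spec$pairs$protein_atom_id[i]),
               "  }")
  }
  lines <- c(lines, "}", "",
             "harmonic {",
             "  colvars unbinding_cv",
             sprintf("  centers %.10g", spec$center),
             sprintf("  forceConstant %.10g", spec$force_constant),
             "}")
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE, warning = function(e) FALSE)
  if (!ok) abort(paste0("cannot write colvars file '", path, "'"))
  invisible(path)
}

#' @rdname export_colvars
#' @export
read_colvars <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path)
  g1 <- as.integer(sub(".*group1 \\{ atomNumbers (\\d+).*", "\\1",
                       grep("group1", lines, value = TRUE)))
  g2 <- as.integer(sub(".*group2 \\{ atomNumbers (\\d+).*", "\\1",
                       grep("group2", lines, value = TRUE)))
  center <- as.numeric(sub(".*centers ", "", grep("centers", lines, value = TRUE)))
  k <- as.numeric(sub(".*forceConstant ", "",
                      grep("forceConstant", lines, value = TRUE)))
  if (length(g1) == 0 || length(g1) != length(g2) ||
      length(center) != 1 || length(k) != 1) {
    abort(paste0("not a restraint colvars file: ", path))
  }
  restraint_spec(tibble(ligand_atom_id = g1, protein_atom_id = g2), center, k)
}
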