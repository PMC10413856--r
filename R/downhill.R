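#' Labeling rule for downhill trajectories
#'
#' A downhill trajectory is scored by a linear combination of distances
#' (the equal-weight sum of the unbinding CV's pairs by default), the score
#' averaged over a terminal window, and the mean compared with two
#' thresholds: `IN` when at or below `s_in` (ligand back in the site),
#' `OUT` when at or above `s_out`, `UNDECIDED` in between.
#'
#' @param s_in,s_out Score thresholds (angstrom on distance scores),
#'   `s_in < s_out`.
#' @param terminal_fraction Fraction of final frames averaged, default 0.1.
#' @param weights Optional per-pair weights for the score (default equal,
#'   i.e. the plain sum).
#' @export
labeling_rule <- function(s_in, s_out, terminal_fraction = 0.1, weights = NULL) {
  if (!(s_in < s_out)) abort("labeling rule needs s_in < s_out")
  if (terminal_fraction <= 0 || terminal_fraction > 1) {
    abort("terminal_fraction must be in (0, 1]")
  }
  structure(list(s_in = s_in, s_out = s_out,
                 terminal_fraction = terminal_fraction, weights = weights),
            class = "labeling_rule")
}

.outcome_levels <- c("IN", "OUT", "UNDECIDED")

#' Label score series IN/OUT/UNDECIDED
#'
#' @param scores A numeric vector (one trajectory's score per frame) or a
#'   matrix with one row per trajectory.
#' @param rule A [labeling_rule()].
#' @return A factor with levels `IN`, `OUT`, `UNDECIDED` (one element per
#'   trajectory).
#' @export
label_outcome <- function(scores, rule) {
  if (is.vector(scores)) scores <- matrix(scores, nrow = 1)
  nt <- ncol(scores)
  n_term <- max(1L, floor(rule$terminal_fraction * nt))
  term <- scores[, (nt - n_term + 1L):nt, drop = FALSE]
  s_bar <- rowMeans(term)
  out <- ifelse(s_bar <= rule$s_in, "IN",
                ifelse(s_bar >= rule$s_out, "OUT", "UNDECIDED"))
  factor(out, levels = .outcome_levels)
}

#' Label a downhill trajectory from its CV distance score
#'
#' Computes the weighted distance score of the trajectory over the CV's
#' pairs and applies [label_outcome()].
#'
#' @param traj A [trajectory()].
#' @param rule A [labeling_rule()].
#' @param cv An [unbinding_cv()] (or pair table) defining the distances.
#' @return A length-1 factor (`IN`/`OUT`/`UNDECIDED`).
#' @export
label_downhill <- function(traj, rule, cv) {
  d <- interatomic_distances(traj, cv)
  w <- rule$weights
  if (is.null(w)) w <- rep(1, ncol(d))
  if (length(w) != ncol(d)) abort("weights length must match the CV pair count")
  label_outcome(as.numeric(d %*% w), rule)
}

#' Per-window IN fractions with Wilson confidence intervals
#'
#' Summarises downhill shots per candidate window: the IN fraction is
#' `#IN / (#IN + #OUT)` (UNDECIDED shots are excluded), with a Wilson
#' score interval at `conf_level`. Windows without any decided shot are
#' dropped with a warning.
#'
#' @param shots Either a data frame of individual shots with columns
#'   `window_id` and `label`, or pre-tabulated counts with columns
#'   `window_id`, `n_in`, `n_out`.
#' @param conf_level Confidence level, default 0.95.
#' @return A tibble of class `committor_profile`, path-ordered:
#'   `window_id`, `n_in`, `n_out`, `n_undecided`, `in_fraction`,
#'   `ci_lower`, `ci_upper`.
#' @export
committor_profile <- function(shots, conf_level = 0.95) {
  shots <- as_tibble(shots)
  if (all(c("window_id", "n_in", "n_out") %in% names(shots))) {
    counts <- shots %>%
      mutate(n_undecided = if ("n_undecided" %in% names(shots)) .data$n_undecided else 0L) %>%
      select("window_id", "n_in", "n_out", "n_undecided")
  } else if (all(c("window_id", "label") %in% names(shots))) {
    counts <- shots %>%
      group_by(.data$window_id) %>%
      summarise(
        n_in = sum(.data$label == "IN"),
        n_out = sum(.data$label == "OUT"),
        n_undecided = sum(.data$label == "UNDECIDED"),
        .groups = "drop"
      )
  } else {
    abort("shots need columns window_id+label or window_id+n_in+n_out")
  }
  empty <- counts$n_in + counts$n_out == 0
  if (any(empty)) {
    warn(paste0("window(s) without decided shots excluded: ",
                paste(counts$window_id[empty], collapse = ", ")))
    counts <- counts[!empty, , drop = FALSE]
  }
  if (nrow(counts) == 0) abort("no window has any decided shot")
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  n <- counts$n_in + counts$n_out
  p <- counts$n_in / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  out <- counts %>%
    mutate(in_fraction = p,
           ci_lower = pmax(0, centre - hw),
           ci_upper = pmin(1, centre + hw)) %>%
    arrange(.data$window_id)
  class(out) <- c("committor_profile", class(out))
  out
}

#' Select the transition-state candidate window
#'
#' The transition state is the window whose downhill outcomes are closest
#' to a 1:1 IN:OUT split: the window minimising `|in_fraction - 0.5|`,
#' ties broken in favour of the smaller window id (earlier along the path).
#'
#' @param profile A [committor_profile()] (or tibble with `window_id` and
#'   `in_fraction`).
#' @return The selected window id.
#' @export
select_ts_candidate <- function(profile) {
  if (nrow(profile) == 0) abort("no windows to select from")
  dev <- abs(profile$in_fraction - 0.5)
  cand <- which(dev == min(dev))
  profile$window_id[cand[which.min(profile$window_id[cand])]]
}
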