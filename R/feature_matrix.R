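#' Feature matrix over a trajectory ensemble
#'
#' The container fed to the ML stage: an `S x T x D` array of feature
#' values (S simulations, T frames, D features), a descriptor table typing
#' each feature (pair distance, residue minimum distance, water distance,
#' PCA component, or synthetic), the per-simulation outcome labels, and
#' the frame times.
#'
#' @param values An `S x T x D` numeric array without missing values.
#' @param descriptors A tibble with one row per feature; must carry a
#'   `feature` name column and a `kind` column, plus whichever id columns
#'   the kind implies.
#' @param labels Factor of length S with levels drawn from `IN`/`OUT`
#'   (UNDECIDED trajectories must be excluded before building features).
#' @param times Numeric vector of length T (ns).
#' @return An object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, descriptors, labels, times) {
  if (length(dim(values)) != 3) abort("values must be an S x T x D array")
  if (anyNA(values)) abort("feature values must not contain missing values")
  descriptors <- as_tibble(descriptors)
  if (dim(values)[3] != nrow(descriptors)) {
    abort("descriptor count must equal the number of features")
  }
  labels <- droplevels(factor(labels))
  if (any(labels == "UNDECIDED", na.rm = TRUE)) {
    abort("UNDECIDED trajectories must be excluded from a feature matrix")
  }
  if (length(labels) != dim(values)[1]) {
    abort("labels length must equal the number of simulations")
  }
  if (length(times) != dim(values)[2]) {
    abort("times length must equal the number of frames")
  }
  structure(list(values = values, descriptors = descriptors,
                 labels = labels, times = as.numeric(times)),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<feature matrix> %d simulations x %d frames x %d features (%s), window %.4g-%.4g ns\n",
    d[1], d[2], d[3], paste(unique(x$descriptors$kind), collapse = "/"),
    min(x$times), max(x$times)))
  print(table(x$labels))
  invisible(x)
}

#' @rdname feature_matrix
#' @param fm A feature matrix.
#' @export
n_simulations <- function(fm) dim(fm$values)[1]

#' @rdname feature_matrix
#' @export
n_features <- function(fm) dim(fm$values)[3]

#' Combine feature matrices along the feature axis
#'
#' @param a,b Feature matrices sharing simulations, frames and labels.
#' @return A [feature_matrix()] with `a`'s features followed by `b`'s.
#' @export
bind_features <- function(a, b) {
  if (!identical(dim(a$values)[1:2], dim(b$values)[1:2])) {
    abort("feature matrices must share simulation and frame dimensions")
  }
  if (!identical(as.character(a$labels), as.character(b$labels))) {
    abort("feature matrices must share labels")
  }
  values <- array(0, dim = c(dim(a$values)[1:2], dim(a$values)[3] + dim(b$values)[3]))
  values[, , seq_len(dim(a$values)[3])] <- a$values
  values[, , dim(a$values)[3] + seq_len(dim(b$values)[3])] <- b$values
  feature_matrix(values, dplyr::bind_rows(a$descriptors, b$descriptors),
                 a$labels, a$times)
}

#' Long-format view of a feature matrix
#'
#' @param x A [feature_matrix()].
#' @param ... Unused.
#' @return A tibble with columns `simulation`, `frame`, `time`, `feature`,
#'   `value`, `label`.
#' @method as_tibble feature_matrix
#' @export
as_tibble.feature_matrix <- function(x, ...) {
  d <- dim(x$values)
  tibble(
    simulation = rep(seq_len(d[1]), times = d[2] * d[3]),
    frame = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    time = rep(rep(x$times, each = d[1]), times = d[3]),
    feature = rep(x$descriptors$feature, each = d[1] * d[2]),
    value = as.numeric(x$values),
    label = rep(as.character(x$labels), times = d[2] * d[3])
  )
}

# flatten the in-window frames into a design matrix with one row per
# simulation-frame; returns X, the per-row simulation index and labels
.design_matrix <- function(fm, window = NULL) {
  # windows are half-open (t_start, t_end]
  idx_t <- if (is.null(window)) {
    seq_along(fm$times)
  } else {
    which(fm$times > window[1] & fm$times <= window[2])
  }
  if (length(idx_t) == 0) abort("no frames fall inside the analysis window")
  s <- dim(fm$values)[1]
  tw <- length(idx_t)
  d <- dim(fm$values)[3]
  x <- matrix(0, s * tw, d, dimnames = list(NULL, fm$descriptors$feature))
  for (i in seq_len(s)) {
    x[(i - 1L) * tw + seq_len(tw), ] <- fm$values[i, idx_t, ]
  }
  list(x = x, sim = rep(seq_len(s), each = tw),
       y = fm$labels[rep(seq_len(s), each = tw)], frames = idx_t)
}

#' Write / read a feature matrix as CSV + JSON sidecar
#'
#' `write_feature_matrix()` stores the values as a wide CSV (one row per
#' simulation-frame) and the descriptors, labels and times in a JSON
#' sidecar; `read_feature_matrix()` restores the object.
#'
#' @param fm A [feature_matrix()].
#' @param prefix Path prefix; `<prefix>_values.csv` and `<prefix>_meta.json`
#'   are written.
#' @return `prefix` (write) or a [feature_matrix()] (read).
#' @export
write_feature_matrix <- function(fm, prefix) {
  des <- .design_matrix(fm)
  df <- data.frame(simulation = des$sim,
                   frame = rep(seq_along(fm$times), times = n_simulations(fm)),
                   des$x, check.names = FALSE)
  utils::write.csv(df, paste0(prefix, "_values.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(descriptors = fm$descriptors,
         labels = as.character(fm$labels),
         times = fm$times),
    paste0(prefix, "_meta.json"), digits = NA, auto_unbox = FALSE
  )
  invisible(prefix)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, "_meta.json"), simplifyVector = TRUE)
  df <- utils::read.csv(paste0(prefix, "_values.csv"), check.names = FALSE)
  s <- length(meta$labels)
  tt <- length(meta$times)
  d <- nrow(meta$descriptors)
  values <- array(0, dim = c(s, tt, d))
  m <- as.matrix(df[, -(1:2), drop = FALSE])
  for (i in seq_len(s)) values[i, , ] <- m[df$simulation == i, , drop = FALSE]
  feature_matrix(values, as_tibble(meta$descriptors),
                 factor(meta$labels), meta$times)
}
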