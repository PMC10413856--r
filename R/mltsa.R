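#' Configuration of a classifier replica ensemble
#'
#' The MLTSA training design: `n_models` independent replicas, each with
#' its own random split of the simulations into training (70%) and
#' validation (30%) sets, trained on all in-window frames of its training
#' simulations (every frame inherits its simulation's IN/OUT label) and
#' scored by frame-level validation accuracy. Replica `r` uses seed
#' `base_seed + r` for both the split and the model initialisation.
#'
#' @param model_kind `"mlp"` (single-hidden-layer perceptron, nnet) or
#'   `"gbdt"` (gradient-boosted decision trees, xgboost).
#' @param n_models Number of replicas, default 100.
#' @param train_fraction Fraction of simulations used for training,
#'   default 0.7.
#' @param window Analysis window `c(t_start, t_end)` in ns, treated as
#'   half-open `(t_start, t_end]`; default `c(0.05, 0.1)` (early-time
#'   prediction near the transition state).
#' @param base_seed Base seed, default 1.
#' @param hyperparameters Model-kind-specific list; defaults are
#'   `list(size = 8, decay = 1e-3, maxit = 100)` for the MLP and
#'   `list(nrounds = 100, max_depth = 3, eta = 0.1)` for the GBDT.
#' @export
ensemble_config <- function(model_kind = c("mlp", "gbdt"), n_models = 100,
                            train_fraction = 0.7, window = c(0.05, 0.1),
                            base_seed = 1L, hyperparameters = list()) {
  model_kind <- match.arg(model_kind)
  if (train_fraction <= 0 || train_fraction >= 1) {
    abort("train_fraction must be in (0, 1)")
  }
  if (n_models < 1) abort("n_models must be >= 1")
  if (length(window) != 2 || window[1] >= window[2]) {
    abort("window must be c(t_start, t_end) with t_start < t_end")
  }
  defaults <- if (model_kind == "mlp") {
    list(size = 8, decay = 1e-3, maxit = 100)
  } else {
    list(nrounds = 100, max_depth = 3, eta = 0.1)
  }
  hp <- utils::modifyList(defaults, hyperparameters)
  structure(
    list(model_kind = model_kind, n_models = as.integer(n_models),
         train_fraction = train_fraction, window = window,
         base_seed = as.integer(base_seed), hyperparameters = hp),
    class = "ensemble_config"
  )
}

.fit_one <- function(kind, x, y01, hp) {
  if (kind == "mlp") {
    nnet::nnet(x = x, y = y01, size = hp$size, decay = hp$decay,
               maxit = hp$maxit, entropy = TRUE, trace = FALSE,
               MaxNWts = 100000)
  } else {
    xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = hp$max_depth,
                    eta = hp$eta, nthread = 1),
      data = xgboost::xgb.DMatrix(x, label = y01),
      nrounds = hp$nrounds, verbose = 0
    )
  }
}

.predict_prob <- function(kind, fit, x) {
  if (kind == "mlp") as.numeric(stats::predict(fit, x))
  else stats::predict(fit, xgboost::xgb.DMatrix(x))
}

#' Train a replica classifier ensemble
#'
#' @param features A [feature_matrix()].
#' @param config An [ensemble_config()].
#' @return An object of class `mltsa_ensemble`: per-replica fitted models,
#'   simulation-level splits, standardisation statistics (MLP), and
#'   frame-level validation accuracies.
#' @export
train_ensemble <- function(features, config = ensemble_config()) {
  labs <- features$labels
  if (nlevels(labs) < 2) abort("training needs both IN and OUT labels")
  s <- n_simulations(features)
  if (s < 10) abort("training needs at least 10 simulations")
  des <- .design_matrix(features, config$window)
  y01 <- as.integer(des$y == levels(labs)[2])
  n_train <- round(config$train_fraction * s)
  kind <- config$model_kind

  replicas <- purrr::map(seq_len(config$n_models), function(r) {
    seed <- config$base_seed + r
    train_sims <- .with_seed(seed, sort(sample.int(s, n_train)))
    tr_rows <- des$sim %in% train_sims
    xtr <- des$x[tr_rows, , drop = FALSE]
    xval <- des$x[!tr_rows, , drop = FALSE]
    centre <- scale_sd <- NULL
    if (kind == "mlp") {
      centre <- colMeans(xtr)
      scale_sd <- apply(xtr, 2, stats::sd)
      scale_sd[scale_sd == 0] <- 1
      xtr <- scale(xtr, center = centre, scale = scale_sd)
      xval <- scale(xval, center = centre, scale = scale_sd)
    }
    fit <- .with_seed(seed, .fit_one(kind, xtr, y01[tr_rows], config$hyperparameters))
    pred <- .predict_prob(kind, fit, xval) > 0.5
    acc <- mean(pred == (y01[!tr_rows] == 1L))
    list(fit = fit, train_sims = train_sims, centre = centre,
         scale = scale_sd, accuracy = acc)
  })

  structure(
    list(config = config, replicas = replicas,
         classes = levels(labs), feature_names = features$descriptors$feature,
         descriptors = features$descriptors,
         n_sims = s, window_frames = des$frames),
    class = "mltsa_ensemble"
  )
}

#' @export
print.mltsa_ensemble <- function(x, ...) {
  acc <- ensemble_accuracy(x)
  cat(sprintf(
    "<mltsa ensemble> %s x %d replicas, %d features, validation accuracy %.3f +/- %.3f\n",
    toupper(x$config$model_kind), length(x$replicas),
    length(x$feature_names), acc$mean, acc$sd))
  invisible(x)
}

#' Mean and standard deviation of validation accuracy across replicas
#'
#' @param ensemble A trained `mltsa_ensemble`.
#' @return A list: `mean`, `sd`, `per_replica`.
#' @export
ensemble_accuracy <- function(ensemble) {
  acc <- vapply(ensemble$replicas, `[[`, numeric(1), "accuracy")
  list(mean = mean(acc), sd = stats::sd(acc), per_replica = acc)
}

.importance_profile <- function(ensemble, per_replica, metric) {
  out <- ensemble$descriptors %>%
    mutate(metric = metric,
           mean = colMeans(per_replica),
           sd = apply(per_replica, 2, stats::sd)) %>%
    arrange(dplyr::desc(.data$mean)) %>%
    mutate(rank = dplyr::row_number()) %>%
    arrange(match(.data$feature, ensemble$descriptors$feature))
  attr(out, "per_replica") <- per_replica
  class(out) <- c("importance_profile", class(out))
  out
}

#' Relative accuracy drop (RAD) feature importance
#'
#' For each feature and replica, the feature's variance is removed by
#' replacing its column with the feature's global mean over the full data
#' set, the replica's validation accuracy is re-evaluated, and the
#' importance is the relative drop `(A0 - A_f) / A0`. The profile averages
#' over replicas. A `"permute"` variant shuffles the column instead of
#' flattening it.
#'
#' @param ensemble A trained `mltsa_ensemble`.
#' @param features The [feature_matrix()] the ensemble was trained on.
#' @param method `"mean_replace"` (default) or `"permute"`.
#' @param seed Seed for the permutation variant.
#' @return An `importance_profile` tibble: descriptors plus `metric`,
#'   `mean`, `sd`, `rank`; per-replica values in `attr(, "per_replica")`.
#' @export
rad_importance <- function(ensemble, features,
                           method = c("mean_replace", "permute"), seed = 1L) {
  method <- match.arg(method)
  if (!identical(ensemble$feature_names, features$descriptors$feature)) {
    abort("features do not match the ensemble's training features")
  }
  des <- .design_matrix(features, ensemble$config$window)
  y01 <- as.integer(des$y == ensemble$classes[2])
  kind <- ensemble$config$model_kind
  global_mean <- colMeans(des$x)
  d <- ncol(des$x)

  per_replica <- t(vapply(ensemble$replicas, function(rep) {
    val_rows <- !(des$sim %in% rep$train_sims)
    xval <- des$x[val_rows, , drop = FALSE]
    yv <- y01[val_rows] == 1L
    apply_scale <- function(x) {
      if (kind == "mlp") scale(x, center = rep$centre, scale = rep$scale) else x
    }
    a0 <- mean((.predict_prob(kind, rep$fit, apply_scale(xval)) > 0.5) == yv)
    vapply(seq_len(d), function(j) {
      xj <- xval
      if (method == "mean_replace") {
        xj[, j] <- global_mean[j]
      } else {
        xj[, j] <- .with_seed(seed + j, sample(xj[, j]))
      }
      af <- mean((.predict_prob(kind, rep$fit, apply_scale(xj)) > 0.5) == yv)
      if (a0 > 0) (a0 - af) / a0 else 0
    }, numeric(1))
  }, numeric(d)))

  .importance_profile(ensemble, per_replica, "RAD")
}

#' Gini relative feature importance (RFI)
#'
#' Per-replica impurity-reduction (gain) importances of the gradient
#' boosted trees, normalised to sum to one over the features, averaged
#' across replicas.
#'
#' @param ensemble A trained `mltsa_ensemble` of kind `"gbdt"`.
#' @return An `importance_profile` tibble (see [rad_importance()]).
#' @export
rfi_importance <- function(ensemble) {
  if (ensemble$config$model_kind != "gbdt") {
    abort("RFI is defined for GBDT ensembles; train with model_kind = 'gbdt'")
  }
  fn <- ensemble$feature_names
  per_replica <- t(vapply(ensemble$replicas, function(rep) {
    imp <- xgboost::xgb.importance(feature_names = fn, model = rep$fit)
    v <- stats::setNames(rep(0, length(fn)), fn)
    v[imp$Feature] <- imp$Gain
    if (sum(v) > 0) v <- v / sum(v)
    v
  }, numeric(length(fn))))
  .importance_profile(ensemble, per_replica, "RFI")
}

#' Aggregate an importance profile per residue
#'
#' Features carrying a residue id (pair distances, residue minima) are
#' grouped and their replica-mean importances averaged; features without a
#' residue (PCA components, waters, synthetic) pass through unchanged.
#'
#' @param profile An `importance_profile`.
#' @return A residue-level `importance_profile`-like tibble with columns
#'   `feature` (residue label or original feature), `residue_id`,
#'   `residue_name`, `metric`, `mean`, `sd`, `n_features`, `rank`.
#' @export
aggregate_by_residue <- function(profile) {
  has_res <- !is.na(profile$residue_id)
  grouped <- profile[has_res, , drop = FALSE] %>%
    group_by(.data$residue_id, .data$residue_name, .data$metric) %>%
    summarise(value = mean(.data$mean), sd = stats::sd(.data$mean),
              n_features = dplyr::n(), .groups = "drop") %>%
    mutate(feature = paste0("residue_", .data$residue_id)) %>%
    select("feature", "residue_id", "residue_name", "metric",
           mean = "value", "sd", "n_features")
  loose <- profile[!has_res, , drop = FALSE] %>%
    select("feature", "residue_id", "residue_name", "metric", "mean", "sd") %>%
    mutate(n_features = 1L)
  out <- dplyr::bind_rows(grouped, loose) %>%
    arrange(dplyr::desc(.data$mean)) %>%
    mutate(rank = dplyr::row_number())
  class(out) <- c("importance_profile", class(out))
  out
}

#' Scan analysis windows for the earliest informative time range
#'
#' Re-trains the ensemble on each candidate window and reports the mean
#' validation accuracy, to locate the earliest window from which outcomes
#' can be predicted accurately but not yet with full confidence.
#'
#' @param features A [feature_matrix()] spanning the full trajectories.
#' @param config An [ensemble_config()]; its `window` field is replaced by
#'   each candidate.
#' @param windows A list of `c(t_start, t_end)` pairs (ns).
#' @return A tibble of class `mltsa_scan`: `t_start`, `t_end`,
#'   `accuracy_mean`, `accuracy_sd`.
#' @export
scan_time_windows <- function(features, config, windows) {
  if (length(windows) == 0) abort("no windows to scan")
  out <- purrr::map_dfr(windows, function(w) {
    cfg <- config
    cfg$window <- w
    acc <- ensemble_accuracy(train_ensemble(features, cfg))
    tibble(t_start = w[1], t_end = w[2],
           accuracy_mean = acc$mean, accuracy_sd = acc$sd)
  })
  class(out) <- c("mltsa_scan", class(out))
  out
}
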