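#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a trained replica ensemble
#'
#' @param x An `mltsa_ensemble`.
#' @param ... Unused.
#' @return One row per replica: `replica`, `seed`, `accuracy`, `n_train`,
#'   `n_validation`.
#' @method tidy mltsa_ensemble
#' @export
tidy.mltsa_ensemble <- function(x, ...) {
  tibble(
    replica = seq_along(x$replicas),
    seed = x$config$base_seed + seq_along(x$replicas),
    accuracy = vapply(x$replicas, `[[`, numeric(1), "accuracy"),
    n_train = vapply(x$replicas, function(r) length(r$train_sims), integer(1)),
    n_validation = x$n_sims -
      vapply(x$replicas, function(r) length(r$train_sims), integer(1))
  )
}

#' One-row summary of a trained replica ensemble
#'
#' @param x An `mltsa_ensemble`.
#' @param ... Unused.
#' @method glance mltsa_ensemble
#' @export
glance.mltsa_ensemble <- function(x, ...) {
  acc <- ensemble_accuracy(x)
  tibble(
    model_kind = x$config$model_kind,
    n_models = length(x$replicas),
    n_features = length(x$feature_names),
    n_simulations = x$n_sims,
    window_start = x$config$window[1],
    window_end = x$config$window[2],
    accuracy_mean = acc$mean,
    accuracy_sd = acc$sd
  )
}

#' @method tidy importance_profile
#' @export
tidy.importance_profile <- function(x, ...) {
  out <- as_tibble(x)
  attr(out, "per_replica") <- NULL
  class(out) <- setdiff(class(out), "importance_profile")
  out
}

#' @method tidy committor_profile
#' @export
tidy.committor_profile <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "committor_profile")
  out
}

#' Plot an importance profile
#'
#' Replica-mean importance per feature (or residue) with one-standard-
#' deviation bars, the top features highlighted.
#'
#' @param object An `importance_profile`.
#' @param top_n Number of top features highlighted, default 6.
#' @param ... Unused.
#' @method autoplot importance_profile
#' @export
autoplot.importance_profile <- function(object, top_n = 6, ...) {
  df <- tidy(object)
  df$feature <- factor(df$feature, levels = df$feature)
  df$highlight <- df$rank <= top_n
  ggplot2::ggplot(df, ggplot2::aes(x = .data$feature, y = .data$mean)) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd,
                   colour = .data$highlight),
      size = 0.3) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40", `TRUE` = "red"),
                                 guide = "none") +
    ggplot2::labs(x = NULL, y = unique(df$metric)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5,
                                                       size = 6))
}

#' Plot a committor profile
#'
#' IN fraction per candidate window with Wilson intervals and the 1:1
#' transition-state line.
#'
#' @param object A `committor_profile`.
#' @param ... Unused.
#' @method autoplot committor_profile
#' @export
autoplot.committor_profile <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$window_id, y = .data$in_fraction)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_lower,
                                          ymax = .data$ci_upper)) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "window (path order)", y = "IN fraction") +
    ggplot2::theme_minimal()
}

#' Plot a time-window accuracy scan
#'
#' @param object An `mltsa_scan`.
#' @param ... Unused.
#' @method autoplot mltsa_scan
#' @export
autoplot.mltsa_scan <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t_start, y = .data$accuracy_mean)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$accuracy_mean - .data$accuracy_sd,
      ymax = .data$accuracy_mean + .data$accuracy_sd)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "window start (ns)", y = "validation accuracy") +
    ggplot2::theme_minimal()
}
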