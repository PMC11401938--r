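#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a cross-validation result
#'
#' @param x An `ampgraph_cv`.
#' @param ... Unused.
#' @return Per-fold metric tibble (`fold`, `acc`, `auc`, `sen`, `spe`).
#' @export
tidy.ampgraph_cv <- function(x, ...) x$folds

#' One-row summary of a cross-validation result
#'
#' @param x An `ampgraph_cv`.
#' @param ... Unused.
#' @return Tibble with `k`, `variant`, and `<metric>_mean` / `<metric>_sd`
#'   columns.
#' @export
glance.ampgraph_cv <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$aggregate, names_from = "metric",
                             values_from = c("mean", "sd"),
                             names_glue = "{metric}_{.value}")
  dplyr::bind_cols(tibble::tibble(k = x$k, variant = x$variant), wide)
}

#' Tidy a fitted model's loss trace
#'
#' @param x An `ampgraph_fit`.
#' @param ... Unused.
#' @return Tibble with one row per epoch: `epoch`, `d_loss`, `f_loss`,
#'   `graph_loss`, `joint_loss`, `val_auc`.
#' @export
tidy.ampgraph_fit <- function(x, ...) x$trace

#' One-row summary of a fitted model
#'
#' @param x An `ampgraph_fit`.
#' @param ... Unused.
#' @return Tibble with the variant, epochs run, final losses and best
#'   validation AUC.
#' @export
glance.ampgraph_fit <- function(x, ...) {
  last <- if (nrow(x$trace)) x$trace[nrow(x$trace), ] else
    tibble::tibble(d_loss = NA_real_, f_loss = NA_real_,
                   graph_loss = NA_real_, joint_loss = NA_real_)
  tibble::tibble(variant = x$variant, epochs = nrow(x$trace),
                 d_loss = last$d_loss, f_loss = last$f_loss,
                 graph_loss = last$graph_loss, joint_loss = last$joint_loss,
                 best_val_auc = x$state$best$val_auc,
                 best_epoch = x$state$best$epoch)
}

#' Plot per-fold metrics of a cross-validation run
#'
#' @param object An `ampgraph_cv`.
#' @param ... Unused.
#' @return A ggplot object: one point per fold and metric, with the mean
#'   marked.
#' @export
autoplot.ampgraph_cv <- function(object, ...) {
  long <- tidyr::pivot_longer(object$folds, -"fold", names_to = "metric")
  ggplot2::ggplot(long, ggplot2::aes(x = toupper(.data$metric), y = .data$value)) +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.6) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          linewidth = 0.3, colour = "firebrick") +
    ggplot2::labs(x = NULL, y = "metric value",
                  title = sprintf("%d-fold cross-validation (%s)",
                                  object$k, object$variant)) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot the loss trace of a fitted model
#'
#' @param object An `ampgraph_fit`.
#' @param ... Unused.
#' @return A ggplot object with one line per loss component.
#' @export
autoplot.ampgraph_fit <- function(object, ...) {
  long <- tidyr::pivot_longer(object$trace,
                              c("d_loss", "f_loss", "graph_loss", "joint_loss"),
                              names_to = "component")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value,
                                     colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "loss", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot learned per-fold fusion weights (modality importance)
#'
#' @param cv An `ampgraph_cv` from a graph-building variant.
#' @return A ggplot object of weight by modality across folds.
#' @export
plot_fusion_weights <- function(cv) {
  stopifnot(inherits(cv, "ampgraph_cv"))
  ggplot2::ggplot(cv$fusion_weights,
                  ggplot2::aes(x = .data$modality, y = .data$weight)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = "fusion weight",
                  title = "Learned modality importance") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
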