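# broom-style tidiers and ggplot2 autoplot methods for the fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a metrics report into the per-event table
#'
#' @param x A `ddi_metrics`.
#' @param ... Unused.
#' @return Tibble with one row per event: `event`, `n_true`, `auc`, `aupr`,
#'   `f1`.
#' @method tidy ddi_metrics
#' @export
tidy.ddi_metrics <- function(x, ...) x$per_event

#' One-row summary of a metrics report
#'
#' @param x A `ddi_metrics`.
#' @param ... Unused.
#' @return One-row tibble: `n`, `acc`, `aupr_micro`, `auc_micro`,
#'   `f1_macro`.
#' @method glance ddi_metrics
#' @export
glance.ddi_metrics <- function(x, ...) {
  tibble::tibble(n = x$n, acc = x$acc, aupr_micro = x$aupr_micro,
                 auc_micro = x$auc_micro, f1_macro = x$f1_macro)
}

#' Tidy a TransE fit into a long entity-embedding table
#'
#' @param x A `transe_fit`.
#' @param ... Unused.
#' @return Tibble `(entity, dimension, value)`.
#' @method tidy transe_fit
#' @export
tidy.transe_fit <- function(x, ...) {
  tibble::as_tibble(x$entities, .name_repair = ~ paste0("d", seq_along(.x))) |>
    dplyr::mutate(entity = rownames(x$entities), .before = 1L) |>
    tidyr::pivot_longer(-"entity", names_to = "dimension",
                        values_to = "value")
}

#' One-row summary of a TransE fit
#'
#' @param x A `transe_fit`.
#' @param ... Unused.
#' @method glance transe_fit
#' @export
glance.transe_fit <- function(x, ...) {
  tibble::tibble(n_entities = nrow(x$entities),
                 n_relations = nrow(x$relations),
                 dim_kge = ncol(x$entities),
                 final_loss = utils::tail(x$loss_trace, 1))
}

#' One-row summary of a trained pair classifier
#'
#' @param x An `mseddi_fit`.
#' @param ... Unused.
#' @method glance mseddi_fit
#' @export
glance.mseddi_fit <- function(x, ...) {
  tibble::tibble(fold = x$fold,
                 channels = paste(x$model$cfg$channel_mask, collapse = "+"),
                 dim = x$model$cfg$dim,
                 epochs = x$train_cfg$epochs,
                 final_loss = utils::tail(x$loss_trace, 1))
}

#' Training-loss curve of a fitted pair classifier
#'
#' @param object An `mseddi_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mseddi_fit
#' @export
autoplot.mseddi_fit <- function(object, ...) {
  df <- tibble::tibble(epoch = seq_along(object$loss_trace),
                       loss = object$loss_trace)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "epoch", y = "mean training loss",
                  title = "Pair-classifier training loss") +
    ggplot2::theme_minimal()
}

#' Per-event performance of a metrics report
#'
#' @param object A `ddi_metrics`.
#' @param ... Unused.
#' @return A ggplot object (per-event AUC and AUPR bars).
#' @method autoplot ddi_metrics
#' @export
autoplot.ddi_metrics <- function(object, ...) {
  df <- tidyr::pivot_longer(object$per_event, c("auc", "aupr"),
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$event), y = .data$value,
                                   fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "event", y = "score",
                  title = "Per-event one-vs-rest performance") +
    ggplot2::theme_minimal()
}

#' Per-fold metrics of an experiment
#'
#' @param object An `mseddi_experiment`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mseddi_experiment
#' @export
autoplot.mseddi_experiment <- function(object, ...) {
  df <- tidyr::pivot_longer(object$per_fold,
                            c("acc", "aupr_micro", "auc_micro", "f1_macro"),
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$value,
                                   colour = .data$task)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::labs(x = NULL, y = "score",
                  title = "Cold-start metrics per fold") +
    ggplot2::theme_minimal()
}

#' @method tidy mseddi_experiment
#' @export
tidy.mseddi_experiment <- function(x, ...) x$per_fold

#' @method glance mseddi_experiment
#' @export
glance.mseddi_experiment <- function(x, ...) x$summary
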