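#' Tidy a fitted model's training history
#'
#' One row per epoch and loss component (long format), plus the
#' validation accuracy, in the broom convention.
#'
#' @param x a [pf_fit()].
#' @param ... unused.
#' @return tibble with `epoch`, `component`, `value`, `val_accuracy`.
#' @method tidy pf_fit
#' @export
tidy.pf_fit <- function(x, ...) {
  x$history |>
    tidyr::pivot_longer(c("pred", "weak", "context", "intra", "inter",
                          "entropy", "consist", "total"),
                        names_to = "component", values_to = "value") |>
    dplyr::select("epoch", "component", "value", "val_accuracy")
}

#' One-row summary of a fit
#'
#' @param x a [pf_fit()].
#' @param ... unused.
#' @return tibble with `epochs`, `best_epoch`, `best_val_accuracy`,
#'   `final_loss`, `n_parameters`.
#' @method glance pf_fit
#' @export
glance.pf_fit <- function(x, ...) {
  tibble(epochs = max(x$history$epoch),
         best_epoch = x$best_epoch,
         best_val_accuracy = x$best_val_accuracy,
         final_loss = x$history$total[nrow(x$history)],
         n_parameters = length(param_unlist(x$model$params)))
}

#' Tidy an attribution map
#'
#' @param x a [pf_attribute()] result.
#' @param ... unused.
#' @return tibble with `pathway`, `dim`, `sensitivity` plus the
#'   per-pathway aggregate `score` and `rank`.
#' @method tidy pf_attribution
#' @export
tidy.pf_attribution <- function(x, ...) {
  long <- as_tibble(x$S, rownames = "pathway") |>
    tidyr::pivot_longer(-"pathway", names_to = "dim",
                        values_to = "sensitivity")
  dplyr::left_join(long, x$per_pathway, by = "pathway")
}

#' Training-history plot
#'
#' Loss components on a log scale across epochs; use `tidy()` for
#' custom displays (e.g. overlaying validation accuracy).
#'
#' @param object a [pf_fit()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot pf_fit
#' @export
autoplot.pf_fit <- function(object, ...) {
  df <- tidy(object) |>
    dplyr::filter(.data$value > 0)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value,
                                   colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "epoch", y = "loss component (sum over batches)",
                  colour = NULL,
                  title = "Composite-objective components during training") +
    ggplot2::theme_minimal()
}

#' Pathway-attribution plot
#'
#' Ranked per-pathway aggregate sensitivities
#' (`sum_j |S[k, j]|`).
#'
#' @param object a [pf_attribute()] result.
#' @param top_n show at most this many pathways.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot pf_attribution
#' @export
autoplot.pf_attribution <- function(object, top_n = 20, ...) {
  df <- head(object$per_pathway, top_n)
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$pathway, .data$score),
                                   y = .data$score)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "aggregate sensitivity",
                  title = "Pathway attribution ranking") +
    ggplot2::theme_minimal()
}
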