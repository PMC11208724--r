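# broom-style accessors and ggplot2 autoplot methods.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-epoch training history of a fitted model
#'
#' @param x A `cliffopt_model`.
#' @param ... Unused.
#' @return A tibble with one row per epoch: loss components
#'   (`l_bio`, `l_afse`, `l_recon`, `l_val`, `total`), the training-set
#'   `reconstruction_rate` and `validity_rate`, the validation metric and
#'   the learning rate.
#' @export
tidy.cliffopt_model <- function(x, ...) {
  x$history
}

#' One-row summary of a fitted model
#'
#' @param x A `cliffopt_model`.
#' @param ... Unused.
#' @return A one-row tibble: task, epochs trained, best epoch, final
#'   reconstruction and validity rates, final validation metric.
#' @export
glance.cliffopt_model <- function(x, ...) {
  h <- x$history
  last <- h[nrow(h), ]
  best <- h[x$best_epoch, ]
  tibble::tibble(
    task = x$config$task,
    epochs = nrow(h),
    best_epoch = x$best_epoch,
    reconstruction_rate = best$reconstruction_rate,
    validity_rate = best$validity_rate,
    val_metric = last$val_metric,
    hidden_dim = x$config$hidden_dim
  )
}

#' Plot the training history of a fitted model
#'
#' Loss components and the reconstruction/validity rates across epochs.
#'
#' @param object A `cliffopt_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cliffopt_model <- function(object, ...) {
  h <- object$history
  long <- tidyr::pivot_longer(
    h[, c("epoch", "l_bio", "l_afse", "l_recon", "l_val",
          "reconstruction_rate", "validity_rate")],
    -"epoch", names_to = "series", values_to = "value")
  kind <- ifelse(grepl("^l_", long$series), "loss", "rate")
  long$panel <- factor(kind, levels = c("loss", "rate"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value,
                                     colour = .data$series)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::facet_wrap(~panel, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an optimization results table
#'
#' Bar chart of outcome statuses and, when present, the distribution of
#' selection confidences of emitted substitutions.
#'
#' @param results A tibble from [optimize_ligands()].
#' @return A ggplot object.
#' @export
plot_optimization_results <- function(results) {
  ggplot2::ggplot(results, ggplot2::aes(x = .data$status,
                                        fill = .data$status)) +
    ggplot2::geom_bar(show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "anchors") +
    ggplot2::theme_minimal()
}
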