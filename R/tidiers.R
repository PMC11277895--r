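#' Tidy a fitted model's training history
#'
#' @param x A `modra_fit`.
#' @param ... Unused.
#' @return The per-epoch history in long form: `epoch`, `split`
#'   (train/val), `loss` (reg/align/total), `value`.
#' @method tidy modra_fit
#' @export
tidy.modra_fit <- function(x, ...) {
  x$history |>
    tidyr::pivot_longer(-"epoch", names_to = "key", values_to = "value") |>
    tidyr::separate_wider_delim("key", "_", names = c("split", "loss")) |>
    dplyr::mutate(loss = dplyr::recode(.data$loss, la = "align", reg = "reg",
                                       total = "total")) |>
    dplyr::filter(!is.na(.data$value))
}

#' One-row summary of a fitted model
#'
#' @param x A `modra_fit`.
#' @param ... Unused.
#' @return A tibble with the architecture switches and final losses.
#' @method glance modra_fit
#' @export
glance.modra_fit <- function(x, ...) {
  last <- if (nrow(x$history)) x$history[nrow(x$history), ] else
    tibble::tibble(train_reg = NA_real_, train_la = NA_real_,
                   train_total = NA_real_)
  tibble::tibble(
    epochs = nrow(x$history),
    use_alignment = x$train_config$use_alignment,
    use_attention = x$train_config$use_attention,
    final_train_reg = last$train_reg,
    final_train_align = last$train_la,
    final_train_total = last$train_total
  )
}

#' @method tidy modra_cv
#' @export
tidy.modra_cv <- function(x, ...) x$folds

#' @method glance modra_cv
#' @export
glance.modra_cv <- function(x, ...) {
  x$summary |>
    tidyr::pivot_wider(names_from = "metric", values_from = c("mean", "sd"),
                       names_glue = "{metric}_{.value}")
}

#' @method tidy modra_metrics
#' @export
tidy.modra_metrics <- function(x, ...) x$per_drug

#' @method glance modra_metrics
#' @export
glance.modra_metrics <- function(x, ...) {
  tibble::tibble(mse = x$mse, f1 = x$f1, auroc = x$auroc, pooled = x$pooled)
}

#' Training-loss curves
#'
#' @param object A `modra_fit`.
#' @param ... Unused.
#' @return A ggplot of the loss components over epochs.
#' @method autoplot modra_fit
#' @export
autoplot.modra_fit <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$epoch, y = .data$value,
                                 colour = .data$loss,
                                 linetype = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "loss", colour = "component",
                  linetype = "split") +
    ggplot2::theme_minimal()
}

#' Drugs-by-views importance heatmap
#'
#' Positive delta (masking the view worsened prediction) means the view
#' carried useful information for that drug.
#'
#' @param object A `modra_importance` tibble from
#'   [omics_mask_importance()].
#' @param ... Unused.
#' @return A ggplot heatmap of masking deltas.
#' @method autoplot modra_importance
#' @export
autoplot.modra_importance <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$drug_id, y = .data$view,
                                       fill = .data$delta)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0) +
    ggplot2::labs(x = "drug", y = "omics view", fill = "masked - baseline MSE") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}
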