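#' Plot a confusion matrix as a heat map
#'
#' @param object A `powder_eval` object.
#' @param scope `"all"` (default) or `"test"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.powder_eval <- function(object, scope = c("all", "test"), ...) {
  scope <- match.arg(scope)
  cm <- if (scope == "all") object$confusion_all else object$confusion_test
  if (is.null(cm)) abort("No test-only confusion matrix in this evaluation.")
  df <- tibble::as_tibble(as.data.frame.table(cm, responseName = "count"))
  names(df) <- c("truth", "predicted", "count")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$truth,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), colour = "white") +
    ggplot2::scale_y_discrete(limits = rev(levels(df$truth))) +
    ggplot2::scale_fill_gradient(low = "grey20", high = "steelblue") +
    ggplot2::labs(
      title = sprintf("%s — correct classification rate %.2f %%",
                      object$classifier,
                      if (scope == "all") object$rate_all else object$rate_test),
      x = "predicted level", y = "true level"
    ) +
    ggplot2::theme_minimal()
}

#' Plot the selection criterion trace
#'
#' Cross-validated deviance after each accepted feature, against the null
#' deviance baseline.
#'
#' @param object A `powder_selection` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.powder_selection <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$step, y = .data$criterion)) +
    ggplot2::geom_hline(yintercept = object$null_deviance, linetype = "dashed") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "features selected", y = "held-out deviance",
                  title = "Sequential forward selection") +
    ggplot2::theme_minimal()
}

#' Plot the ANN training trace
#'
#' Training and validation MSE per epoch, with the best-validation epoch
#' marked — the early-stopping artefact of Levenberg-Marquardt training.
#'
#' @param object A `powder_ann` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.powder_ann <- function(object, ...) {
  df <- tidyr::pivot_longer(object$trace, c("train_mse", "val_mse"),
                            names_to = "partition", values_to = "mse")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$mse,
                                   colour = .data$partition)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = "dotted") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(y = "mean squared error",
                  title = sprintf("LM training, %d-%d-%d network",
                                  object$n_in, object$n_hidden, object$n_class)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
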