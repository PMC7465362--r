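#' Tidy a cross-validation result
#'
#' @param x A `fourmc_cv`.
#' @param ... Unused.
#' @return The per-fold metric tibble (one row per rotation).
#' @method tidy fourmc_cv
#' @export
tidy.fourmc_cv <- function(x, ...) {
  x$per_fold
}

#' One-row summary of a cross-validation result
#'
#' @param x A `fourmc_cv`.
#' @param ... Unused.
#' @return A one-row tibble: scheme, k, mean test-fold mcc/acc/sn/sp/auc.
#' @method glance fourmc_cv
#' @export
glance.fourmc_cv <- function(x, ...) {
  dplyr::bind_cols(
    tibble(scheme = x$scheme, k = x$k),
    x$summary[, c("mcc", "acc", "sn", "sp", "auc")]
  )
}

#' Tidy a trained model's history
#'
#' @param x A `fourmc_cnn`.
#' @param ... Unused.
#' @return The per-epoch training history tibble.
#' @method tidy fourmc_cnn
#' @export
tidy.fourmc_cnn <- function(x, ...) {
  if (is.null(x$history)) {
    abort("model has no training history")
  }
  x$history
}

#' One-row summary of a trained model
#'
#' @param x A `fourmc_cnn`.
#' @param ... Unused.
#' @return A one-row tibble: scheme, parameter count, epochs run, best epoch,
#'   final/best losses.
#' @method glance fourmc_cnn
#' @export
glance.fourmc_cnn <- function(x, ...) {
  h <- x$history
  tibble(
    scheme = if (is.null(x$scheme)) NA_character_ else x$scheme,
    n_params = n_params(x),
    epochs_run = if (is.null(h)) 0L else nrow(h),
    best_epoch = if (is.null(x$best_epoch)) NA_integer_ else x$best_epoch,
    final_loss = if (is.null(h)) NA_real_ else h$loss[nrow(h)],
    best_val_loss = if (is.null(h) || all(is.na(h$val_loss))) NA_real_
                    else min(h$val_loss, na.rm = TRUE)
  )
}

#' ROC curves of a cross-validation result
#'
#' One curve per test fold plus the chance diagonal.
#'
#' @param object A `fourmc_cv`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot fourmc_cv
#' @export
autoplot.fourmc_cv <- function(object, ...) {
  ggplot2::ggplot(object$roc,
                  ggplot2::aes(x = .data$fpr, y = .data$tpr,
                               group = .data$fold)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_path(alpha = 0.6) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "false positive rate", y = "true positive rate",
      title = sprintf("%d-fold ROC (%s), mean AUC %.3f",
                      object$k, object$scheme, object$summary$auc)
    ) +
    ggplot2::theme_minimal()
}
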