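# broom-style tidiers and ggplot2 autoplot methods for result objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a cross-validation result
#'
#' @param x A `pinnet_cv`.
#' @param ... Unused.
#' @return Tibble with one row per fold: selected hyperparameters,
#'   validation AUC, epochs run, test AUC and F1.
#' @method tidy pinnet_cv
#' @export
tidy.pinnet_cv <- function(x, ...) x$reports

#' One-row cross-validation summary
#'
#' @param x A `pinnet_cv`.
#' @param ... Unused.
#' @return Tibble with fold count, mean/sd of test AUC and F1.
#' @method glance pinnet_cv
#' @export
glance.pinnet_cv <- function(x, ...) {
  tibble::tibble(n_folds = nrow(x$reports),
                 mean_test_auc = mean(x$reports$test_auc),
                 sd_test_auc = sd(x$reports$test_auc),
                 mean_test_f1 = mean(x$reports$test_f1),
                 sd_test_f1 = sd(x$reports$test_f1))
}

#' Tidy a fitted network
#'
#' @param x A `pinnet_model` fitted with [fit_network()].
#' @param ... Unused.
#' @return The per-epoch training history tibble.
#' @method tidy pinnet_model
#' @export
tidy.pinnet_model <- function(x, ...) {
  x$history %||% abort("model has no training history (not fitted)")
}

#' One-row fitted-network summary
#'
#' @param x A fitted `pinnet_model`.
#' @param ... Unused.
#' @return Tibble with architecture widths, best validation AUC, best epoch
#'   and epochs run.
#' @method glance pinnet_model
#' @export
glance.pinnet_model <- function(x, ...) {
  tibble::tibble(n_genes = x$cfg$n_genes, n_pathways = x$cfg$n_pathways,
                 n_fc = x$cfg$n_fc, n_hidden = x$cfg$n_hidden,
                 best_val_auc = x$best_val_auc %||% NA_real_,
                 best_epoch = x$best_epoch %||% NA_integer_,
                 epochs_run = x$epochs_run %||% NA_integer_)
}

#' Tidy an attribution result
#'
#' @param x A `pinnet_attribution`.
#' @param ... Unused.
#' @return Long tibble: `sample`, `node_id`, `attribution`.
#' @method tidy pinnet_attribution
#' @export
tidy.pinnet_attribution <- function(x, ...) {
  tibble::tibble(
    sample = rep(rownames(x$C) %||% paste0("s", seq_len(nrow(x$C))),
                 times = ncol(x$C)),
    node_id = rep(x$node_ids, each = nrow(x$C)),
    attribution = as.vector(x$C))
}

#' Bar chart of the top importance scores
#'
#' @param object A `pinnet_importance` tibble.
#' @param top_n Number of highest-importance nodes to show, default 20.
#' @param highlight Optional node ids (e.g. known disease genes) to colour.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pinnet_importance
#' @export
autoplot.pinnet_importance <- function(object, top_n = 20, highlight = NULL, ...) {
  df <- dplyr::arrange(tibble::as_tibble(object), dplyr::desc(.data$importance))
  df <- utils::head(df, top_n)
  df$node_id <- factor(df$node_id, levels = rev(df$node_id))
  df$known <- df$node_id %in% (highlight %||% character(0))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$importance, y = .data$node_id))
  p <- if (is.null(highlight)) {
    p + ggplot2::geom_col(fill = "steelblue")
  } else {
    p + ggplot2::geom_col(ggplot2::aes(fill = .data$known)) +
      ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick"),
                                 name = "known gene")
  }
  p + ggplot2::labs(x = "importance score (mean cross-fold z-score)", y = NULL)
}

#' Per-fold test AUC plot for a cross-validation run
#'
#' @param object A `pinnet_cv`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pinnet_cv
#' @export
autoplot.pinnet_cv <- function(object, ...) {
  df <- object$reports
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$fold), y = .data$test_auc)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = mean(df$test_auc), linetype = 2) +
    ggplot2::labs(x = "fold", y = "test AUC")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
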