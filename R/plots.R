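#' Plot ROC and precision-recall curves
#'
#' @param object An `eval_curves` object from [roc_pr_curves()].
#' @param ... Unused.
#' @return A ggplot with one panel per curve type, areas in the panel labels.
#' @export
autoplot.eval_curves <- function(object, ...) {
  dat <- dplyr::bind_rows(
    tibble::tibble(panel = sprintf("ROC (area %.3f)", object$auc_roc),
                   x = object$roc$fpr, y = object$roc$tpr),
    tibble::tibble(panel = sprintf("PR (area %.3f)", object$auc_pr),
                   x = object$pr$recall, y = object$pr$precision))
  ggplot2::ggplot(dat, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_path(linewidth = 0.7, colour = "#2c7fb8") +
    ggplot2::facet_wrap(~panel) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "FPR / recall", y = "TPR / precision") +
    ggplot2::theme_bw()
}

#' @export
autoplot.eval_report <- function(object, ...) {
  if (is.null(object$curves)) stop("report has no score curves", call. = FALSE)
  autoplot(object$curves) +
    ggplot2::ggtitle(sprintf("%s, LOO Acc %.1f%%",
                             object$classifier$kind, object$metrics$acc))
}

#' Plot electrode weights
#'
#' Bar chart of the accuracy-based weight of each electrode in montage
#' order; when the `standardized` column is present
#' (see [standardize_weights()]) bars are coloured by it.
#'
#' @param object An [electrode_weights()] tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.electrode_weights <- function(object, ...) {
  dat <- tibble::as_tibble(object)
  dat$electrode <- factor(dat$electrode, levels = dat$electrode)
  p <- ggplot2::ggplot(dat, ggplot2::aes(.data$electrode, .data$weight))
  p <- if ("standardized" %in% names(dat)) {
    p + ggplot2::geom_col(ggplot2::aes(fill = .data$standardized)) +
      ggplot2::scale_fill_viridis_c(name = "standardised")
  } else {
    p + ggplot2::geom_col(fill = "#2c7fb8")
  }
  p + ggplot2::labs(x = NULL, y = "weight V") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Plot a grid-search accuracy surface
#'
#' @param search Result of [grid_search_svm()].
#' @return A ggplot tile map of LOO accuracy over the `log2` lattice, with
#'   the maximising pair marked.
#' @export
plot_grid_search <- function(search) {
  ggplot2::ggplot(search$surface,
                  ggplot2::aes(.data$c_exp, .data$g_exp, fill = .data$acc)) +
    ggplot2::geom_tile() +
    ggplot2::geom_point(data = tibble::tibble(c_exp = search$best_c_exp,
                                              g_exp = search$best_g_exp),
                        ggplot2::aes(.data$c_exp, .data$g_exp),
                        inherit.aes = FALSE, shape = 4, size = 3) +
    ggplot2::scale_fill_viridis_c(name = "LOO Acc (%)") +
    ggplot2::labs(x = "log2(cost)", y = "log2(gamma)") +
    ggplot2::theme_bw()
}
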