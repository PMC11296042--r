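#' Plot factor loadings
#'
#' Horizontal bar panels per factor, absolute loading on the x axis, color
#' by sign — the standard display for oblique evoked-emotion solutions.
#'
#' @param object an `emospace_factor_model`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.emospace_factor_model <- function(object, ...) {
  td <- tidy(object)
  td$sign <- ifelse(td$loading >= 0, "positive", "negative")
  ggplot2::ggplot(td, ggplot2::aes(x = abs(.data$loading),
                                   y = stats::reorder(.data$scale_id, abs(.data$loading)),
                                   fill = .data$sign,
                                   alpha = abs(.data$loading))) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~factor, nrow = 1) +
    ggplot2::scale_fill_manual(values = c(positive = "#b2182b",
                                          negative = "#2166ac")) +
    ggplot2::scale_alpha(range = c(0.35, 1), guide = "none") +
    ggplot2::labs(x = "|loading|", y = NULL, fill = NULL,
                  title = object$method) +
    ggplot2::theme_minimal()
}

#' Plot retention cross-validation curves
#'
#' Mean explained variance (EFA half) and mean RMSEA (CFA half) against the
#' number of factors, with the chosen k marked.
#'
#' @param object an `emospace_retention`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.emospace_retention <- function(object, ...) {
  cu <- tidyr::pivot_longer(object$curves,
                            cols = c("mean_explained", "mean_rmsea"),
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(cu, ggplot2::aes(x = .data$k, y = .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$chosen_k, linetype = 2) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "number of factors", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a 2-D embedding
#'
#' Scatter of the embedded instances, colored by an attached factor score
#' (default: the first score column) or category label.
#'
#' @param object an `emospace_embedding`.
#' @param colour column of `object$coords` to color by (default: first
#'   score/label column after the coordinates).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.emospace_embedding <- function(object, colour = NULL, ...) {
  co <- object$coords
  colour <- colour %||% setdiff(names(co), c("instance", "dim1", "dim2"))[1]
  p <- ggplot2::ggplot(co, ggplot2::aes(x = .data$dim1, y = .data$dim2))
  if (!is.na(colour) && !is.null(colour)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data[[colour]]),
                                 size = 1)
    if (is.numeric(co[[colour]])) {
      p <- p + ggplot2::scale_colour_gradient2(low = "#2166ac", mid = "grey85",
                                               high = "#b2182b")
    }
  } else {
    p <- p + ggplot2::geom_point(size = 1)
  }
  p + ggplot2::labs(x = "UMAP 1", y = "UMAP 2") + ggplot2::theme_minimal()
}

#' Plot scale-quality medians
#'
#' Dot plot of median test-retest and split-half reliability per scale,
#' sorted by test-retest reliability.
#'
#' @param report a [scale_quality()] tibble.
#' @param flagged optional character vector of flagged scales to grey out.
#' @return a ggplot object.
#' @export
plot_scale_quality <- function(report, flagged = NULL) {
  td <- tidyr::pivot_longer(report,
                            cols = c("median_test_retest", "median_split_half"),
                            names_to = "metric", values_to = "r")
  td$flagged <- td$scale_id %in% (flagged %||% character(0))
  ggplot2::ggplot(td, ggplot2::aes(
    x = .data$r,
    y = stats::reorder(.data$scale_id, .data$r, FUN = function(v) mean(v, na.rm = TRUE)),
    colour = .data$flagged)) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "black", `TRUE` = "grey60")) +
    ggplot2::labs(x = "median reliability (r)", y = NULL, colour = "flagged") +
    ggplot2::theme_minimal()
}

#' Plot a correlation structure as a seriated heatmap
#'
#' @param c an `emospace_corr_structure`.
#' @param order optional ordering (default: [seriate()]).
#' @return a ggplot object.
#' @export
plot_corr_structure <- function(c, order = NULL) {
  r <- unclass(c)
  ord <- order %||% seriate(c)
  r <- r[ord, ord]
  td <- tibble::tibble(
    row = factor(rep(rownames(r), ncol(r)), levels = rownames(r)),
    col = factor(rep(colnames(r), each = nrow(r)), levels = colnames(r)),
    r = as.vector(r))
  ggplot2::ggplot(td, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       hjust = 1, vjust = 0.5))
}
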