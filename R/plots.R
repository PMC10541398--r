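#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Scatter plot of an ordination
#'
#' First two components with contribution ratios in the axis labels,
#' optionally colored by a sample grouping.
#'
#' @param object An `ordination` (from [genotype_pca()],
#'   [classical_mds()] or [trait_pca()]).
#' @param groups Optional named vector (`sample_id` -> group) or tibble
#'   with `sample_id` and `group`.
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot ordination
#' @export
autoplot.ordination <- function(object, groups = NULL, ...) {
  df <- object$scores
  if (ncol(df) < 3) stop("need at least two components to plot", call. = FALSE)
  if (!is.null(groups)) {
    if (is.data.frame(groups)) {
      groups <- stats::setNames(as.character(groups$group), groups$sample_id)
    }
    df$group <- groups[df$sample_id]
  }
  lab <- function(i) {
    sprintf("PC%d (%.1f%%)", i, object$contrib[i])
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::labs(
      x = lab(1), y = lab(2),
      title = toupper(object$method)
    ) +
    ggplot2::theme_minimal()
  if (is.null(groups)) {
    p + ggplot2::geom_point()
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$group))
  }
}

#' Stacked ancestry bar plot for an admixture fit
#'
#' One bar per sample, one fill per ancestry cluster, the standard
#' admixture display.
#'
#' @param object An [admix_fit()].
#' @param order_by Optional vector of sample IDs giving the bar order.
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot admix_fit
#' @export
autoplot.admix_fit <- function(object, order_by = NULL, ...) {
  df <- tidy(object)
  lv <- if (is.null(order_by)) unique(df$sample_id) else order_by
  df$sample_id <- factor(df$sample_id, levels = lv)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$sample_id, y = .data$proportion, fill = .data$cluster
  )) +
    ggplot2::geom_col(width = 1) +
    ggplot2::labs(
      x = NULL, y = "ancestry proportion",
      title = sprintf("Admixture, K = %d", object$K)
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Cross-validation error curve over K
#'
#' @param object An [admix_cv()].
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot admix_cv
#' @export
autoplot.admix_cv <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$K, y = .data$cv_error)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_point(
      data = object$curve[which.min(object$curve$cv_error), ],
      colour = "red", size = 3
    ) +
    ggplot2::labs(y = "CV error", title = "Cross-validated choice of K") +
    ggplot2::theme_minimal()
}
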