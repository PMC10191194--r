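#' Plot per-isolate carbon acquisition
#'
#' Bar chart of per-isolate mean host-derived carbon with standard-error
#' bars, the standard display for isotope-derived C acquisition.
#'
#' @param object A `carbon_flux` object.
#' @param quantity `"amount"` (mg C) or `"percent"` (%C from symbiosis).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot carbon_flux
#' @export
autoplot.carbon_flux <- function(object, quantity = c("amount", "percent"), ...) {
  quantity <- match.arg(quantity)
  d <- object$isolates
  if (quantity == "amount") {
    d$y <- d$mean_c_symbiosis_mg
    d$se <- d$se_c_symbiosis_mg
    ylab <- "Host-derived C retained (mg)"
  } else {
    d$y <- d$mean_pct_c_symbiosis
    d$se <- d$se_pct_c_symbiosis
    ylab <- "Mycelium C from symbiosis (%)"
  }
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$isolate, -.data$y), y = .data$y)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$y - .data$se, ymax = .data$y + .data$se),
      width = 0.25
    ) +
    ggplot2::labs(x = "Isolate", y = ylab) +
    ggplot2::theme_minimal()
}

#' Biplot of a trait PCA
#'
#' Scores for the first two components with loading arrows overlaid,
#' annotated with the percentage of variance each component explains.
#'
#' @param object A `trait_pca` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot trait_pca
#' @export
autoplot.trait_pca <- function(object, ...) {
  sc <- object$scores
  ld <- object$loadings
  id_col <- setdiff(names(sc), grep("^PC", names(sc), value = TRUE))[1]
  r <- max(abs(c(sc$PC1, sc$PC2))) / max(abs(c(ld$PC1, ld$PC2)))
  p <- ggplot2::ggplot(sc, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::geom_segment(
      data = ld,
      ggplot2::aes(x = 0, y = 0, xend = .data$PC1 * r, yend = .data$PC2 * r),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")), colour = "steelblue"
    ) +
    ggplot2::geom_text(
      data = ld,
      ggplot2::aes(x = .data$PC1 * r * 1.08, y = .data$PC2 * r * 1.08, label = .data$variable),
      colour = "steelblue", size = 3
    ) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$var_explained[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$var_explained[2])
    ) +
    ggplot2::theme_minimal()
  if (!is.na(id_col)) {
    p <- p + ggplot2::geom_text(
      ggplot2::aes(label = .data[[id_col]]),
      nudge_y = 0.12, size = 3
    )
  }
  p
}

#' Histogram of screen correlations with percentile thresholds
#'
#' Frequency histogram of per-transcript Pearson correlations with dashed
#' lines at the q0.99 and q0.01 selection thresholds.
#'
#' @param object A `correlation_screen` object.
#' @param bins Histogram bin count.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot correlation_screen
#' @export
autoplot.correlation_screen <- function(object, bins = 60, ...) {
  ggplot2::ggplot(object$result, ggplot2::aes(x = .data$pearson_r)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey65", colour = "grey30") +
    ggplot2::geom_vline(xintercept = c(object$q01, object$q99), linetype = "dashed") +
    ggplot2::labs(
      x = "Pearson r with C acquisition", y = "Transcripts",
      subtitle = sprintf("q0.99 = %.2f, q0.01 = %.2f", object$q99, object$q01)
    ) +
    ggplot2::theme_minimal()
}

#' Heatmap of a clustered fold-change matrix
#'
#' Tile heatmap of a log2 fold-change matrix with rows (and optionally
#' columns) ordered by hierarchical clustering leaf order.
#'
#' @param fc Matrix from [foldchange_matrix()].
#' @param cluster_rows,cluster_cols Reorder by [cluster_order()]?
#' @param linkage Linkage method for clustering.
#' @return A ggplot object.
#' @export
plot_foldchange_heatmap <- function(fc, cluster_rows = TRUE, cluster_cols = FALSE,
                                    linkage = "average") {
  if (cluster_rows && nrow(fc) >= 2) fc <- fc[cluster_order(fc, "rows", linkage), , drop = FALSE]
  if (cluster_cols && ncol(fc) >= 2) fc <- fc[, cluster_order(fc, "cols", linkage), drop = FALSE]
  d <- tibble::as_tibble(fc, rownames = "transcript") |>
    tidyr::pivot_longer(-"transcript", names_to = "condition", values_to = "log2fc") |>
    dplyr::mutate(
      transcript = factor(.data$transcript, levels = rev(rownames(fc))),
      condition = factor(.data$condition, levels = colnames(fc))
    )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$condition, y = .data$transcript, fill = .data$log2fc)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red") +
    ggplot2::labs(x = NULL, y = NULL, fill = "log2 FC") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}
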