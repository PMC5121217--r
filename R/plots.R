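#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a fitted k-u correlation
#'
#' Scatter of per-period overall mass transfer coefficients against
#' superficial velocity with the fitted (or published) line overlaid.
#'
#' @param object A `ku_model`.
#' @param points Optional data frame `(u, k)` to overlay; defaults to the
#'   model's own fitting data when available.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ku_model <- function(object, points = NULL, ...) {
  if (is.null(points) && !is.null(object$fit)) {
    points <- object$fit$model[, c("u", "k")]
  }
  p <- ggplot2::ggplot() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "steelblue") +
    ggplot2::labs(
      x = "Superficial velocity u (m/d)",
      y = "Overall mass transfer coefficient k (mm/d)",
      title = sprintf("k = %.3g u + %.3g", object$slope, object$intercept)
    )
  if (!is.null(points)) {
    p <- p + ggplot2::geom_point(data = points,
                                 ggplot2::aes(x = .data$u, y = .data$k))
  }
  p
}

#' Plot a principal coordinates ordination
#'
#' First two axes of a [pcoa()] result, axis labels annotated with the
#' fraction of (positive-eigenvalue) variance each explains.
#'
#' @param object A `pcoa_ordination`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pcoa_ordination <- function(object, ...) {
  ve <- round(100 * object$variance_explained)
  pts <- object$points
  if (!"Axis.2" %in% names(pts)) pts$Axis.2 <- 0
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$Axis.1, y = .data$Axis.2,
                                    label = .data$sample_id)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(vjust = -0.8, size = 3) +
    ggplot2::labs(
      x = sprintf("PC1 (%d%%)", ve[1]),
      y = if (length(ve) > 1) sprintf("PC2 (%d%%)", ve[2]) else "PC2"
    )
}

#' Relative-abundance heat map
#'
#' Tile map of relative OTU abundances with both margins ordered by
#' Bray-Curtis / average-linkage (UPGMA) clustering, the conventional
#' layout for community time-course heat maps.
#'
#' @param counts An OTU count tibble.
#' @param cluster_samples Order sample columns by clustering too (default
#'   `TRUE`; requires at least 2 samples).
#' @return A ggplot.
#' @export
plot_abundance_heatmap <- function(counts, cluster_samples = TRUE) {
  prop <- relative_abundance(counts)
  otu_order <- bray_curtis_cluster(prop, margin = "otus")$order
  sample_ids <- setdiff(names(prop), "otu_id")
  if (cluster_samples && length(sample_ids) >= 2) {
    sample_ids <- bray_curtis_cluster(prop, margin = "samples")$order
  }
  long <- tidyr::pivot_longer(prop, -"otu_id", names_to = "sample_id",
                              values_to = "abundance") |>
    dplyr::mutate(
      otu_id = factor(.data$otu_id, levels = otu_order),
      sample_id = factor(.data$sample_id, levels = sample_ids)
    )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample_id, y = .data$otu_id,
                                     fill = .data$abundance)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "darkred",
                                 name = "Relative\nabundance") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
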