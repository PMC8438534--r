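# ggplot2 autoplot() methods for the result objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Biplot of a screening PCA
#'
#' Genotype scores on the first two components with trait loading arrows;
#' the quadrant structure of this plot drives [select_genotypes()].
#'
#' @param object A [pca_screen()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method
autoplot.pca_screen <- function(object, ...) {
  sc <- tibble::tibble(genotype = rownames(object$scores),
                       PC1 = object$scores[, 1L],
                       PC2 = object$scores[, min(2L, ncol(object$scores))])
  scale_arrows <- max(abs(sc$PC1), abs(sc$PC2)) * 0.8
  ld <- tibble::tibble(trait = rownames(object$loadings),
                       PC1 = object$loadings[, 1L] * scale_arrows,
                       PC2 = object$loadings[, min(2L, ncol(object$loadings))] *
                         scale_arrows)
  ex <- object$explained_pct
  ggplot2::ggplot(sc, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey70") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey70") +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = .data$genotype),
                       vjust = -0.7, size = 3) +
    ggplot2::geom_segment(data = ld,
                          ggplot2::aes(x = 0, y = 0, xend = .data$PC1,
                                       yend = .data$PC2),
                          arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
                          colour = "steelblue") +
    ggplot2::geom_text(data = ld, ggplot2::aes(label = .data$trait),
                       colour = "steelblue", vjust = 1.4, size = 3) +
    ggplot2::labs(x = sprintf("PC1 (%.1f%%)", ex[1L]),
                  y = sprintf("PC2 (%.1f%%)", if (length(ex) >= 2L) ex[2L] else 0),
                  title = "Genotype screening biplot")
}

#' Correlation heat map
#'
#' @param object A [correlation_matrix()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method
autoplot.trait_correlations <- function(object, ...) {
  traits <- colnames(object$r)
  d <- tidy(object)
  d <- dplyr::bind_rows(d,
                        tibble::tibble(trait1 = d$trait2, trait2 = d$trait1,
                                       r = d$r, p_value = d$p_value),
                        tibble::tibble(trait1 = traits, trait2 = traits,
                                       r = diag(object$r), p_value = NA_real_))
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$trait1, traits),
                                  y = factor(.data$trait2, rev(traits)),
                                  fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "firebrick", mid = "white",
                                  high = "navy", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, title = "Trait correlations") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Sum-of-squares partition plot
#'
#' @param object A [two_way_anova()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method
autoplot.anova_partition <- function(object, ...) {
  d <- tibble::as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$term, d$term),
                                  y = .data$ss_pct)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "share of total SS (%)",
                  title = paste0("Variance partition: ", attr(object, "trait")))
}

#' Row-scaled cluster heat map
#'
#' Z-scored matrix with rows and columns ordered by their Ward-D2
#' dendrograms, the standard screening heat map.
#'
#' @param object A [ward_cluster()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method
autoplot.ward_cluster <- function(object, ...) {
  m <- object$scaled
  row_ord <- object$item_hclust$order
  col_ord <- if (!is.null(object$feature_hclust)) {
    object$feature_hclust$order
  } else seq_len(ncol(m))
  d <- tibble::tibble(
    item = factor(rep(rownames(m), ncol(m)),
                  levels = rownames(m)[row_ord]),
    feature = factor(rep(colnames(m), each = nrow(m)),
                     levels = colnames(m)[col_ord]),
    z = as.vector(m)
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$feature, y = .data$item,
                                  fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white",
                                  high = "firebrick", limits = c(-2, 2),
                                  oob = scales_squish) +
    ggplot2::labs(x = NULL, y = NULL, fill = "row Z",
                  title = "Ward-D2 cluster heat map") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

# clamp out-of-range Z values into the fill limits (avoids a scales dep)
scales_squish <- function(x, range = c(-2, 2)) {
  pmin(pmax(x, range[1L]), range[2L])
}

#' Control versus stress performance plot
#'
#' Genotype means under deficiency against control, coloured by the stress
#' tolerance index; the diagonal marks no stress response.
#'
#' @param object A [compute_indices()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method
autoplot.tolerance_indices <- function(object, ...) {
  d <- tibble::as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$y_ns, y = .data$y_s,
                                  colour = .data$STI)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = .data$genotype),
                       vjust = -0.7, size = 3, show.legend = FALSE) +
    ggplot2::scale_colour_viridis_c() +
    ggplot2::labs(x = "control mean", y = "deficient mean",
                  title = sprintf("Stress response (SI = %.2f)",
                                  attr(object, "si")))
}
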