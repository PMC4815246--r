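#' Heatmap of a metagene density matrix
#'
#' Renders the expression-ranked gene-body heatmap with the standard
#' colour-map normalisation (clip at the 80th quantile of nonzero values,
#' min-max to `[0, 1]`). Rows keep their expression order, highest on top;
#' the 5' end is on the left.
#'
#' @param object A [metagene_matrix()].
#' @param q Clipping quantile passed to [quantile_scale()] (default 0.8).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.metagene_matrix <- function(object, q = 0.8, ...) {
  m <- quantile_scale(object$matrix, q = q)
  d <- tibble::tibble(
    gene = rep(seq_len(nrow(m)), times = ncol(m)),
    bin = rep(seq_len(ncol(m)), each = nrow(m)),
    density = as.vector(m))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$bin, y = .data$gene,
                                  fill = .data$density)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "bin (5' flank | body | 3' flank)",
                  y = "genes by descending expression",
                  fill = "scaled\ndensity") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Strip plot of per-library repeat-class densities
#'
#' @param cpm A [repeat_cpm()] tibble.
#' @return A ggplot object: CPM per repeat class, one point per library,
#'   coloured by tissue, faceted by mark when several are present.
#' @export
plot_repeat_cpm <- function(cpm) {
  p <- ggplot2::ggplot(cpm, ggplot2::aes(x = .data$class, y = .data$cpm,
                                         colour = .data$tissue)) +
    ggplot2::geom_jitter(width = 0.15, height = 0) +
    ggplot2::labs(x = NULL, y = "tags per million repeat tags") +
    ggplot2::theme_minimal()
  if (dplyr::n_distinct(cpm$mark) > 1) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$mark))
  }
  p
}

#' Bar chart of genomic-category composition
#'
#' @param comp A [category_composition()] tibble.
#' @return A ggplot object (stacked fraction bars per library; the pie-chart
#'   data in bar form).
#' @export
plot_category_composition <- function(comp) {
  ggplot2::ggplot(comp, ggplot2::aes(x = .data$library_id,
                                     y = .data$fraction,
                                     fill = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "fraction of tags") +
    ggplot2::theme_minimal()
}

#' Significance of the four directional overlap pairs
#'
#' @param venn A [venn_summary()] tibble.
#' @return A ggplot object: -log10 p per direction pair, the top pair
#'   highlighted.
#' @export
plot_overlap_summary <- function(venn) {
  d <- dplyr::mutate(venn,
                     pair = paste0("5mC ", .data$direction_a, " / 5hmC ",
                                   .data$direction_b))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pair,
                                  y = -log10(pmax(.data$p, 1e-300)),
                                  fill = .data$top)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60",
                                          `TRUE` = "firebrick"),
                               guide = "none") +
    ggplot2::labs(x = NULL, y = expression(-log[10] ~ p)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
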