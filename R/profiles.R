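#' Expression-ranked metagene density matrix
#'
#' Builds the numeric matrix behind a DIP-Seq gene-body heatmap: per gene,
#' tag density in fixed-width flank bins (500 bp by default) upstream and
#' downstream plus a fixed number of length-normalised gene-body bins.
#' Minus-strand genes are reversed so the 5' end is always leftmost. Rows
#' are ordered by descending expression; values are per-bp tag density
#' scaled to tags-per-million of the library (so libraries of different
#' depth are comparable; for cross-library figures scale instead to the
#' median library size via `scale_to`).
#'
#' @param tags Tidy tag tibble (a single track; pool libraries upstream if
#'   desired).
#' @param genes Gene-model tibble; genes shorter than `body_bins` bp are
#'   skipped with a warning.
#' @param expression Optional tibble (`gene_id`, `expression`); defaults to
#'   the `expression` column of `genes`. Genes without a value are dropped.
#' @param flank Flank width in bp; must be a multiple of `bin_size`
#'   (default 5000).
#' @param body_bins Number of gene-body bins (default 40).
#' @param bin_size Flank bin width in bp (default 500).
#' @param scale_to Library size the densities are scaled to per million;
#'   defaults to the tag count of `tags` itself (plain tags-per-million).
#' @return Object of class `metagene_matrix`: list with `matrix` (genes x
#'   bins, rownames = gene ids), `genes` (id + expression in row order),
#'   `n_flank_bins`, `body_bins`, `bin_size`.
#' @export
metagene_matrix <- function(tags, genes, expression = NULL, flank = 5000,
                            body_bins = 40, bin_size = 500,
                            scale_to = 1e6) {
  stopifnot(flank %% bin_size == 0, body_bins >= 1)
  if (is.null(expression)) {
    stopifnot("expression" %in% names(genes))
    expression <- genes[, c("gene_id", "expression")]
  }
  g <- dplyr::inner_join(genes, expression[, c("gene_id", "expression")],
                         by = "gene_id", suffix = c(".drop", "")) |>
    dplyr::arrange(dplyr::desc(.data$expression))
  too_short <- g$end - g$start < body_bins
  if (any(too_short)) {
    warning(sum(too_short), " gene(s) shorter than body_bins bp skipped")
    g <- g[!too_short, , drop = FALSE]
  }
  n_flank <- flank / bin_size
  n_cols <- 2 * n_flank + body_bins
  scale_f <- scale_to / max(1, nrow(tags))
  pos_split <- lapply(split(tags$pos, tags$chrom), sort)

  m <- matrix(0, nrow = nrow(g), ncol = n_cols)
  rownames(m) <- g$gene_id
  colnames(m) <- c(paste0("up", seq_len(n_flank)),
                   paste0("body", seq_len(body_bins)),
                   paste0("down", seq_len(n_flank)))
  for (i in seq_len(nrow(g))) {
    p <- pos_split[[g$chrom[i]]]
    if (is.null(p)) next
    s <- g$start[i]; e <- g$end[i]
    p <- p[p >= s - flank & p < e + flank]
    if (length(p) == 0) next
    body_w <- (e - s) / body_bins
    bin <- integer(length(p))
    up <- p < s
    dn <- p >= e
    body <- !up & !dn
    bin[up] <- floor((p[up] - (s - flank)) / bin_size)
    bin[body] <- n_flank + pmin(body_bins - 1, floor((p[body] - s) / body_w))
    bin[dn] <- n_flank + body_bins + floor((p[dn] - e) / bin_size)
    width <- c(rep(bin_size, n_flank), rep(body_w, body_bins),
               rep(bin_size, n_flank))
    cnt <- tabulate(bin + 1L, nbins = n_cols)
    row <- cnt / width * scale_f
    if (g$strand[i] == "-") row <- rev(row)
    m[i, ] <- row
  }
  structure(list(matrix = m,
                 genes = g[, c("gene_id", "expression")],
                 n_flank_bins = n_flank, body_bins = body_bins,
                 bin_size = bin_size),
            class = "metagene_matrix")
}

#' @export
print.metagene_matrix <- function(x, ...) {
  cat("<metagene_matrix>\n")
  cat(sprintf("  %d genes x %d bins (%d flank + %d body + %d flank)\n",
              nrow(x$matrix), ncol(x$matrix), x$n_flank_bins, x$body_bins,
              x$n_flank_bins))
  invisible(x)
}

#' Clip a matrix at an upper quantile and min-max scale to the unit range
#'
#' The colour-map normalisation used for density heatmaps: values are
#' clipped at the `q`-th quantile of the nonzero entries (an order
#' statistic, so the operation is idempotent) and then min-max scaled so the
#' clip value maps to 1. A constant matrix maps to all zeros.
#'
#' @param m Numeric matrix (or a `metagene_matrix`).
#' @param q Clipping quantile in (0, 1), default 0.8.
#' @return Matrix of the same shape with values in `[0, 1]`.
#' @export
quantile_scale <- function(m, q = 0.8) {
  if (inherits(m, "metagene_matrix")) m <- m$matrix
  stopifnot(q > 0, q < 1)
  nz <- m[m != 0]
  if (length(nz) == 0) return(m * 0)
  t <- stats::quantile(nz, q, type = 1, names = FALSE)
  mn <- min(m)
  if (t <= mn) return(m * 0)
  pmax(pmin((m - mn) / (t - mn), 1), 0) |>
    matrix(nrow = nrow(m), ncol = ncol(m), dimnames = dimnames(m))
}

#' Background-thresholded, scaled wiggle values
#'
#' Per-bin tag density for genome-browser display: bins are the tiled
#' windows of the segmentation threshold; a bin's (scaled) count is emitted
#' only where the raw count reaches the enrichment threshold, i.e. only
#' signal above background at the threshold's empirical FDR survives.
#'
#' @param tags Tidy tag tibble (the track's library or pooled libraries).
#' @param threshold An `enrichment_threshold` from
#'   [mc_enrichment_threshold()] (at a 5% empirical FDR for the standard
#'   browser track).
#' @param chrom_sizes Chrom-sizes tibble.
#' @param scale_factor Multiplier applied to emitted counts, e.g. median
#'   library size / this library's size for median-scaled tracks
#'   (default 1).
#' @return Tibble (`chrom`, `bin`, `value`) of nonzero bins, ready for
#'   [write_wiggle()] with `bin_size = threshold$window`.
#' @export
background_subtracted_wiggle <- function(tags, threshold, chrom_sizes,
                                         scale_factor = 1) {
  stopifnot(inherits(threshold, "enrichment_threshold"))
  counts <- count_windows(tags, chrom_sizes, window = threshold$window,
                          step = threshold$window)
  keep <- counts$count >= threshold$threshold
  tibble::tibble(chrom = counts$chrom[keep],
                 bin = counts$start[keep] / threshold$window,
                 value = counts$count[keep] * scale_factor)
}
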