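# Feature table for category assignment: TSS windows, exons, introns.
gene_features <- function(genes, tss_flank = 1000) {
  feats <- list()
  if (nrow(genes) > 0) {
    feats$tss <- tibble::tibble(
      chrom = genes$chrom,
      start = pmax(0, genes$tss - tss_flank),
      end = genes$tss + tss_flank + 1,
      category = "TSS", gene_id = genes$gene_id)
    ex <- tibble::tibble(
      chrom = rep(genes$chrom, lengths(genes$exon_starts)),
      start = unlist(genes$exon_starts),
      end = unlist(genes$exon_ends),
      category = "exon",
      gene_id = rep(genes$gene_id, lengths(genes$exon_starts)))
    feats$exon <- ex
    introns <- purrr::pmap(
      genes[, c("chrom", "gene_id", "exon_starts", "exon_ends")],
      function(chrom, gene_id, exon_starts, exon_ends) {
        k <- length(exon_starts)
        if (k < 2) return(NULL)
        s <- exon_ends[-k]
        e <- exon_starts[-1]
        keep <- e > s
        if (!any(keep)) return(NULL)
        tibble::tibble(chrom = chrom, start = s[keep], end = e[keep],
                       category = "intron", gene_id = gene_id)
      })
    feats$intron <- dplyr::bind_rows(introns)
  }
  out <- dplyr::bind_rows(feats)
  if (nrow(out) == 0) {
    out <- tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric(), category = character(),
                          gene_id = character())
  }
  out$midpoint <- (out$start + out$end) / 2
  out
}

# Overlap join intervals x features, then pick the feature whose midpoint is
# nearest the interval midpoint; ties by a fixed priority vector.
closest_feature <- function(x, features, priority) {
  n <- nrow(x)
  pick <- tibble::tibble(row = seq_len(n), category = NA_character_,
                         feature_id = NA_character_, distance = NA_real_)
  if (n == 0 || nrow(features) == 0) return(pick)
  xmid <- (x$start + x$end) / 2
  prio <- stats::setNames(seq_along(priority), priority)
  for (cn in intersect(unique(x$chrom), unique(features$chrom))) {
    xi <- which(x$chrom == cn)
    fi <- which(features$chrom == cn)
    h <- IRanges::findOverlaps(
      IRanges::IRanges(x$start[xi] + 1, x$end[xi]),
      IRanges::IRanges(features$start[fi] + 1, features$end[fi]))
    if (length(h) == 0) next
    q <- xi[S4Vectors::queryHits(h)]
    f <- fi[S4Vectors::subjectHits(h)]
    cand <- tibble::tibble(row = q, category = features$category[f],
                           feature_id = features$gene_id[f],
                           distance = abs(xmid[q] - features$midpoint[f]),
                           prio = prio[features$category[f]])
    best <- cand |>
      dplyr::arrange(.data$row, .data$distance, .data$prio) |>
      dplyr::distinct(.data$row, .keep_all = TRUE)
    pick$category[best$row] <- best$category
    pick$feature_id[best$row] <- best$feature_id
    pick$distance[best$row] <- best$distance
  }
  pick
}

#' Assign intervals (or tag positions) to genomic categories
#'
#' Each input interval is matched to one of `TSS`, `exon`, `intron`, or
#' `intergenic`. Candidates are all features the interval overlaps (the TSS
#' window being the TSS +/- `tss_flank`); when several match, the feature
#' whose midpoint lies closest to the interval midpoint wins, with ties
#' broken by the fixed priority TSS > exon > intron. Intervals overlapping
#' nothing are intergenic.
#'
#' @param x Interval tibble (`chrom`, `start`, `end`); tags can be passed as
#'   1-bp intervals (see [category_composition()]).
#' @param genes Gene-model tibble.
#' @param tss_flank Half-width of the TSS window in bp (default 1000).
#' @return `x` with columns `category`, `gene_id` (NA when intergenic) and
#'   `distance` (midpoint distance to the assigned feature; NA when
#'   intergenic).
#' @export
assign_category <- function(x, genes, tss_flank = 1000) {
  stopifnot(tss_flank >= 0)
  feats <- gene_features(genes, tss_flank = tss_flank)
  pick <- closest_feature(x, feats, priority = c("TSS", "exon", "intron"))
  out <- tibble::as_tibble(x)
  out$category <- ifelse(is.na(pick$category), "intergenic", pick$category)
  out$gene_id <- pick$feature_id
  out$distance <- pick$distance
  out
}

#' Coarse intragenic/intergenic classification
#'
#' Two-way split: an interval overlapping any transcribed region is
#' intragenic, otherwise intergenic.
#'
#' @inheritParams assign_category
#' @return `x` with a logical `intragenic` column.
#' @export
classify_genic <- function(x, genes) {
  out <- tibble::as_tibble(x)
  out$intragenic <- count_overlapping_any(x, genes) > 0
  out
}

count_overlapping_any <- function(x, features) {
  n <- numeric(nrow(x))
  for (cn in intersect(unique(x$chrom), unique(features$chrom))) {
    xi <- which(x$chrom == cn)
    fi <- which(features$chrom == cn)
    n[xi] <- IRanges::countOverlaps(
      IRanges::IRanges(x$start[xi] + 1, x$end[xi]),
      IRanges::IRanges(features$start[fi] + 1, features$end[fi]))
  }
  n
}

#' Genomic-category composition of a tag library
#'
#' Assigns every tag (as a 1-bp interval at its 5' position) to a category
#' and tabulates counts and fractions — the numeric data behind a
#' category pie chart. Counts are conserved: they sum to the library size.
#'
#' @param tags Tidy tag tibble.
#' @param genes Gene-model tibble.
#' @param tss_flank TSS window half-width (default 1000).
#' @return Tibble of `category`, `n`, `fraction` per library.
#' @export
category_composition <- function(tags, genes, tss_flank = 1000) {
  pts <- tibble::tibble(chrom = tags$chrom, start = tags$pos,
                        end = tags$pos + 1)
  asg <- assign_category(pts, genes, tss_flank = tss_flank)
  tags |>
    dplyr::mutate(category = asg$category) |>
    dplyr::count(.data$library_id, .data$tissue, .data$condition, .data$mark,
                 .data$replicate, .data$category, name = "n") |>
    dplyr::group_by(.data$library_id) |>
    dplyr::mutate(fraction = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
}

#' Repeat-class tag densities in counts per million
#'
#' Tags overlapping a repeat element are assigned exclusively to one repeat
#' class (the element with the closest midpoint when several overlap), and
#' per-class densities are expressed as counts per million. The default
#' denominator is the library's repeat-overlapping tag total, so per-library
#' CPM sums to 1e6 across classes; `denominator = "library"` divides by the
#' full library size instead.
#'
#' @param tags Tidy tag tibble (one or more libraries).
#' @param repeats Repeat-annotation tibble (`chrom`, `start`, `end`,
#'   `class`).
#' @param denominator `"repeat"` (default) or `"library"`.
#' @return Tibble with one row per library x repeat class: metadata,
#'   `count`, `cpm` (all classes present, zero-filled).
#' @export
repeat_cpm <- function(tags, repeats, denominator = c("repeat", "library")) {
  denominator <- match.arg(denominator)
  pts <- tibble::tibble(chrom = tags$chrom, start = tags$pos,
                        end = tags$pos + 1)
  feats <- repeats |>
    dplyr::mutate(category = .data$class, gene_id = NA_character_,
                  midpoint = (.data$start + .data$end) / 2)
  pick <- closest_feature(pts, feats, priority = REPEAT_CLASSES)
  d <- tags |>
    dplyr::mutate(class = pick$category) |>
    dplyr::filter(!is.na(.data$class))
  if (nrow(d) == 0) stop("no tag overlaps any repeat element")
  libs <- library_sizes(tags)
  counts <- d |>
    dplyr::count(.data$library_id, .data$class, name = "count")
  out <- tidyr::expand_grid(library_id = libs$library_id,
                            class = REPEAT_CLASSES) |>
    dplyr::left_join(counts, by = c("library_id", "class")) |>
    dplyr::mutate(count = dplyr::coalesce(.data$count, 0L)) |>
    dplyr::left_join(libs, by = "library_id") |>
    dplyr::group_by(.data$library_id) |>
    dplyr::mutate(denom = if (denominator == "repeat") sum(.data$count) else
      .data$n_tags[1]) |>
    dplyr::ungroup()
  if (any(out$denom == 0)) {
    stop("library with zero repeat-overlapping tags: ",
         out$library_id[out$denom == 0][1])
  }
  out |>
    dplyr::mutate(cpm = 1e6 * .data$count / .data$denom) |>
    dplyr::select("library_id", "tissue", "condition", "mark", "replicate",
                  "class", "count", "cpm")
}

#' Compare per-library repeat densities between two tissues
#'
#' Two-sided Welch t-test per repeat class (and mark, when several marks are
#' present) on per-library CPM values; p < 0.05 is flagged significant.
#'
#' @param cpm A [repeat_cpm()] tibble covering both tissues.
#' @param tissues Length-2 character vector naming the tissues compared
#'   (default: the two present).
#' @return Tibble per mark x class: group means, `statistic`, `p`,
#'   `significant`.
#' @export
compare_tissue_density <- function(cpm, tissues = NULL) {
  if (is.null(tissues)) tissues <- sort(unique(cpm$tissue))
  stopifnot(length(tissues) == 2)
  cpm |>
    dplyr::filter(.data$tissue %in% tissues) |>
    dplyr::group_by(.data$mark, .data$class) |>
    dplyr::group_modify(function(d, key) {
      a <- d$cpm[d$tissue == tissues[1]]
      b <- d$cpm[d$tissue == tissues[2]]
      stopifnot(length(a) >= 2, length(b) >= 2)
      if (stats::var(a) == 0 && stats::var(b) == 0) {
        same <- isTRUE(all.equal(mean(a), mean(b)))
        return(tibble::tibble(mean_a = mean(a), mean_b = mean(b),
                              statistic = if (same) 0 else Inf,
                              p = if (same) 1 else 0))
      }
      tt <- stats::t.test(a, b)
      tibble::tibble(mean_a = mean(a), mean_b = mean(b),
                     statistic = unname(tt$statistic), p = tt$p.value)
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(significant = .data$p < 0.05)
}

#' Map top differential regions to genes near a TSS
#'
#' Ranks regions by q (ties by |log2fc| descending, then coordinate), keeps
#' the `top_k` best, drops regions with no TSS within `max_distance` bp, and
#' assigns each remaining region to its nearest TSS. The gene list is
#' non-redundant: a gene hit by several regions keeps only its best-ranked
#' one. The signed distance is measured from the region edge to the TSS on
#' the gene's strand — negative upstream of the TSS, zero when the TSS lies
#' inside the region.
#'
#' @param regions Differential-region tibble with `q` and `log2fc`.
#' @param genes Gene-model tibble.
#' @param max_distance Maximum |distance| to a TSS in bp (default 50000).
#' @param top_k Regions kept after ranking (default 2000).
#' @return Tibble of `gene_id`, region coordinates, `distance`, `rank`,
#'   plus the region's `q`, `log2fc`, `direction`.
#' @export
regions_to_genes <- function(regions, genes, max_distance = 50000,
                             top_k = 2000) {
  if (nrow(regions) == 0 || nrow(genes) == 0) {
    return(tibble::tibble(gene_id = character(), chrom = character(),
                          start = numeric(), end = numeric(),
                          distance = numeric(), rank = integer(),
                          q = numeric(), log2fc = numeric(),
                          direction = character()))
  }
  ranked <- regions |>
    dplyr::arrange(.data$q, dplyr::desc(abs(.data$log2fc)), .data$chrom,
                   .data$start) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::slice_head(n = top_k)
  hits <- list()
  for (cn in intersect(unique(ranked$chrom), unique(genes$chrom))) {
    ri <- which(ranked$chrom == cn)
    gi <- which(genes$chrom == cn)
    h <- IRanges::findOverlaps(
      IRanges::IRanges(pmax(0, ranked$start[ri] - max_distance) + 1,
                       ranked$end[ri] + max_distance),
      IRanges::IRanges(genes$tss[gi] + 1, width = 1))
    if (length(h) == 0) next
    r <- ri[S4Vectors::queryHits(h)]
    g <- gi[S4Vectors::subjectHits(h)]
    d <- tss_signed_distance(ranked$start[r], ranked$end[r],
                             genes$tss[g], genes$strand[g])
    keep <- abs(d) <= max_distance
    hits[[cn]] <- tibble::tibble(row = r[keep], gene = g[keep],
                                 distance = d[keep])
  }
  hits <- if (length(hits)) dplyr::bind_rows(hits) else
    tibble::tibble(row = integer(), gene = integer(), distance = numeric())
  if (nrow(hits) == 0) {
    return(regions_to_genes(regions[0, ], genes))
  }
  hits |>
    dplyr::arrange(.data$row, abs(.data$distance)) |>
    dplyr::distinct(.data$row, .keep_all = TRUE) |>          # nearest TSS per region
    dplyr::mutate(gene_id = genes$gene_id[.data$gene],
                  chrom = ranked$chrom[.data$row],
                  start = ranked$start[.data$row],
                  end = ranked$end[.data$row],
                  rank = ranked$rank[.data$row],
                  q = ranked$q[.data$row],
                  log2fc = ranked$log2fc[.data$row],
                  direction = ranked$direction[.data$row]) |>
    dplyr::arrange(.data$rank) |>
    dplyr::distinct(.data$gene_id, .keep_all = TRUE) |>      # non-redundant genes
    dplyr::select("gene_id", "chrom", "start", "end", "distance", "rank",
                  "q", "log2fc", "direction")
}

# Signed region-edge to TSS distance on the gene strand: 0 when the TSS is
# inside [start, end); negative when the region sits upstream of the TSS.
tss_signed_distance <- function(start, end, tss, strand) {
  inside <- tss >= start & tss < end
  left <- end <= tss    # region entirely left of the TSS (genome coords)
  gap_left <- tss - end    # region ... TSS
  gap_right <- start - tss # TSS ... region
  d <- ifelse(left, gap_left, gap_right)
  sign <- ifelse(strand == "-", -1, 1) * ifelse(left, -1, 1)
  # on '+': left-of-TSS is upstream (negative); on '-': left is downstream
  out <- sign * d
  out[inside] <- 0
  out
}
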