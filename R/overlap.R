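#' Pair regions of one set with a second set within a distance window
#'
#' A region of `set_a` is "paired" when at least one region of `set_b` lies
#' on the same chromosome with an inter-interval gap of at most `window` bp
#' (overlapping regions have gap 0). Each A region counts once however many
#' partners it has; its nearest partner is reported.
#'
#' @param set_a,set_b Interval tibbles (`chrom`, `start`, `end`).
#' @param window Maximum gap in bp (default 25000).
#' @return `set_a` with added columns `paired` (logical), `partner_start`,
#'   `partner_end`, `gap` (NA when unpaired). `sum(out$paired)` is the
#'   paired count.
#' @export
pair_within_window <- function(set_a, set_b, window = 25000) {
  stopifnot(window >= 0)
  out <- tibble::as_tibble(set_a)
  out$paired <- FALSE
  out$partner_start <- NA_real_
  out$partner_end <- NA_real_
  out$gap <- NA_real_
  if (nrow(set_a) == 0 || nrow(set_b) == 0) return(out)
  for (cn in intersect(unique(set_a$chrom), unique(set_b$chrom))) {
    ai <- which(out$chrom == cn)
    bi <- which(set_b$chrom == cn)
    ra <- IRanges::IRanges(out$start[ai] + 1, out$end[ai])
    rb <- IRanges::IRanges(set_b$start[bi] + 1, set_b$end[bi])
    h <- IRanges::distanceToNearest(ra, rb)
    qi <- S4Vectors::queryHits(h)
    d <- S4Vectors::mcols(h)$distance
    keep <- d <= window
    rows <- ai[qi[keep]]
    out$paired[rows] <- TRUE
    out$gap[rows] <- d[keep]
    part <- bi[S4Vectors::subjectHits(h)[keep]]
    out$partner_start[rows] <- set_b$start[part]
    out$partner_end[rows] <- set_b$end[part]
  }
  out
}

#' Significance of directional spatial overlap between two region sets
#'
#' Asks whether significant regions of mark A lie near significant regions
#' of mark B more often than chance, conditioning on the universe of all
#' tested regions of mark A. Under the hypergeometric null, each universe
#' region is labelled paired/unpaired with respect to `set_b`'s positions
#' (gap <= `window`), and the upper-tail probability of observing at least
#' the attained number of paired regions among `|set_a|` draws is reported.
#' The permutation null instead permutes which universe regions carry the
#' "significant" label, preserving set sizes.
#'
#' @param set_a Significant regions of mark A (subset of `universe_a` by
#'   coordinates).
#' @param set_b Significant regions of mark B (positions held fixed).
#' @param universe_a All tested regions of mark A.
#' @param window Maximum gap in bp (default 25000).
#' @param method `"hypergeom"` (default) or `"permutation"`.
#' @param permutations Number of label permutations (default 10000).
#' @param seed Seed for the permutation null.
#' @return One-row tibble of class `overlap_table`: `n_a`, `n_b`,
#'   `n_paired`, `n_universe`, `n_universe_paired`, `window`, `method`, `p`.
#' @export
overlap_significance <- function(set_a, set_b, universe_a, window = 25000,
                                 method = c("hypergeom", "permutation"),
                                 permutations = 10000, seed = 1) {
  method <- match.arg(method)
  key <- function(x) paste(x$chrom, x$start, x$end)
  if (!all(key(set_a) %in% key(universe_a))) {
    stop("set_a contains regions absent from universe_a")
  }
  uni <- pair_within_window(universe_a, set_b, window = window)
  in_set <- key(uni) %in% key(set_a)
  n_a <- sum(in_set)
  k_obs <- sum(uni$paired & in_set)
  K <- sum(uni$paired)
  n_u <- nrow(uni)
  if (method == "hypergeom") {
    p <- stats::phyper(k_obs - 1, K, n_u - K, n_a, lower.tail = FALSE)
  } else {
    p <- withr::with_seed(seed, {
      exceed <- 0L
      for (b in seq_len(permutations)) {
        kb <- sum(sample(uni$paired, n_a))
        if (kb >= k_obs) exceed <- exceed + 1L
      }
      (1 + exceed) / (1 + permutations)
    })
  }
  structure(tibble::tibble(n_a = n_a, n_b = nrow(set_b), n_paired = k_obs,
                           n_universe = n_u, n_universe_paired = K,
                           window = window, method = method, p = p),
            class = c("overlap_table", "tbl_df", "tbl", "data.frame"))
}

#' Directional overlap summary over all four direction pairs
#'
#' Computes the spatial-overlap significance for each combination of 5mC
#' direction x 5hmC direction (up/up, up/down, down/up, down/down) between
#' two differential call sets, ranks the pairs by p value, and flags the
#' most significant pair(s) — the tabular counterpart of a highlighted
#' Venn-diagram panel.
#'
#' @param calls_a Differential calls for mark A (5mC), with `direction`.
#' @param calls_b Differential calls for mark B (5hmC).
#' @param universe_a All tested regions of mark A ([test_differential()]
#'   output).
#' @param window Maximum gap in bp (default 25000).
#' @inheritParams overlap_significance
#' @return Tibble with one row per direction pair: `direction_a`,
#'   `direction_b`, counts, `p`, `rank` (min-rank by p), and `top`.
#' @export
venn_summary <- function(calls_a, calls_b, universe_a, window = 25000,
                         method = c("hypergeom", "permutation"),
                         permutations = 10000, seed = 1) {
  method <- match.arg(method)
  grid <- tidyr::expand_grid(direction_a = c("up", "down"),
                             direction_b = c("up", "down"))
  out <- purrr::pmap(grid, function(direction_a, direction_b) {
    sa <- calls_a[calls_a$direction == direction_a, , drop = FALSE]
    sb <- calls_b[calls_b$direction == direction_b, , drop = FALSE]
    if (nrow(sa) == 0 || nrow(sb) == 0) {
      tab <- tibble::tibble(n_a = nrow(sa), n_b = nrow(sb), n_paired = 0L,
                            n_universe = nrow(universe_a),
                            n_universe_paired = NA_integer_,
                            window = window, method = method, p = 1)
    } else {
      tab <- overlap_significance(sa, sb, universe_a, window = window,
                                  method = method,
                                  permutations = permutations, seed = seed)
    }
    dplyr::mutate(tibble::as_tibble(tab), direction_a = direction_a,
                  direction_b = direction_b, .before = 1)
  }) |> dplyr::bind_rows()
  out$rank <- rank(out$p, ties.method = "min")
  out$top <- out$rank == 1
  out
}
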