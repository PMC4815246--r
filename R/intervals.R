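#' Construct a tibble of genomic intervals
#'
#' Intervals are the coordinate currency of the package: 0-based, half-open
#' `[start, end)` spans on named chromosomes, following the BED convention.
#' All other modules accept and return interval tibbles with at least the
#' columns `chrom`, `start`, `end`.
#'
#' @param chrom Character vector of chromosome names (opaque strings; no
#'   "chr" normalisation is performed).
#' @param start,end Integer-valued vectors; `0 <= start < end` required.
#' @param strand Optional strand, one of `"+"`, `"-"`, `"."` (unstranded).
#' @param ... Further columns (e.g. `name`, `score`) recycled tidyverse-style.
#'
#' @return A tibble with columns `chrom`, `start`, `end`, `strand`, plus any
#'   extras, one row per interval.
#' @examples
#' genomic_intervals("chr1", 0, 1000)
#' @export
genomic_intervals <- function(chrom, start, end, strand = ".", ...) {
  out <- tibble::tibble(
    chrom = as.character(chrom),
    start = as.numeric(start),
    end = as.numeric(end),
    strand = strand,
    ...
  )
  validate_intervals(out)
  out
}

#' Validate an interval tibble
#'
#' Checks the structural invariants every interval table must satisfy:
#' non-empty chromosome names, `0 <= start < end`, and (when `chrom_sizes`
#' is supplied) containment within chromosome bounds.
#'
#' @param x A data frame with columns `chrom`, `start`, `end`.
#' @param chrom_sizes Optional chromosome-size tibble (see [read_chrom_sizes()]).
#' @return `x`, invisibly. Errors describe the first violated invariant.
#' @export
validate_intervals <- function(x, chrom_sizes = NULL) {
  stopifnot(is.data.frame(x))
  missing_cols <- setdiff(c("chrom", "start", "end"), names(x))
  if (length(missing_cols) > 0) {
    stop("interval table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(x) == 0) return(invisible(x))
  if (any(is.na(x$chrom)) || any(!nzchar(x$chrom))) {
    stop("interval table has empty chromosome names")
  }
  if (any(x$start < 0)) stop("negative start coordinate")
  bad <- which(x$start >= x$end)
  if (length(bad) > 0) {
    stop("empty or inverted interval at row ", bad[1],
         " (start ", x$start[bad[1]], " >= end ", x$end[bad[1]], ")")
  }
  if (!is.null(chrom_sizes)) {
    len <- chrom_size_lookup(chrom_sizes)
    unknown <- setdiff(unique(x$chrom), names(len))
    if (length(unknown) > 0) {
      stop("chromosome(s) absent from chrom sizes: ", paste(unknown, collapse = ", "))
    }
    over <- which(x$end > len[x$chrom])
    if (length(over) > 0) {
      stop("interval beyond chromosome end at row ", over[1])
    }
  }
  invisible(x)
}

# named vector chrom -> length
chrom_size_lookup <- function(chrom_sizes) {
  stats::setNames(chrom_sizes$length, chrom_sizes$chrom)
}

#' Gap between two genomic intervals
#'
#' Distance in bp separating two half-open intervals. Overlapping or abutting
#' intervals have gap 0; intervals on different chromosomes have gap `Inf`.
#' Vectorised over both arguments; the operation is symmetric.
#'
#' @param chrom_a,start_a,end_a First interval (vectors recycled).
#' @param chrom_b,start_b,end_b Second interval.
#' @return Numeric vector of gaps (bp), `Inf` for different chromosomes.
#' @examples
#' interval_gap("chr1", 0, 100, "chr1", 25100, 25200) # 25000
#' @export
interval_gap <- function(chrom_a, start_a, end_a, chrom_b, start_b, end_b) {
  gap <- pmax(start_a, start_b) - pmin(end_a, end_b)
  gap <- pmax(gap, 0)
  gap[as.character(chrom_a) != as.character(chrom_b)] <- Inf
  gap
}

# Interval union (merge overlapping/abutting) per chromosome; input a tibble
# with chrom/start/end, output sorted disjoint intervals.
union_intervals <- function(x) {
  if (nrow(x) == 0) {
    return(tibble::tibble(chrom = character(), start = numeric(), end = numeric()))
  }
  x |>
    dplyr::group_by(.data$chrom) |>
    dplyr::group_modify(function(d, key) {
      r <- IRanges::reduce(IRanges::IRanges(start = d$start + 1, end = d$end),
                           min.gapwidth = 1L)
      tibble::tibble(start = as.numeric(IRanges::start(r)) - 1,
                     end = as.numeric(IRanges::end(r)))
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$chrom, .data$start)
}

# IRanges view of an interval tibble (1-based closed, as IRanges expects).
as_iranges0 <- function(x) {
  IRanges::IRanges(start = x$start + 1, end = x$end)
}

# Count how many points (chrom,pos) fall in each interval row of `regions`.
# Tags are single positions (the 5' end of the mapped read).
count_points_in_regions <- function(regions, chrom, pos) {
  n <- nrow(regions)
  counts <- numeric(n)
  idx <- split(seq_len(n), regions$chrom)
  tag_split <- split(pos, chrom)
  for (cn in names(idx)) {
    p <- tag_split[[cn]]
    if (is.null(p) || length(p) == 0) next
    i <- idx[[cn]]
    hits <- IRanges::countOverlaps(
      IRanges::IRanges(start = regions$start[i] + 1, end = regions$end[i]),
      IRanges::IRanges(start = p + 1, width = 1L)
    )
    counts[i] <- hits
  }
  counts
}
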