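#' Merge condition-level enriched domains into candidate regions
#'
#' The differential test operates on the interval union of the enriched
#' domains called in each condition, so that a region enriched in either
#' condition is interrogated once. Overlapping or abutting domains collapse
#' into a single candidate region; output is sorted.
#'
#' @param ... Domain tibbles (`chrom`, `start`, `end`), one per condition,
#'   or a single list of them.
#' @return Sorted tibble of disjoint candidate regions with a `region_id`.
#' @export
merge_condition_domains <- function(...) {
  dots <- list(...)
  if (length(dots) == 1 && is.list(dots[[1]]) && !is.data.frame(dots[[1]])) {
    dots <- dots[[1]]
  }
  stopifnot(length(dots) >= 1)
  merged <- union_intervals(dplyr::bind_rows(lapply(dots, function(d) {
    d[, c("chrom", "start", "end")]
  })))
  if (nrow(merged) > 0) {
    merged$region_id <- sprintf("region%05d", seq_len(nrow(merged)))
  } else {
    merged$region_id <- character(0)
  }
  merged
}

#' Count tags per candidate region and library
#'
#' @param regions Candidate-region tibble from [merge_condition_domains()].
#' @param tags Tidy tag tibble covering all libraries of one mark/tissue.
#' @return Long tibble of class `region_counts`: one row per region x
#'   library with the library metadata, `count`, and the library size
#'   `n_tags`.
#' @export
region_counts <- function(regions, tags) {
  libs <- library_sizes(tags)
  out <- purrr::map(seq_len(nrow(libs)), function(i) {
    lt <- tags[tags$library_id == libs$library_id[i], ]
    dplyr::mutate(regions,
                  library_id = libs$library_id[i], tissue = libs$tissue[i],
                  condition = libs$condition[i], mark = libs$mark[i],
                  replicate = libs$replicate[i], n_tags = libs$n_tags[i],
                  count = count_points_in_regions(regions, lt$chrom, lt$pos))
  }) |> dplyr::bind_rows()
  class(out) <- c("region_counts", class(out))
  out
}

#' Pearson chi-square test on tag counts from two pooled conditions
#'
#' Tests each region's 2x2 table `[[count_a, lib_a - count_a], [count_b,
#' lib_b - count_b]]` with the 1-df Pearson statistic, no continuity
#' correction, two-sided p. Vectorised over regions.
#'
#' @param count_a,count_b Region tag counts in conditions A and B.
#' @param lib_a,lib_b Total (pooled) library sizes.
#' @return Tibble with `statistic`, `p`, and `low_count` (TRUE when any
#'   expected cell is below 1; the p value is still returned). Regions with
#'   both counts zero get statistic 0 and p 1.
#' @export
chisq_region_test <- function(count_a, count_b, lib_a, lib_b) {
  stopifnot(all(lib_a > 0), all(lib_b > 0),
            all(count_a >= 0), all(count_b >= 0),
            all(count_a <= lib_a), all(count_b <= lib_b))
  n <- lib_a + lib_b
  c1 <- count_a + count_b          # "in region" column margin
  c2 <- n - c1
  e11 <- lib_a * c1 / n
  e12 <- lib_a * c2 / n
  e21 <- lib_b * c1 / n
  e22 <- lib_b * c2 / n
  stat <- (count_a - e11)^2 / e11 + ((lib_a - count_a) - e12)^2 / e12 +
    (count_b - e21)^2 / e21 + ((lib_b - count_b) - e22)^2 / e22
  zero <- c1 == 0
  stat[zero] <- 0
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  p[zero] <- 1
  tibble::tibble(statistic = stat, p = p,
                 low_count = pmin(e11, e12, e21, e22) < 1)
}

#' Method-of-moments common negative-binomial dispersion
#'
#' Pools a single dispersion across regions: counts are scaled to the median
#' library size, per-region-per-condition means and variances are computed
#' across replicates, and the moment identity `var = mu + phi * mu^2` is
#' solved in pooled form `phi = sum(var - mu) / sum(mu^2)`. Since with `k`
#' replicates `E[m^2] = mu^2 + var/k`, the denominator uses the unbiased
#' `m^2 - v/k` in place of `m^2`.
#'
#' @param counts A [region_counts()] tibble.
#' @return Estimated dispersion (may be negative when data are
#'   under-dispersed; [negbin_region_test()] then falls back to Poisson).
#' @export
estimate_common_dispersion <- function(counts) {
  med_n <- stats::median(library_sizes_of(counts)$n_tags)
  d <- counts |>
    dplyr::mutate(norm = .data$count * med_n / .data$n_tags) |>
    dplyr::group_by(.data$region_id, .data$condition) |>
    dplyr::summarise(m = mean(.data$norm), v = stats::var(.data$norm),
                     k = dplyr::n(), .groups = "drop") |>
    dplyr::filter(.data$k >= 2, .data$m > 0)
  if (nrow(d) == 0) return(0)
  denom <- sum(d$m^2 - d$v / d$k)
  if (denom <= 0) return(0)
  sum(d$v - d$m) / denom
}

library_sizes_of <- function(counts) {
  dplyr::distinct(tibble::as_tibble(counts)[, c("library_id", "n_tags")])
}

#' Negative-binomial likelihood-ratio test for one region
#'
#' Fits an NB GLM (log link, offset = log library size, fixed common
#' dispersion) with and without a condition effect and compares deviances on
#' 1 df. With dispersion at (or below) zero the fit reduces to a Poisson
#' GLM likelihood-ratio test.
#'
#' @param count Tag counts across the region's libraries.
#' @param condition Factor/character of condition labels (two levels).
#' @param lib_size Library sizes aligned with `count`.
#' @param dispersion Common NB dispersion (see
#'   [estimate_common_dispersion()]).
#' @return Tibble with `statistic` and `p`. All-zero regions get p 1.
#' @export
negbin_region_test <- function(count, condition, lib_size, dispersion) {
  if (all(count == 0)) return(tibble::tibble(statistic = 0, p = 1))
  fam <- if (dispersion > 0) {
    MASS::negative.binomial(theta = 1 / dispersion)
  } else {
    stats::poisson()
  }
  cond <- factor(condition)
  off <- log(lib_size)
  fit1 <- suppressWarnings(stats::glm(count ~ cond + offset(off), family = fam))
  fit0 <- suppressWarnings(stats::glm(count ~ 1 + offset(off), family = fam))
  stat <- max(0, fit0$deviance - fit1$deviance)
  tibble::tibble(statistic = stat,
                 p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p values (q values); thin wrapper kept as the package's
#' single FDR entry point.
#'
#' @param p Numeric vector of p values in `[0, 1]`.
#' @return Vector of q values, same length and order as `p`.
#' @export
adjust_fdr <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  stats::p.adjust(p, method = "BH")
}

#' Test candidate regions for differential methylation
#'
#' Runs the chosen per-region test (chi-square on condition-pooled counts,
#' or a negative-binomial likelihood-ratio test using replicates) across a
#' region-count table, then adjusts p values with Benjamini-Hochberg across
#' all tested regions. Fold changes are computed on counts scaled to the
#' median library size, with a pseudocount added to each condition sum;
#' direction is "up" when the non-reference (irradiated) condition is
#' higher.
#'
#' @param counts A [region_counts()] tibble (one mark x tissue; BH
#'   adjustment spans exactly the regions given here).
#' @param test `"chisq"` (default) or `"negbin"`.
#' @param reference Condition treated as baseline (default the
#'   lexicographically later-discovered `"sham"` if present, else the first
#'   condition level encountered).
#' @param pseudocount Added to each condition's scaled count sum before the
#'   log2 ratio (default 0.5).
#' @param dispersion Optional fixed NB dispersion; estimated from the data
#'   when `NULL`.
#' @return Tibble with one row per region: coordinates, per-condition raw
#'   and scaled count sums, `log2fc`, `direction`, `statistic`, `p`, `q`,
#'   `test`, and `low_count`.
#' @export
test_differential <- function(counts, test = c("chisq", "negbin"),
                              reference = NULL, pseudocount = 0.5,
                              dispersion = NULL) {
  test <- match.arg(test)
  counts <- tibble::as_tibble(counts)
  conds <- unique(counts$condition)
  stopifnot(length(conds) == 2)
  if (is.null(reference)) {
    reference <- if ("sham" %in% conds) "sham" else conds[1]
  }
  alt <- setdiff(conds, reference)
  med_n <- stats::median(library_sizes_of(counts)$n_tags)

  per_cond <- counts |>
    dplyr::group_by(.data$region_id, .data$chrom, .data$start, .data$end,
                    .data$condition) |>
    dplyr::summarise(count = sum(.data$count), lib = sum(.data$n_tags),
                     scaled = sum(.data$count * med_n / .data$n_tags),
                     .groups = "drop")
  wide <- per_cond |>
    tidyr::pivot_wider(names_from = "condition",
                       values_from = c("count", "lib", "scaled"))
  ca <- wide[[paste0("count_", reference)]]
  cb <- wide[[paste0("count_", alt)]]
  la <- wide[[paste0("lib_", reference)]]
  lb <- wide[[paste0("lib_", alt)]]
  sa <- wide[[paste0("scaled_", reference)]]
  sb <- wide[[paste0("scaled_", alt)]]

  if (test == "chisq") {
    res <- chisq_region_test(ca, cb, la, lb)
  } else {
    if (is.null(dispersion)) dispersion <- estimate_common_dispersion(counts)
    if (dispersion < 0) {
      warning("negative moment dispersion estimate; falling back to Poisson")
      dispersion <- 0
    }
    split_counts <- split(counts[, c("count", "condition", "n_tags")],
                          counts$region_id)
    res <- purrr::map(wide$region_id, function(rid) {
      d <- split_counts[[rid]]
      negbin_region_test(d$count, d$condition, d$n_tags, dispersion)
    }) |> dplyr::bind_rows()
    res$low_count <- FALSE
  }

  out <- tibble::tibble(
    region_id = wide$region_id, chrom = wide$chrom,
    start = wide$start, end = wide$end,
    count_ref = ca, count_alt = cb,
    scaled_ref = sa, scaled_alt = sb,
    log2fc = log2((sb + pseudocount) / (sa + pseudocount)),
    statistic = res$statistic, p = res$p,
    low_count = res$low_count
  )
  out$direction <- ifelse(out$log2fc > 0, "up", "down")
  out$q <- adjust_fdr(out$p)
  out$test <- test
  dplyr::arrange(out, .data$chrom, .data$start)
}

#' Call significant differential regions (DMRs / DHMRs)
#'
#' Filters a [test_differential()] table at an FDR threshold; q < 0.01 is
#' the package default for reporting differentially methylated (DMR) and
#' hydroxymethylated (DHMR) regions.
#'
#' @param tested Output of [test_differential()].
#' @param q_threshold FDR cutoff (default 0.01).
#' @return The significant subset, ordered by q.
#' @export
call_differential <- function(tested, q_threshold = 0.01) {
  dplyr::arrange(dplyr::filter(tested, .data$q < q_threshold), .data$q)
}

#' Write a differential call set as BED6
#'
#' Name column carries the direction; score is `-10 * log10(q)` capped at
#' 1000.
#'
#' @param calls A [call_differential()] (or tested) tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_differential_bed <- function(calls, path) {
  write_bed(tibble::tibble(
    chrom = calls$chrom, start = calls$start, end = calls$end,
    name = calls$direction,
    score = round(pmin(1000, -10 * log10(pmax(calls$q, 1e-300))), 1),
    strand = "."), path)
}
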