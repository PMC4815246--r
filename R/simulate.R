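#' Simulation configuration for synthetic DIP-Seq experiments
#'
#' Bundles every knob of the synthetic-data generator. The defaults emulate
#' the study design the package targets: two tissues x two radiation
#' conditions x two replicate libraries per mark (5mC and 5hmC), a
#' homogeneous Poisson tag background, enriched domains at elevated tag
#' density, and planted condition-specific differential regions whose
#' 5hmC/5mC placements can be spatially coupled within a 25-kb window.
#'
#' @param seed Integer seed; the generator derives per-library substreams
#'   from it, so a fixed seed reproduces every tag bit-for-bit.
#' @param n_chroms,chrom_length Genome shape: `n_chroms` chromosomes of
#'   `chrom_length` bp each (default 2 x 5 Mb = 10 Mb).
#' @param background_rate Background tag rate lambda0 in tags/bp/library
#'   (default 0.01, i.e. an expected 10 tags per 1-kb window).
#' @param n_domains Enriched domains planted per mark and tissue.
#' @param domain_length Length range (min, max) of planted domains, bp.
#' @param min_domain_gap Minimum separation enforced between planted domains
#'   of one mark, so that neighbouring domains are not merged into one call.
#' @param enrichment_fold Domain tag rate as a multiple of `background_rate`.
#' @param n_diff Number of domains per mark/tissue carrying a differential
#'   signal between conditions.
#' @param diff_fold Fold change phi: in "up" regions the irradiated-condition
#'   rate is `phi` times the sham rate; in "down" regions it is divided by
#'   `phi`.
#' @param coupling Fraction kappa in `[0, 1]` of 5hmC differential regions
#'   placed within `coupling_window` of a 5mC differential region of the
#'   paired direction.
#' @param coupling_pair Length-2 character vector `c(mC direction, hmC
#'   direction)` for coupled pairs; the default `c("down", "up")` plants the
#'   5hmC-gain/5mC-loss association.
#' @param coupling_window Maximum gap (bp) between coupled differential
#'   regions (default 25000).
#' @param replicates Replicate libraries per tissue x condition x mark.
#' @param tissues,conditions,marks Factor levels of the design; the first
#'   condition is the reference (sham).
#' @param n_genes,gene_length Gene count per genome and length range (bp)
#'   for the synthetic annotation.
#' @param n_repeats,repeat_length Repeat-element count and length range.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 2L,
                       chrom_length = 5e6,
                       background_rate = 0.01,
                       n_domains = 200L,
                       domain_length = c(1000, 3000),
                       min_domain_gap = 5000,
                       enrichment_fold = 8,
                       n_diff = 40L,
                       diff_fold = 3,
                       coupling = 0.5,
                       coupling_pair = c("down", "up"),
                       coupling_window = 25000,
                       replicates = 2L,
                       tissues = c("hippocampus", "ventricle"),
                       conditions = c("sham", "proton"),
                       marks = c("5mC", "5hmC"),
                       n_genes = 300L,
                       gene_length = c(2000, 20000),
                       n_repeats = 1500L,
                       repeat_length = c(100, 500)) {
  cfg <- as.list(environment())
  stopifnot(cfg$background_rate > 0,
            cfg$enrichment_fold > 1,
            cfg$diff_fold > 0, cfg$diff_fold != 1,
            cfg$coupling >= 0, cfg$coupling <= 1,
            length(cfg$conditions) == 2,
            length(cfg$marks) == 2,
            cfg$replicates >= 1)
  stopifnot(all(cfg$coupling_pair %in% c("up", "down")))
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  genome: %d x %s bp; background %g tags/bp\n",
              x$n_chroms, format(x$chrom_length, big.mark = ","),
              x$background_rate))
  cat(sprintf("  %d domains/mark (fold %g), %d differential (fold %g), coupling %g\n",
              x$n_domains, x$enrichment_fold, x$n_diff, x$diff_fold, x$coupling))
  cat(sprintf("  design: %s x %s x %d replicates, marks %s\n",
              paste(x$tissues, collapse = "/"), paste(x$conditions, collapse = "/"),
              x$replicates, paste(x$marks, collapse = "/")))
  invisible(x)
}

sim_chrom_sizes <- function(config) {
  tibble::tibble(chrom = paste0("chr", seq_len(config$n_chroms)),
                 length = rep(config$chrom_length, config$n_chroms))
}

#' Simulate a toy genome annotation
#'
#' Generates chromosome sizes, non-overlapping gene models with 1-10 exons
#' and a log-normal synthetic expression value per gene, and repeat elements
#' covering all seven repeat classes. Deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return List with elements `chrom_sizes`, `genes` (gene-model tibble with
#'   `expression`), and `repeats`.
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed + 104729L, {
    chrom_sizes <- sim_chrom_sizes(config)
    genes <- sim_genes(config, chrom_sizes)
    repeats <- sim_repeats(config, chrom_sizes)
    list(chrom_sizes = chrom_sizes, genes = genes, repeats = repeats)
  })
}

# Place n non-overlapping intervals with given length range, uniformly over
# the genome, keeping >= min_gap bp between any two. Rejection sampling.
place_nonoverlapping <- function(n, len_range, chrom_sizes, min_gap = 0,
                                 max_tries = 200L) {
  if (n == 0) {
    return(tibble::tibble(chrom = character(), start = numeric(), end = numeric()))
  }
  placed <- vector("list", n)
  by_chrom <- stats::setNames(
    replicate(nrow(chrom_sizes), matrix(numeric(0), ncol = 2), simplify = FALSE),
    chrom_sizes$chrom)
  total <- sum(chrom_sizes$length)
  k <- 0
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      len <- floor(stats::runif(1, len_range[1], len_range[2] + 1))
      ci <- sample.int(nrow(chrom_sizes), 1, prob = chrom_sizes$length)
      L <- chrom_sizes$length[ci]
      if (L < len) next
      s <- floor(stats::runif(1, 0, L - len + 1))
      e <- s + len
      m <- by_chrom[[ci]]
      if (nrow(m) == 0 || all(s - min_gap >= m[, 2] | e + min_gap <= m[, 1])) {
        by_chrom[[ci]] <- rbind(m, c(s, e))
        placed[[i]] <- tibble::tibble(chrom = chrom_sizes$chrom[ci], start = s, end = e)
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("could not place ", n, " features of ",
                  len_range[2], " bp: genome too short or too crowded")
  }
  dplyr::arrange(dplyr::bind_rows(placed), .data$chrom, .data$start)
}

sim_genes <- function(config, chrom_sizes) {
  g <- place_nonoverlapping(config$n_genes, config$gene_length, chrom_sizes,
                            min_gap = 100)
  if (nrow(g) == 0) {
    return(tibble::tibble(gene_id = character(), chrom = character(),
                          start = numeric(), end = numeric(), strand = character(),
                          exon_starts = list(), exon_ends = list(),
                          expression = numeric(), tss = numeric()))
  }
  g$gene_id <- sprintf("gene%04d", seq_len(nrow(g)))
  g$strand <- sample(c("+", "-"), nrow(g), replace = TRUE)
  exons <- mapply(function(s, e) {
    k <- sample.int(10, 1)
    cuts <- sort(sample(seq(s, e - 1), 2 * k))
    list(starts = cuts[seq(1, 2 * k, 2)], ends = cuts[seq(2, 2 * k, 2)] + 1)
  }, g$start, g$end, SIMPLIFY = FALSE)
  g$exon_starts <- lapply(exons, `[[`, "starts")
  g$exon_ends <- lapply(exons, `[[`, "ends")
  g$expression <- stats::rlnorm(nrow(g), meanlog = 2, sdlog = 1.5)
  g <- g[, c("gene_id", "chrom", "start", "end", "strand",
             "exon_starts", "exon_ends", "expression")]
  validate_gene_models(g)
}

sim_repeats <- function(config, chrom_sizes) {
  n <- config$n_repeats
  if (n == 0) {
    return(tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric(), class = character()))
  }
  len <- floor(stats::runif(n, config$repeat_length[1], config$repeat_length[2] + 1))
  ci <- sample.int(nrow(chrom_sizes), n, replace = TRUE, prob = chrom_sizes$length)
  s <- floor(stats::runif(n, 0, chrom_sizes$length[ci] - len + 1))
  cls <- sample(REPEAT_CLASSES, n, replace = TRUE,
                prob = c(0.3, 0.3, 0.2, 0.08, 0.04, 0.04, 0.04))
  # guarantee every class is present when n allows it
  if (n >= length(REPEAT_CLASSES)) cls[seq_along(REPEAT_CLASSES)] <- REPEAT_CLASSES
  dplyr::arrange(tibble::tibble(chrom = chrom_sizes$chrom[ci], start = s,
                                end = s + len, class = cls),
                 .data$chrom, .data$start)
}

#' Simulate DIP-Seq tag libraries with planted truth
#'
#' Draws one tag library per tissue x condition x mark x replicate from a
#' piecewise-homogeneous Poisson model: background at `background_rate`,
#' planted enriched domains at `enrichment_fold` times that rate, and, inside
#' differential domains, the irradiated condition scaled by `diff_fold` (up)
#' or its reciprocal (down). A fraction `coupling` of 5hmC differential
#' domains is placed within `coupling_window` bp of a 5mC differential
#' domain of the paired direction.
#'
#' @param config A [sim_config()].
#' @return List of class `dip_simulation` with elements:
#'   * `tags`: tidy tibble of all tags (`library_id`, `tissue`, `condition`,
#'     `mark`, `replicate`, `chrom`, `pos`, `strand`);
#'   * `truth`: list with `domains` (all planted enriched domains),
#'     `diff_regions` (the differential subset, with `direction` = change in
#'     the irradiated condition and `log2fc` = signed log2 fold), and
#'     `coupled_pairs`;
#'   * `chrom_sizes` and `config`.
#' @export
simulate_libraries <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  chrom_sizes <- sim_chrom_sizes(config)
  lam_bg <- config$background_rate
  lam_dom <- config$enrichment_fold * lam_bg
  mean_len <- mean(config$domain_length)
  if (config$n_domains > 0 && lam_dom * config$domain_length[1] < 1) {
    warning("expected tags per domain < 1; detection power will be near zero")
  }

  withr::with_seed(config$seed, {
    placements <- lapply(config$tissues, function(tis) plant_marks(config, chrom_sizes))
    names(placements) <- config$tissues
    n_libs <- length(config$tissues) * length(config$marks) *
      length(config$conditions) * config$replicates
    lib_seeds <- sample.int(2^30, n_libs)

    design <- tidyr::expand_grid(
      tissue = config$tissues, mark = config$marks,
      condition = config$conditions, replicate = seq_len(config$replicates))
    design$library_id <- sprintf("%s_%s_%s_rep%d", design$tissue, design$mark,
                                 design$condition, design$replicate)

    tags <- purrr::pmap(design, function(tissue, mark, condition, replicate,
                                         library_id) {
      i <- which(design$library_id == library_id)
      domains <- placements[[tissue]]$domains
      domains <- domains[domains$mark == mark, , drop = FALSE]
      irradiated <- condition != config$conditions[1]
      withr::with_seed(lib_seeds[i], {
        draw_library(domains, chrom_sizes, lam_bg, lam_dom,
                     diff_fold = config$diff_fold, irradiated = irradiated)
      }) |>
        dplyr::mutate(library_id = library_id, tissue = tissue,
                      condition = condition, mark = mark,
                      replicate = as.integer(replicate), .before = 1)
    }) |> dplyr::bind_rows()

    truth_domains <- purrr::imap(placements, function(p, tis) {
      dplyr::mutate(p$domains, tissue = tis, .before = 1)
    }) |> dplyr::bind_rows()
    truth <- list(
      domains = dplyr::select(truth_domains, "tissue", "mark", "chrom",
                              "start", "end"),
      diff_regions = truth_domains |>
        dplyr::filter(!is.na(.data$direction)) |>
        dplyr::mutate(log2fc = ifelse(.data$direction == "up", 1, -1) *
                        log2(config$diff_fold)) |>
        dplyr::select("tissue", "mark", "chrom", "start", "end",
                      "direction", "log2fc"),
      coupled_pairs = purrr::imap(placements, function(p, tis) {
        if (nrow(p$coupled) == 0) return(p$coupled)
        dplyr::mutate(p$coupled, tissue = tis, .before = 1)
      }) |> dplyr::bind_rows()
    )
    structure(list(tags = tags, truth = truth, chrom_sizes = chrom_sizes,
                   config = config),
              class = "dip_simulation")
  })
}

#' @export
print.dip_simulation <- function(x, ...) {
  cat("<dip_simulation>\n")
  cat(sprintf("  %d libraries, %s tags total\n",
              dplyr::n_distinct(x$tags$library_id),
              format(nrow(x$tags), big.mark = ",")))
  cat(sprintf("  truth: %d domains, %d differential regions, %d coupled pairs\n",
              nrow(x$truth$domains), nrow(x$truth$diff_regions),
              nrow(x$truth$coupled_pairs)))
  invisible(x)
}

# Plant domains and differential regions for both marks in one tissue.
# The first mark (5mC) is placed freely; coupled 5hmC differential domains
# are rejection-sampled to land within coupling_window of a 5mC partner of
# the paired direction.
plant_marks <- function(config, chrom_sizes) {
  mc_mark <- config$marks[1]
  hmc_mark <- config$marks[2]
  mc <- plant_one_mark(config, chrom_sizes)
  mc$mark <- mc_mark

  n_coupled <- round(config$coupling * min(config$n_diff, config$n_domains))
  partner_pool <- mc[!is.na(mc$direction) &
                       mc$direction == config$coupling_pair[1], , drop = FALSE]
  if (n_coupled > 0 && nrow(partner_pool) == 0) {
    stop("coupling requested but no 5mC differential region has direction '",
         config$coupling_pair[1], "'")
  }

  hmc_free <- plant_one_mark(config, chrom_sizes,
                             n_diff = config$n_diff - n_coupled,
                             n_domains = config$n_domains - n_coupled)
  coupled <- place_coupled(config, chrom_sizes, partner_pool, hmc_free,
                           n_coupled)
  hmc <- dplyr::bind_rows(hmc_free, coupled$domains)
  hmc$mark <- hmc_mark

  list(domains = dplyr::bind_rows(mc, hmc),
       coupled = coupled$pairs)
}

# One mark's domains with n_diff of them differential (balanced up/down).
plant_one_mark <- function(config, chrom_sizes, n_diff = config$n_diff,
                           n_domains = config$n_domains) {
  d <- place_nonoverlapping(n_domains, config$domain_length,
                            chrom_sizes, min_gap = config$min_domain_gap)
  d$direction <- NA_character_
  n_diff <- min(n_diff, nrow(d))
  if (n_diff > 0) {
    pick <- sample.int(nrow(d), n_diff)
    dirs <- rep(c("up", "down"), length.out = n_diff)
    d$direction[pick] <- sample(dirs)
  }
  d
}

place_coupled <- function(config, chrom_sizes, partner_pool, existing,
                          n_coupled, max_tries = 500L) {
  empty <- tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric(), direction = character())
  pairs <- tibble::tibble(chrom = character(),
                          mc_start = numeric(), mc_end = numeric(),
                          hmc_start = numeric(), hmc_end = numeric(),
                          gap = numeric())
  if (n_coupled == 0) return(list(domains = empty, pairs = pairs))
  occupied <- existing
  out <- vector("list", n_coupled)
  partners <- partner_pool[sample.int(nrow(partner_pool), n_coupled,
                                      replace = n_coupled > nrow(partner_pool)), ]
  len_chrom <- chrom_size_lookup(chrom_sizes)
  for (i in seq_len(n_coupled)) {
    p <- partners[i, ]
    L <- len_chrom[[p$chrom]]
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      len <- floor(stats::runif(1, config$domain_length[1],
                                config$domain_length[2] + 1))
      lo <- max(0, p$start - config$coupling_window - len)
      hi <- min(L - len, p$end + config$coupling_window)
      if (hi < lo) break
      s <- floor(stats::runif(1, lo, hi + 1))
      e <- s + len
      gap <- interval_gap(p$chrom, s, e, p$chrom, p$start, p$end)
      if (gap > config$coupling_window) next
      same <- occupied[occupied$chrom == p$chrom, , drop = FALSE]
      if (nrow(same) == 0 ||
          all(s - config$min_domain_gap >= same$end |
                e + config$min_domain_gap <= same$start)) {
        cand <- tibble::tibble(chrom = p$chrom, start = s, end = e,
                               direction = config$coupling_pair[2])
        out[[i]] <- cand
        occupied <- dplyr::bind_rows(occupied, cand[, c("chrom", "start", "end")])
        pairs <- dplyr::add_row(pairs, chrom = p$chrom,
                                mc_start = p$start, mc_end = p$end,
                                hmc_start = s, hmc_end = e, gap = gap)
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("failed to place a coupled differential region near ",
                  p$chrom, ":", p$start)
  }
  list(domains = dplyr::bind_rows(out), pairs = pairs)
}

# Draw one library's tags: Poisson counts per genomic span, uniform positions
# within the span. Domains replace the background rate over their span.
draw_library <- function(domains, chrom_sizes, lam_bg, lam_dom, diff_fold,
                         irradiated) {
  spans <- vector("list", nrow(chrom_sizes))
  for (ci in seq_len(nrow(chrom_sizes))) {
    cn <- chrom_sizes$chrom[ci]
    L <- chrom_sizes$length[ci]
    d <- domains[domains$chrom == cn, , drop = FALSE]
    d <- d[order(d$start), , drop = FALSE]
    rate <- rep(lam_dom, nrow(d))
    if (irradiated && nrow(d) > 0) {
      rate[!is.na(d$direction) & d$direction == "up"] <- lam_dom * diff_fold
      rate[!is.na(d$direction) & d$direction == "down"] <- lam_dom / diff_fold
    }
    bg_bounds <- c(0, rbind(d$start, d$end), L)
    bg_start <- bg_bounds[seq(1, length(bg_bounds) - 1, 2)]
    bg_end <- bg_bounds[seq(2, length(bg_bounds), 2)]
    keep <- bg_end > bg_start
    spans[[ci]] <- tibble::tibble(
      chrom = cn,
      start = c(bg_start[keep], d$start),
      end = c(bg_end[keep], d$end),
      rate = c(rep(lam_bg, sum(keep)), rate))
  }
  spans <- dplyr::bind_rows(spans)
  n <- stats::rpois(nrow(spans), spans$rate * (spans$end - spans$start))
  idx <- rep.int(seq_len(nrow(spans)), n)
  if (length(idx) == 0) {
    return(tibble::tibble(chrom = character(), pos = numeric(),
                          strand = character()))
  }
  pos <- floor(stats::runif(length(idx), spans$start[idx], spans$end[idx]))
  out <- tibble::tibble(chrom = spans$chrom[idx], pos = pos,
                        strand = sample(c("+", "-"), length(idx), replace = TRUE))
  dplyr::arrange(out, .data$chrom, .data$pos)
}

#' Expected library size under a simulation configuration
#'
#' Analytic expectation of the number of tags per library (sham condition),
#' useful for power planning and checked by the generator's tests.
#'
#' @param config A [sim_config()].
#' @return Expected tag count (a single number).
#' @export
expected_library_size <- function(config) {
  genome <- config$n_chroms * config$chrom_length
  # per tissue/mark: n_domains domains at mean length
  dom_bp <- config$n_domains * mean(config$domain_length)
  config$background_rate * (genome - dom_bp) +
    config$enrichment_fold * config$background_rate * dom_bp
}
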