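test_that("merge_condition_domains unions overlapping and abutting domains", {
  a <- tibble::tibble(chrom = "chr1", start = 0, end = 2000)
  b <- tibble::tibble(chrom = "chr1", start = 1500, end = 3000)
  m <- merge_condition_domains(a, b)
  expect_equal(c(m$start, m$end), c(0, 3000))

  d1 <- tibble::tibble(chrom = "chr1", start = c(0, 5000), end = c(1000, 6000))
  m2 <- merge_condition_domains(d1, d1)
  expect_equal(m2[, c("chrom", "start", "end")], d1, ignore_attr = TRUE)
})

test_that("merge_condition_domains equals a sweep-line union oracle", {
  withr::local_seed(12)
  for (rep in 1:20) {
    x <- tibble::tibble(chrom = sample(c("chr1", "chr2"), 40, TRUE),
                        start = sample.int(5e4, 40))
    x$end <- x$start + sample.int(3000, 40)
    got <- merge_condition_domains(x)
    # oracle: per-bp occupancy scan
    want <- dplyr::bind_rows(lapply(split(x, x$chrom), function(d) {
      cov <- logical(max(d$end))
      for (i in seq_len(nrow(d))) cov[(d$start[i] + 1):d$end[i]] <- TRUE
      r <- rle(cov)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths
      tibble::tibble(chrom = d$chrom[1], start = starts[r$values],
                     end = ends[r$values])
    }))
    want <- dplyr::arrange(want, .data$chrom, .data$start)
    expect_equal(got[, c("chrom", "start", "end")], want, ignore_attr = TRUE)
  }
})

test_that("chi-square statistic matches the 2x2 oracle to 1e-10", {
  oracle <- function(a, b, na, nb) {
    suppressWarnings(stats::chisq.test(rbind(c(a, na - a), c(b, nb - b)),
                                       correct = FALSE))
  }
  cases <- list(c(100, 50, 1e6, 1e6), c(7, 19, 5e5, 8e5),
                c(0, 12, 1e6, 1e6), c(3, 1, 1e4, 2e4))
  for (cs in cases) {
    got <- chisq_region_test(cs[1], cs[2], cs[3], cs[4])
    want <- oracle(cs[1], cs[2], cs[3], cs[4])
    expect_equal(got$statistic, unname(want$statistic), tolerance = 1e-10)
    expect_equal(got$p, want$p.value, tolerance = 1e-10)
  }
  # symmetry and degenerate cases
  expect_equal(chisq_region_test(50, 50, 1e6, 1e6)$statistic, 0)
  expect_equal(chisq_region_test(50, 50, 1e6, 1e6)$p, 1)
  expect_equal(chisq_region_test(0, 0, 1e6, 1e6)$p, 1)
  expect_true(chisq_region_test(1, 0, 5, 5)$low_count)
  # exchangeability
  expect_equal(chisq_region_test(100, 50, 1e6, 2e6)$p,
               chisq_region_test(50, 100, 2e6, 1e6)$p)
  # statistic grows with exposure at fixed proportions
  expect_gt(chisq_region_test(1000, 500, 1e7, 1e7)$statistic,
            chisq_region_test(100, 50, 1e6, 1e6)$statistic)
})

test_that("negative-binomial test reduces to the Poisson LRT at zero dispersion", {
  poisson_lrt <- function(y, cond, N) {
    r0 <- sum(y) / sum(N)
    rc <- tapply(y, cond, sum) / tapply(N, cond, sum)
    stat <- 2 * sum(y * log(rc[cond] / r0), na.rm = TRUE)
    stats::pchisq(stat, 1, lower.tail = FALSE)
  }
  y <- c(14, 19, 44, 38)
  cond <- c("A", "A", "B", "B")
  N <- c(1e5, 1.2e5, 0.9e5, 1.1e5)
  got <- negbin_region_test(y, cond, N, dispersion = 1e-8)
  expect_equal(got$p, poisson_lrt(y, cond, N), tolerance = 1e-6)

  expect_equal(negbin_region_test(c(5, 5, 5, 5), cond, rep(1e5, 4),
                                  dispersion = 0.1)$p, 1, tolerance = 1e-6)
  expect_equal(negbin_region_test(c(0, 0, 0, 0), cond, rep(1e5, 4),
                                  dispersion = 0.1)$p, 1)
})

test_that("common dispersion is recovered by the moment estimator", {
  withr::local_seed(41)
  m <- 1500; disp <- 0.2
  counts <- sapply(1:4, function(j) stats::rnbinom(m, size = 1 / disp, mu = 40))
  rc <- region_counts_fx(counts, condition = c("A", "A", "B", "B"),
                         lib_sizes = rep(1e6, 4))
  est <- estimate_common_dispersion(rc)
  expect_gt(est, 0.15)
  expect_lt(est, 0.25)
  # under-dispersed data falls back to Poisson with a warning
  const <- region_counts_fx(matrix(5, 20, 4), condition = c("A", "A", "B", "B"),
                            lib_sizes = rep(1e6, 4))
  expect_lte(estimate_common_dispersion(const), 0)
  expect_warning(test_differential(const, test = "negbin",
                                   dispersion = -0.1, reference = "A"),
                 "Poisson")
})

test_that("Benjamini-Hochberg adjustment follows the step-up formula", {
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(adjust_fdr(rep(1, 5)), rep(1, 5))
  expect_equal(adjust_fdr(0.2), 0.2)
  expect_equal(adjust_fdr(numeric()), numeric())
  # invariant to input order
  withr::local_seed(2)
  p <- stats::runif(100)
  ord <- sample.int(100)
  expect_equal(adjust_fdr(p)[ord], adjust_fdr(p[ord]))
  expect_true(all(diff(adjust_fdr(sort(p))) >= -1e-12))
  expect_error(adjust_fdr(c(0.5, 1.2)))
})

test_that("test_differential reports direction from scaled fold change", {
  counts <- rbind(c(20, 22, 61, 59),   # up in proton
                  c(50, 48, 15, 17),   # down
                  c(30, 31, 33, 32))   # near-null, mildly up
  rc <- region_counts_fx(counts, condition = c("sham", "sham", "proton",
                                               "proton"),
                         lib_sizes = rep(1e6, 4))
  tested <- test_differential(rc)
  expect_equal(tested$direction, c("up", "down", "up"))
  expect_equal(tested$test, rep("chisq", 3))
  expect_true(all(tested$q >= tested$p))
  expect_gt(tested$log2fc[1], 1)
  expect_lt(tested$log2fc[2], -1)
  # q-filtered call set shrinks monotonically with the threshold
  n_calls <- vapply(c(0.1, 0.01, 0.001), function(th) {
    nrow(call_differential(tested, th))
  }, numeric(1))
  expect_true(all(diff(n_calls) <= 0))
  # swapping the reference flips direction, keeps p
  swapped <- test_differential(rc, reference = "proton")
  expect_equal(swapped$p, tested$p)
  expect_equal(swapped$direction,
               ifelse(tested$direction == "up", "down", "up"))
})

test_that("empty candidate lists propagate cleanly", {
  empty_regions <- merge_condition_domains(
    tibble::tibble(chrom = character(), start = numeric(), end = numeric()))
  expect_equal(nrow(empty_regions), 0)
  rc <- region_counts(empty_regions, tags_fx("chr1", c(1, 2)))
  expect_equal(nrow(rc), 0)
})

test_that("differential BED export encodes direction and capped q score", {
  calls <- tibble::tibble(chrom = "chr1", start = c(0, 5000),
                          end = c(1000, 6000), direction = c("up", "down"),
                          q = c(1e-5, 1e-200))
  f <- withr::local_tempfile()
  write_differential_bed(calls, f)
  lines <- strsplit(readLines(f), "\t")
  expect_equal(vapply(lines, `[[`, "", 4), c("up", "down"))
  expect_equal(as.numeric(vapply(lines, `[[`, "", 5)), c(50, 1000))
})
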