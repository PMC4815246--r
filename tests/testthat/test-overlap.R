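test_that("pair_within_window honors the exact 25-kb gap boundary", {
  a <- tibble::tibble(chrom = "chr1", start = 0, end = 1000)
  expect_true(pair_within_window(
    a, tibble::tibble(chrom = "chr1", start = 26000, end = 27000))$paired)
  expect_false(pair_within_window(
    a, tibble::tibble(chrom = "chr1", start = 26001, end = 27000))$paired)
  expect_false(pair_within_window(
    a, tibble::tibble(chrom = "chr2", start = 0, end = 1000))$paired)
  empty <- tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric())
  expect_equal(sum(pair_within_window(a, empty)$paired), 0)
})

test_that("pair_within_window matches a brute-force all-pairs scan", {
  withr::local_seed(23)
  for (rep in 1:10) {
    a <- tibble::tibble(chrom = sample(c("chr1", "chr2"), 30, TRUE),
                        start = sample.int(2e5, 30))
    a$end <- a$start + sample.int(2000, 30)
    b <- tibble::tibble(chrom = sample(c("chr1", "chr2"), 25, TRUE),
                        start = sample.int(2e5, 25))
    b$end <- b$start + sample.int(2000, 25)
    w <- 10000
    got <- pair_within_window(a, b, window = w)
    want <- vapply(seq_len(nrow(a)), function(i) {
      any(interval_gap(a$chrom[i], a$start[i], a$end[i],
                       b$chrom, b$start, b$end) <= w)
    }, logical(1))
    expect_equal(got$paired, want)
    # reported gap is the minimum over partners
    for (i in which(want)) {
      expect_equal(got$gap[i],
                   min(interval_gap(a$chrom[i], a$start[i], a$end[i],
                                    b$chrom, b$start, b$end)))
    }
  }
})

# deterministic geometry: 10 universe regions on one chromosome, the first
# `n_paired_universe` of them within reach of a set_b region
overlap_fixture <- function(n_universe = 10, n_paired_universe = 5) {
  universe <- tibble::tibble(chrom = "chr1",
                             start = seq_len(n_universe) * 1e6)
  universe$end <- universe$start + 1000
  b <- tibble::tibble(chrom = "chr1",
                      start = universe$start[seq_len(n_paired_universe)] + 5000)
  b$end <- b$start + 1000
  list(universe = universe, b = b)
}

test_that("hypergeometric overlap p equals exhaustive enumeration", {
  fx <- overlap_fixture()
  set_a <- fx$universe[c(1, 2, 3, 4), ]  # all four paired (K = 5)
  got <- overlap_significance(set_a, fx$b, fx$universe, window = 25000)
  expect_equal(got$n_paired, 4L)
  expect_equal(got$n_universe_paired, 5L)
  draws <- utils::combn(10, 4)
  n_hits <- colSums(matrix(draws %in% 1:5, nrow = 4))
  expect_equal(got$p, mean(n_hits >= 4))

  # a mixed draw: 2 of 4 paired
  set_a2 <- fx$universe[c(1, 2, 8, 9), ]
  got2 <- overlap_significance(set_a2, fx$b, fx$universe, window = 25000)
  expect_equal(got2$p, mean(n_hits >= 2))

  # drawing the whole universe is certain
  got3 <- overlap_significance(fx$universe, fx$b, fx$universe, window = 25000)
  expect_equal(got3$p, 1)

  expect_error(overlap_significance(
    tibble::tibble(chrom = "chr9", start = 1, end = 2), fx$b, fx$universe),
    "absent")
})

test_that("permutation p agrees with hypergeometric within Monte-Carlo error", {
  fx <- overlap_fixture(n_universe = 40, n_paired_universe = 18)
  set_a <- fx$universe[c(1:8, 30:35), ]
  hyp <- overlap_significance(set_a, fx$b, fx$universe, window = 25000)
  perm <- overlap_significance(set_a, fx$b, fx$universe, window = 25000,
                               method = "permutation", permutations = 1e4,
                               seed = 9)
  se <- sqrt(hyp$p * (1 - hyp$p) / 1e4)
  expect_lt(abs(perm$p - hyp$p), 3 * se + 2e-4)
  # deterministic given seed
  perm2 <- overlap_significance(set_a, fx$b, fx$universe, window = 25000,
                                method = "permutation", permutations = 1e4,
                                seed = 9)
  expect_identical(perm$p, perm2$p)
})

test_that("overlap p is invariant to joint coordinate translation", {
  fx <- overlap_fixture()
  set_a <- fx$universe[c(1, 2, 6, 7), ]
  p0 <- overlap_significance(set_a, fx$b, fx$universe)$p
  shift <- function(x, d) dplyr::mutate(x, start = .data$start + d,
                                        end = .data$end + d)
  p1 <- overlap_significance(shift(set_a, 1e4), shift(fx$b, 1e4),
                             shift(fx$universe, 1e4))$p
  expect_equal(p0, p1)
})

test_that("venn_summary ranks direction pairs and handles degenerate input", {
  fx <- overlap_fixture()
  mk <- function(x, dir) dplyr::mutate(x, direction = dir)
  # plant coupling only for (down, up): the down A-regions are the paired ones
  calls_a <- dplyr::bind_rows(mk(fx$universe[1:4, ], "down"),
                              mk(fx$universe[8:10, ], "up"))
  calls_b <- mk(fx$b, "up")
  v <- venn_summary(calls_a, calls_b, fx$universe)
  expect_equal(nrow(v), 4)
  top <- v[v$top, ]
  expect_equal(c(top$direction_a, top$direction_b), c("down", "up"))
  # empty significant sets yield p = 1 and zero counts
  v0 <- venn_summary(calls_a[0, ], calls_b, fx$universe)
  expect_true(all(v0$p == 1))
  expect_true(all(v0$n_paired == 0))
})
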