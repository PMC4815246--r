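small_cfg <- function(...) {
  args <- utils::modifyList(
    list(n_chroms = 1, chrom_length = 1e6, n_domains = 20, n_diff = 8,
         n_genes = 30, n_repeats = 150, tissues = "hippocampus"),
    list(...))
  do.call(sim_config, args)
}

test_that("simulation is deterministic given the seed", {
  cfg <- small_cfg(seed = 5)
  a <- simulate_libraries(cfg)
  b <- simulate_libraries(cfg)
  expect_identical(a$tags, b$tags)
  expect_identical(a$truth, b$truth)
  ann1 <- simulate_annotation(cfg)
  ann2 <- simulate_annotation(cfg)
  expect_identical(ann1, ann2)
  c <- simulate_libraries(small_cfg(seed = 6))
  expect_false(identical(a$tags, c$tags))
})

test_that("annotation generator respects structural invariants", {
  ann <- simulate_annotation(small_cfg(seed = 2))
  g <- ann$genes
  expect_true(all(vapply(seq_len(nrow(g)), function(i) {
    all(g$exon_starts[[i]] >= g$start[i]) && all(g$exon_ends[[i]] <= g$end[i])
  }, logical(1))))
  expect_true(all(lengths(g$exon_starts) >= 1 & lengths(g$exon_starts) <= 10))
  # genes non-overlapping
  gs <- dplyr::arrange(g, .data$chrom, .data$start)
  expect_true(all(diff(gs$start) >= (gs$end - gs$start)[-nrow(gs)] |
                    gs$chrom[-1] != gs$chrom[-nrow(gs)]))
  expect_setequal(unique(ann$repeats$class), REPEAT_CLASSES)
  validate_intervals(ann$repeats, ann$chrom_sizes)

  empty <- simulate_annotation(small_cfg(seed = 2, n_genes = 0))
  expect_equal(nrow(empty$genes), 0)
  expect_equal(empty$chrom_sizes$length, 1e6)
})

test_that("background-only libraries are Poisson in 1-kb bins", {
  cfg <- sim_config(seed = 3, n_chroms = 2, chrom_length = 5e6,
                    n_domains = 0, n_diff = 0, tissues = "hippocampus",
                    replicates = 1, n_genes = 0, n_repeats = 0)
  sim <- simulate_libraries(cfg)
  one <- sim$tags[sim$tags$library_id == sim$tags$library_id[1], ]
  cw <- count_windows(one, sim$chrom_sizes, window = 1000)
  expect_gte(nrow(cw), 1e4)
  iod <- stats::var(cw$count) / mean(cw$count)
  expect_gt(iod, 0.9)
  expect_lt(iod, 1.1)
})

test_that("library sizes match the analytic expectation within 3 sigma", {
  cfg <- small_cfg(seed = 9)
  sim <- simulate_libraries(cfg)
  exp_n <- expected_library_size(cfg)
  sham <- library_sizes(sim$tags) |> dplyr::filter(.data$condition == "sham")
  for (n in sham$n_tags) {
    expect_lt(abs(n - exp_n), 3 * sqrt(exp_n) + 0.03 * exp_n)
  }
  # conservation: per-library size equals emitted tag rows by construction
  expect_equal(sum(library_sizes(sim$tags)$n_tags), nrow(sim$tags))
})

test_that("planted domains carry the configured enrichment fold", {
  cfg <- sim_config(seed = 4, n_chroms = 1, chrom_length = 2e6,
                    background_rate = 0.05, n_domains = 30,
                    domain_length = c(1000, 2000), enrichment_fold = 8,
                    n_diff = 0, tissues = "hippocampus", replicates = 1,
                    n_genes = 0, n_repeats = 0)
  sim <- simulate_libraries(cfg)
  tg <- sim$tags[sim$tags$mark == "5mC" & sim$tags$condition == "sham", ]
  dom <- sim$truth$domains[sim$truth$domains$mark == "5mC", ]
  in_dom <- sum(dipseqr:::count_points_in_regions(dom, tg$chrom, tg$pos))
  dom_bp <- sum(dom$end - dom$start)
  genome_bp <- sum(sim$chrom_sizes$length)
  dens_dom <- in_dom / dom_bp
  dens_bg <- (nrow(tg) - in_dom) / (genome_bp - dom_bp)
  expect_gt(dens_dom / dens_bg, 8 * 0.9)
  expect_lt(dens_dom / dens_bg, 8 * 1.1)
})

test_that("full coupling places every 5hmC differential region near a 5mC one", {
  cfg <- small_cfg(seed = 7, coupling = 1)
  sim <- simulate_libraries(cfg)
  hmc <- sim$truth$diff_regions |> dplyr::filter(.data$mark == "5hmC")
  mc <- sim$truth$diff_regions |> dplyr::filter(.data$mark == "5mC")
  paired <- pair_within_window(hmc, mc, window = 25000)
  expect_true(all(paired$paired))
  expect_true(all(sim$truth$coupled_pairs$gap <= 25000))
  expect_equal(nrow(sim$truth$coupled_pairs), nrow(hmc))
  # the coupled direction pairing is (5mC down, 5hmC up) by default
  expect_true(all(hmc$direction == "up"))
})

test_that("empirical fold change in differential regions converges to phi", {
  err <- vapply(c(low = 0.005, high = 0.05), function(rate) {
    cfg <- sim_config(seed = 12, n_chroms = 1, chrom_length = 2e6,
                      background_rate = rate, n_domains = 20, n_diff = 20,
                      diff_fold = 3, tissues = "hippocampus",
                      n_genes = 0, n_repeats = 0)
    sim <- simulate_libraries(cfg)
    up <- sim$truth$diff_regions |>
      dplyr::filter(.data$mark == "5mC", .data$direction == "up")
    tg <- sim$tags[sim$tags$mark == "5mC", ]
    cnt <- function(cond) {
      sub <- tg[tg$condition == cond, ]
      sum(dipseqr:::count_points_in_regions(up, sub$chrom, sub$pos))
    }
    abs(log2(cnt("proton") / cnt("sham")) - log2(3))
  }, numeric(1))
  expect_lt(err[["high"]], err[["low"]])
  expect_lt(err[["high"]], 0.1)
})

test_that("config invariants are enforced", {
  expect_error(sim_config(background_rate = 0), "background_rate")
  expect_error(sim_config(enrichment_fold = 1), "enrichment_fold")
  expect_error(sim_config(diff_fold = 1), "diff_fold")
  expect_error(sim_config(coupling = 1.2), "coupling")
  expect_warning(
    simulate_libraries(sim_config(seed = 1, n_chroms = 1, chrom_length = 1e6,
                                  background_rate = 1e-5, n_domains = 5,
                                  domain_length = c(500, 600), n_diff = 0,
                                  tissues = "hippocampus", replicates = 1,
                                  n_genes = 0, n_repeats = 0)),
    "power")
})
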