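test_that("assign_category applies the closest-midpoint rule with priority", {
  g <- genes_fx(chrom = "chr1", start = 10000, end = 30000, strand = "+",
                exon_starts = list(c(10000, 20000)),
                exon_ends = list(c(12000, 30000)))
  # wholly inside the second exon, far from the TSS window
  got <- assign_category(tibble::tibble(chrom = "chr1", start = 24000,
                                        end = 24500), g)
  expect_equal(got$category, "exon")
  # overlapping the TSS window and the first exon; TSS midpoint (10000) is
  # closer to the interval midpoint than the exon midpoint (11000)
  got <- assign_category(tibble::tibble(chrom = "chr1", start = 9900,
                                        end = 10500), g)
  expect_equal(got$category, "TSS")
  # intron gap 12000-20000
  got <- assign_category(tibble::tibble(chrom = "chr1", start = 15000,
                                        end = 15100), g)
  expect_equal(got$category, "intron")
  # gene-free chromosome
  got <- assign_category(tibble::tibble(chrom = "chrX", start = 0,
                                        end = 100), g)
  expect_equal(got$category, "intergenic")
  expect_true(is.na(got$distance))
})

test_that("category counts are conserved and match a brute-force scan", {
  withr::local_seed(77)
  cs <- chrom_sizes_fx(c(chr1 = 2e5, chr2 = 1e5))
  n <- 40
  gstart <- c(sort(sample.int(18e4, 30)), sort(sample.int(8e4, 10)))
  gchrom <- rep(c("chr1", "chr2"), c(30, 10))
  g <- genes_fx(chrom = gchrom, start = gstart, end = gstart + 5000,
                strand = sample(c("+", "-"), n, TRUE))
  tg <- null_tags_fx(cs, rate = 0.005)
  comp <- category_composition(tg, g, tss_flank = 1000)
  expect_equal(sum(comp$n), nrow(tg))
  expect_equal(sum(comp$fraction), 1)

  # brute-force oracle over every tag x feature pair
  feats <- dipseqr:::gene_features(g, tss_flank = 1000)
  asg <- assign_category(tibble::tibble(chrom = tg$chrom, start = tg$pos,
                                        end = tg$pos + 1), g)
  prio <- c(TSS = 1, exon = 2, intron = 3)
  want <- vapply(seq_len(nrow(tg)), function(i) {
    hit <- feats$chrom == tg$chrom[i] & feats$start <= tg$pos[i] &
      feats$end > tg$pos[i]
    if (!any(hit)) return("intergenic")
    d <- abs((tg$pos[i] + 0.5) - feats$midpoint[hit])
    cand <- feats$category[hit]
    cand[order(d, prio[cand])][1]
  }, character(1))
  expect_equal(asg$category, want)
})

test_that("repeat CPM normalizes to one million and matches brute force", {
  withr::local_seed(55)
  cs <- chrom_sizes_fx(c(chr1 = 1e5))
  reps <- tibble::tibble(chrom = "chr1",
                         start = seq(0, 9e4, by = 1000))
  reps$end <- reps$start + sample(c(200, 400), nrow(reps), TRUE)
  reps$class <- sample(REPEAT_CLASSES, nrow(reps), TRUE)
  tg <- null_tags_fx(cs, rate = 0.05)
  cpm <- repeat_cpm(tg, reps)
  expect_equal(sum(cpm$cpm), 1e6)
  expect_setequal(cpm$class, REPEAT_CLASSES)

  # brute force: non-overlapping repeats here, so simple membership
  want <- vapply(REPEAT_CLASSES, function(cl) {
    r <- reps[reps$class == cl, ]
    sum(vapply(seq_len(nrow(r)), function(i) {
      sum(tg$pos >= r$start[i] & tg$pos < r$end[i])
    }, numeric(1)))
  }, numeric(1))
  got <- stats::setNames(cpm$count, cpm$class)[REPEAT_CLASSES]
  expect_equal(got, want)

  # degenerate: every tag in a SINE
  sine <- tibble::tibble(chrom = "chr1", start = 0, end = 1e5,
                         class = "SINE")
  cpm1 <- repeat_cpm(tg, sine)
  expect_equal(cpm1$cpm[cpm1$class == "SINE"], 1e6)
  expect_true(all(cpm1$cpm[cpm1$class != "SINE"] == 0))

  far <- tibble::tibble(chrom = "chr9", start = 0, end = 100, class = "LINE")
  expect_error(repeat_cpm(tg, far), "repeat")
})

test_that("overlapping repeats resolve to the closest element exclusively", {
  reps <- tibble::tibble(chrom = "chr1", start = c(0, 50), end = c(100, 400),
                         class = c("SINE", "LINE"))
  tg <- tags_fx("chr1", c(60, 90))
  # tag 60: SINE midpoint 50 (d=10.5) vs LINE midpoint 225 -> SINE
  # tag 90: SINE d=40.5 vs LINE d=134.5 -> SINE
  cpm <- repeat_cpm(tg, reps)
  expect_equal(cpm$count[cpm$class == "SINE"], 2)
  expect_equal(cpm$count[cpm$class == "LINE"], 0)
})

test_that("tissue comparison is symmetric, calibrated, and powered", {
  base <- tidyr::expand_grid(library_id = paste0("L", 1:8),
                             class = REPEAT_CLASSES)
  base$tissue <- rep(c("hippocampus", "ventricle"), each = 4 * 7)[
    seq_len(nrow(base))]
  base$mark <- "5mC"
  base$condition <- "sham"
  base$replicate <- 1L

  same <- dplyr::mutate(base, cpm = rep(c(1e5, 2e5, 3e5, 1e5, 5e4, 3e4, 2e4),
                                        8))
  res <- compare_tissue_density(same)
  expect_true(all(res$p == 1))
  expect_false(any(res$significant))

  withr::local_seed(10)
  hits <- 0
  for (s in 1:50) {
    d <- base
    mu <- ifelse(d$class == "tRNA" & d$tissue == "ventricle", 2e5, 1e5)
    d$cpm <- stats::rnorm(nrow(d), mu, 0.1 * mu)
    res <- compare_tissue_density(d)
    hits <- hits + res$significant[res$class == "tRNA"]
    if (s == 1) {
      swapped <- compare_tissue_density(
        dplyr::mutate(d, tissue = ifelse(d$tissue == "ventricle",
                                         "hippocampus", "ventricle")))
      expect_equal(swapped$p, res$p)
    }
  }
  expect_gte(hits, 45)
})

test_that("regions_to_genes ranks, bounds distance, and deduplicates genes", {
  g <- genes_fx(chrom = "chr1", start = c(100000, 400000),
                end = c(110000, 410000), strand = c("+", "-"))
  # TSSs at 100000 (plus) and 409999 (minus)
  mk_regions <- function(starts, q) {
    tibble::tibble(chrom = "chr1", start = starts, end = starts + 1000,
                   q = q, log2fc = 1, direction = "up")
  }
  # region ending 10 bp upstream of the plus-strand TSS
  r <- mk_regions(98990, q = 1e-5)
  got <- regions_to_genes(r, g)
  expect_equal(got$gene_id, "g001")
  expect_equal(got$distance, -10)

  # 50 kb boundary: TSS at 100000; region start 150001 -> distance 50001
  expect_equal(nrow(regions_to_genes(mk_regions(150001, 1e-5),
                                     g[1, ])), 0)
  expect_equal(nrow(regions_to_genes(mk_regions(150000, 1e-5),
                                     g[1, ])), 1)

  # two regions near one gene: best q kept; top_k truncates
  r2 <- mk_regions(c(98990, 101000), q = c(1e-3, 1e-6))
  got2 <- regions_to_genes(r2, g)
  expect_equal(nrow(got2), 1)
  expect_equal(got2$q, 1e-6)
  expect_equal(nrow(regions_to_genes(r2, g, top_k = 1)), 1)
  expect_lte(nrow(regions_to_genes(r2, g)), min(2000, nrow(r2), nrow(g)))

  # minus-strand sign convention: region left of a minus TSS is downstream
  r3 <- mk_regions(405000, q = 1e-4)
  got3 <- regions_to_genes(r3, g)
  expect_equal(got3$gene_id, "g002")
  # TSS at 409999; the region ends 3999 bp to its genomic left, which is
  # downstream of a minus-strand gene: positive distance
  expect_equal(got3$distance, 3999)
})

test_that("intragenic classification is a coarse overlap test", {
  g <- genes_fx(chrom = "chr1", start = 1000, end = 2000)
  x <- tibble::tibble(chrom = "chr1", start = c(1500, 5000),
                      end = c(1600, 5100))
  expect_equal(classify_genic(x, g)$intragenic, c(TRUE, FALSE))
})
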