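# Shared fixture builders. Everything is generated in code; no data files.

chrom_sizes_fx <- function(lengths = c(chr1 = 1e6)) {
  tibble::tibble(chrom = names(lengths), length = unname(lengths))
}

tags_fx <- function(chrom, pos, library_id = "lib1", tissue = "hippocampus",
                    condition = "sham", mark = "5mC", replicate = 1L) {
  tibble::tibble(library_id = library_id, tissue = tissue,
                 condition = condition, mark = mark,
                 replicate = as.integer(replicate),
                 chrom = chrom, pos = pos, strand = "+")
}

# Uniform background tags over a genome at the given per-bp rate.
null_tags_fx <- function(chrom_sizes, rate, ...) {
  n <- stats::rpois(1, rate * sum(chrom_sizes$length))
  ci <- sample.int(nrow(chrom_sizes), n, replace = TRUE,
                   prob = chrom_sizes$length)
  tags_fx(chrom = chrom_sizes$chrom[ci],
          pos = floor(stats::runif(n, 0, chrom_sizes$length[ci])), ...)
}

# Minimal gene-model tibble from parallel vectors; exons default to the
# whole transcribed region.
genes_fx <- function(chrom, start, end, strand = "+",
                     gene_id = sprintf("g%03d", seq_along(start)),
                     exon_starts = NULL, exon_ends = NULL,
                     expression = seq_along(start)) {
  g <- tibble::tibble(
    gene_id = gene_id, chrom = chrom, start = start, end = end,
    strand = strand,
    exon_starts = exon_starts %||% as.list(start),
    exon_ends = exon_ends %||% as.list(end),
    expression = expression)
  g$tss <- ifelse(g$strand == "-", g$end - 1, g$start)
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Long region-count tibble for the differential tests: counts is a
# regions x libraries matrix.
region_counts_fx <- function(counts, condition, lib_sizes,
                             replicate = NULL) {
  m <- nrow(counts)
  k <- ncol(counts)
  if (is.null(replicate)) replicate <- stats::ave(seq_len(k), condition,
                                                  FUN = seq_along)
  rc <- tibble::tibble(
    region_id = rep(sprintf("r%05d", seq_len(m)), k),
    chrom = "chr1",
    start = rep(seq_len(m), k) * 2000,
    end = rep(seq_len(m), k) * 2000 + 1000,
    library_id = rep(paste0("L", seq_len(k)), each = m),
    tissue = "hippocampus",
    condition = rep(condition, each = m),
    mark = "5mC",
    replicate = rep(as.integer(replicate), each = m),
    n_tags = rep(lib_sizes, each = m),
    count = as.vector(counts))
  class(rc) <- c("region_counts", class(rc))
  rc
}
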