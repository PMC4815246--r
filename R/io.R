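#' Read a BED file into an interval tibble
#'
#' Reads BED3/BED6 (tab-separated, 0-based half-open). Optional columns 4-6
#' (`name`, `score`, `strand`) are preserved when present; row order is kept.
#'
#' @param path Path to a BED file.
#' @return Interval tibble with `chrom`, `start`, `end` and, if present,
#'   `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble::tibble(chrom = character(), start = numeric(), end = numeric()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(fields)
  if (any(ncol < 3)) {
    stop("malformed BED line ", which(ncol < 3)[1], ": fewer than 3 columns")
  }
  k <- min(ncol)
  starts <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2)))
  ends <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3)))
  bad <- which(is.na(starts) | is.na(ends) |
                 starts != floor(starts) | ends != floor(ends))
  if (length(bad) > 0) {
    stop("malformed BED line ", bad[1], ": non-integer coordinate")
  }
  bad <- which(starts >= ends)
  if (length(bad) > 0) {
    stop("malformed BED line ", bad[1], ": start >= end (empty interval)")
  }
  out <- tibble::tibble(
    chrom = vapply(fields, `[[`, "", 1),
    start = starts,
    end = ends
  )
  if (k >= 4) out$name <- vapply(fields, `[[`, "", 4)
  if (k >= 5) out$score <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 5)))
  if (k >= 6) out$strand <- vapply(fields, `[[`, "", 6)
  validate_intervals(out)
  out
}

#' Write an interval tibble as BED
#'
#' Emits BED3, or BED6 when `name`/`score`/`strand` columns are present
#' (missing middle columns are filled with `"."`/`0`).
#'
#' @param x Interval tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  validate_intervals(x)
  cols <- list(x$chrom, format_coord(x$start), format_coord(x$end))
  has6 <- any(c("name", "score", "strand") %in% names(x))
  if (has6) {
    cols <- c(cols, list(
      if (!is.null(x$name)) as.character(x$name) else rep(".", nrow(x)),
      if (!is.null(x$score)) as.character(x$score) else rep("0", nrow(x)),
      if (!is.null(x$strand)) as.character(x$strand) else rep(".", nrow(x))
    ))
  }
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

format_coord <- function(x) format(x, scientific = FALSE, trim = TRUE)

#' Read a two-column chrom.sizes file
#'
#' @param path Tab-separated file with chromosome name and length.
#' @return Tibble with columns `chrom`, `length`.
#' @export
read_chrom_sizes <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("chrom", "length"),
                         colClasses = c("character", "numeric"))
  out <- tibble::as_tibble(d)
  if (any(out$length <= 0)) stop("non-positive chromosome length")
  out
}

#' @rdname read_chrom_sizes
#' @param x Chrom-sizes tibble.
#' @export
write_chrom_sizes <- function(x, path) {
  writeLines(paste(x$chrom, format_coord(x$length), sep = "\t"), path)
  invisible(path)
}

#' Write binned track values as fixedStep wiggle
#'
#' Values are per fixed-width bin from position 0 of each chromosome
#' (0-based); the wiggle standard is 1-based, so bin `i` becomes
#' `start = i * bin_size + 1`. Runs of zero bins are omitted, each
#' resumption opening a new `fixedStep` declaration.
#'
#' @param x Tibble with columns `chrom`, `bin` (0-based bin index) and
#'   `value`; bins absent from the table are treated as zero.
#' @param bin_size Bin width in bp (> 0); used as both `step` and `span`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wiggle <- function(x, bin_size, path) {
  if (bin_size <= 0) stop("bin_size must be > 0")
  con <- file(path, open = "wt")
  on.exit(close(con))
  x <- x[x$value != 0, , drop = FALSE]
  x <- x[order(x$chrom, x$bin), , drop = FALSE]
  if (nrow(x) > 0) {
    new_block <- c(TRUE, x$chrom[-1] != x$chrom[-nrow(x)] |
                     x$bin[-1] != x$bin[-nrow(x)] + 1)
    block <- cumsum(new_block)
    for (b in unique(block)) {
      rows <- which(block == b)
      writeLines(sprintf("fixedStep chrom=%s start=%s step=%s span=%s",
                         x$chrom[rows[1]],
                         format_coord(x$bin[rows[1]] * bin_size + 1),
                         format_coord(bin_size), format_coord(bin_size)), con)
      writeLines(format(x$value[rows], scientific = FALSE, trim = TRUE), con)
    }
  }
  invisible(path)
}

#' Read a fixedStep wiggle file back into binned values
#'
#' Inverse of [write_wiggle()] for tracks written by this package
#' (`step == span`, starts aligned to the bin grid).
#'
#' @param path Path to a fixedStep wiggle file.
#' @return Tibble with columns `chrom`, `bin`, `value` (zero bins absent).
#' @export
read_wiggle <- function(path) {
  lines <- readLines(path)
  out <- list()
  chrom <- NULL; start <- NA; step <- NA; i <- 0
  for (ln in lines) {
    if (startsWith(ln, "fixedStep")) {
      kv <- strsplit(strsplit(ln, " +")[[1]][-1], "=", fixed = TRUE)
      par <- stats::setNames(vapply(kv, `[[`, "", 2), vapply(kv, `[[`, "", 1))
      chrom <- par[["chrom"]]
      start <- as.numeric(par[["start"]])
      step <- as.numeric(par[["step"]])
      i <- 0
    } else if (nzchar(ln)) {
      out[[length(out) + 1]] <- tibble::tibble(
        chrom = chrom,
        bin = (start - 1 + i * step) / step,
        value = as.numeric(ln)
      )
      i <- i + 1
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(chrom = character(), bin = numeric(), value = numeric()))
  }
  dplyr::bind_rows(out)
}

#' Read and write tabular gene models
#'
#' The gene-model exchange format is a TSV with header columns `gene_id`,
#' `chrom`, `start`, `end`, `strand`, `exon_starts`, `exon_ends` (the exon
#' columns comma-separated, 0-based half-open, sorted, non-overlapping,
#' contained in `[start, end)`), plus optional extra columns such as
#' `expression`. The strand-aware TSS is derived, not stored: `start` for
#' `+` genes, `end - 1` for `-` genes.
#'
#' @param path Path to the TSV.
#' @return Tibble with the columns above, `exon_starts`/`exon_ends` as
#'   list-columns of numeric vectors, and a derived `tss` column.
#' @export
read_gene_models <- function(path) {
  d <- tibble::as_tibble(utils::read.table(path, sep = "\t", header = TRUE,
                                           colClasses = "character"))
  d$start <- as.numeric(d$start)
  d$end <- as.numeric(d$end)
  d$exon_starts <- lapply(strsplit(d$exon_starts, ",", fixed = TRUE), as.numeric)
  d$exon_ends <- lapply(strsplit(d$exon_ends, ",", fixed = TRUE), as.numeric)
  if ("expression" %in% names(d)) d$expression <- as.numeric(d$expression)
  validate_gene_models(d)
}

#' @rdname read_gene_models
#' @param x Gene-model tibble (as produced by [simulate_annotation()]).
#' @export
write_gene_models <- function(x, path) {
  d <- x
  d$tss <- NULL
  d$exon_starts <- vapply(d$exon_starts, function(v) paste(format_coord(v), collapse = ","), "")
  d$exon_ends <- vapply(d$exon_ends, function(v) paste(format_coord(v), collapse = ","), "")
  readr::write_tsv(d, path)
  invisible(path)
}

validate_gene_models <- function(d) {
  stopifnot(all(c("gene_id", "chrom", "start", "end", "strand",
                  "exon_starts", "exon_ends") %in% names(d)))
  validate_intervals(d)
  ok <- mapply(function(es, ee, s, e) {
    length(es) == length(ee) && all(es < ee) && all(es >= s) && all(ee <= e) &&
      !is.unsorted(es) && all(ee[-length(ee)] <= es[-1])
  }, d$exon_starts, d$exon_ends, d$start, d$end)
  if (!all(ok)) stop("invalid exon structure for gene ", d$gene_id[which(!ok)[1]])
  d$tss <- ifelse(d$strand == "-", d$end - 1, d$start)
  d
}

#' Repeat classes recognised by the annotation module
#' @export
REPEAT_CLASSES <- c("SINE", "LINE", "LTR", "satellite", "tRNA", "rRNA", "other")

#' Read and write repeat annotation tables
#'
#' TSV with header columns `chrom`, `start`, `end`, `class`; the class label
#' must belong to the closed vocabulary in [REPEAT_CLASSES].
#'
#' @param path Path to the TSV.
#' @return Tibble with columns `chrom`, `start`, `end`, `class`.
#' @export
read_repeats <- function(path) {
  d <- tibble::as_tibble(utils::read.table(path, sep = "\t", header = TRUE,
                                           colClasses = c("character", "numeric",
                                                          "numeric", "character")))
  validate_intervals(d)
  bad <- setdiff(unique(d$class), REPEAT_CLASSES)
  if (length(bad) > 0) stop("unknown repeat class: ", paste(bad, collapse = ", "))
  d
}

#' @rdname read_repeats
#' @param x Repeat tibble.
#' @export
write_repeats <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

#' Read and write tag libraries
#'
#' A tag library is the list of uniquely-mapped 5' tag positions of one
#' DIP-Seq library. On disk each library is a BED6 file of 1-bp intervals
#' (name column unused, score 0); in memory tags live in a tidy tibble with
#' one row per tag and the library metadata as columns.
#'
#' @param path BED file of tag positions.
#' @param library_id,tissue,condition,mark,replicate Metadata attached to
#'   every tag row.
#' @return Tibble with columns `library_id`, `tissue`, `condition`, `mark`,
#'   `replicate`, `chrom`, `pos`, `strand`.
#' @export
read_tags <- function(path, library_id, tissue = NA_character_,
                      condition = NA_character_, mark = NA_character_,
                      replicate = NA_integer_) {
  b <- read_bed(path)
  tibble::tibble(
    library_id = library_id, tissue = tissue, condition = condition,
    mark = mark, replicate = as.integer(replicate),
    chrom = b$chrom, pos = b$start,
    strand = if ("strand" %in% names(b)) b$strand else "."
  )
}

#' @rdname read_tags
#' @param tags Tag tibble for a single library.
#' @export
write_tags <- function(tags, path) {
  write_bed(tibble::tibble(chrom = tags$chrom, start = tags$pos,
                           end = tags$pos + 1, name = ".", score = 0,
                           strand = tags$strand), path)
}

#' Per-library sizes of a tag tibble
#'
#' @param tags Tidy tag tibble (possibly several libraries).
#' @return Tibble with one row per `library_id` and its metadata plus
#'   `n_tags`, the library size.
#' @export
library_sizes <- function(tags) {
  tags |>
    dplyr::count(.data$library_id, .data$tissue, .data$condition, .data$mark,
                 .data$replicate, name = "n_tags")
}
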