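#' Pipeline configuration
#'
#' One object holding every stage parameter of the end-to-end synthetic
#' analysis: simulate -> segment -> diff -> overlap -> annotate -> profile.
#' Defaults mirror the analysis conventions used throughout the package:
#' 1-kb windows at a 5% segmentation FDR, q < 0.01 differential calls, a
#' 25-kb overlap window, genes within 50 kb of a TSS, top 2000 regions,
#' 500-bp heatmap bins scaled to the 80th quantile. All stage seeds derive
#' deterministically from the single `seed`.
#'
#' @param seed Global integer seed.
#' @param sim A [sim_config()]; its own seed is overridden by `seed`.
#' @param window,step,alpha,iterations,merge_gap Segmentation parameters
#'   (see [segment_tags()]).
#' @param test,q_threshold,pseudocount Differential parameters (see
#'   [test_differential()]).
#' @param overlap_window,overlap_method,permutations Overlap parameters
#'   (see [venn_summary()]).
#' @param tss_flank,max_tss_distance,top_k Annotation parameters.
#' @param flank,body_bins,bin_size,quantile Profile parameters.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            sim = sim_config(),
                            window = 1000, step = window, alpha = 0.05,
                            iterations = 20, merge_gap = window,
                            test = "chisq", q_threshold = 0.01,
                            pseudocount = 0.5,
                            overlap_window = 25000,
                            overlap_method = "hypergeom",
                            permutations = 10000,
                            tss_flank = 1000, max_tss_distance = 50000,
                            top_k = 2000,
                            flank = 5000, body_bins = 40, bin_size = 500,
                            quantile = 0.8) {
  cfg <- as.list(environment())
  cfg$sim$seed <- as.integer(seed)
  class(cfg) <- "pipeline_config"
  cfg
}

stage_seed <- function(config, stage) {
  offsets <- c(simulate = 11, segment = 23, diff = 37, overlap = 47,
               annotate = 59, profile = 61)
  as.integer((as.numeric(config$seed) * 101 + offsets[[stage]]) %% 2147483647)
}

#' Run the full synthetic DIP-Seq pipeline
#'
#' Executes all six stages on simulated data, writing every intermediate as
#' a plain BED/TSV file under `out_dir` plus a JSON manifest (config hash,
#' seeds, per-stage row counts). Rerunning with the same config and seed
#' reproduces byte-identical outputs. Any stage failure aborts with the
#' failing stage named.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress per-stage progress messages.
#' @return Invisibly, a list with the in-memory stage results and
#'   `manifest`.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(...)
  run_stage <- function(name, expr) {
    say("[", name, "] ...")
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  manifest <- list(package = "dipseqr",
                   version = as.character(utils::packageVersion("dipseqr")),
                   seed = config$seed,
                   config_hash = rlang::hash(config),
                   stages = list())

  # -- simulate ---------------------------------------------------------
  sim <- run_stage("simulate", {
    cfg <- config$sim
    cfg$seed <- stage_seed(config, "simulate")
    ann <- simulate_annotation(cfg)
    libs <- simulate_libraries(cfg)
    write_chrom_sizes(ann$chrom_sizes, file.path(out_dir, "chrom.sizes"))
    write_gene_models(ann$genes, file.path(out_dir, "genes.tsv"))
    write_repeats(ann$repeats, file.path(out_dir, "repeats.tsv"))
    for (lib in unique(libs$tags$library_id)) {
      write_tags(libs$tags[libs$tags$library_id == lib, ],
                 file.path(out_dir, paste0("tags_", lib, ".bed")))
    }
    truth_bed <- libs$truth$diff_regions
    write_bed(tibble::tibble(chrom = truth_bed$chrom, start = truth_bed$start,
                             end = truth_bed$end,
                             name = paste(truth_bed$tissue, truth_bed$mark,
                                          truth_bed$direction, sep = "|"),
                             score = 0, strand = "."),
              file.path(out_dir, "truth_differential.bed"))
    list(annotation = ann, libraries = libs)
  })
  manifest$stages$simulate <- list(
    n_tags = nrow(sim$libraries$tags),
    n_libraries = dplyr::n_distinct(sim$libraries$tags$library_id),
    n_genes = nrow(sim$annotation$genes),
    n_repeats = nrow(sim$annotation$repeats))

  tags <- sim$libraries$tags
  chrom_sizes <- sim$libraries$chrom_sizes
  groups <- dplyr::distinct(tags[, c("tissue", "mark")])

  # -- segment: pooled per tissue x mark x condition --------------------
  seg <- run_stage("segment", {
    cells <- dplyr::distinct(tags[, c("tissue", "mark", "condition")])
    purrr::pmap(cells, function(tissue, mark, condition) {
      sub <- tags[tags$tissue == tissue & tags$mark == mark &
                    tags$condition == condition, ]
      s <- segment_tags(sub, chrom_sizes, window = config$window,
                        step = config$step, alpha = config$alpha,
                        iterations = config$iterations,
                        merge_gap = config$merge_gap,
                        seed = stage_seed(config, "segment"))
      slug <- paste(tissue, mark, condition, sep = "_")
      write_bed(dplyr::mutate(s$domains, name = slug, score = .data$count,
                              strand = "."),
                file.path(out_dir, paste0("domains_", slug, ".bed")))
      readr::write_tsv(tidy(s$threshold),
                       file.path(out_dir, paste0("threshold_", slug, ".tsv")))
      tibble::tibble(tissue = tissue, mark = mark, condition = condition,
                     segmentation = list(s))
    }) |> dplyr::bind_rows()
  })
  manifest$stages$segment <- list(
    n_tracks = nrow(seg),
    n_domains = sum(purrr::map_int(seg$segmentation,
                                   ~ nrow(.x$domains))))

  # -- diff: per tissue x mark ------------------------------------------
  diffs <- run_stage("diff", {
    purrr::pmap(groups, function(tissue, mark) {
      segs <- seg[seg$tissue == tissue & seg$mark == mark, ]
      regions <- merge_condition_domains(
        purrr::map(segs$segmentation, ~ .x$domains))
      sub <- tags[tags$tissue == tissue & tags$mark == mark, ]
      rc <- region_counts(regions, sub)
      tested <- test_differential(rc, test = config$test,
                                  pseudocount = config$pseudocount)
      calls <- call_differential(tested, q_threshold = config$q_threshold)
      slug <- paste(tissue, mark, sep = "_")
      readr::write_tsv(tested, file.path(out_dir, paste0("tested_", slug, ".tsv")))
      write_differential_bed(calls,
                             file.path(out_dir, paste0("differential_", slug, ".bed")))
      tibble::tibble(tissue = tissue, mark = mark,
                     tested = list(tested), calls = list(calls))
    }) |> dplyr::bind_rows()
  })
  manifest$stages$diff <- list(
    n_tested = sum(purrr::map_int(diffs$tested, nrow)),
    n_significant = sum(purrr::map_int(diffs$calls, nrow)))

  # -- overlap: per tissue, 5mC vs 5hmC ---------------------------------
  overlaps <- run_stage("overlap", {
    marks <- config$sim$marks
    purrr::map(unique(groups$tissue), function(tissue) {
      get <- function(col, mk) {
        diffs[[col]][[which(diffs$tissue == tissue & diffs$mark == mk)]]
      }
      v <- venn_summary(get("calls", marks[1]), get("calls", marks[2]),
                        universe_a = get("tested", marks[1]),
                        window = config$overlap_window,
                        method = config$overlap_method,
                        permutations = config$permutations,
                        seed = stage_seed(config, "overlap"))
      readr::write_tsv(v, file.path(out_dir, paste0("overlap_", tissue, ".tsv")))
      dplyr::mutate(v, tissue = tissue, .before = 1)
    }) |> dplyr::bind_rows()
  })
  manifest$stages$overlap <- list(n_pairs = nrow(overlaps))

  # -- annotate ----------------------------------------------------------
  ann_out <- run_stage("annotate", {
    comp <- category_composition(tags, sim$annotation$genes,
                                 tss_flank = config$tss_flank)
    readr::write_tsv(comp, file.path(out_dir, "category_composition.tsv"))
    cpm <- repeat_cpm(tags, sim$annotation$repeats)
    readr::write_tsv(cpm, file.path(out_dir, "repeat_cpm.tsv"))
    tiscmp <- if (dplyr::n_distinct(tags$tissue) == 2) {
      tc <- compare_tissue_density(cpm)
      readr::write_tsv(tc, file.path(out_dir, "tissue_comparison.tsv"))
      tc
    } else NULL
    gene_maps <- purrr::pmap(groups, function(tissue, mark) {
      calls <- diffs$calls[[which(diffs$tissue == tissue & diffs$mark == mark)]]
      ga <- regions_to_genes(calls, sim$annotation$genes,
                             max_distance = config$max_tss_distance,
                             top_k = config$top_k)
      dplyr::mutate(ga, tissue = tissue, mark = mark, .before = 1)
    }) |> dplyr::bind_rows()
    readr::write_tsv(gene_maps, file.path(out_dir, "gene_assignments.tsv"))
    list(composition = comp, cpm = cpm, tissue_comparison = tiscmp,
         gene_assignments = gene_maps)
  })
  manifest$stages$annotate <- list(
    n_gene_assignments = nrow(ann_out$gene_assignments))

  # -- profile -----------------------------------------------------------
  profiles <- run_stage("profile", {
    med_n <- stats::median(library_sizes(tags)$n_tags)
    purrr::pmap(groups, function(tissue, mark) {
      ref_cond <- config$sim$conditions[1]
      sub <- tags[tags$tissue == tissue & tags$mark == mark &
                    tags$condition == ref_cond, ]
      mm <- metagene_matrix(sub, sim$annotation$genes, flank = config$flank,
                            body_bins = config$body_bins,
                            bin_size = config$bin_size)
      slug <- paste(tissue, mark, sep = "_")
      utils::write.table(mm$matrix,
                         file.path(out_dir, paste0("metagene_", slug, ".tsv")),
                         sep = "\t", quote = FALSE, col.names = NA)
      segrow <- seg[seg$tissue == tissue & seg$mark == mark &
                      seg$condition == ref_cond, ]
      thr <- segrow$segmentation[[1]]$threshold
      wig <- background_subtracted_wiggle(sub, thr, chrom_sizes,
                                          scale_factor = med_n / max(1, nrow(sub)))
      write_wiggle(wig, bin_size = thr$window,
                   file.path(out_dir, paste0("density_", slug, ".wig")))
      tibble::tibble(tissue = tissue, mark = mark, metagene = list(mm))
    }) |> dplyr::bind_rows()
  })
  manifest$stages$profile <- list(n_matrices = nrow(profiles))

  manifest$files <- sort(setdiff(list.files(out_dir), "manifest.json"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  say("pipeline complete: ", out_dir)
  invisible(list(simulate = sim, segment = seg, diff = diffs,
                 overlap = overlaps, annotate = ann_out, profile = profiles,
                 manifest = manifest))
}
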