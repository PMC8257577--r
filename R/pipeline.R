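PIPELINE_STAGES <- c("simulate", "binarize", "learn", "decode", "annotate",
                     "methyl", "te", "expr")

#' Pipeline configuration
#'
#' Exactly one of `simulate` (a [simulation_config()]) or `paths` (a named
#' list of input files: `genome`, `track`, `genes`, `methylation`, `tes`,
#' `fpkm`, and a named list `peaks`; optional `peaks_30h`) must be given.
#'
#' @param simulate A `sim_config`, or NULL when reading real inputs.
#' @param paths Named list of input paths, or NULL when simulating.
#' @param K States to learn (default 6).
#' @param seed Root seed for fitting/decoding (default: the simulate
#'   config's seed, else 1).
#' @param alpha Binarization tail threshold (default 1e-4; used when the
#'   input track holds counts).
#' @param fpkm_threshold Expression threshold (default 1).
#' @param meth_lower,meth_upper CpG classification thresholds.
#' @param window TSS half-window bp (default 5000).
#' @param kmeans_k Bivalency cluster count (default 3).
#' @param n_restarts EM restarts (default 1).
#' @param max_iter EM iteration cap (default 200).
#' @return Validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = simulation_config(), paths = NULL,
                            K = 6, seed = NULL, alpha = 1e-4,
                            fpkm_threshold = 1, meth_lower = 0.2,
                            meth_upper = 0.8, window = 5000, kmeans_k = 3,
                            n_restarts = 1, max_iter = 200) {
  if (is.null(simulate) == is.null(paths)) {
    abort("exactly one of `simulate` or `paths` must be supplied")
  }
  if (!is.null(simulate)) stopifnot(inherits(simulate, "sim_config"))
  if (!is.null(paths)) {
    need <- c("genome", "track", "genes", "methylation", "tes", "fpkm", "peaks")
    if (!all(need %in% names(paths))) {
      abort(paste0("`paths` needs elements ", paste(need, collapse = ", ")))
    }
  }
  check_number(K, "K", lower = 1)
  check_number(alpha, "alpha", lower = 1e-300, upper = 1 - 1e-12)
  check_number(fpkm_threshold, "fpkm_threshold", lower = 0)
  check_number(meth_lower, "meth_lower", 0, 1)
  check_number(meth_upper, "meth_upper", 0, 1)
  if (meth_lower >= meth_upper) abort("meth_lower must be below meth_upper")
  check_number(window, "window", lower = 1)
  check_number(kmeans_k, "kmeans_k", lower = 1)
  structure(
    list(simulate = simulate, paths = paths, K = as.integer(K),
         seed = as.integer(seed %||% (if (!is.null(simulate)) simulate$seed else 1)),
         alpha = alpha, fpkm_threshold = fpkm_threshold,
         meth_lower = meth_lower, meth_upper = meth_upper,
         window = as.integer(window), kmeans_k = as.integer(kmeans_k),
         n_restarts = as.integer(n_restarts), max_iter = as.integer(max_iter)),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the [pipeline_config()] arguments; a `simulate`
#' mapping is passed to [simulation_config()].
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulate)) {
    y$simulate <- do.call(simulation_config, y$simulate)
  }
  do.call(pipeline_config, y)
}

load_pipeline_inputs <- function(config) {
  if (!is.null(config$simulate)) {
    epi <- simulate_epigenome(config$simulate)
    list(
      genome = epi$grid$genome, grid = epi$grid, track = epi$track,
      genes = epi$genes, annotation = epi$annotation,
      expression = epi$expression, cpgs = epi$cpgs, tes = epi$tes,
      peaks = epi$peaks$baseline, peaks_30h = epi$peaks$post30h,
      truth = epi$truth, epi = epi
    )
  } else {
    p <- config$paths
    genome <- read_genome(p$genome)
    track <- read_track_tsv(p$track, genome)
    genes <- read_gene_models(p$genes)
    peaks <- lapply(p$peaks, read_bed)
    list(
      genome = genome, grid = track$grid, track = track, genes = genes,
      annotation = build_element_partition(genes, genome),
      expression = read_fpkm(p$fpkm),
      cpgs = read_methylation(p$methylation),
      tes = read_repeatmasker(p$tes),
      peaks = peaks,
      peaks_30h = if (!is.null(p$peaks_30h)) lapply(p$peaks_30h, read_bed) else NULL,
      truth = NULL, epi = NULL
    )
  }
}

write_tsv_plain <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

#' Run the full integration pipeline
#'
#' Orchestrates simulate (or load) -> binarize -> learn -> decode ->
#' annotate -> methyl -> te -> expr, writes every stage's outputs under
#' `output_dir` and finishes with a manifest listing every file with its
#' md5 checksum, plus a run-info YAML echoing seed and parameters. The run
#' is deterministic given the config: re-running with the same seed
#' reproduces identical checksums.
#'
#' @param config A `pipeline_config`.
#' @param output_dir Output directory (created).
#' @param stages Subset of stages to run (default all). Later stages reuse
#'   earlier in-memory results and fail with the stage named if a
#'   prerequisite was gated off.
#' @return Invisibly, a list of stage results (class `pipeline_result`)
#'   including the `manifest` tibble.
#' @export
run_pipeline <- function(config, output_dir,
                         stages = PIPELINE_STAGES) {
  stopifnot(inherits(config, "pipeline_config"))
  bad <- setdiff(stages, PIPELINE_STAGES)
  if (length(bad)) abort(paste0("unknown stage(s): ", paste(bad, collapse = ", ")))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list(config = config)
  files <- character(0)
  out <- function(...) file.path(output_dir, ...)
  t0 <- Sys.time()
  stage_log <- function(stage) {
    inform(sprintf("[%s] %+.1fs %s", format(Sys.time(), "%H:%M:%S"),
                   as.numeric(difftime(Sys.time(), t0, units = "secs")), stage))
  }
  need <- function(what, stage) {
    if (is.null(res[[what]])) {
      abort(paste0("stage '", stage, "' requires '", what,
                   "' from an earlier stage that did not run"))
    }
    res[[what]]
  }

  if ("simulate" %in% stages) {
    stage_log("simulate: generating/loading inputs")
    res$inputs <- load_pipeline_inputs(config)
    if (!is.null(res$inputs$epi)) {
      files <- c(files, write_epigenome(res$inputs$epi, out("inputs"))$file)
    }
  }

  if ("binarize" %in% stages) {
    inp <- need("inputs", "binarize")
    stage_log("binarize: preparing binary observations")
    res$binary <- if (is_binary_track(inp$track)) inp$track else {
      binarize_counts(inp$track, alpha = config$alpha)
    }
    files <- c(files, write_tsv_plain(as_tibble(res$binary), out("binary_track.tsv")))
  }

  if ("learn" %in% stages) {
    track <- need("binary", "learn")
    stage_log(paste0("learn: EM fit, K = ", config$K))
    res$fit <- fit_hmm(track, K = config$K, seed = sub_seed(config$seed, "fit"),
                       n_restarts = config$n_restarts, max_iter = config$max_iter)
    files <- c(files,
               write_tsv_plain(tidy(res$fit), out("emissions.tsv")),
               write_tsv_plain(as_tibble(res$fit$params$transitions), out("transitions.tsv")),
               write_tsv_plain(res$fit$trace, out("fit_trace.tsv")))
  }

  if ("decode" %in% stages) {
    fit <- need("fit", "decode")
    track <- need("binary", "decode")
    stage_log("decode: posterior decoding")
    res$segmentation <- decode_states(fit, track, keep_posterior = FALSE)
    res$fractions <- genome_fraction(res$segmentation)
    files <- c(files, {
      write_segmentation(res$segmentation, out("segmentation.bed"))
      out("segmentation.bed")
    }, write_tsv_plain(res$fractions, out("genome_fraction.tsv")))
  }

  if ("annotate" %in% stages) {
    seg <- need("segmentation", "annotate")
    inp <- need("inputs", "annotate")
    stage_log("annotate: gene/element/peak integration")
    res$gene_states <- assign_genes_to_states(inp$genes, seg,
                                              window = config$window,
                                              peaks = inp$peaks)
    res$composition <- state_element_composition(seg, inp$annotation)
    files <- c(files,
               write_tsv_plain(res$gene_states, out("gene_states.tsv")),
               write_tsv_plain(res$composition, out("state_element_composition.tsv")))
    if (!is.null(inp$peaks_30h)) {
      res$peak_comparison <- compare_peak_sets(inp$peaks$H3K27me3,
                                               inp$peaks_30h$H3K27me3,
                                               inp$annotation)
      files <- c(files,
                 write_tsv_plain(res$peak_comparison$summary, out("peak_comparison.tsv")))
      write_bed(res$peak_comparison$unique_a[, c("chrom", "start", "end")],
                out("peaks_unique_baseline.bed"))
      write_bed(res$peak_comparison$unique_b[, c("chrom", "start", "end")],
                out("peaks_unique_30h.bed"))
      files <- c(files, out("peaks_unique_baseline.bed"), out("peaks_unique_30h.bed"))
    }
  }

  if ("methyl" %in% stages) {
    seg <- need("segmentation", "methyl")
    inp <- need("inputs", "methyl")
    stage_log("methyl: CpG integration")
    res$methylation <- state_methylation_summary(
      inp$cpgs, seg, lower = config$meth_lower, upper = config$meth_upper
    )
    files <- c(files, write_tsv_plain(res$methylation, out("methylation_by_state.tsv")))
    for (m in intersect(c("H3K9me3", "H3K27me3"), names(inp$peaks))) {
      tab <- mark_cooccupancy_methylation(inp$cpgs, inp$peaks[[m]], seg,
                                          lower = config$meth_lower,
                                          upper = config$meth_upper)
      res$mark_methylation[[m]] <- tab
      files <- c(files, write_tsv_plain(tab, out(paste0("methylation_under_", m, ".tsv"))))
    }
    res$te_metaplot <- methylation_metaplot(inp$cpgs, inp$tes)
    files <- c(files, write_tsv_plain(res$te_metaplot, out("te_methylation_metaplot.tsv")))
  }

  if ("te" %in% stages) {
    seg <- need("segmentation", "te")
    inp <- need("inputs", "te")
    stage_log("te: transposable-element integration")
    dist <- te_state_distribution(inp$tes, seg)
    res$te_distribution <- dist
    tes_grouped <- te_mark_groups(inp$tes, inp$peaks, inp$cpgs,
                                  lower = config$meth_lower,
                                  upper = config$meth_upper)
    res$te_groups <- tes_grouped
    groups <- split(tes_grouped$sw_score, tes_grouped$mark_group, drop = TRUE)
    groups <- groups[vapply(groups, length, integer(1)) >= 2]
    if (length(groups) >= 2) res$te_age_anova <- anova_tukey(groups)
    nmin <- min(500, vapply(groups, length, integer(1)))
    key <- intersect(c("meC+K9", "meC-only"), names(groups))
    if (length(key) == 2 && nmin >= 10) {
      res$te_age_test <- subsampled_age_test(
        groups[["meC+K9"]], tes_grouped$sw_score, n = nmin, reps = 100,
        seed = sub_seed(config$seed, "te"), replace = TRUE
      )
    }
    files <- c(files,
               write_tsv_plain(dist$states, out("te_state_distribution.tsv")),
               write_tsv_plain(dist$classes, out("te_class_composition.tsv")),
               write_tsv_plain(count(tes_grouped, .data$mark_group), out("te_mark_groups.tsv")))
  }

  if ("expr" %in% stages) {
    inp <- need("inputs", "expr")
    gs <- need("gene_states", "expr")
    stage_log("expr: expression and bivalency")
    res$expression_summary <- state_expression_summary(
      gs, inp$expression, baseline = names(inp$expression)[2],
      threshold = config$fpkm_threshold
    )
    files <- c(files, write_tsv_plain(res$expression_summary, out("expression_by_state.tsv")))
    if (all(c("H3K4me3", "H3K27me3") %in% names(inp$peaks))) {
      m_k4 <- tss_signal_matrix(inp$peaks$H3K4me3, inp$genes, mark = "H3K4me3",
                                window = config$window)
      m_k27 <- tss_signal_matrix(inp$peaks$H3K27me3, inp$genes, mark = "H3K27me3",
                                 window = config$window)
      res$clusters <- kmeans_bivalent_clusters(m_k4, m_k27, k = config$kmeans_k,
                                               seed = sub_seed(config$seed, "misc"))
      res$trajectories <- cluster_expression_trajectories(res$clusters, inp$expression)
      files <- c(files,
                 write_tsv_plain(res$clusters$clusters, out("bivalency_clusters.tsv")),
                 write_tsv_plain(res$trajectories, out("cluster_trajectories.tsv")))
      marked <- gs$gene_id[gs[["occ_H3K27me3"]] %||% rep(FALSE, nrow(gs))]
      base_col <- names(inp$expression)[2]
      fpkm <- setNames(inp$expression[[base_col]], inp$expression$gene_id)
      a <- fpkm[intersect(marked, names(fpkm))]
      b <- fpkm[setdiff(names(fpkm), marked)]
      if (length(a) > 1 && length(b) > 1) {
        res$k27_expression <- mark_expression_comparison(
          a, b, seed = sub_seed(config$seed, "expression")
        )
        files <- c(files, write_tsv_plain(res$k27_expression, out("k27_expression_test.tsv")))
      }
    }
  }

  info <- list(
    package = "hepachrom",
    version = as.character(utils::packageVersion("hepachrom")),
    seed = config$seed, K = config$K, alpha = config$alpha,
    fpkm_threshold = config$fpkm_threshold,
    meth_lower = config$meth_lower, meth_upper = config$meth_upper,
    window = config$window, kmeans_k = config$kmeans_k,
    stages = stages,
    simulated = !is.null(config$simulate)
  )
  yaml::write_yaml(info, out("run_info.yaml"))
  files <- unique(c(files, out("run_info.yaml")))
  manifest <- tibble(
    file = sub(paste0("^", gsub("([][{}()+*^$|\\\\.?])", "\\\\\\1", output_dir), "/?"),
               "", files),
    bytes = file.size(files),
    md5 = unname(tools::md5sum(files))
  ) |> arrange(.data$file)
  write_tsv_plain(manifest, out("manifest.tsv"))
  res$manifest <- manifest
  stage_log("done")
  invisible(structure(res, class = "pipeline_result"))
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> ", nrow(x$manifest), " output files\n", sep = "")
  invisible(x)
}
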