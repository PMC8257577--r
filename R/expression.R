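#' Classify baseline expression
#'
#' A gene is `expressed` when its FPKM exceeds 1 and `silenced` otherwise
#' (FPKM of exactly 1 is silenced).
#'
#' @param fpkm Non-negative numeric vector.
#' @param threshold Expression threshold (default 1).
#' @return Factor with levels expressed / silenced.
#' @export
classify_expression <- function(fpkm, threshold = 1) {
  if (any(is.na(fpkm)) || any(fpkm < 0)) abort("FPKM must be non-negative")
  factor(ifelse(fpkm > threshold, "expressed", "silenced"),
         levels = c("expressed", "silenced"))
}

#' Read an FPKM table (gene x timepoint TSV with header)
#' @param path Input path; first column `gene_id`, remaining columns
#'   timepoint labels.
#' @return Tibble.
#' @export
read_fpkm <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  x <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  if (names(x)[1] != "gene_id") abort("first column must be gene_id")
  as_tibble(x)
}

#' Expression classes and FPKM distribution per chromatin state
#'
#' Joins the gene-state table with baseline expression; genes missing from
#' the expression table are counted as `no-data`. Counts partition the
#' genes: per state, expressed + silenced + no-data sums to the state's
#' gene count.
#'
#' @param gene_states Tibble from [assign_genes_to_states()] (`gene_id`,
#'   `state`).
#' @param expression Expression tibble (`gene_id` plus timepoint columns).
#' @param baseline Name of the baseline timepoint column (default `0h`).
#' @param threshold FPKM threshold (default 1).
#' @return Tibble per state: `n_genes`, `n_expressed`, `n_silenced`,
#'   `n_no_data`, `frac_expressed`, FPKM quartiles.
#' @export
state_expression_summary <- function(gene_states, expression, baseline = "0h",
                                     threshold = 1) {
  if (!baseline %in% names(expression)) {
    abort(paste0("baseline column '", baseline, "' not in expression table"))
  }
  df <- left_join(gene_states[, c("gene_id", "state")],
                  expression[, c("gene_id", baseline)], by = "gene_id")
  df$fpkm <- df[[baseline]]
  missing <- is.na(df$fpkm)
  if (any(missing)) {
    inform(paste0(sum(missing), " gene(s) missing expression; counted as no-data"))
  }
  df$class <- NA_character_
  df$class[!missing] <- as.character(classify_expression(df$fpkm[!missing], threshold))
  df |>
    group_by(.data$state, .drop = FALSE) |>
    summarise(
      n_genes = n(),
      n_expressed = sum(.data$class == "expressed", na.rm = TRUE),
      n_silenced = sum(.data$class == "silenced", na.rm = TRUE),
      n_no_data = sum(is.na(.data$class)),
      frac_expressed = ifelse(.data$n_genes - .data$n_no_data > 0,
                              .data$n_expressed / (.data$n_genes - .data$n_no_data),
                              NA_real_),
      fpkm_q25 = if (any(!is.na(.data$fpkm))) unname(quantile(.data$fpkm, 0.25, na.rm = TRUE)) else NA_real_,
      fpkm_median = if (any(!is.na(.data$fpkm))) unname(median(.data$fpkm, na.rm = TRUE)) else NA_real_,
      fpkm_q75 = if (any(!is.na(.data$fpkm))) unname(quantile(.data$fpkm, 0.75, na.rm = TRUE)) else NA_real_,
      .groups = "drop"
    )
}

#' Hypergeometric enrichment of a gene set across states
#'
#' For each state, the upper-tail hypergeometric probability of observing
#' at least the overlap between the gene set and the state's genes, given
#' the universe of the gene-state table; Benjamini-Hochberg adjusted across
#' states. Gene-set members absent from the universe are dropped and
#' reported via the `n_dropped` attribute.
#'
#' @param geneset Character vector of gene ids (e.g. liver-enriched genes).
#' @param gene_states Tibble with `gene_id`, `state`.
#' @return Tibble `state`, `state_size`, `overlap`, `expected`, `p.value`,
#'   `p.adjust`.
#' @export
geneset_state_enrichment <- function(geneset, gene_states) {
  geneset <- unique(as.character(geneset))
  if (length(geneset) == 0) abort("`geneset` must be non-empty")
  universe <- unique(gene_states$gene_id)
  inset <- intersect(geneset, universe)
  n_dropped <- length(geneset) - length(inset)
  if (length(inset) == 0) abort("no gene-set member is in the universe")
  if (n_dropped > 0) {
    inform(paste0(n_dropped, " gene-set member(s) not in the universe; dropped"))
  }
  N <- length(universe)
  k <- length(inset)
  out <- gene_states |>
    distinct(.data$gene_id, .keep_all = TRUE) |>
    group_by(.data$state, .drop = FALSE) |>
    summarise(state_size = n(),
              overlap = sum(.data$gene_id %in% inset), .groups = "drop") |>
    mutate(
      expected = .data$state_size * k / N,
      p.value = phyper(.data$overlap - 1, .data$state_size,
                       N - .data$state_size, k, lower.tail = FALSE),
      p.adjust = p.adjust(.data$p.value, method = "BH")
    )
  attr(out, "n_dropped") <- n_dropped
  attr(out, "universe_size") <- N
  out
}

#' Signal matrix around transcription start sites
#'
#' For each gene, the window `[TSS - window, TSS + window)` is divided into
#' columns of `bin_width` bp; each cell holds the fraction of the column
#' covered by the signal's intervals (a binarized track mark or a peak
#' set). Rows are oriented 5' to 3' (minus-strand rows reversed); columns
#' falling off the chromosome are NA.
#'
#' @param signal Either a binary `track_matrix` (then `mark` selects the
#'   column) or an interval tibble.
#' @param genes Gene tibble (`gene_id`, `chrom`, `strand`, `tss`).
#' @param mark Mark name when `signal` is a `track_matrix`.
#' @param window Half-window in bp (default 5000).
#' @param bin_width Column width in bp (default 50).
#' @return An object of class `tss_matrix`: `values` (genes x columns),
#'   `positions` (column centres relative to the TSS), `gene_id`, `mark`.
#' @export
tss_signal_matrix <- function(signal, genes, mark = NULL, window = 5000,
                              bin_width = 50) {
  genes <- check_genes(genes)
  check_number(window, "window", lower = 1)
  check_number(bin_width, "bin_width", lower = 1)
  if (window %% bin_width != 0) abort("`window` must be a multiple of `bin_width`")
  if (inherits(signal, "track_matrix")) {
    if (is.null(mark) || !mark %in% signal$marks) {
      abort("supply `mark` (one of the track's marks)")
    }
    iv <- track_mark_intervals(signal, mark)
    genome <- signal$grid$genome
  } else {
    check_intervals(signal, "signal")
    iv <- flatten_intervals(signal)
    genome <- NULL
    if (is.null(mark)) mark <- "signal"
  }
  n_col <- as.integer(2 * window / bin_width)
  n <- nrow(genes)
  # all gene x column windows as one interval batch
  col0 <- rep(seq_len(n_col) - 1L, times = n)
  gidx <- rep(seq_len(n), each = n_col)
  cstart <- genes$tss[gidx] - window + col0 * bin_width
  cend <- cstart + bin_width
  cells <- tibble(chrom = genes$chrom[gidx], start = cstart, end = cend)
  valid <- cells$start >= 0
  if (!is.null(genome)) {
    chrlen <- setNames(genome$length, genome$chrom)
    valid <- valid & cells$end <= chrlen[cells$chrom] & !is.na(chrlen[cells$chrom])
  }
  cov <- rep(NA_real_, n * n_col)
  vc <- cells[valid, , drop = FALSE]
  if (nrow(vc) > 0) {
    vgr <- GenomicRanges::GRanges(vc$chrom, IRanges::IRanges(vc$start + 1, vc$end))
    covered <- numeric(nrow(vc))
    if (nrow(iv) > 0) {
      igr <- as_gr(iv[, c("chrom", "start", "end")])
      hits <- GenomicRanges::findOverlaps(vgr, igr, ignore.strand = TRUE)
      qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
      ov <- pmin(vc$end[qh], iv$end[sh]) - pmax(vc$start[qh], iv$start[sh])
      if (length(qh)) {
        agg <- rowsum(as.numeric(ov), qh)
        covered[as.integer(rownames(agg))] <- agg[, 1]
      }
    }
    cov[valid] <- covered / bin_width
  }
  m <- matrix(cov, nrow = n, ncol = n_col, byrow = TRUE,
              dimnames = list(genes$gene_id, NULL))
  minus <- genes$strand == "-"
  m[minus, ] <- m[minus, n_col:1, drop = FALSE]
  structure(
    list(values = m,
         positions = seq(-window + bin_width / 2, window - bin_width / 2, by = bin_width),
         gene_id = genes$gene_id, mark = mark,
         window = window, bin_width = bin_width),
    class = "tss_matrix"
  )
}

#' @export
print.tss_matrix <- function(x, ...) {
  cat("<tss_matrix> ", nrow(x$values), " genes x ", ncol(x$values),
      " position bins (", x$bin_width, " bp), mark: ", x$mark, "\n", sep = "")
  invisible(x)
}

#' K-means clustering of bivalent promoter profiles
#'
#' Concatenates each gene's H3K4me3 and H3K27me3 TSS-profile rows into one
#' feature vector and clusters with Lloyd's k-means (seeded initialisation,
#' Euclidean distance). Clusters are reported canonically, ordered by
#' descending mean H3K4me3 centroid signal, so labels are stable across
#' seeds up to sampling noise. NA cells (clipped windows) enter as 0.
#'
#' @param m_k4,m_k27 `tss_matrix` objects over the same genes, same order.
#' @param k Number of clusters (default 3).
#' @param seed Integer seed.
#' @param nstart Random starts (default 10).
#' @return An object of class `bivalent_clusters`: `clusters` (tibble
#'   `gene_id`, `cluster`), `centers`, `sizes`, `k`, `seed`.
#' @export
kmeans_bivalent_clusters <- function(m_k4, m_k27, k = 3, seed = 1, nstart = 10) {
  stopifnot(inherits(m_k4, "tss_matrix"), inherits(m_k27, "tss_matrix"))
  if (!identical(m_k4$gene_id, m_k27$gene_id)) {
    abort("the two matrices must cover the same genes in the same order")
  }
  n <- nrow(m_k4$values)
  if (k > n) abort("`k` exceeds the number of genes")
  X <- cbind(m_k4$values, m_k27$values)
  X[is.na(X)] <- 0
  km <- withr::with_seed(as.integer(seed), {
    kmeans(X, centers = k, nstart = nstart, iter.max = 100, algorithm = "Lloyd")
  })
  k4_cols <- seq_len(ncol(m_k4$values))
  ord <- order(-rowMeans(km$centers[, k4_cols, drop = FALSE]))
  relabel <- match(seq_len(k), ord)
  labels <- relabel[km$cluster]
  structure(
    list(
      clusters = tibble(gene_id = m_k4$gene_id,
                        cluster = factor(paste0("C", labels),
                                         levels = paste0("C", seq_len(k)))),
      centers = km$centers[ord, , drop = FALSE],
      sizes = as.integer(table(labels)),
      k = k, seed = seed
    ),
    class = "bivalent_clusters"
  )
}

#' @export
print.bivalent_clusters <- function(x, ...) {
  cat("<bivalent_clusters> k = ", x$k, ", sizes: ",
      paste(x$sizes, collapse = "/"), "\n", sep = "")
  invisible(x)
}

#' @method tidy bivalent_clusters
#' @export
tidy.bivalent_clusters <- function(x, ...) x$clusters

#' Mean log(FPKM + 1) trajectory per cluster
#'
#' @param clusters A `bivalent_clusters` object or a tibble with `gene_id`
#'   and `cluster` columns.
#' @param expression Expression tibble (`gene_id` plus timepoint columns).
#' @param log_base Base for `log(FPKM + 1)` (default natural log).
#' @return Tibble `cluster`, `timepoint` (ordered factor in column order),
#'   `mean_log_fpkm`, `n_genes`.
#' @export
cluster_expression_trajectories <- function(clusters, expression,
                                            log_base = exp(1)) {
  cl <- if (inherits(clusters, "bivalent_clusters")) clusters$clusters else as_tibble(clusters)
  if (!all(c("gene_id", "cluster") %in% names(cl))) {
    abort("`clusters` needs gene_id and cluster columns")
  }
  tps <- setdiff(names(expression), "gene_id")
  df <- dplyr::inner_join(cl, expression, by = "gene_id") |>
    tidyr::pivot_longer(all_of(tps), names_to = "timepoint", values_to = "fpkm")
  df |>
    mutate(timepoint = factor(.data$timepoint, levels = tps)) |>
    group_by(.data$cluster, .data$timepoint) |>
    summarise(mean_log_fpkm = mean(log1p(.data$fpkm) / log(log_base)),
              n_genes = n(), .groups = "drop")
}

#' Downsampled expression comparison between marked and unmarked genes
#'
#' The larger group is downsampled (seeded, without replacement) to the
#' smaller group's size, then a two-sided Welch t-test is applied to
#' log(FPKM + 1) (e.g. genes with vs without H3K27me3 at the TSS).
#'
#' @param fpkm_marked,fpkm_unmarked Non-negative FPKM vectors.
#' @param seed Integer seed for the downsampling.
#' @return One-row tibble: `n_per_group`, `estimate` (marked minus unmarked
#'   mean log FPKM), `statistic`, `df`, `p.value`.
#' @export
mark_expression_comparison <- function(fpkm_marked, fpkm_unmarked, seed = 1) {
  if (length(fpkm_marked) == 0 || length(fpkm_unmarked) == 0) {
    abort("both groups must be non-empty")
  }
  if (any(fpkm_marked < 0) || any(fpkm_unmarked < 0)) abort("FPKM must be non-negative")
  m <- min(length(fpkm_marked), length(fpkm_unmarked))
  withr::with_seed(as.integer(seed), {
    a <- if (length(fpkm_marked) > m) sample(fpkm_marked, m) else fpkm_marked
    b <- if (length(fpkm_unmarked) > m) sample(fpkm_unmarked, m) else fpkm_unmarked
    la <- log1p(a); lb <- log1p(b)
    if (stats::sd(la) == 0 && stats::sd(lb) == 0) {
      tibble(n_per_group = m, estimate = mean(la) - mean(lb),
             statistic = 0, df = NA_real_,
             p.value = if (mean(la) == mean(lb)) 1 else 0)
    } else {
      ht <- t.test(la, lb)
      tibble(n_per_group = m, estimate = mean(la) - mean(lb),
             statistic = unname(ht$statistic), df = unname(ht$parameter),
             p.value = ht$p.value)
    }
  })
}
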