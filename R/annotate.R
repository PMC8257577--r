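#' Assign genes to chromatin states by TSS-window majority
#'
#' For each gene, the bp of the window `[TSS - window, TSS + window)`
#' overlapping each state is computed against the segmentation; the gene is
#' assigned the state with the most bp (ties broken towards the lower state
#' index, flagged in the output). Windows are clipped at chromosome edges
#' and clipped genes flagged. When per-mark peak sets are supplied, each
#' gene also gets an `occ_<mark>` flag (>= 1 bp peak overlap inside the
#' window), and `exclude_unmarked = TRUE` drops genes whose window contains
#' no profiled mark.
#'
#' @param genes Gene tibble (`gene_id`, `chrom`, `strand`, `tss`).
#' @param seg A `state_segmentation`.
#' @param window Half-window around the TSS in bp (default 5000).
#' @param peaks Optional named list of peak interval tibbles, one per mark.
#' @param exclude_unmarked Drop genes with no mark in the window (requires
#'   `peaks`; default FALSE).
#' @return Tibble with one row per gene: `gene_id`, `chrom`, `strand`,
#'   `tss`, `state` (assigned), per-state window bp columns `bp_<state>`,
#'   `window_bp`, `tie`, `clipped`, and occupancy flags when peaks given.
#'   Genes with a TSS off the genome are skipped with a warning.
#' @export
assign_genes_to_states <- function(genes, seg, window = 5000, peaks = NULL,
                                   exclude_unmarked = FALSE) {
  stopifnot(inherits(seg, "state_segmentation"))
  check_number(window, "window", lower = 1)
  genes <- check_genes(genes)
  genome <- seg$grid$genome
  chrlen <- setNames(genome$length, genome$chrom)
  off <- !genes$chrom %in% genome$chrom |
    genes$tss < 0 | genes$tss >= chrlen[genes$chrom]
  off[is.na(off)] <- TRUE
  if (any(off)) {
    warn(paste0("skipping ", sum(off), " gene(s) with TSS off the genome"))
    genes <- genes[!off, , drop = FALSE]
  }
  K <- length(seg$states)
  win <- tibble(
    chrom = genes$chrom,
    start = pmax(genes$tss - window, 0),
    end = pmin(genes$tss + window, chrlen[genes$chrom])
  )
  clipped <- (genes$tss - window < 0) | (genes$tss + window > chrlen[genes$chrom])
  si <- state_intervals(seg)
  wgr <- as_gr(win)
  sgr <- as_gr(si[, c("chrom", "start", "end")])
  hits <- GenomicRanges::findOverlaps(wgr, sgr, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  ov_bp <- pmin(win$end[qh], si$end[sh]) - pmax(win$start[qh], si$start[sh])
  bp <- matrix(0, nrow(genes), K, dimnames = list(NULL, seg$states))
  if (length(qh)) {
    idx <- cbind(qh, as.integer(si$state[sh]))
    for (r in seq_along(qh)) bp[idx[r, 1], idx[r, 2]] <- bp[idx[r, 1], idx[r, 2]] + ov_bp[r]
  }
  assigned <- max.col(bp, ties.method = "first")
  tie <- vapply(seq_len(nrow(bp)), function(i) sum(bp[i, ] == max(bp[i, ])) > 1, logical(1))
  if (any(tie)) inform(paste0(sum(tie), " gene(s) had tied window bp; lower state index used"))
  out <- tibble(
    gene_id = genes$gene_id, chrom = genes$chrom, strand = genes$strand,
    tss = genes$tss,
    state = factor(seg$states[assigned], levels = seg$states),
    window_bp = rowSums(bp), tie = tie, clipped = unname(clipped)
  )
  colnames(bp) <- paste0("bp_", seg$states)
  out <- bind_cols(out, as_tibble(bp))
  if (!is.null(peaks)) {
    for (m in names(peaks)) {
      pk <- peaks[[m]]
      out[[paste0("occ_", m)]] <- if (nrow(pk) == 0) FALSE else {
        IRanges::overlapsAny(wgr, as_gr(pk[, c("chrom", "start", "end")]),
                             ignore.strand = TRUE)
      }
    }
    if (exclude_unmarked) {
      occ <- as.matrix(out[, paste0("occ_", names(peaks)), drop = FALSE])
      drop <- rowSums(occ) == 0
      if (any(drop)) {
        inform(paste0("excluding ", sum(drop), " gene(s) with no mark in the window"))
        out <- out[!drop, , drop = FALSE]
      }
    }
  } else if (exclude_unmarked) {
    abort("`exclude_unmarked = TRUE` requires `peaks`")
  }
  out
}

#' Cross-tabulate chromatin states against genomic elements
#'
#' Intersects the segmentation's state intervals with the element partition
#' and reports both normalisations: element fractions within each state and
#' state fractions within each element. Total bp is conserved against the
#' genome size.
#'
#' @param seg A `state_segmentation`.
#' @param annotation A `genome_annotation` on the same genome.
#' @return Tibble `state`, `element`, `bp`, `frac_of_state`,
#'   `frac_of_element`.
#' @export
state_element_composition <- function(seg, annotation) {
  stopifnot(inherits(seg, "state_segmentation"),
            inherits(annotation, "genome_annotation"))
  if (!identical(as.data.frame(seg$grid$genome), as.data.frame(annotation$genome))) {
    abort("segmentation and annotation are on different genomes")
  }
  si <- state_intervals(seg)
  el <- annotation$elements
  sgr <- as_gr(si[, c("chrom", "start", "end")])
  egr <- as_gr(el[, c("chrom", "start", "end")])
  hits <- GenomicRanges::findOverlaps(sgr, egr, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  ov <- pmin(si$end[qh], el$end[sh]) - pmax(si$start[qh], el$start[sh])
  tab <- tibble(state = si$state[qh], element = el$element[sh], bp = as.numeric(ov)) |>
    group_by(.data$state, .element = .data$element) |>
    summarise(bp = sum(.data$bp), .groups = "drop") |>
    rename(element = ".element")
  full <- tidyr::expand_grid(
    state = factor(seg$states, levels = seg$states),
    element = factor(element_levels(), levels = element_levels())
  )
  safe_frac <- function(bp) if (sum(bp) > 0) bp / sum(bp) else rep(0, length(bp))
  tab <- left_join(full, tab, by = c("state", "element")) |>
    mutate(bp = ifelse(is.na(.data$bp), 0, .data$bp)) |>
    group_by(.data$state) |>
    mutate(frac_of_state = safe_frac(.data$bp)) |>
    ungroup() |>
    group_by(.data$element) |>
    mutate(frac_of_element = safe_frac(.data$bp)) |>
    ungroup()
  tab
}

majority_element <- function(x, annotation) {
  # majority-bp element class per interval
  el <- annotation$elements
  xgr <- as_gr(x[, c("chrom", "start", "end")])
  egr <- as_gr(el[, c("chrom", "start", "end")])
  hits <- GenomicRanges::findOverlaps(xgr, egr, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  ov <- pmin(x$end[qh], el$end[sh]) - pmax(x$start[qh], el$start[sh])
  bp <- matrix(0, nrow(x), 4, dimnames = list(NULL, element_levels()))
  for (r in seq_along(qh)) {
    j <- as.integer(el$element[sh[r]])
    bp[qh[r], j] <- bp[qh[r], j] + ov[r]
  }
  factor(element_levels()[max.col(bp, ties.method = "first")],
         levels = element_levels())
}

#' Compare two peak sets and annotate the unique peaks
#'
#' A peak is "shared" when it overlaps the other set by >= 1 bp. Unique
#' peaks of each set are annotated with their majority-bp genomic element
#' when an annotation is given (the promoter-to-intergenic redistribution
#' readout).
#'
#' @param peaks_a,peaks_b Peak interval tibbles (e.g. baseline and 30 h).
#' @param annotation Optional `genome_annotation`.
#' @return An object of class `peak_comparison`: `summary` (one-row
#'   tibble), `unique_a`, `unique_b` (tibbles, with `element` and its
#'   composition when annotated).
#' @export
compare_peak_sets <- function(peaks_a, peaks_b, annotation = NULL) {
  check_intervals(peaks_a, "peaks_a"); check_intervals(peaks_b, "peaks_b")
  stats <- interval_overlap_stats(peaks_a, peaks_b)
  agr <- as_gr(peaks_a[, c("chrom", "start", "end")])
  bgr <- as_gr(peaks_b[, c("chrom", "start", "end")])
  ua <- peaks_a[!IRanges::overlapsAny(agr, bgr, ignore.strand = TRUE), , drop = FALSE]
  ub <- peaks_b[!IRanges::overlapsAny(bgr, agr, ignore.strand = TRUE), , drop = FALSE]
  if (!is.null(annotation)) {
    if (nrow(ua)) ua$element <- majority_element(ua, annotation)
    if (nrow(ub)) ub$element <- majority_element(ub, annotation)
  }
  structure(
    list(summary = bind_cols(stats,
                             tibble(n_unique_a = nrow(ua), n_unique_b = nrow(ub))),
         unique_a = as_tibble(ua), unique_b = as_tibble(ub)),
    class = "peak_comparison"
  )
}

#' @export
print.peak_comparison <- function(x, ...) {
  s <- x$summary
  cat("<peak_comparison> A: ", s$n_a, " peaks (", s$n_a_overlapping,
      " shared), B: ", s$n_b, " peaks (", s$n_b_overlapping, " shared); shared ",
      s$shared_bp, " bp\n", sep = "")
  invisible(x)
}
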