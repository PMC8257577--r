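METH_LEVELS <- c("unmethylated", "intermediate", "methylated")

#' Classify CpG methylation fractions
#'
#' A CpG is `methylated` when its methylation fraction exceeds 0.8 and
#' `unmethylated` below 0.2 (strict inequalities; exactly 0.8 or 0.2 is
#' `intermediate`).
#'
#' @param beta Numeric vector of methylation fractions in `[0, 1]`.
#' @param lower,upper Classification thresholds (defaults 0.2 and 0.8).
#' @return Factor with levels unmethylated / intermediate / methylated.
#' @export
classify_cpg <- function(beta, lower = 0.2, upper = 0.8) {
  if (any(is.na(beta)) || any(beta < 0 | beta > 1)) {
    abort("methylation fractions must lie in [0, 1]")
  }
  out <- rep("intermediate", length(beta))
  out[beta > upper] <- "methylated"
  out[beta < lower] <- "unmethylated"
  factor(out, levels = METH_LEVELS)
}

check_cpgs <- function(cpgs) {
  need <- c("chrom", "pos", "beta")
  if (!is.data.frame(cpgs) || !all(need %in% names(cpgs))) {
    abort("CpG table needs columns chrom, pos, beta (and optionally coverage)")
  }
  if (!"coverage" %in% names(cpgs)) cpgs$coverage <- NA_integer_
  as_tibble(cpgs)
}

#' Read a per-CpG methylation table
#'
#' TSV with header columns `chrom`, `pos`, `beta`, `coverage` (0-based
#' positions, beta in `[0, 1]`), or a bedGraph dialect (`chrom`, `start`,
#' `end`, value in percent) with `format = "bedgraph"`.
#'
#' @param path Input path.
#' @param format `"tsv"` (default) or `"bedgraph"`.
#' @return CpG tibble (`chrom`, `pos`, `beta`, `coverage`).
#' @export
read_methylation <- function(path, format = c("tsv", "bedgraph")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  if (format == "tsv") {
    x <- utils::read.table(path, header = TRUE, sep = "\t")
    check_cpgs(as_tibble(x))
  } else {
    x <- utils::read.table(path, header = FALSE, sep = "\t",
                           col.names = c("chrom", "start", "end", "value"))
    tibble(chrom = as.character(x$chrom), pos = as.integer(x$start),
           beta = x$value / 100, coverage = NA_integer_)
  }
}

cpg_state <- function(cpgs, seg) {
  idx <- bin_of(seg$grid, cpgs$chrom, cpgs$pos)
  st <- rep("unassigned", nrow(cpgs))
  ok <- !is.na(idx)
  st[ok] <- seg$states[seg$labels[idx[ok]]]
  factor(st, levels = c(seg$states, "unassigned"))
}

#' Per-state methylation summary
#'
#' Every CpG is counted in exactly one state (the state of the bin holding
#' its position); CpGs off the genome land in an `unassigned` bucket. CpG
#' density is CpGs per kb of state territory.
#'
#' @param cpgs CpG tibble.
#' @param seg A `state_segmentation`.
#' @param min_coverage Minimum read coverage to keep a CpG (default 5;
#'   CpGs with unknown coverage are kept).
#' @param lower,upper Classification thresholds passed to [classify_cpg()].
#' @return Tibble per state: `n_cpg`, `density_per_kb`, category counts and
#'   fractions, quartiles of beta.
#' @export
state_methylation_summary <- function(cpgs, seg, min_coverage = 5,
                                      lower = 0.2, upper = 0.8) {
  stopifnot(inherits(seg, "state_segmentation"))
  cpgs <- check_cpgs(cpgs)
  keep <- is.na(cpgs$coverage) | cpgs$coverage >= min_coverage
  cpgs <- cpgs[keep, , drop = FALSE]
  cpgs$state <- cpg_state(cpgs, seg)
  cpgs$category <- classify_cpg(cpgs$beta, lower, upper)
  state_bp <- genome_fraction(seg)
  out <- cpgs |>
    group_by(.data$state, .drop = FALSE) |>
    summarise(
      n_cpg = n(),
      n_methylated = sum(.data$category == "methylated"),
      n_unmethylated = sum(.data$category == "unmethylated"),
      n_intermediate = sum(.data$category == "intermediate"),
      beta_q25 = if (n() > 0) unname(quantile(.data$beta, 0.25)) else NA_real_,
      beta_median = if (n() > 0) unname(median(.data$beta)) else NA_real_,
      beta_q75 = if (n() > 0) unname(quantile(.data$beta, 0.75)) else NA_real_,
      .groups = "drop"
    )
  out <- left_join(out, rename(state_bp, state_bp = "bp")[, c("state", "state_bp")],
                   by = "state")
  out |>
    mutate(
      density_per_kb = ifelse(is.na(.data$state_bp) | .data$state_bp == 0,
                              NA_real_, .data$n_cpg / .data$state_bp * 1000),
      frac_methylated = ifelse(.data$n_cpg > 0, .data$n_methylated / .data$n_cpg, NA_real_),
      frac_unmethylated = ifelse(.data$n_cpg > 0, .data$n_unmethylated / .data$n_cpg, NA_real_)
    )
}

#' Methylation of CpGs under a mark, split by chromatin state
#'
#' Restricts the CpG table to positions covered (>= 1 bp) by the mark's
#' intervals, then tabulates methylation categories per state, with an
#' `all` row giving the overall under-mark beta distribution.
#'
#' @param cpgs CpG tibble.
#' @param mark Interval tibble of the mark's peaks (or 1-bins).
#' @param seg A `state_segmentation`.
#' @inheritParams state_methylation_summary
#' @return Tibble per state plus an `all` row: counts, category fractions,
#'   beta quartiles.
#' @export
mark_cooccupancy_methylation <- function(cpgs, mark, seg, min_coverage = 5,
                                         lower = 0.2, upper = 0.8) {
  stopifnot(inherits(seg, "state_segmentation"))
  cpgs <- check_cpgs(cpgs)
  check_intervals(mark, "mark")
  keep <- is.na(cpgs$coverage) | cpgs$coverage >= min_coverage
  cpgs <- cpgs[keep, , drop = FALSE]
  if (nrow(mark) == 0 || nrow(cpgs) == 0) {
    under <- cpgs[0, , drop = FALSE]
  } else {
    cgr <- GenomicRanges::GRanges(cpgs$chrom, IRanges::IRanges(cpgs$pos + 1L, cpgs$pos + 1L))
    under <- cpgs[IRanges::overlapsAny(cgr, as_gr(mark[, c("chrom", "start", "end")]),
                                       ignore.strand = TRUE), , drop = FALSE]
  }
  under$state <- cpg_state(under, seg)
  under$category <- classify_cpg(under$beta, lower, upper)
  per_state <- under |>
    group_by(.data$state, .drop = FALSE) |>
    summarise(
      n_cpg = n(),
      n_methylated = sum(.data$category == "methylated"),
      n_unmethylated = sum(.data$category == "unmethylated"),
      n_intermediate = sum(.data$category == "intermediate"),
      beta_median = if (n() > 0) unname(median(.data$beta)) else NA_real_,
      .groups = "drop"
    )
  overall <- tibble(
    state = factor("all"),
    n_cpg = nrow(under),
    n_methylated = sum(under$category == "methylated"),
    n_unmethylated = sum(under$category == "unmethylated"),
    n_intermediate = sum(under$category == "intermediate"),
    beta_median = if (nrow(under) > 0) unname(median(under$beta)) else NA_real_
  )
  out <- bind_rows(mutate(per_state, state = as.character(.data$state)),
                   mutate(overall, state = as.character(.data$state)))
  mutate(out, frac_methylated = ifelse(.data$n_cpg > 0,
                                       .data$n_methylated / .data$n_cpg, NA_real_))
}

#' Winsorized mean
#'
#' Values below the lower percentile are raised to it and values above the
#' upper percentile lowered to it (percentiles by linear interpolation of
#' order statistics), then averaged. With limits (0, 100) this is the plain
#' mean.
#'
#' @param values Non-empty numeric vector.
#' @param lower_pct,upper_pct Percentile limits (defaults 1 and 99).
#' @return Scalar.
#' @export
winsorized_mean <- function(values, lower_pct = 1, upper_pct = 99) {
  values <- values[!is.na(values)]
  if (length(values) == 0) abort("cannot winsorize an empty vector")
  if (lower_pct > upper_pct) abort("lower_pct must be <= upper_pct")
  q <- quantile(values, c(lower_pct, upper_pct) / 100, names = FALSE, type = 7)
  mean(pmin(pmax(values, q[1]), q[2]))
}

#' Metaplot of CpG methylation over a region set
#'
#' Each region is divided into `n_bins` equal-length bins (strand-aware:
#' bin 1 is the 5' end of the element); CpG methylation fractions are
#' pooled per bin index across regions and summarised by the winsorized
#' mean (1-99 percentile by default). Built for transposons of unequal
#' length, but any region set works.
#'
#' @param cpgs CpG tibble.
#' @param regions Interval tibble (optional `strand` column).
#' @param n_bins Number of metaplot bins (default 40).
#' @param lower_pct,upper_pct Winsorizing limits.
#' @param min_coverage Minimum CpG coverage (default 5).
#' @return Tibble `bin` (1..n_bins), `n_cpg`, `mean_beta` (NA where a bin
#'   received no CpGs).
#' @export
methylation_metaplot <- function(cpgs, regions, n_bins = 40,
                                 lower_pct = 1, upper_pct = 99, min_coverage = 5) {
  cpgs <- check_cpgs(cpgs)
  check_intervals(regions, "regions")
  if (nrow(regions) == 0) abort("`regions` must be non-empty")
  check_number(n_bins, "n_bins", lower = 1)
  keep <- is.na(cpgs$coverage) | cpgs$coverage >= min_coverage
  cpgs <- cpgs[keep, , drop = FALSE]
  cgr <- GenomicRanges::GRanges(cpgs$chrom, IRanges::IRanges(cpgs$pos + 1L, cpgs$pos + 1L))
  rgr <- as_gr(regions[, c("chrom", "start", "end")])
  hits <- GenomicRanges::findOverlaps(cgr, rgr, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  if (length(qh) == 0) {
    return(tibble(bin = seq_len(n_bins), n_cpg = 0L, mean_beta = NA_real_))
  }
  offset <- cpgs$pos[qh] - regions$start[sh]
  width <- regions$end[sh] - regions$start[sh]
  idx <- pmin(floor(offset * n_bins / width), n_bins - 1)
  if ("strand" %in% names(regions)) {
    minus <- regions$strand[sh] == "-"
    minus[is.na(minus)] <- FALSE
    idx[minus] <- n_bins - 1 - idx[minus]
  }
  df <- tibble(bin = as.integer(idx) + 1L, beta = cpgs$beta[qh])
  out <- df |>
    group_by(.data$bin) |>
    summarise(n_cpg = n(),
              mean_beta = winsorized_mean(.data$beta, lower_pct, upper_pct),
              .groups = "drop")
  left_join(tibble(bin = seq_len(n_bins)), out, by = "bin") |>
    mutate(n_cpg = ifelse(is.na(.data$n_cpg), 0L, .data$n_cpg))
}
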