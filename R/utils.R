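#' @importFrom rlang abort warn inform %||%
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join bind_rows bind_cols n across all_of rename count distinct pull
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom purrr map map2 map_dbl map_int map_chr pmap imap
#' @importFrom stats ppois rbeta rpois rlnorm rnorm runif rgamma setNames
#'   quantile aov TukeyHSD t.test phyper p.adjust kmeans qpois median
#' @importFrom utils head tail
NULL

# Deterministic sub-seed for a named substream hanging off one root seed.
# Kept strictly below 2^31 so it is always a valid R integer seed.
sub_seed <- function(seed, stream) {
  offsets <- c(
    tracks = 101L, genes = 202L, expression = 303L, methylome = 404L,
    te = 505L, peaks = 606L, fit = 707L, decode = 808L, misc = 909L
  )
  off <- offsets[[stream]] %||% abort(paste0("unknown seed stream: ", stream))
  as.integer((as.numeric(seed) + off) %% 2147483647)
}

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single number in [%s, %s]", name, lower, upper))
  }
  invisible(x)
}

# genome: tibble with columns chrom, length
check_genome <- function(genome) {
  if (!is.data.frame(genome) || !all(c("chrom", "length") %in% names(genome))) {
    abort("`genome` must be a data frame with columns `chrom` and `length`")
  }
  if (anyDuplicated(genome$chrom)) abort("duplicated chromosome names in genome")
  if (any(genome$length <= 0)) abort("chromosome lengths must be positive")
  as_tibble(genome)
}

check_intervals <- function(x, name = "intervals") {
  if (!is.data.frame(x) || !all(c("chrom", "start", "end") %in% names(x))) {
    abort(sprintf("`%s` must have columns chrom, start, end", name))
  }
  if (nrow(x) > 0) {
    if (any(x$start < 0)) abort(sprintf("`%s`: negative start coordinates", name))
    if (any(x$end <= x$start)) abort(sprintf("`%s`: end <= start", name))
  }
  invisible(x)
}

# tibble (chrom, start, end [, strand]) -> GRanges; 0-based half-open in,
# 1-based closed inside GRanges.
as_gr <- function(x, genome = NULL) {
  if (nrow(x) == 0) return(GenomicRanges::GRanges())
  strand <- if ("strand" %in% names(x)) {
    s <- as.character(x$strand)
    s[is.na(s) | !s %in% c("+", "-")] <- "*"
    s
  } else "*"
  if (!is.null(genome)) {
    genome <- check_genome(genome)
    seqlengths <- setNames(genome$length, genome$chrom)
    bad <- setdiff(unique(as.character(x$chrom)), genome$chrom)
    if (length(bad)) abort(paste0("chromosomes absent from genome: ", paste(bad, collapse = ", ")))
    if (nrow(x) > 0 && any(x$end > seqlengths[as.character(x$chrom)])) {
      abort("interval beyond chromosome bounds")
    }
  }
  GenomicRanges::GRanges(
    seqnames = as.character(x$chrom),
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = strand
  )
}

state_labels <- function(K) paste0("S", seq_len(K))

# -- light-weight per-chromosome IRanges backend for set arithmetic --------
# (GRanges dispatch is too heavy for the tight loops in the partition and
# coverage code; chromosomes are handled as parallel IRanges lists)

irl_of <- function(x, chroms) {
  idx <- split(seq_len(nrow(x)), factor(x$chrom, levels = chroms))
  lapply(idx, function(i) IRanges::IRanges(start = x$start[i] + 1L, end = x$end[i]))
}

irl_tbl <- function(irl) {
  n <- vapply(irl, length, integer(1))
  tibble(
    chrom = rep(names(irl), n),
    start = unlist(lapply(irl, IRanges::start), use.names = FALSE) - 1L,
    end = unlist(lapply(irl, IRanges::end), use.names = FALSE)
  )
}

irl_map2 <- function(f, a, b) {
  out <- lapply(names(a), function(ch) f(a[[ch]], b[[ch]]))
  names(out) <- names(a)
  out
}

irl_reduce <- function(irl) lapply(irl, IRanges::reduce)
irl_setdiff <- function(a, b) irl_map2(IRanges::setdiff, a, b)
irl_intersect <- function(a, b) irl_map2(IRanges::intersect, a, b)
irl_union <- function(a, b) irl_map2(IRanges::union, a, b)
irl_width <- function(irl) sum(vapply(irl, function(r) sum(as.numeric(IRanges::width(r))), numeric(1)))
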