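#' Tile a genome into fixed-width bins
#'
#' Bins tile each chromosome left to right; the last bin of a chromosome may
#' be shorter than `bin_size`. Bin indices are global (1-based), chromosome
#' by chromosome in genome order.
#'
#' @param genome Genome tibble (`chrom`, `length`).
#' @param bin_size Bin width in bp (default 200).
#' @return An object of class `bin_grid`.
#' @export
bin_grid <- function(genome, bin_size = 200) {
  genome <- check_genome(genome)
  check_number(bin_size, "bin_size", lower = 1)
  nb <- as.integer(ceiling(genome$length / bin_size))
  structure(
    list(
      genome = genome,
      bin_size = as.integer(bin_size),
      chrom_bins = tibble(chrom = genome$chrom, n_bins = nb,
                          offset = cumsum(c(0L, head(nb, -1)))),
      n_bins = sum(nb)
    ),
    class = "bin_grid"
  )
}

#' @export
print.bin_grid <- function(x, ...) {
  cat("<bin_grid> ", x$n_bins, " bins of ", x$bin_size, " bp over ",
      nrow(x$genome), " chromosome(s)\n", sep = "")
  invisible(x)
}

#' Genomic intervals of every bin in a grid
#' @param grid A `bin_grid`.
#' @return Tibble `bin`, `chrom`, `start`, `end` (last bin per chromosome
#'   clipped to the chromosome length).
#' @export
bin_intervals <- function(grid) {
  stopifnot(inherits(grid, "bin_grid"))
  cb <- grid$chrom_bins
  idx <- rep(seq_len(nrow(cb)), cb$n_bins)
  local <- sequence(cb$n_bins) - 1L
  start <- local * grid$bin_size
  tibble(
    bin = seq_len(grid$n_bins),
    chrom = cb$chrom[idx],
    start = start,
    end = pmin(start + grid$bin_size, grid$genome$length[idx])
  )
}

# global bin index of positions (vectorised); NA when off-genome
bin_of <- function(grid, chrom, pos) {
  cb <- grid$chrom_bins
  i <- match(chrom, cb$chrom)
  local <- pos %/% grid$bin_size
  out <- cb$offset[i] + local + 1L
  out[is.na(i) | pos < 0 | pos >= grid$genome$length[i]] <- NA_integer_
  as.integer(out)
}

#' Construct a per-bin track matrix
#'
#' @param values Numeric matrix, bins x marks (binary after binarization, or
#'   non-negative counts before).
#' @param grid The `bin_grid` the rows refer to.
#' @param marks Character vector of mark names (defaults to the matrix
#'   column names).
#' @return An object of class `track_matrix`.
#' @export
track_matrix <- function(values, grid, marks = colnames(values)) {
  stopifnot(inherits(grid, "bin_grid"))
  values <- as.matrix(values)
  if (is.null(marks)) abort("mark names are required")
  if (nrow(values) != grid$n_bins) abort("track rows must equal grid bins")
  if (ncol(values) != length(marks)) abort("one column per mark required")
  if (any(values < 0) || anyNA(values)) abort("track values must be non-negative")
  colnames(values) <- marks
  structure(list(grid = grid, marks = marks, values = values),
            class = "track_matrix")
}

#' @export
print.track_matrix <- function(x, ...) {
  kind <- if (is_binary_track(x)) "binary" else "count"
  cat("<track_matrix> ", nrow(x$values), " bins x ", length(x$marks),
      " marks (", kind, "): ", paste(x$marks, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @method as_tibble track_matrix
#' @export
as_tibble.track_matrix <- function(x, ...) {
  bind_cols(bin_intervals(x$grid), as_tibble(x$values))
}

is_binary_track <- function(track) all(track$values %in% c(0, 1))

#' Minimal count called "present" under a Poisson background
#'
#' Smallest integer `c >= 1` such that the upper-tail probability
#' `P(X >= c)` of a Poisson(`lambda`) background is at most `alpha`.
#' Count 0 is never called present since `P(X >= 0) = 1`.
#'
#' @param lambda Expected background reads per bin (> 0).
#' @param alpha Upper-tail threshold, in (0, 1).
#' @return Integer threshold.
#' @export
poisson_min_count <- function(lambda, alpha) {
  check_number(lambda, "lambda")
  if (lambda <= 0) abort("`lambda` must be > 0")
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    abort("`alpha` must be in (0, 1)")
  }
  # P(X >= c) = ppois(c - 1, lower.tail = FALSE); qpois gives the ballpark,
  # then walk to the exact minimum.
  cc <- max(1L, as.integer(qpois(alpha, lambda, lower.tail = FALSE)) - 1L)
  while (ppois(cc - 1, lambda, lower.tail = FALSE) > alpha) cc <- cc + 1L
  while (cc > 1L && ppois(cc - 2, lambda, lower.tail = FALSE) <= alpha) cc <- cc - 1L
  cc
}

#' Binarize a count track against per-mark Poisson backgrounds
#'
#' The background rate for each mark is its genome-wide mean count per bin;
#' a bin is called present (1) when its count reaches
#' [poisson_min_count()] for that rate. Marks are treated independently.
#' An all-zero mark is emitted all-zero with a warning.
#'
#' @param track A count `track_matrix` (non-negative integers).
#' @param alpha Poisson upper-tail threshold (default 1e-4).
#' @return A binary `track_matrix`.
#' @export
binarize_counts <- function(track, alpha = 1e-4) {
  stopifnot(inherits(track, "track_matrix"))
  v <- track$values
  if (any(v != round(v))) abort("counts must be integers")
  out <- matrix(0L, nrow(v), ncol(v), dimnames = dimnames(v))
  for (j in seq_len(ncol(v))) {
    lambda <- mean(v[, j])
    if (lambda == 0) {
      warn(paste0("mark '", track$marks[j], "' has no signal; emitted all-zero"))
      next
    }
    thr <- poisson_min_count(lambda, alpha)
    out[, j] <- as.integer(v[, j] >= thr)
  }
  track_matrix(out, track$grid, track$marks)
}

#' Binarize per-mark peak calls onto a bin grid
#'
#' A bin is set to 1 for a mark iff it overlaps (>= 1 bp) any peak of that
#' mark.
#'
#' @param peaks Named list of interval tibbles, one per mark.
#' @param grid A `bin_grid`.
#' @return A binary `track_matrix` with one column per peak set.
#' @export
binarize_from_peaks <- function(peaks, grid) {
  stopifnot(inherits(grid, "bin_grid"))
  if (!is.list(peaks) || is.null(names(peaks)) || any(!nzchar(names(peaks)))) {
    abort("`peaks` must be a named list of interval tibbles")
  }
  bins <- bin_intervals(grid)
  bgr <- as_gr(bins[, c("chrom", "start", "end")])
  out <- matrix(0L, grid$n_bins, length(peaks),
                dimnames = list(NULL, names(peaks)))
  for (j in seq_along(peaks)) {
    p <- peaks[[j]]
    check_intervals(p, names(peaks)[j])
    if (nrow(p) == 0) next
    pgr <- as_gr(p[, c("chrom", "start", "end")], genome = grid$genome)
    out[IRanges::overlapsAny(bgr, pgr, ignore.strand = TRUE), j] <- 1L
  }
  track_matrix(out, grid, names(peaks))
}

#' Write / read a dense track matrix as TSV
#'
#' Columns: `chrom`, `start`, `end`, then one column per mark.
#' @param track A `track_matrix`.
#' @param path Output path.
#' @export
write_track_tsv <- function(track, path) {
  stopifnot(inherits(track, "track_matrix"))
  utils::write.table(as.data.frame(as_tibble(track))[, -1], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_track_tsv
#' @param genome Genome tibble matching the file's bins.
#' @export
read_track_tsv <- function(path, genome) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  x <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  bin_size <- max(x$end - x$start)
  grid <- bin_grid(genome, bin_size)
  if (nrow(x) != grid$n_bins) abort("track file does not tile the genome")
  marks <- setdiff(names(x), c("chrom", "start", "end"))
  track_matrix(as.matrix(x[, marks, drop = FALSE]), grid, marks)
}

#' Write each mark's present bins as a merged BED file
#' @param track Binary `track_matrix`.
#' @param dir Output directory; one `<mark>.bed` per mark.
#' @return Tibble of written paths.
#' @export
write_track_beds <- function(track, dir) {
  stopifnot(inherits(track, "track_matrix"), is_binary_track(track))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  bins <- bin_intervals(track$grid)
  paths <- map_chr(track$marks, function(m) {
    p <- file.path(dir, paste0(gsub("[^A-Za-z0-9._-]", "_", m), ".bed"))
    on <- bins[track$values[, m] == 1, c("chrom", "start", "end")]
    write_bed(flatten_intervals(on), p)
    p
  })
  tibble(mark = track$marks, path = paths)
}
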