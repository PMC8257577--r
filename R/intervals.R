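#' Read a chromosome-size file
#'
#' Two-column whitespace-delimited file: chromosome name, length in bp.
#'
#' @param path Path to the genome (chrom-size) file.
#' @return A tibble with columns `chrom`, `length`.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  x <- utils::read.table(path, header = FALSE, col.names = c("chrom", "length"),
                         colClasses = c("character", "numeric"))
  check_genome(as_tibble(x))
}

#' Write a chromosome-size file
#' @param genome Tibble with columns `chrom`, `length`.
#' @param path Output path.
#' @export
write_genome <- function(genome, path) {
  genome <- check_genome(genome)
  utils::write.table(genome[, c("chrom", "length")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read intervals from a BED file
#'
#' Accepts BED3 and wider dialects (name, score, strand used when present).
#' Coordinates are 0-based half-open. Malformed lines (fewer than three
#' fields, non-numeric or negative coordinates, `end <= start`) are rejected
#' with their line numbers.
#'
#' @param path Path to a BED file.
#' @param genome Optional genome tibble; if given, intervals are checked
#'   against chromosome bounds and the genome is attached as an attribute.
#' @return A tibble with columns `chrom`, `start`, `end` and, when present in
#'   the file, `name`, `score`, `strand`, sorted by (chrom, start, end).
#' @export
read_bed <- function(path, genome = NULL) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines)]
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  if (length(lines) == 0) {
    out <- tibble(chrom = character(), start = integer(), end = integer())
    attr(out, "genome") <- genome
    return(out)
  }
  fields <- strsplit(lines, "[ \t]+")
  nf <- lengths(fields)
  bad <- which(nf < 3)
  get_col <- function(i) vapply(fields, function(f) if (length(f) >= i) f[[i]] else NA_character_, character(1))
  chrom <- get_col(1)
  start <- suppressWarnings(as.numeric(get_col(2)))
  end <- suppressWarnings(as.numeric(get_col(3)))
  bad <- sort(unique(c(bad, which(is.na(start) | is.na(end) | start < 0 | end <= start))))
  if (length(bad)) {
    abort(paste0(
      "malformed BED line(s) ", paste(head(bad, 10), collapse = ", "),
      if (length(bad) > 10) " ..." else "",
      " in ", path, " (need >=3 fields, start >= 0, end > start)"
    ))
  }
  out <- tibble(chrom = chrom, start = as.integer(start), end = as.integer(end))
  if (max(nf) >= 4) out$name <- get_col(4)
  if (max(nf) >= 5) out$score <- suppressWarnings(as.numeric(get_col(5)))
  if (max(nf) >= 6) out$strand <- get_col(6)
  if (!is.null(genome)) as_gr(out, genome) # bounds check
  out <- arrange(out, .data$chrom, .data$start, .data$end)
  attr(out, "genome") <- genome
  out
}

#' Write intervals to a BED file
#' @param x Interval tibble (`chrom`, `start`, `end`, optionally `name`,
#'   `score`, `strand`).
#' @param path Output path.
#' @export
write_bed <- function(x, path) {
  check_intervals(x)
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"), names(x))
  # BED columns are positional: stop at the first absent one
  want <- c("chrom", "start", "end", "name", "score", "strand")
  upto <- which(!want %in% cols)
  cols <- if (length(upto)) want[seq_len(min(upto) - 1)] else want
  utils::write.table(as.data.frame(x)[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Flatten intervals to non-overlapping sorted form
#'
#' Merges overlapping or bookended intervals per chromosome (strand ignored).
#' Idempotent; the flattened total length is independent of input order.
#'
#' @param x Interval tibble.
#' @return Tibble `chrom`, `start`, `end`, sorted, non-overlapping.
#' @export
flatten_intervals <- function(x) {
  check_intervals(x)
  if (nrow(x) == 0) return(tibble(chrom = character(), start = integer(), end = integer()))
  chroms <- sort(unique(as.character(x$chrom)))
  irl_tbl(irl_reduce(irl_of(x, chroms)))
}

#' Total base pairs covered by an interval set (after flattening)
#' @param x Interval tibble.
#' @return Numeric scalar, bp.
#' @export
intervals_bp <- function(x) {
  f <- flatten_intervals(x)
  sum(as.numeric(f$end - f$start))
}

check_genes <- function(genes) {
  need <- c("gene_id", "chrom", "strand", "start", "end")
  if (!is.data.frame(genes) || !all(need %in% names(genes))) {
    abort(paste0("`genes` must have columns ", paste(need, collapse = ", ")))
  }
  genes <- as_tibble(genes)
  if (!"tss" %in% names(genes)) {
    genes$tss <- ifelse(genes$strand == "-", genes$end - 1L, genes$start)
  }
  unstranded <- !genes$strand %in% c("+", "-")
  if (any(unstranded)) {
    warn(paste0(sum(unstranded), " unstranded gene(s) treated as '+'"))
    genes$strand[unstranded] <- "+"
    genes$tss[unstranded] <- genes$start[unstranded]
  }
  genes
}

# exon tibble(gene_id, start, end) from genes (list-columns exon_starts /
# exon_ends), falling back to the whole transcript span
gene_exons <- function(genes) {
  if (all(c("exon_starts", "exon_ends") %in% names(genes))) {
    tibble(
      gene_id = rep(genes$gene_id, lengths(genes$exon_starts)),
      chrom = rep(genes$chrom, lengths(genes$exon_starts)),
      start = unlist(genes$exon_starts, use.names = FALSE),
      end = unlist(genes$exon_ends, use.names = FALSE)
    )
  } else {
    tibble(gene_id = genes$gene_id, chrom = genes$chrom,
           start = genes$start, end = genes$end)
  }
}

#' Partition the genome into promoter / exon / intron / intergenic
#'
#' Proximal promoters are the 500 bp (configurable) upstream of each TSS,
#' strand-aware. Where element classes overlap, precedence is
#' promoter > exon > intron > intergenic, so the four classes are disjoint
#' and jointly cover the genome exactly once.
#'
#' @param genes Gene-model tibble (`gene_id`, `chrom`, `strand`, `start`,
#'   `end`, optional `tss` and exon list-columns `exon_starts`/`exon_ends`;
#'   coordinates 0-based half-open). Genes with an exon outside the
#'   transcript span are dropped with a warning.
#' @param genome Genome tibble (`chrom`, `length`).
#' @param promoter_width Upstream promoter extent in bp (default 500).
#' @return An object of class `genome_annotation`: list with `genes`,
#'   `elements` (tibble `chrom`, `start`, `end`, `element`), `genome`,
#'   `promoter_width`.
#' @export
build_element_partition <- function(genes, genome, promoter_width = 500) {
  genome <- check_genome(genome)
  check_number(promoter_width, "promoter_width", lower = 1)
  genes <- check_genes(genes)
  if (nrow(genes) > 0) {
    bad_chrom <- !genes$chrom %in% genome$chrom
    if (any(bad_chrom)) abort("gene on chromosome absent from genome")
    exons <- gene_exons(genes)
    span <- genes[match(exons$gene_id, genes$gene_id), c("start", "end")]
    bad <- exons$start < span$start | exons$end > span$end
    if (any(bad)) {
      drop_ids <- unique(exons$gene_id[bad])
      warn(paste0("dropping ", length(drop_ids),
                  " gene(s) with exons outside the transcript span"))
      genes <- filter(genes, !.data$gene_id %in% drop_ids)
    }
  }

  chroms <- genome$chrom
  genome_irl <- lapply(setNames(seq_along(chroms), chroms), function(i) {
    IRanges::IRanges(1L, genome$length[i])
  })
  if (nrow(genes) == 0) {
    empty <- lapply(genome_irl, function(.) IRanges::IRanges())
    prom <- exon <- intron <- empty
  } else {
    chrlen <- setNames(genome$length, genome$chrom)
    pstart <- ifelse(genes$strand == "-", genes$tss + 1L, genes$tss - promoter_width)
    pend <- ifelse(genes$strand == "-", genes$tss + 1L + promoter_width, genes$tss)
    pstart <- pmax(pstart, 0)
    pend <- pmin(pend, chrlen[genes$chrom])
    prom_tbl <- tibble(chrom = genes$chrom, start = pstart, end = pend)
    prom_tbl <- prom_tbl[prom_tbl$end > prom_tbl$start, ]
    prom <- irl_reduce(irl_of(prom_tbl, chroms))
    exons <- gene_exons(genes)
    exon <- irl_reduce(irl_of(exons, chroms))
    span <- irl_reduce(irl_of(genes, chroms))
    intron <- irl_setdiff(span, exon)
  }
  exon <- irl_setdiff(exon, prom)
  intron <- irl_setdiff(intron, irl_union(prom, exon))
  genic <- irl_union(irl_union(prom, exon), intron)
  intergenic <- irl_setdiff(genome_irl, genic)

  to_tbl <- function(irl, el) {
    out <- irl_tbl(irl)
    out$element <- rep(el, nrow(out))
    out
  }
  elements <- bind_rows(
    to_tbl(prom, "promoter"), to_tbl(exon, "exon"),
    to_tbl(intron, "intron"), to_tbl(intergenic, "intergenic")
  )
  elements$element <- factor(elements$element, levels = element_levels())
  elements <- arrange(elements, .data$chrom, .data$start)
  structure(
    list(genes = genes, elements = elements, genome = genome,
         promoter_width = promoter_width),
    class = "genome_annotation"
  )
}

element_levels <- function() c("promoter", "exon", "intron", "intergenic")

#' @export
print.genome_annotation <- function(x, ...) {
  bp <- x$elements |>
    group_by(.data$element) |>
    summarise(bp = sum(as.numeric(.data$end - .data$start)), .groups = "drop")
  cat("<genome_annotation> ", nrow(x$genes), " genes, ",
      sum(as.numeric(x$genome$length)), " bp genome\n", sep = "")
  print(bp)
  invisible(x)
}

#' Base pairs of a query interval set in each genomic element class
#'
#' The query is flattened first; total bp is conserved exactly (integer
#' arithmetic) because the element partition is disjoint and exhaustive.
#'
#' @param query Interval tibble.
#' @param annotation A `genome_annotation`.
#' @return Tibble `element`, `bp`, `fraction` (fractions sum to 1 for a
#'   non-empty query; all zero for an empty one).
#' @export
coverage_by_category <- function(query, annotation) {
  stopifnot(inherits(annotation, "genome_annotation"))
  check_intervals(query, "query")
  if (nrow(query) == 0) {
    return(tibble(element = factor(element_levels(), levels = element_levels()),
                  bp = 0, fraction = 0))
  }
  genome <- annotation$genome
  chrlen <- setNames(genome$length, genome$chrom)
  bad <- setdiff(unique(as.character(query$chrom)), genome$chrom)
  if (length(bad)) abort(paste0("chromosomes absent from genome: ", paste(bad, collapse = ", ")))
  if (any(query$end > chrlen[as.character(query$chrom)])) {
    abort("interval beyond chromosome bounds")
  }
  q_irl <- irl_reduce(irl_of(query, genome$chrom))
  el <- annotation$elements
  bp <- vapply(element_levels(), function(e) {
    irl_width(irl_intersect(q_irl, irl_of(el[el$element == e, ], genome$chrom)))
  }, numeric(1))
  total <- sum(bp)
  tibble(
    element = factor(element_levels(), levels = element_levels()),
    bp = unname(bp),
    fraction = if (total > 0) unname(bp) / total else 0
  )
}

#' Overlap accounting between two interval sets
#'
#' An interval "overlaps" the other set when they share at least 1 bp.
#' Shared bp is symmetric; `unique_bp_a + shared_bp` equals the flattened
#' length of `a`.
#'
#' @param a,b Interval tibbles. If both carry a `genome` attribute (as set by
#'   [read_bed()]) the genomes must be identical.
#' @return One-row tibble: `n_a`, `n_b`, `n_a_overlapping`,
#'   `n_b_overlapping`, `shared_bp`, `unique_bp_a`, `unique_bp_b`.
#' @export
interval_overlap_stats <- function(a, b) {
  check_intervals(a, "a"); check_intervals(b, "b")
  ga <- attr(a, "genome"); gb <- attr(b, "genome")
  if (!is.null(ga) && !is.null(gb) && !identical(as.data.frame(ga), as.data.frame(gb))) {
    abort("interval sets are on different genomes")
  }
  agr <- as_gr(a[, c("chrom", "start", "end")])
  bgr <- as_gr(b[, c("chrom", "start", "end")])
  fa <- GenomicRanges::reduce(agr); fb <- GenomicRanges::reduce(bgr)
  shared <- sum(as.numeric(GenomicRanges::width(
    GenomicRanges::intersect(fa, fb, ignore.strand = TRUE)
  )))
  len_a <- sum(as.numeric(GenomicRanges::width(fa)))
  len_b <- sum(as.numeric(GenomicRanges::width(fb)))
  tibble(
    n_a = length(agr),
    n_b = length(bgr),
    n_a_overlapping = sum(IRanges::overlapsAny(agr, bgr)),
    n_b_overlapping = sum(IRanges::overlapsAny(bgr, agr)),
    shared_bp = shared,
    unique_bp_a = len_a - shared,
    unique_bp_b = len_b - shared
  )
}

#' Read gene models
#'
#' `format = "bed12"` reads standard BED12 (blocks become exons). `format =
#' "tsv"` reads a GTF-lite table with header columns `gene_id`, `chrom`,
#' `strand`, `start`, `end` and optional comma-separated `exon_starts`,
#' `exon_ends`, all 1-based inclusive; coordinates are converted to 0-based
#' half-open on read.
#'
#' @param path Input path.
#' @param format `"bed12"` or `"tsv"`.
#' @return Gene tibble with `gene_id`, `chrom`, `strand`, `start`, `end`,
#'   `tss` and exon list-columns.
#' @export
read_gene_models <- function(path, format = c("bed12", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  if (format == "bed12") {
    x <- read_bed(path)
    need <- c("name", "strand")
    if (!all(need %in% names(x))) abort("BED12 gene file needs name and strand columns")
    raw <- utils::read.table(path, sep = "\t", header = FALSE, colClasses = "character",
                             comment.char = "#")
    if (ncol(raw) < 12) abort("not a BED12 file (fewer than 12 columns)")
    sizes <- strsplit(raw[[11]], ",")
    offs <- strsplit(raw[[12]], ",")
    start <- as.integer(raw[[2]])
    genes <- tibble(
      gene_id = raw[[4]], chrom = raw[[1]], strand = raw[[6]],
      start = start, end = as.integer(raw[[3]]),
      exon_starts = map2(offs, start, ~ as.integer(.x) + .y),
      exon_ends = pmap(list(offs, sizes, start),
                       function(o, s, st) as.integer(o) + as.integer(s) + st)
    )
  } else {
    raw <- utils::read.table(path, sep = "\t", header = TRUE, colClasses = "character")
    genes <- tibble(
      gene_id = raw$gene_id, chrom = raw$chrom, strand = raw$strand,
      start = as.integer(raw$start) - 1L, end = as.integer(raw$end)
    )
    if (all(c("exon_starts", "exon_ends") %in% names(raw))) {
      genes$exon_starts <- map(strsplit(raw$exon_starts, ","), ~ as.integer(.x) - 1L)
      genes$exon_ends <- map(strsplit(raw$exon_ends, ","), as.integer)
    }
  }
  check_genes(genes)
}

#' Write gene models as BED12
#' @param genes Gene tibble as returned by [read_gene_models()].
#' @param path Output path.
#' @export
write_gene_models <- function(genes, path) {
  genes <- check_genes(genes)
  es <- if ("exon_starts" %in% names(genes)) genes$exon_starts else as.list(genes$start)
  ee <- if ("exon_ends" %in% names(genes)) genes$exon_ends else as.list(genes$end)
  lines <- vapply(seq_len(nrow(genes)), function(i) {
    s <- sort(es[[i]]); e <- ee[[i]][order(es[[i]])]
    paste(genes$chrom[i], genes$start[i], genes$end[i], genes$gene_id[i], 0,
          genes$strand[i], genes$start[i], genes$end[i], "0",
          length(s), paste0(paste(e - s, collapse = ","), ","),
          paste0(paste(s - genes$start[i], collapse = ","), ","),
          sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
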