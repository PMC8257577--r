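TE_MARK_GROUPS <- c("K27-only", "meC-only", "meC+K9", "meC+K9+K27",
                    "none", "other", "no-data")

#' Read a RepeatMasker .out annotation
#'
#' Whitespace-delimited with the standard three header lines. Fields used:
#' Smith-Waterman score (column 1), query sequence/begin/end (5-7; 1-based
#' inclusive, converted to 0-based half-open), strand (9; `C` means minus),
#' repeat name (10) and class/family (11, e.g. `LINE/L1`). Simple repeats
#' and low-complexity annotations are excluded by default.
#'
#' @param path Path to the .out file.
#' @param exclude_simple Drop Simple_repeat/Low_complexity/Satellite rows
#'   (default TRUE).
#' @return TE tibble: `chrom`, `start`, `end`, `strand`, `te_class`
#'   (LINE/SINE/LTR/DNA/Other), `te_family`, `sw_score`, `repeat_name`.
#' @export
read_repeatmasker <- function(path, exclude_simple = TRUE) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path)
  # header: two column-label lines plus a blank; be tolerant and skip any
  # leading lines that do not start with a number
  is_data <- grepl("^\\s*\\d", lines)
  first <- which(is_data)[1]
  if (is.na(first)) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  strand = character(), te_class = character(),
                  te_family = character(), sw_score = integer(),
                  repeat_name = character()))
  }
  fields <- strsplit(trimws(lines[is_data]), "\\s+")
  short <- which(lengths(fields) < 11)
  if (length(short)) {
    abort(paste0("malformed .out line(s): ",
                 paste(head(which(is_data)[short], 5), collapse = ", ")))
  }
  col <- function(i) vapply(fields, `[[`, character(1), i)
  clsfam <- col(11)
  cls <- sub("/.*$", "", clsfam)
  fam <- ifelse(grepl("/", clsfam), sub("^[^/]*/", "", clsfam), clsfam)
  out <- tibble(
    chrom = col(5),
    start = as.integer(col(6)) - 1L,
    end = as.integer(col(7)),
    strand = ifelse(col(9) == "C", "-", "+"),
    te_class = dplyr::case_when(
      grepl("^LINE", cls) ~ "LINE",
      grepl("^SINE", cls) ~ "SINE",
      grepl("^LTR", cls) ~ "LTR",
      grepl("^DNA", cls) ~ "DNA",
      TRUE ~ "Other"
    ),
    te_family = fam,
    sw_score = as.integer(col(1)),
    repeat_name = col(10)
  )
  if (exclude_simple) {
    out <- filter(out, !grepl("Simple_repeat|Low_complexity|Satellite", clsfam))
  }
  if (any(out$sw_score < 0)) abort("negative Smith-Waterman score")
  arrange(out, .data$chrom, .data$start)
}

#' Write a TE catalogue as a RepeatMasker-style .out file
#' @param tes TE tibble (as from [read_repeatmasker()] or
#'   [simulate_te_catalog()]).
#' @param path Output path.
#' @export
write_repeatmasker <- function(tes, path) {
  check_intervals(tes, "tes")
  hdr <- c(
    "   SW   perc perc perc  query      position in query           matching       repeat              position in repeat",
    "score   div. del. ins.  sequence   begin end          (left)   repeat         class/family      begin  end    (left)    ID",
    ""
  )
  fam <- if ("te_family" %in% names(tes)) tes$te_family else tes$te_class
  name <- if ("repeat_name" %in% names(tes)) tes$repeat_name else paste0(fam, "_el")
  lines <- sprintf(
    "%6d %5.1f %4.1f %4.1f  %s %8d %8d (%d) %s %-14s %-18s %6d %6d (%d) %5d",
    tes$sw_score, 10.0, 1.0, 1.0, tes$chrom, tes$start + 1L, tes$end, 0L,
    ifelse(tes$strand == "-", "C", "+"), name,
    paste0(tes$te_class, "/", fam), 1L, tes$end - tes$start, 0L,
    seq_len(nrow(tes))
  )
  writeLines(c(hdr, lines), path)
  invisible(path)
}

te_state <- function(tes, seg) {
  # majority-bp state per TE
  si <- state_intervals(seg)
  tgr <- as_gr(tes[, c("chrom", "start", "end")])
  sgr <- as_gr(si[, c("chrom", "start", "end")])
  hits <- GenomicRanges::findOverlaps(tgr, sgr, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  ov <- pmin(tes$end[qh], si$end[sh]) - pmax(tes$start[qh], si$start[sh])
  K <- length(seg$states)
  bp <- matrix(0, nrow(tes), K)
  for (r in seq_along(qh)) {
    j <- as.integer(si$state[sh[r]])
    bp[qh[r], j] <- bp[qh[r], j] + ov[r]
  }
  factor(seg$states[max.col(bp, ties.method = "first")], levels = seg$states)
}

#' TE distribution across states and class composition per state
#'
#' Each TE is assigned one state by majority bp. Returns the fraction of
#' all TEs residing in each state, and the class composition within each
#' state alongside the whole-catalogue composition (pseudo-state
#' `catalogue`).
#'
#' @param tes TE tibble.
#' @param seg A `state_segmentation`.
#' @return List of two tibbles: `states` (`state`, `n`, `fraction`) and
#'   `classes` (`state`, `te_class`, `n`, `fraction` within state).
#' @export
te_state_distribution <- function(tes, seg) {
  stopifnot(inherits(seg, "state_segmentation"))
  check_intervals(tes, "tes")
  tes <- as_tibble(tes)
  tes$state <- te_state(tes, seg)
  states <- tes |>
    group_by(.data$state, .drop = FALSE) |>
    summarise(n = n(), .groups = "drop") |>
    mutate(fraction = if (nrow(tes) > 0) .data$n / nrow(tes) else rep(0, dplyr::n()))
  by_class <- tes |>
    mutate(state = as.character(.data$state)) |>
    count(.data$state, .data$te_class)
  whole <- tes |> count(.data$te_class) |> mutate(state = "catalogue")
  classes <- bind_rows(by_class, whole) |>
    group_by(.data$state) |>
    mutate(fraction = .data$n / sum(.data$n)) |>
    ungroup() |>
    arrange(.data$state, .data$te_class)
  list(states = states, classes = classes)
}

#' Repressive-mark group of each TE
#'
#' A TE is "DNA methylated" when at least `min_cpgs` contained CpG is
#' classified methylated; mark occupancy is >= 1 bp overlap with the mark's
#' intervals. Groups (mutually exclusive): `K27-only`, `meC-only`,
#' `meC+K9`, `meC+K9+K27`, `none` (no mark, unmethylated), `other`
#' (remaining combinations), and `no-data` for TEs containing no classified
#' CpG, which are excluded from the methylation-conditioned groups.
#'
#' @param tes TE tibble.
#' @param marks Named list of interval tibbles with elements `H3K27me3` and
#'   `H3K9me3`.
#' @param cpgs CpG tibble.
#' @param min_cpgs Methylated CpGs required to call a TE methylated
#'   (default 1).
#' @param lower,upper CpG classification thresholds.
#' @return `tes` with added logical columns `has_k27`, `has_k9`,
#'   `methylated` and factor `mark_group`.
#' @export
te_mark_groups <- function(tes, marks, cpgs, min_cpgs = 1,
                           lower = 0.2, upper = 0.8) {
  check_intervals(tes, "tes")
  if (!all(c("H3K27me3", "H3K9me3") %in% names(marks))) {
    abort("`marks` must contain H3K27me3 and H3K9me3 interval sets")
  }
  cpgs <- check_cpgs(cpgs)
  tes <- as_tibble(tes)
  tgr <- as_gr(tes[, c("chrom", "start", "end")])
  occ <- function(iv) {
    if (nrow(iv) == 0) rep(FALSE, nrow(tes))
    else IRanges::overlapsAny(tgr, as_gr(iv[, c("chrom", "start", "end")]),
                              ignore.strand = TRUE)
  }
  tes$has_k27 <- occ(marks$H3K27me3)
  tes$has_k9 <- occ(marks$H3K9me3)
  category <- classify_cpg(cpgs$beta, lower, upper)
  cgr <- GenomicRanges::GRanges(cpgs$chrom, IRanges::IRanges(cpgs$pos + 1L, cpgs$pos + 1L))
  hits <- GenomicRanges::findOverlaps(cgr, tgr, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  n_cpg <- tabulate(sh, nbins = nrow(tes))
  n_meth <- tabulate(sh[category[qh] == "methylated"], nbins = nrow(tes))
  tes$n_cpg <- n_cpg
  tes$methylated <- n_meth >= min_cpgs
  has_data <- n_cpg > 0
  if (any(!has_data)) {
    inform(paste0(sum(!has_data), " TE(s) contain no CpG; mark group set to 'no-data'"))
  }
  grp <- dplyr::case_when(
    !has_data ~ "no-data",
    tes$has_k27 & !tes$has_k9 & !tes$methylated ~ "K27-only",
    tes$methylated & !tes$has_k9 & !tes$has_k27 ~ "meC-only",
    tes$methylated & tes$has_k9 & !tes$has_k27 ~ "meC+K9",
    tes$methylated & tes$has_k9 & tes$has_k27 ~ "meC+K9+K27",
    !tes$has_k27 & !tes$has_k9 & !tes$methylated ~ "none",
    TRUE ~ "other"
  )
  tes$mark_group <- factor(grp, levels = TE_MARK_GROUPS)
  tes
}

#' Subsampled age comparison of Smith-Waterman scores
#'
#' To accommodate large TE counts and high score variance, `reps`
#' subsamples of `n` scores are drawn (without replacement by default) from
#' the group and from the reference; the subsample means form replicate
#' distributions compared by a two-sided Welch t-test (`compare =
#' "replicate_means"`, the default) or by a t-test on the pooled subsampled
#' values (`compare = "pooled"`).
#'
#' @param group_scores,reference_scores Numeric score vectors.
#' @param n Subsample size (default 1000).
#' @param reps Number of subsamples (default 100).
#' @param seed Integer seed.
#' @param replace Sample with replacement (default FALSE; without it `n`
#'   must not exceed either group's size).
#' @param compare What the t-test is applied to.
#' @return An object of class `age_test` with the replicate means, the test
#'   result and the configuration. Use [generics::tidy()] for a one-row
#'   summary.
#' @export
subsampled_age_test <- function(group_scores, reference_scores, n = 1000,
                                reps = 100, seed = 1, replace = FALSE,
                                compare = c("replicate_means", "pooled")) {
  compare <- match.arg(compare)
  check_number(n, "n", lower = 1)
  if (reps < 2) abort("`reps` must be at least 2")
  if (!replace && (n > length(group_scores) || n > length(reference_scores))) {
    abort("`n` exceeds a group size; use `replace = TRUE` to sample with replacement")
  }
  draws <- withr::with_seed(as.integer(seed), {
    g <- replicate(reps, sample(group_scores, n, replace = replace))
    r <- replicate(reps, sample(reference_scores, n, replace = replace))
    list(g = g, r = r)
  })
  g_means <- colMeans(draws$g)
  r_means <- colMeans(draws$r)
  if (compare == "replicate_means") {
    if (stats::sd(g_means) == 0 && stats::sd(r_means) == 0) {
      ht <- list(statistic = c(t = 0),
                 p.value = if (mean(g_means) == mean(r_means)) 1 else 0,
                 parameter = c(df = NA_real_),
                 estimate = c(mean(g_means), mean(r_means)))
    } else {
      ht <- t.test(g_means, r_means)
    }
  } else {
    ht <- t.test(as.numeric(draws$g), as.numeric(draws$r))
  }
  structure(
    list(group_means = g_means, reference_means = r_means,
         statistic = unname(ht$statistic), p.value = ht$p.value,
         df = unname(ht$parameter), estimate = mean(g_means) - mean(r_means),
         n = n, reps = reps, seed = seed, replace = replace, compare = compare),
    class = "age_test"
  )
}

#' @export
print.age_test <- function(x, ...) {
  cat("<age_test> ", x$reps, " subsamples of ", x$n, " (",
      if (x$replace) "with" else "without", " replacement), ", x$compare,
      ": diff = ", format(x$estimate, digits = 4), ", t = ",
      format(x$statistic, digits = 4), ", p = ", format(x$p.value, digits = 4),
      "\n", sep = "")
  invisible(x)
}

#' @method tidy age_test
#' @export
tidy.age_test <- function(x, ...) {
  tibble(estimate = x$estimate, statistic = x$statistic, p.value = x$p.value,
         df = x$df, n = x$n, reps = x$reps, method = x$compare)
}

#' One-way ANOVA with Tukey HSD pairwise comparisons
#'
#' Standard one-way decomposition followed by Tukey-corrected pairwise
#' contrasts, for comparing Smith-Waterman score distributions across
#' states or mark groups.
#'
#' @param data Either a data frame plus the names of a value and a group
#'   column, or a named list of numeric vectors.
#' @param values,group Column names when `data` is a data frame.
#' @return List: `anova` (tibble `statistic` (F), `df1`, `df2`, `p.value`)
#'   and `tukey` (tibble `contrast`, `estimate`, `conf.low`, `conf.high`,
#'   `adj.p.value`).
#' @export
anova_tukey <- function(data, values = "value", group = "group") {
  if (is.list(data) && !is.data.frame(data)) {
    if (is.null(names(data))) abort("a list of groups must be named")
    data <- tibble(
      value = unlist(data, use.names = FALSE),
      group = rep(names(data), lengths(data))
    )
    values <- "value"; group <- "group"
  }
  df <- tibble(value = as.numeric(data[[values]]),
               group = factor(data[[group]]))
  sizes <- table(df$group)
  if (length(sizes) < 2) abort("need at least two groups")
  if (any(sizes < 2)) abort("every group needs at least two values")
  fit <- aov(value ~ group, data = df)
  s <- summary(fit)[[1]]
  tk <- TukeyHSD(fit)$group
  list(
    anova = tibble(statistic = s[["F value"]][1], df1 = s[["Df"]][1],
                   df2 = s[["Df"]][2], p.value = s[["Pr(>F)"]][1]),
    tukey = tibble(contrast = rownames(tk), estimate = tk[, "diff"],
                   conf.low = tk[, "lwr"], conf.high = tk[, "upr"],
                   adj.p.value = tk[, "p adj"])
  )
}
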