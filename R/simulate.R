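default_emissions <- function() {
  # States qualitatively mirror the liver map: two open/active promoter-like
  # states (ATAC + H3K4me3 + H2A.Z), an H2A.Z-dominant state, a large empty
  # state, an H3K9me3 constitutive-heterochromatin state and an H3K27me3
  # facultative-heterochromatin state. Values are this package's choices.
  m <- rbind(
    S1 = c(0.80, 0.90, 0.70, 0.15, 0.02),
    S2 = c(0.90, 0.95, 0.85, 0.10, 0.02),
    S3 = c(0.30, 0.10, 0.80, 0.05, 0.02),
    S4 = c(0.02, 0.01, 0.02, 0.02, 0.02),
    S5 = c(0.02, 0.01, 0.02, 0.05, 0.85),
    S6 = c(0.02, 0.02, 0.05, 0.85, 0.03)
  )
  colnames(m) <- c("ATAC", "H3K4me3", "H2AZ", "H3K27me3", "H3K9me3")
  m
}

# Row-stochastic transition matrix with a prescribed stationary distribution:
# A[i, j] = c * pi[j] off-diagonal, diagonal absorbs the remainder, which
# leaves pi invariant for any switching rate c in (0, 1/max term).
stationary_transitions <- function(pi0, switch_rate = 0.15) {
  K <- length(pi0)
  A <- switch_rate * matrix(pi0, K, K, byrow = TRUE)
  diag(A) <- 0
  diag(A) <- 1 - rowSums(A)
  if (any(diag(A) <= 0)) abort("switch_rate too large for the stationary target")
  A
}

#' Configuration for the synthetic epigenome generator
#'
#' Defaults define the study conditions the generator emulates: a 10 Mb
#' single-chromosome genome binned at 200 bp (50,000 bins), six chromatin
#' states whose stationary distribution mirrors the published genome
#' fractions (88.5% empty state, ~4% open states, ~7.5% repressive states),
#' five binary mark tracks, state-dependent gene expression (log-normal
#' FPKM), CpG methylation (Beta by state, forced high under H3K9me3),
#' a transposable-element catalogue whose class mix and Smith-Waterman age
#' scores depend on state (young/high-sw TEs concentrated in the
#' H3K9me3-like state), and baseline vs 30 h H3K27me3 peak sets with 58%
#' turnover.
#'
#' @param seed Root seed; all generator randomness derives from it.
#' @param n_bins Total genome bins (default 50,000).
#' @param bin_size Bin width in bp (default 200).
#' @param n_chroms Number of synthetic chromosomes the bins are split over.
#' @param marks Mark names (M columns of the emission matrix).
#' @param true_initial Stationary/initial state distribution.
#' @param switch_rate Off-diagonal transition mass scale (default 0.015, giving
#'   multi-kb state domains at 200 bp bins).
#' @param true_transitions Optional explicit K x K transition matrix
#'   (defaults to one with `true_initial` as stationary distribution).
#' @param true_emissions K x M Bernoulli emission probabilities.
#' @param gene_count,te_count,cpg_count Entity counts.
#' @param gene_state_weights Probability that a gene's TSS is planted in
#'   each state.
#' @param bivalent_fraction Fraction of genes in the two active states that
#'   are bivalent-induced (silenced at baseline, induced during
#'   regeneration).
#' @param fpkm_meanlog,fpkm_sdlog Per-state log-normal baseline FPKM
#'   parameters.
#' @param repressed_meanlog Baseline meanlog for repressed-trajectory and
#'   bivalent-at-baseline genes.
#' @param induced_fold Fold-change applied to bivalent-induced genes at the
#'   induction timepoints (default 8).
#' @param induced_timepoints Timepoints at which induction applies.
#' @param timepoints Expression timepoints (baseline `0h` plus the
#'   post-hepatectomy series).
#' @param expr_noise_sdlog Multiplicative log-normal noise per timepoint.
#' @param meth_beta Per-state `c(shape1, shape2)` Beta parameters for CpG
#'   methylation fraction.
#' @param k9_beta Beta parameters overriding state for CpGs in bins where
#'   the H3K9me3 track is present.
#' @param cpg_density_weights Relative CpG density per state.
#' @param te_state_weights Probability a TE resides in each state.
#' @param te_class_weights State x class matrix of TE class probabilities
#'   (classes LINE, SINE, LTR, DNA, Other).
#' @param te_sw_mean,te_sw_sd Per-state normal parameters for the
#'   Smith-Waterman score (higher = younger).
#' @param te_len_range TE length range in bp.
#' @param peak_turnover Fraction of the 30 h H3K27me3 peak set sitting on
#'   loci not occupied at baseline (default 0.58, i.e. 42% of 30 h peaks
#'   retain their baseline loci); the 30 h set is ~15% smaller than
#'   baseline.
#' @return An object of class `sim_config` (a validated list).
#' @export
simulation_config <- function(
    seed = 1,
    n_bins = 50000,
    bin_size = 200,
    n_chroms = 1,
    marks = colnames(default_emissions()),
    true_initial = c(S1 = 0.012, S2 = 0.018, S3 = 0.010,
                     S4 = 0.885, S5 = 0.040, S6 = 0.035),
    switch_rate = 0.015,
    true_transitions = NULL,
    true_emissions = default_emissions(),
    gene_count = 400,
    te_count = 2000,
    cpg_count = 20000,
    gene_state_weights = c(S1 = 0.18, S2 = 0.40, S3 = 0.03,
                           S4 = 0.25, S5 = 0.02, S6 = 0.12),
    bivalent_fraction = 0.2,
    fpkm_meanlog = c(S1 = 1.8, S2 = 2.2, S3 = 0, S4 = -1.2, S5 = -3, S6 = -3),
    fpkm_sdlog = 1,
    repressed_meanlog = -3,
    induced_fold = 8,
    induced_timepoints = c("40h", "48h"),
    timepoints = c("0h", "24h", "30h", "40h", "48h", "96h", "120h", "168h", "4wk"),
    expr_noise_sdlog = 0.2,
    meth_beta = list(S1 = c(1, 20), S2 = c(1, 20), S3 = c(2, 12),
                     S4 = c(20, 1), S5 = c(20, 1), S6 = c(2, 6)),
    k9_beta = c(20, 1),
    cpg_density_weights = c(S1 = 8, S2 = 10, S3 = 3, S4 = 1, S5 = 1, S6 = 4),
    te_state_weights = c(S1 = 0.004, S2 = 0.004, S3 = 0.015,
                         S4 = 0.880, S5 = 0.065, S6 = 0.032),
    te_class_weights = NULL,
    te_sw_mean = c(S1 = 2000, S2 = 2000, S3 = 2000, S4 = 2500, S5 = 6000, S6 = 2400),
    te_sw_sd = c(S1 = 1000, S2 = 1000, S3 = 1000, S4 = 1200, S5 = 1500, S6 = 1200),
    te_len_range = c(300, 6000),
    peak_turnover = 0.58) {
  K <- length(true_initial)
  if (is.null(true_transitions)) {
    true_transitions <- stationary_transitions(true_initial / sum(true_initial),
                                               switch_rate)
  }
  true_transitions <- as.matrix(true_transitions)
  if (any(abs(rowSums(true_transitions) - 1) > STOCHASTIC_TOL)) {
    abort("`true_transitions` rows must sum to 1")
  }
  true_emissions <- as.matrix(true_emissions)
  if (nrow(true_emissions) != K || ncol(true_emissions) != length(marks)) {
    abort("`true_emissions` must be K x length(marks)")
  }
  if (any(true_emissions < 0 | true_emissions > 1)) abort("emission probabilities outside [0, 1]")
  if (any(unlist(meth_beta) <= 0) || any(k9_beta <= 0)) {
    abort("Beta parameters must be positive")
  }
  check_number(peak_turnover, "peak_turnover", 0, 1)
  check_number(bivalent_fraction, "bivalent_fraction", 0, 1)
  if (is.null(te_class_weights)) {
    te_class_weights <- rbind(
      S1 = c(0.15, 0.60, 0.14, 0.10, 0.01),
      S2 = c(0.15, 0.60, 0.14, 0.10, 0.01),
      S3 = c(0.25, 0.40, 0.20, 0.14, 0.01),
      S4 = c(0.38, 0.25, 0.27, 0.09, 0.01),
      S5 = c(0.50, 0.01, 0.40, 0.08, 0.01),
      S6 = c(0.15, 0.60, 0.14, 0.10, 0.01)
    )
    colnames(te_class_weights) <- c("LINE", "SINE", "LTR", "DNA", "Other")
  }
  states <- names(true_initial) %||% state_labels(K)
  cfg <- list(
    seed = as.integer(seed), n_bins = as.integer(n_bins),
    bin_size = as.integer(bin_size), n_chroms = as.integer(n_chroms),
    K = K, states = states, marks = marks,
    true_initial = setNames(true_initial / sum(true_initial), states),
    true_transitions = true_transitions, true_emissions = true_emissions,
    gene_count = as.integer(gene_count), te_count = as.integer(te_count),
    cpg_count = as.integer(cpg_count),
    gene_state_weights = gene_state_weights,
    bivalent_fraction = bivalent_fraction,
    fpkm_meanlog = fpkm_meanlog, fpkm_sdlog = fpkm_sdlog,
    repressed_meanlog = repressed_meanlog,
    induced_fold = induced_fold, induced_timepoints = induced_timepoints,
    timepoints = timepoints, expr_noise_sdlog = expr_noise_sdlog,
    meth_beta = meth_beta, k9_beta = k9_beta,
    cpg_density_weights = cpg_density_weights,
    te_state_weights = te_state_weights, te_class_weights = te_class_weights,
    te_sw_mean = te_sw_mean, te_sw_sd = te_sw_sd,
    te_len_range = te_len_range, peak_turnover = peak_turnover
  )
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> seed ", x$seed, ": ", x$n_bins, " bins x ", x$bin_size,
      " bp, K = ", x$K, ", ", length(x$marks), " marks, ", x$gene_count,
      " genes, ", x$te_count, " TEs, ", x$cpg_count, " CpGs\n", sep = "")
  invisible(x)
}

sim_genome <- function(config) {
  per <- rep(config$n_bins %/% config$n_chroms, config$n_chroms)
  per[config$n_chroms] <- per[config$n_chroms] + config$n_bins %% config$n_chroms
  tibble(chrom = paste0("synth", seq_len(config$n_chroms)),
         length = per * config$bin_size)
}

#' Simulate the ground-truth state sequence and binary mark track
#'
#' States follow the configured Markov chain (restarting at the initial
#' distribution on each chromosome); each mark bit is Bernoulli with the
#' state's emission probability. Byte-identical under a fixed seed.
#'
#' @param config A `sim_config`.
#' @return List with `truth` (integer per-bin state vector), `track`
#'   (binary `track_matrix`), `grid` (the `bin_grid`).
#' @export
simulate_tracks <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  genome <- sim_genome(config)
  grid <- bin_grid(genome, config$bin_size)
  K <- config$K
  A <- config$true_transitions
  withr::with_seed(sub_seed(config$seed, "tracks"), {
    truth <- integer(grid$n_bins)
    for (ci in seq_len(nrow(grid$chrom_bins))) {
      nb <- grid$chrom_bins$n_bins[ci]
      off <- grid$chrom_bins$offset[ci]
      s <- sample.int(K, 1, prob = config$true_initial)
      truth[off + 1L] <- s
      if (nb > 1) {
        u <- runif(nb - 1)
        cumA <- t(apply(A, 1, cumsum))
        for (t in 2:nb) {
          s <- findInterval(u[t - 1], cumA[s, ], left.open = TRUE) + 1L
          truth[off + t] <- s
        }
      }
    }
    p <- config$true_emissions[truth, , drop = FALSE]
    vals <- matrix(as.integer(runif(length(p)) < p), nrow(p), ncol(p))
    colnames(vals) <- config$marks
    list(truth = truth, track = track_matrix(vals, grid, config$marks), grid = grid)
  })
}

#' Simulate gene models whose placement depends on chromatin state
#'
#' TSS bins are sampled so genes land in states with the configured
#' probabilities; each gene gets a trajectory class: `constitutive`
#' (expression follows its state's baseline distribution throughout),
#' `bivalent_induced` (genes in the two active states, silenced at baseline
#' and induced during regeneration) or `repressed` (silenced throughout;
#' genes in the repressive states).
#'
#' @param truth Per-bin true state vector (from [simulate_tracks()]).
#' @param grid The matching `bin_grid`.
#' @param config A `sim_config`.
#' @return Gene tibble with model columns plus `true_state` and
#'   `trajectory_class`.
#' @export
simulate_genes <- function(truth, grid, config) {
  stopifnot(inherits(config, "sim_config"))
  bins <- bin_intervals(grid)
  withr::with_seed(sub_seed(config$seed, "genes"), {
    w <- config$gene_state_weights[config$states]
    target_states <- sample(seq_len(config$K), config$gene_count,
                            replace = TRUE, prob = w)
    # promoters sit at the centre of their chromatin domain, so TSSs are
    # planted mid-run (runs sampled in proportion to their length)
    runs <- rle(truth)
    run_end <- cumsum(runs$lengths)
    run_start <- run_end - runs$lengths + 1L
    run_mid <- run_start + (runs$lengths - 1L) %/% 2L
    runs_by_state <- split(seq_along(runs$values), runs$values)
    tss_bin <- vapply(target_states, function(s) {
      pool <- runs_by_state[[as.character(s)]]
      if (is.null(pool) || length(pool) == 0) return(sample.int(grid$n_bins, 1))
      r <- pool[sample.int(length(pool), 1, prob = runs$lengths[pool])]
      run_mid[r]
    }, integer(1))
    strand <- sample(c("+", "-"), config$gene_count, replace = TRUE)
    len <- sample(seq(2000, 20000, by = 200), config$gene_count, replace = TRUE)
    chrom <- bins$chrom[tss_bin]
    chrlen <- setNames(grid$genome$length, grid$genome$chrom)
    tss <- bins$start[tss_bin] + sample.int(config$bin_size, config$gene_count,
                                            replace = TRUE) - 1L
    tss <- pmin(tss, chrlen[chrom] - 1L)
    gstart <- ifelse(strand == "+", tss, pmax(tss + 1L - len, 0))
    gend <- ifelse(strand == "+", pmin(tss + len, chrlen[chrom]), tss + 1L)
    true_state <- truth[tss_bin]
    n_ex <- sample(1:4, config$gene_count, replace = TRUE)
    exons <- map(seq_len(config$gene_count), function(i) {
      span <- gend[i] - gstart[i]
      k <- min(n_ex[i], max(1, span %/% 400))
      if (k == 1 || span < 2 * k) {
        es <- gstart[i]; ee <- gend[i]
      } else {
        cuts <- sort(sample.int(span - 1, 2 * k - 1))
        es <- gstart[i] + c(0L, cuts[seq_len(k - 1) * 2])
        ee <- gstart[i] + c(cuts[seq_len(k - 1) * 2 - 1], span)
      }
      list(starts = as.integer(es), ends = as.integer(ee))
    })
    active <- true_state %in% 1:2
    u <- runif(config$gene_count)
    trajectory <- ifelse(
      active & u < config$bivalent_fraction, "bivalent_induced",
      ifelse(true_state %in% 5:6 & u < 0.9, "repressed", "constitutive")
    )
    tibble(
      gene_id = sprintf("gene%04d", seq_len(config$gene_count)),
      chrom = chrom, strand = strand,
      start = as.integer(gstart), end = as.integer(gend), tss = as.integer(tss),
      exon_starts = map(exons, "starts"), exon_ends = map(exons, "ends"),
      true_state = config$states[true_state],
      trajectory_class = trajectory
    )
  })
}

#' Simulate the expression timecourse (FPKM per gene per timepoint)
#'
#' Baseline FPKM is log-normal with the gene's state meanlog; repressed and
#' bivalent-induced genes use the repressed baseline; bivalent-induced genes
#' are multiplied by `induced_fold` at the induction timepoints. Each
#' timepoint gets independent multiplicative log-normal noise.
#'
#' @param genes Gene tibble from [simulate_genes()].
#' @param config A `sim_config`.
#' @return Tibble `gene_id` x timepoint columns (FPKM).
#' @export
simulate_expression <- function(genes, config) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(genes) == 0) {
    return(as_tibble(setNames(
      c(list(character(0)), rep(list(numeric(0)), length(config$timepoints))),
      c("gene_id", config$timepoints)
    )))
  }
  bad <- setdiff(unique(genes$trajectory_class),
                 c("constitutive", "bivalent_induced", "repressed"))
  if (length(bad)) abort(paste0("unknown trajectory class: ", paste(bad, collapse = ", ")))
  withr::with_seed(sub_seed(config$seed, "expression"), {
    n <- nrow(genes)
    meanlog <- config$fpkm_meanlog[genes$true_state]
    meanlog[genes$trajectory_class != "constitutive"] <- config$repressed_meanlog
    base <- rlnorm(n, meanlog = meanlog, sdlog = config$fpkm_sdlog)
    out <- matrix(NA_real_, n, length(config$timepoints),
                  dimnames = list(NULL, config$timepoints))
    for (tp in config$timepoints) {
      fold <- ifelse(
        genes$trajectory_class == "bivalent_induced" & tp %in% config$induced_timepoints,
        config$induced_fold, 1
      )
      out[, tp] <- base * fold * rlnorm(n, 0, config$expr_noise_sdlog)
    }
    bind_cols(tibble(gene_id = genes$gene_id), as_tibble(out))
  })
}

#' Simulate a per-CpG methylation table
#'
#' CpG positions are placed with state-dependent density (CpG-dense open
#' states, sparse heterochromatin); the methylation fraction is Beta with
#' the state's parameters, except that CpGs in bins where the H3K9me3 track
#' is present draw from the `k9_beta` distribution regardless of state
#' (constitutive heterochromatin is methylated wherever H3K9me3 sits).
#'
#' @param truth Per-bin state vector.
#' @param track Binary `track_matrix` (used for the H3K9me3 condition; pass
#'   NULL to disable).
#' @param grid The `bin_grid`.
#' @param config A `sim_config`.
#' @return Tibble `chrom`, `pos`, `beta`, `coverage`.
#' @export
simulate_methylome <- function(truth, track, grid, config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$cpg_count == 0) {
    return(tibble(chrom = character(), pos = integer(),
                  beta = numeric(), coverage = integer()))
  }
  bins <- bin_intervals(grid)
  withr::with_seed(sub_seed(config$seed, "methylome"), {
    w <- config$cpg_density_weights[truth]
    cpg_bin <- sample.int(grid$n_bins, config$cpg_count, replace = TRUE, prob = w)
    pos <- bins$start[cpg_bin] +
      sample.int(config$bin_size, config$cpg_count, replace = TRUE) - 1L
    pos <- pmin(pos, bins$end[cpg_bin] - 1L)
    st <- truth[cpg_bin]
    shape1 <- vapply(config$meth_beta, `[`, numeric(1), 1)[st]
    shape2 <- vapply(config$meth_beta, `[`, numeric(1), 2)[st]
    if (!is.null(track) && "H3K9me3" %in% track$marks) {
      under_k9 <- track$values[cpg_bin, "H3K9me3"] == 1
      shape1[under_k9] <- config$k9_beta[1]
      shape2[under_k9] <- config$k9_beta[2]
    }
    out <- tibble(
      chrom = bins$chrom[cpg_bin],
      pos = as.integer(pos),
      beta = rbeta(config$cpg_count, shape1, shape2),
      coverage = 5L + rpois(config$cpg_count, 25)
    )
    arrange(out, .data$chrom, .data$pos)
  })
}

#' Simulate a transposable-element catalogue
#'
#' TE anchor bins are drawn with state-dependent probability (most TEs in
#' the empty state, LINEs/LTRs concentrated in the H3K9me3-like state);
#' class, family and Smith-Waterman score are drawn from state-conditional
#' distributions, with the highest (youngest) scores in the
#' H3K9me3-like state.
#'
#' @param truth Per-bin state vector.
#' @param grid The `bin_grid`.
#' @param config A `sim_config`.
#' @return TE tibble: interval columns, `strand`, `te_class`, `te_family`,
#'   `sw_score`, `true_state`.
#' @export
simulate_te_catalog <- function(truth, grid, config) {
  stopifnot(inherits(config, "sim_config"))
  bins <- bin_intervals(grid)
  families <- list(
    LINE = c("L1", "L2", "CR1"),
    SINE = c("B1", "B2", "B4", "ID"),
    LTR = c("ERVK", "ERVL", "ERVL-MaLR"),
    DNA = c("hAT-Charlie", "TcMar-Tigger"),
    Other = c("Unknown")
  )
  withr::with_seed(sub_seed(config$seed, "te"), {
    # per-bin weight = target state share / bins in that state, so the
    # fraction of TEs landing in each state matches te_state_weights
    # irrespective of how much genome the state covers
    state_bins <- tabulate(truth, nbins = config$K)
    w <- (config$te_state_weights / pmax(state_bins, 1))[truth]
    w[state_bins[truth] == 0] <- 0
    anchor <- sample.int(grid$n_bins, config$te_count, replace = TRUE, prob = w)
    st <- truth[anchor]
    chrlen <- setNames(grid$genome$length, grid$genome$chrom)
    len <- sample(seq(config$te_len_range[1], config$te_len_range[2]),
                  config$te_count, replace = TRUE)
    start <- bins$start[anchor]
    chrom <- bins$chrom[anchor]
    end <- pmin(start + len, chrlen[chrom])
    cls <- vapply(st, function(s) {
      sample(colnames(config$te_class_weights), 1,
             prob = config$te_class_weights[s, ])
    }, character(1))
    fam <- vapply(cls, function(cl) sample(families[[cl]], 1), character(1))
    sw <- round(rnorm(config$te_count, config$te_sw_mean[st], config$te_sw_sd[st]))
    sw <- pmax(sw, 200)
    out <- tibble(
      chrom = chrom, start = as.integer(start), end = as.integer(end),
      strand = sample(c("+", "-"), config$te_count, replace = TRUE),
      te_class = cls, te_family = fam, sw_score = as.integer(sw),
      true_state = config$states[st]
    )
    arrange(out, .data$chrom, .data$start)
  })
}

track_mark_intervals <- function(track, mark) {
  bins <- bin_intervals(track$grid)
  on <- bins[track$values[, mark] == 1, c("chrom", "start", "end")]
  flatten_intervals(on)
}

#' Simulate baseline and 30 h peak sets
#'
#' Baseline peaks for each mark are the merged runs of present bins in the
#' simulated track, with H3K4me3 + H3K27me3 peaks implanted over
#' bivalent-induced genes' TSSs (the bivalent promoter signature). The 30 h
#' H3K27me3 set loses the bivalent-TSS peaks first, then random peaks up to
#' the configured turnover, and gains replacement peaks placed in
#' empty-state regions (the redistribution from promoters towards
#' intergenic space).
#'
#' @param truth Per-bin state vector.
#' @param track Binary `track_matrix`.
#' @param genes Gene tibble from [simulate_genes()].
#' @param config A `sim_config`.
#' @return List: `baseline` (named list of interval tibbles per mark),
#'   `post30h` (list with `H3K27me3`).
#' @export
simulate_peak_sets <- function(truth, track, genes, config) {
  stopifnot(inherits(config, "sim_config"))
  grid <- track$grid
  bins <- bin_intervals(grid)
  withr::with_seed(sub_seed(config$seed, "peaks"), {
    baseline <- setNames(
      lapply(track$marks, function(m) track_mark_intervals(track, m)),
      track$marks
    )
    biv <- genes[genes$trajectory_class == "bivalent_induced", , drop = FALSE]
    if (nrow(biv) > 0) {
      implant <- tibble(chrom = biv$chrom,
                        start = pmax(biv$tss - 400L, 0L),
                        end = biv$tss + 400L)
      for (m in intersect(c("H3K4me3", "H3K27me3"), names(baseline))) {
        baseline[[m]] <- flatten_intervals(bind_rows(baseline[[m]], implant))
      }
    }
    k27 <- baseline[["H3K27me3"]]
    n_base <- nrow(k27)
    # the 30 h set is somewhat smaller than baseline and a fraction
    # `peak_turnover` of it sits on loci not occupied at baseline
    n_total30 <- round(0.85 * n_base)
    n_keep <- max(0L, round((1 - config$peak_turnover) * n_total30))
    n_drop <- n_base - n_keep
    over_biv <- if (nrow(biv) > 0) {
      IRanges::overlapsAny(as_gr(k27), as_gr(
        tibble(chrom = biv$chrom, start = pmax(biv$tss - 400L, 0L), end = biv$tss + 400L)
      ))
    } else rep(FALSE, n_base)
    drop_idx <- which(over_biv)
    if (length(drop_idx) < n_drop) {
      pool <- setdiff(seq_len(n_base), drop_idx)
      drop_idx <- c(drop_idx, sample(pool, min(n_drop - length(drop_idx), length(pool))))
    } else {
      drop_idx <- drop_idx[seq_len(n_drop)]
    }
    retained <- if (length(drop_idx)) k27[-drop_idx, , drop = FALSE] else k27
    # replacement peaks in empty-state bins (redistribution away from promoters)
    n_new <- max(0L, n_total30 - nrow(retained))
    s4_bins <- which(truth == 4L)
    if (length(s4_bins) > 0 && n_new > 0) {
      anchor <- sample(s4_bins, n_new, replace = length(s4_bins) < n_new)
      width_bins <- sample(1:3, n_new, replace = TRUE)
      new_peaks <- tibble(
        chrom = bins$chrom[anchor],
        start = bins$start[anchor],
        end = pmin(bins$start[anchor] + width_bins * grid$bin_size,
                   setNames(grid$genome$length, grid$genome$chrom)[bins$chrom[anchor]])
      )
      post <- flatten_intervals(bind_rows(retained, new_peaks))
    } else {
      post <- retained
    }
    list(baseline = baseline, post30h = list(H3K27me3 = post))
  })
}

#' Generate a complete synthetic epigenome with known ground truth
#'
#' Runs every generator and assembles the shared-genome bundle: truth
#' states, binary track, gene models with element partition, expression
#' timecourse, CpG methylome, TE catalogue, and baseline/30 h peak sets.
#'
#' @param config A `sim_config` (default: `simulation_config()`).
#' @return An object of class `synthetic_epigenome`.
#' @export
simulate_epigenome <- function(config = simulation_config()) {
  stopifnot(inherits(config, "sim_config"))
  tr <- simulate_tracks(config)
  genes <- simulate_genes(tr$truth, tr$grid, config)
  annotation <- build_element_partition(genes, tr$grid$genome)
  expression <- simulate_expression(genes, config)
  cpgs <- simulate_methylome(tr$truth, tr$track, tr$grid, config)
  tes <- simulate_te_catalog(tr$truth, tr$grid, config)
  peaks <- simulate_peak_sets(tr$truth, tr$track, genes, config)
  structure(
    list(config = config, grid = tr$grid, truth = tr$truth, track = tr$track,
         genes = genes, annotation = annotation, expression = expression,
         cpgs = cpgs, tes = tes, peaks = peaks),
    class = "synthetic_epigenome"
  )
}

#' @export
print.synthetic_epigenome <- function(x, ...) {
  cat("<synthetic_epigenome> seed ", x$config$seed, ": ", x$grid$n_bins,
      " bins, ", nrow(x$genes), " genes, ", nrow(x$tes), " TEs, ",
      nrow(x$cpgs), " CpGs\n", sep = "")
  invisible(x)
}

#' Ground-truth segmentation of a synthetic epigenome
#'
#' Wraps the generator's true per-bin states as a `state_segmentation` so
#' downstream integration functions can run against planted truth.
#'
#' @param epi A `synthetic_epigenome`.
#' @return A `state_segmentation`.
#' @export
truth_segmentation <- function(epi) {
  stopifnot(inherits(epi, "synthetic_epigenome"))
  structure(
    list(grid = epi$grid, labels = epi$truth, states = epi$config$states,
         posterior = NULL, method = "truth"),
    class = "state_segmentation"
  )
}

#' Write a synthetic epigenome in standard file formats
#'
#' Genome as chrom-size TSV, truth states as dense BED, the binary track as
#' dense TSV, genes as BED12 plus a truth table TSV, FPKM TSV, methylation
#' TSV, TEs as a RepeatMasker-style .out, peaks as per-mark BED files.
#'
#' @param epi A `synthetic_epigenome`.
#' @param dir Output directory (created if needed).
#' @return Tibble of written files.
#' @export
write_epigenome <- function(epi, dir) {
  stopifnot(inherits(epi, "synthetic_epigenome"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(dir, ...)
  write_genome(epi$grid$genome, p("genome.tsv"))
  write_segmentation(truth_segmentation(epi), p("truth_states.bed"))
  write_track_tsv(epi$track, p("track.tsv"))
  write_gene_models(epi$genes, p("genes.bed12"))
  utils::write.table(
    as.data.frame(epi$genes[, c("gene_id", "true_state", "trajectory_class")]),
    p("gene_truth.tsv"), sep = "\t", quote = FALSE, row.names = FALSE
  )
  utils::write.table(as.data.frame(epi$expression), p("fpkm.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(epi$cpgs), p("methylation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_repeatmasker(epi$tes, p("tes.out"))
  peak_files <- character(0)
  for (m in names(epi$peaks$baseline)) {
    f <- p(paste0("peaks_baseline_", m, ".bed"))
    write_bed(epi$peaks$baseline[[m]], f)
    peak_files <- c(peak_files, f)
  }
  write_bed(epi$peaks$post30h$H3K27me3, p("peaks_30h_H3K27me3.bed"))
  files <- c(p(c("genome.tsv", "truth_states.bed", "track.tsv", "genes.bed12",
                 "gene_truth.tsv", "fpkm.tsv", "methylation.tsv", "tes.out")),
             peak_files, p("peaks_30h_H3K27me3.bed"))
  tibble(file = files)
}
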