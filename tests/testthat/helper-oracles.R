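# Independent oracles and fixture builders shared across tests.
# Everything here is deliberately brute-force and free of package internals.

# probability of one observation vector under one state, computed directly
oracle_emission <- function(p_row, x) {
  prod(ifelse(x == 1, p_row, 1 - p_row))
}

# exhaustive-path likelihood: sum over all K^T state paths
oracle_likelihood <- function(initial, transitions, emissions, X) {
  K <- length(initial)
  T_ <- nrow(X)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), T_)))
  total <- 0
  for (r in seq_len(nrow(paths))) {
    path <- as.integer(paths[r, ])
    pr <- initial[path[1]] * oracle_emission(emissions[path[1], ], X[1, ])
    if (T_ > 1) {
      for (t in 2:T_) {
        pr <- pr * transitions[path[t - 1], path[t]] *
          oracle_emission(emissions[path[t], ], X[t, ])
      }
    }
    total <- total + pr
  }
  total
}

# exhaustive posterior P(state at t | X): path enumeration
oracle_posterior <- function(initial, transitions, emissions, X) {
  K <- length(initial)
  T_ <- nrow(X)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), T_)))
  post <- matrix(0, T_, K)
  total <- 0
  for (r in seq_len(nrow(paths))) {
    path <- as.integer(paths[r, ])
    pr <- initial[path[1]] * oracle_emission(emissions[path[1], ], X[1, ])
    if (T_ > 1) {
      for (t in 2:T_) {
        pr <- pr * transitions[path[t - 1], path[t]] *
          oracle_emission(emissions[path[t], ], X[t, ])
      }
    }
    total <- total + pr
    for (t in seq_len(T_)) post[t, path[t]] <- post[t, path[t]] + pr
  }
  post / total
}

# smallest count with Poisson upper tail <= alpha, by pmf accumulation
oracle_min_count <- function(lambda, alpha) {
  cc <- 1
  repeat {
    tail_p <- 1 - sum(stats::dpois(0:(cc - 1), lambda))
    if (tail_p <= alpha) return(cc)
    cc <- cc + 1
  }
}

random_hmm_draw <- function(K, M) {
  initial <- stats::runif(K, 0.2, 1)
  initial <- initial / sum(initial)
  transitions <- matrix(stats::runif(K * K, 0.1, 1), K, K)
  transitions <- transitions / rowSums(transitions)
  emissions <- matrix(stats::runif(K * M, 0.1, 0.9), K, M)
  list(initial = initial, transitions = transitions, emissions = emissions)
}

# the worked single-gene annotation: + strand, transcript [1000, 3000),
# exons [1000, 1500) and [2500, 3000), genome of one 5000 bp chromosome
toy_genome <- function(len = 5000) tibble::tibble(chrom = "chr1", length = len)

toy_gene <- function() {
  tibble::tibble(
    gene_id = "g1", chrom = "chr1", strand = "+",
    start = 1000L, end = 3000L, tss = 1000L,
    exon_starts = list(c(1000L, 2500L)), exon_ends = list(c(1500L, 3000L))
  )
}

toy_annotation <- function() {
  suppressWarnings(build_element_partition(toy_gene(), toy_genome()))
}

# segmentation with explicit per-bin labels on a single-chromosome grid
manual_segmentation <- function(labels, states, bin_size = 1000,
                                genome_len = length(labels) * bin_size) {
  grid <- bin_grid(tibble::tibble(chrom = "chr1", length = genome_len), bin_size)
  structure(
    list(grid = grid, labels = as.integer(labels), states = states,
         posterior = NULL, method = "manual"),
    class = "state_segmentation"
  )
}

# adjusted Rand index between two labelings
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / choose2(n)
  maxi <- (sum_a + sum_b) / 2
  (sum_ij - expected) / (maxi - expected)
}

# a small, well-separated three-state generator configuration (shared by
# recovery and model-selection tests)
recovery_emissions <- function() {
  em <- rbind(S1 = c(0.90, 0.80, 0.85, 0.10, 0.05),
              S2 = c(0.10, 0.05, 0.10, 0.80, 0.10),
              S3 = c(0.05, 0.10, 0.05, 0.05, 0.90))
  colnames(em) <- c("ATAC", "H3K4me3", "H2AZ", "H3K27me3", "H3K9me3")
  em
}

recovery_config <- function(seed, n_bins) {
  simulation_config(
    seed = seed, n_bins = n_bins,
    true_initial = c(S1 = 0.3, S2 = 0.4, S3 = 0.3),
    switch_rate = 0.05, true_emissions = recovery_emissions()
  )
}

medium_epigenome <- function(seed = 1) {
  simulate_epigenome(simulation_config(seed = seed, n_bins = 20000))
}

small_epigenome <- function(seed = 4) {
  simulate_epigenome(simulation_config(
    seed = seed, n_bins = 4000, gene_count = 80,
    te_count = 400, cpg_count = 4000
  ))
}
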