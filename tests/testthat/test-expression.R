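test_that("expression classification applies a strict FPKM > 1 rule", {
  expect_equal(as.character(classify_expression(1.5)), "expressed")
  expect_equal(as.character(classify_expression(1.0)), "silenced")
  expect_equal(as.character(classify_expression(0)), "silenced")
  expect_error(classify_expression(-1), "non-negative")
})

test_that("per-state expression summaries conserve gene counts", {
  gene_states <- tibble::tibble(
    gene_id = paste0("g", 1:6),
    state = factor(c("S1", "S1", "S2", "S2", "S2", "S1"), levels = c("S1", "S2"))
  )
  expr <- tibble::tibble(gene_id = paste0("g", 1:5),
                         `0h` = c(5, 0.2, 3, 0.5, 1))
  summ <- suppressMessages(state_expression_summary(gene_states, expr))
  expect_equal(sum(summ$n_expressed + summ$n_silenced + summ$n_no_data), 6)
  expect_equal(summ$n_no_data[summ$state == "S1"], 1)
  expect_equal(summ$n_expressed[summ$state == "S2"], 1)  # FPKM exactly 1 silenced
  expect_equal(summ$n_silenced[summ$state == "S2"], 2)
  # all genes expressed -> silenced counts zero
  expr_all <- tibble::tibble(gene_id = paste0("g", 1:6), `0h` = 10)
  summ2 <- state_expression_summary(gene_states, expr_all)
  expect_true(all(summ2$n_silenced == 0))
  expect_error(state_expression_summary(gene_states, expr, baseline = "xx"), "baseline")
})

test_that("planted state-expression coupling is recovered from ground truth", {
  epi <- simulate_epigenome(simulation_config(seed = 44, n_bins = 20000,
                                              gene_count = 300))
  gene_states <- tibble::tibble(gene_id = epi$genes$gene_id,
                                state = factor(epi$genes$true_state,
                                               levels = epi$config$states))
  summ <- state_expression_summary(gene_states, epi$expression)
  expect_gt(summ$frac_expressed[summ$state == "S2"], 0.5)
  expect_lt(summ$frac_expressed[summ$state == "S6"], 0.1)
})

test_that("hypergeometric enrichment matches the combinatorial oracle", {
  gene_states <- tibble::tibble(
    gene_id = paste0("g", 1:20),
    state = factor(rep(c("S1", "S2"), each = 10))
  )
  # the whole 5-gene set inside the 10-gene state: p = 252 / 15504
  enr <- geneset_state_enrichment(paste0("g", 1:5), gene_states)
  expect_equal(enr$overlap[enr$state == "S1"], 5)
  expect_equal(enr$p.value[enr$state == "S1"], 252 / 15504, tolerance = 1e-12)
  # overlap at expectation is unremarkable
  enr2 <- geneset_state_enrichment(c("g1", "g2", "g11", "g12"), gene_states)
  expect_true(all(enr2$p.value >= 0.5))
  # set == universe: overlap = state size, p = 1
  enr3 <- geneset_state_enrichment(paste0("g", 1:20), gene_states)
  expect_equal(enr3$overlap, enr3$state_size)
  expect_true(all(enr3$p.value == 1))
  expect_error(geneset_state_enrichment(character(0), gene_states), "non-empty")
  expect_message(geneset_state_enrichment(c("g1", "nope"), gene_states), "dropped")
})

test_that("TSS matrices are strand-oriented with NA-padded clipped windows", {
  genes <- tibble::tibble(gene_id = c("plus", "minus"), chrom = "chr1",
                          strand = c("+", "-"), start = c(20000L, 20000L),
                          end = c(21000L, 21000L), tss = c(20000L, 20999L))
  # one peak 300 bp downstream (in + orientation) of the plus gene's TSS
  peak <- tibble::tibble(chrom = "chr1", start = 20300, end = 20350)
  m <- tss_signal_matrix(peak, genes, window = 1000, bin_width = 50)
  expect_equal(dim(m$values), c(2, 40))
  hot_plus <- which(m$values["plus", ] > 0)
  expect_equal(hot_plus, 27)  # column covering +300..+350
  # for the minus gene (TSS 20999) the peak lies 649-699 bp downstream in
  # gene orientation, so after row reversal it lights columns 33-34
  hot_minus <- which(m$values["minus", ] > 0)
  expect_true(all(hot_minus %in% 33:34))
  # uniform signal gives a constant matrix
  all_cov <- tibble::tibble(chrom = "chr1", start = 0, end = 50000)
  mu <- tss_signal_matrix(all_cov, genes, window = 1000, bin_width = 50)
  expect_true(all(mu$values == 1))
  # clipped window yields NA columns
  edge <- tibble::tibble(gene_id = "e", chrom = "chr1", strand = "+",
                         start = 200L, end = 900L, tss = 200L)
  me <- tss_signal_matrix(peak, edge, window = 1000, bin_width = 50)
  expect_true(anyNA(me$values))
})

test_that("orientation symmetry: a minus-strand row equals its reversed plus twin", {
  withr::with_seed(10, {
    ps <- sort(sample(seq(1000, 19000, 50), 20))
    peaks <- tibble::tibble(chrom = "chr1", start = ps, end = ps + 40)
    genes <- tibble::tibble(gene_id = c("p", "m"), chrom = "chr1",
                            strand = c("+", "-"), start = 10000L, end = 11000L,
                            tss = c(10000L, 10000L))
    m <- tss_signal_matrix(peaks, genes, window = 2000, bin_width = 50)
    expect_equal(unname(m$values["m", ]), unname(rev(m$values["p", ])))
  })
})

test_that("k-means recovers planted TSS-profile archetypes", {
  withr::with_seed(55, {
    n_per <- 40; n_col <- 100
    prof <- function(center, width, height) {
      v <- height * exp(-((seq_len(n_col) - center) / width)^2)
      v
    }
    arch <- list(
      k4_high = list(k4 = prof(50, 8, 1), k27 = prof(50, 8, 0.05)),
      k4_down = list(k4 = prof(70, 8, 0.8), k27 = prof(50, 10, 0.2)),
      k27_high = list(k4 = prof(50, 8, 0.1), k27 = prof(50, 15, 0.9))
    )
    truth <- rep(1:3, each = n_per)
    noise <- function() matrix(rnorm(3 * n_per * n_col, 0, 0.05), 3 * n_per, n_col)
    k4 <- do.call(rbind, lapply(arch, function(a) {
      matrix(a$k4, n_per, n_col, byrow = TRUE)
    })) + noise()
    k27 <- do.call(rbind, lapply(arch, function(a) {
      matrix(a$k27, n_per, n_col, byrow = TRUE)
    })) + noise()
    ids <- paste0("g", seq_len(3 * n_per))
    mk <- function(values) {
      rownames(values) <- ids
      structure(list(values = values,
                     positions = seq(-2475, 2475, by = 50),
                     gene_id = ids, mark = "x", window = 2500, bin_width = 50),
                class = "tss_matrix")
    }
    cl <- kmeans_bivalent_clusters(mk(k4), mk(k27), k = 3, seed = 7)
    ari <- adjusted_rand_index(as.integer(cl$clusters$cluster), truth)
    expect_gte(ari, 0.9)
    # canonical order: C1 has the highest mean H3K4me3 centroid
    k4_means <- rowMeans(cl$centers[, 1:n_col])
    expect_equal(order(-k4_means), 1:3)
    # duplicate rows land together
    expect_equal(cl$clusters$cluster[1], cl$clusters$cluster[2])
    # k = 1 centroid is the column means
    c1 <- kmeans_bivalent_clusters(mk(k4), mk(k27), k = 1, seed = 7)
    expect_equal(unname(c1$centers[1, ]), unname(colMeans(cbind(k4, k27))),
                 tolerance = 1e-8)
    expect_error(kmeans_bivalent_clusters(mk(k4), mk(k27), k = 500), "exceeds")
  })
})

test_that("cluster trajectories average log(FPKM + 1) per timepoint", {
  clusters <- tibble::tibble(gene_id = c("a", "b", "c"),
                             cluster = factor(c("C1", "C1", "C2")))
  expr <- tibble::tibble(gene_id = c("a", "b", "c"),
                         `0h` = c(0, 0, exp(1) - 1), `24h` = c(exp(1) - 1, exp(1) - 1, 0))
  tr <- cluster_expression_trajectories(clusters, expr)
  expect_equal(tr$mean_log_fpkm[tr$cluster == "C1" & tr$timepoint == "0h"], 0)
  expect_equal(tr$mean_log_fpkm[tr$cluster == "C1" & tr$timepoint == "24h"], 1)
  expect_equal(tr$mean_log_fpkm[tr$cluster == "C2" & tr$timepoint == "0h"], 1)
  # gene order does not matter
  tr2 <- cluster_expression_trajectories(clusters[3:1, ], expr)
  expect_equal(dplyr::arrange(tr, cluster, timepoint),
               dplyr::arrange(tr2, cluster, timepoint))
  # log2 option
  tr3 <- cluster_expression_trajectories(clusters, dplyr::mutate(expr, `0h` = 3),
                                         log_base = 2)
  expect_equal(tr3$mean_log_fpkm[tr3$timepoint == "0h"], c(2, 2))
})

test_that("bivalent-induced genes peak at the induction window by construction", {
  epi <- small_epigenome(seed = 21)
  cl <- tibble::tibble(gene_id = epi$genes$gene_id,
                       cluster = factor(epi$genes$trajectory_class))
  tr <- cluster_expression_trajectories(cl, epi$expression)
  biv <- tr[tr$cluster == "bivalent_induced", ]
  expect_equal(as.character(biv$timepoint[which.max(biv$mean_log_fpkm)]) %in%
                 c("40h", "48h"), TRUE)
})

test_that("marked-vs-unmarked comparison downsamples and tests correctly", {
  withr::with_seed(60, {
    a <- rlnorm(120, 1, 0.5)
    out_same <- mark_expression_comparison(a, a, seed = 2)
    expect_equal(out_same$n_per_group, 120)
    expect_equal(out_same$estimate, 0)
    expect_gt(out_same$p.value, 0.99)
    # planted -1.0 shift in log space is detected
    marked <- exp(rnorm(200, 0, 0.5))
    unmarked <- exp(rnorm(800, 1, 0.5))
    out <- mark_expression_comparison(marked, unmarked, seed = 5)
    expect_equal(out$n_per_group, 200)
    expect_lt(out$p.value, 0.001)
    expect_lt(out$estimate, 0)
    expect_error(mark_expression_comparison(numeric(0), a), "non-empty")
  })
})
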