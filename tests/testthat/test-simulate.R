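test_that("track simulation is shape-correct and seed-reproducible", {
  cfg <- simulation_config(seed = 1, n_bins = 1000)
  a <- simulate_tracks(cfg)
  expect_length(a$truth, 1000)
  expect_equal(dim(a$track$values), c(1000, 5))
  b <- simulate_tracks(cfg)
  expect_identical(a$truth, b$truth)
  expect_identical(a$track$values, b$track$values)
  c2 <- simulate_tracks(simulation_config(seed = 2, n_bins = 1000))
  expect_false(identical(a$truth, c2$truth))
})

test_that("single-state chains emit marks at their Bernoulli rates", {
  em <- matrix(c(0.3, 0.7, 0.05), 1, 3,
               dimnames = list("S1", c("m1", "m2", "m3")))
  cfg <- simulation_config(seed = 6, n_bins = 20000, marks = colnames(em),
                           true_initial = c(S1 = 1), switch_rate = NULL,
                           true_transitions = matrix(1), true_emissions = em)
  tr <- simulate_tracks(cfg)
  freq <- colMeans(tr$track$values)
  se <- sqrt(em[1, ] * (1 - em[1, ]) / 20000)
  expect_true(all(abs(freq - em[1, ]) < 3 * se))
})

test_that("zero emissions give an all-zero track and bad transitions error", {
  em <- matrix(0, 2, 2, dimnames = list(c("S1", "S2"), c("a", "b")))
  cfg <- simulation_config(seed = 1, n_bins = 500, marks = c("a", "b"),
                           true_initial = c(S1 = 0.5, S2 = 0.5),
                           true_emissions = em)
  expect_true(all(simulate_tracks(cfg)$track$values == 0))
  expect_error(
    simulation_config(true_transitions = matrix(0.4, 6, 6)),
    "sum to 1"
  )
})

test_that("empirical transition frequencies approach the generating matrix", {
  cfg <- simulation_config(seed = 3)
  tr <- simulate_tracks(cfg)
  truth <- tr$truth
  from <- truth[-length(truth)]
  to <- truth[-1]
  for (i in seq_len(cfg$K)) {
    n_i <- sum(from == i)
    if (n_i < 200) next
    phat <- tabulate(to[from == i], nbins = cfg$K) / n_i
    p <- cfg$true_transitions[i, ]
    se <- sqrt(p * (1 - p) / n_i)
    expect_true(all(abs(phat - p) < pmax(3 * se, 0.01)),
                info = paste("row", i))
  }
})

test_that("gene models respect the genome and carry valid trajectory classes", {
  epi <- small_epigenome()
  g <- epi$genes
  chrlen <- epi$grid$genome$length[match(g$chrom, epi$grid$genome$chrom)]
  expect_true(all(g$tss >= 0 & g$tss < chrlen))
  expect_true(all(g$start >= 0 & g$end <= chrlen & g$end > g$start))
  expect_true(all(g$trajectory_class %in% c("constitutive", "bivalent_induced", "repressed")))
  # exons within span
  ex <- purrr::map2_lgl(g$exon_starts, g$start, ~ all(.x >= .y))
  expect_true(all(ex))
  # bivalent genes only in the active states
  expect_true(all(g$true_state[g$trajectory_class == "bivalent_induced"] %in% c("S1", "S2")))
})

test_that("expression honours trajectory classes", {
  epi <- small_epigenome(seed = 8)
  expr <- epi$expression
  tps <- setdiff(names(expr), "gene_id")
  # repressed genes stay at or below the threshold nearly always
  rep_ids <- epi$genes$gene_id[epi$genes$trajectory_class == "repressed"]
  if (length(rep_ids) >= 10) {
    sub <- as.matrix(expr[expr$gene_id %in% rep_ids, tps])
    expect_gt(mean(apply(sub, 1, function(r) all(r <= 1))), 0.9)
  }
  # bivalent-induced genes peak at the induction timepoints
  biv_ids <- epi$genes$gene_id[epi$genes$trajectory_class == "bivalent_induced"]
  sub <- as.matrix(expr[expr$gene_id %in% biv_ids, tps])
  mean_traj <- colMeans(log1p(sub))
  expect_true(names(which.max(mean_traj)) %in% c("40h", "48h"))
  # fold-change 1 removes the induction signal
  cfg0 <- simulation_config(seed = 8, n_bins = 4000, gene_count = 80,
                            te_count = 400, cpg_count = 4000, induced_fold = 1)
  tr0 <- simulate_tracks(cfg0)
  g0 <- simulate_genes(tr0$truth, tr0$grid, cfg0)
  e0 <- simulate_expression(g0, cfg0)
  biv0 <- as.matrix(e0[g0$trajectory_class == "bivalent_induced",
                       c("0h", "40h")])
  expect_lt(abs(mean(log1p(biv0[, "40h"])) - mean(log1p(biv0[, "0h"]))), 0.2)
  # zero genes give an empty table
  e_empty <- simulate_expression(g0[0, ], cfg0)
  expect_equal(nrow(e_empty), 0)
  expect_error(simulate_expression(dplyr::mutate(g0, trajectory_class = "wobbly"), cfg0),
               "unknown trajectory class")
})

test_that("methylome follows state- and H3K9me3-conditional Beta laws", {
  epi <- medium_epigenome(seed = 12)
  seg <- truth_segmentation(epi)
  summ <- state_methylation_summary(epi$cpgs, seg, min_coverage = 0)
  hetero <- summ[summ$state %in% c("S4", "S5"), ]
  expect_true(all(hetero$frac_methylated > 0.9))
  active <- summ[summ$state %in% c("S1", "S2"), ]
  expect_true(all(active$frac_methylated < 0.1))
  # CpG-dense open states
  expect_gt(summ$density_per_kb[summ$state == "S2"],
            summ$density_per_kb[summ$state == "S4"])
  # no CpGs requested -> empty table
  cfg0 <- simulation_config(seed = 1, n_bins = 500, cpg_count = 0)
  tr0 <- simulate_tracks(cfg0)
  expect_equal(nrow(simulate_methylome(tr0$truth, tr0$track, tr0$grid, cfg0)), 0)
  expect_error(simulation_config(meth_beta = list(S1 = c(-1, 2))), "positive")
})

test_that("TE catalogue carries planted state-conditional structure", {
  epi <- medium_epigenome(seed = 30)
  tes <- epi$tes
  expect_true(all(tes$sw_score >= 0))
  expect_true(all(tes$te_class %in% c("LINE", "SINE", "LTR", "DNA", "Other")))
  # young (high-sw) TEs in the H3K9me3-like state by construction
  expect_gt(mean(tes$sw_score[tes$true_state == "S5"]),
            mean(tes$sw_score) + 1000)
  # most TEs in the empty state
  expect_gt(mean(tes$true_state == "S4"), 0.8)
})

test_that("peak sets carry the configured 30 h turnover structure", {
  epi <- small_epigenome(seed = 19)
  expect_setequal(names(epi$peaks$baseline), epi$config$marks)
  k27_base <- epi$peaks$baseline$H3K27me3
  k27_30h <- epi$peaks$post30h$H3K27me3
  s <- interval_overlap_stats(k27_30h, k27_base)
  # a substantial minority of 30 h peaks occupy baseline loci
  frac_shared <- s$n_a_overlapping / s$n_a
  expect_gt(frac_shared, 0.2)
  expect_lt(frac_shared, 0.75)
  # bivalent TSSs are covered by baseline H3K4me3 and H3K27me3 but lose
  # H3K27me3 at 30 h
  biv <- epi$genes[epi$genes$trajectory_class == "bivalent_induced", ]
  tssw <- tibble::tibble(chrom = biv$chrom, start = pmax(biv$tss - 100, 0),
                         end = biv$tss + 100)
  gr <- function(x) GenomicRanges::GRanges(x$chrom, IRanges::IRanges(x$start + 1, x$end))
  expect_true(all(IRanges::overlapsAny(gr(tssw), gr(k27_base))))
  expect_true(all(IRanges::overlapsAny(gr(tssw), gr(epi$peaks$baseline$H3K4me3))))
  expect_false(any(IRanges::overlapsAny(gr(tssw), gr(k27_30h))))
})

test_that("a written epigenome reads back through the standard formats", {
  epi <- small_epigenome(seed = 2)
  dir <- withr::local_tempdir()
  files <- write_epigenome(epi, dir)
  expect_true(all(file.exists(files$file)))
  genome <- read_genome(file.path(dir, "genome.tsv"))
  expect_equal(genome, epi$grid$genome)
  track <- read_track_tsv(file.path(dir, "track.tsv"), genome)
  expect_equal(track$values, epi$track$values)
  genes <- read_gene_models(file.path(dir, "genes.bed12"))
  expect_equal(nrow(genes), nrow(epi$genes))
  expect_equal(genes$tss, epi$genes$tss)
  tes <- read_repeatmasker(file.path(dir, "tes.out"))
  expect_equal(nrow(tes), nrow(epi$tes))
  expect_equal(tes$sw_score[order(tes$chrom, tes$start, tes$end)],
               epi$tes$sw_score[order(epi$tes$chrom, epi$tes$start, epi$tes$end)])
  cpgs <- read_methylation(file.path(dir, "methylation.tsv"))
  expect_equal(nrow(cpgs), nrow(epi$cpgs))
  fpkm <- read_fpkm(file.path(dir, "fpkm.tsv"))
  expect_equal(dim(fpkm), dim(epi$expression))
})
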