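test_that("RepeatMasker round trip preserves the catalogue", {
  epi <- small_epigenome(seed = 16)
  f <- withr::local_tempfile(fileext = ".out")
  write_repeatmasker(epi$tes, f)
  back <- read_repeatmasker(f)
  expect_equal(nrow(back), nrow(epi$tes))
  ord_a <- order(back$chrom, back$start, back$end)
  ord_b <- order(epi$tes$chrom, epi$tes$start, epi$tes$end)
  expect_equal(back$start[ord_a], epi$tes$start[ord_b])
  expect_equal(back$sw_score[ord_a], epi$tes$sw_score[ord_b])
  expect_equal(back$te_class[ord_a], epi$tes$te_class[ord_b])
})

test_that("simple repeats are excluded and malformed lines rejected", {
  f <- withr::local_tempfile(fileext = ".out")
  writeLines(c(
    "   SW   perc perc perc  query  position ...",
    "score   div. del. ins.  sequence ...",
    "",
    "  225  10.0  1.0  1.0  chr1      101      300 (0) + B1   SINE/B1     1 200 (0)  1",
    "  900  10.0  1.0  1.0  chr1      501      900 (0) C (TA)n Simple_repeat 1 400 (0) 2",
    " 1200  10.0  1.0  1.0  chr1     1001     2200 (0) + L1Md  LINE/L1     1 1200 (0) 3"
  ), f)
  tes <- read_repeatmasker(f)
  expect_equal(nrow(tes), 2)
  expect_equal(tes$te_class, c("SINE", "LINE"))
  expect_equal(tes$start, c(100L, 1000L))  # 1-based begin converted
  expect_equal(nrow(read_repeatmasker(f, exclude_simple = FALSE)), 3)
  writeLines(c("", "", "", "  225 10.0 1.0"), f)
  expect_error(read_repeatmasker(f), "malformed")
})

test_that("TE state distribution counts by majority bp", {
  seg <- manual_segmentation(c(1L, 1L, 2L), states = c("S1", "S2"), bin_size = 1000)
  tes <- tibble::tibble(
    chrom = "chr1",
    start = c(rep(100L, 0), seq(0L, 700L, by = 100L)[1:8], 2100L, 1800L),
    end = c(seq(0L, 700L, by = 100L)[1:8] + 50L, 2500L, 2400L),
    te_class = c(rep("LINE", 8), "SINE", "SINE"),
    sw_score = 1000L
  )
  dist <- te_state_distribution(tes, seg)
  expect_equal(dist$states$fraction[dist$states$state == "S1"], 0.8)
  expect_equal(dist$states$fraction[dist$states$state == "S2"], 0.2)
  expect_equal(sum(dist$states$fraction), 1)
  # class composition per state and whole-catalogue row
  cat_row <- dist$classes[dist$classes$state == "catalogue", ]
  expect_equal(cat_row$fraction[cat_row$te_class == "LINE"], 0.8)
  s1_rows <- dist$classes[dist$classes$state == "S1", ]
  expect_equal(sum(s1_rows$fraction), 1)
})

test_that("planted LINE enrichment in the H3K9me3-like state is recovered", {
  epi <- medium_epigenome(seed = 33)
  dist <- te_state_distribution(epi$tes, truth_segmentation(epi))
  cls <- dist$classes
  # the H3K9me3-like state is selectively enriched for retrotransposons
  # that can still mobilise (LINEs + LTRs together)
  retro <- function(st) sum(cls$fraction[cls$state == st & cls$te_class %in% c("LINE", "LTR")])
  expect_gt(retro("S5"), retro("catalogue") + 0.1)
  sine_s5 <- cls$fraction[cls$state == "S5" & cls$te_class == "SINE"]
  expect_lt(ifelse(length(sine_s5) == 0, 0, sine_s5), 0.1)
})

test_that("mark groups follow their definitions and partition the catalogue", {
  tes <- tibble::tibble(
    chrom = "chr1", start = c(0L, 1000L, 2000L, 3000L, 4000L),
    end = c(500L, 1500L, 2500L, 3500L, 4500L), sw_score = 1000L
  )
  marks <- list(
    H3K9me3 = tibble::tibble(chrom = "chr1", start = 0L, end = 600L),
    H3K27me3 = tibble::tibble(chrom = "chr1", start = 2000L, end = 2500L)
  )
  cpgs <- tibble::tibble(
    chrom = "chr1", pos = c(100L, 1100L, 2100L, 3100L),
    beta = c(0.95, 0.9, 0.1, 0.1), coverage = 10L
  )
  out <- suppressMessages(te_mark_groups(tes, marks, cpgs))
  expect_equal(as.character(out$mark_group),
               c("meC+K9", "meC-only", "K27-only", "none", "no-data"))
  expect_equal(sum(table(out$mark_group)), nrow(tes))
})

test_that("TEs under H3K9me3 are also methylated on synthetic data", {
  epi <- small_epigenome(seed = 27)
  out <- suppressMessages(te_mark_groups(epi$tes, epi$peaks$baseline, epi$cpgs))
  k9 <- out[out$has_k9 & out$n_cpg > 0, ]
  expect_gt(nrow(k9), 10)
  expect_gt(mean(k9$methylated), 0.9)
  # cross-module identity: CpGs inside K9-marked TEs are themselves nearly
  # all methylated when tabulated through the methylation module
  tab <- mark_cooccupancy_methylation(
    epi$cpgs, k9[, c("chrom", "start", "end")], truth_segmentation(epi)
  )
  expect_gt(tab$frac_methylated[tab$state == "all"], 0.9)
})

test_that("subsampled age test is seeded, degenerate-safe and validates n", {
  x <- c(1, 2, 3, 4, 5)
  at <- subsampled_age_test(x, x, n = 5, reps = 2, seed = 1)
  expect_equal(at$statistic, 0)
  expect_equal(at$p.value, 1)
  expect_error(subsampled_age_test(x, x, n = 10, reps = 5), "replace")
  expect_error(subsampled_age_test(x, x, n = 2, reps = 1), "at least 2")
  withr::with_seed(2, {
    g <- rnorm(5000, 1); r <- rnorm(5000)
    a1 <- subsampled_age_test(g, r, n = 500, reps = 20, seed = 9)
    a2 <- subsampled_age_test(g, r, n = 500, reps = 20, seed = 9)
    expect_identical(a1$group_means, a2$group_means)
    expect_lt(a1$p.value, 1e-6)
    expect_gt(a1$estimate, 0.8)
    td <- tidy(a1)
    expect_equal(td$n, 500)
    # pooled-value variant also detects the shift
    ap <- subsampled_age_test(g, r, n = 500, reps = 20, seed = 9, compare = "pooled")
    expect_lt(ap$p.value, 1e-6)
    # with-replacement sampling allows n above the group size
    aw <- subsampled_age_test(g[1:100], r, n = 500, reps = 10, seed = 3, replace = TRUE)
    expect_s3_class(aw, "age_test")
  })
})

test_that("one-way ANOVA with Tukey matches the sum-of-squares oracle", {
  groups <- list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(7, 8, 9))
  out <- anova_tukey(groups)
  # SSB = 62 on 2 df, SSW = 6 on 6 df -> F = 31
  expect_equal(out$anova$statistic, 31, tolerance = 1e-12)
  expect_equal(out$anova$df1, 2)
  expect_equal(out$anova$df2, 6)
  # far group has smaller Tukey p than the near pair
  p_far <- out$tukey$adj.p.value[out$tukey$contrast == "c-a"]
  p_near <- out$tukey$adj.p.value[out$tukey$contrast == "b-a"]
  expect_lt(p_far, p_near)
  # identical groups: F = 0, p = 1
  out0 <- anova_tukey(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(out0$anova$statistic, 0)
  expect_equal(out0$anova$p.value, 1)
  # data-frame interface agrees with the list interface
  df <- tibble::tibble(value = unlist(groups), group = rep(names(groups), each = 3))
  expect_equal(anova_tukey(df, "value", "group")$anova, out$anova)
  expect_error(anova_tukey(list(a = 1, b = c(1, 2))), "at least two values")
})

test_that("planted sw-score ordering of repressive groups is recovered", {
  epi <- simulate_epigenome(simulation_config(seed = 40, n_bins = 20000,
                                              te_count = 3000, cpg_count = 20000))
  out <- suppressMessages(te_mark_groups(epi$tes, epi$peaks$baseline, epi$cpgs))
  mean_sw <- tapply(out$sw_score, out$mark_group, mean)
  # meC-only TEs (mostly the empty state) are older than meC+K9 TEs
  # (concentrated in the young H3K9me3-like state)
  expect_lt(mean_sw[["meC-only"]], mean_sw[["meC+K9"]])
  # the H3K9me3-like state itself holds the young TEs: subsampled contrast
  # of its scores against the whole catalogue is strongly significant
  at <- subsampled_age_test(out$sw_score[out$true_state == "S5"],
                            out$sw_score, n = 100, reps = 50, seed = 2,
                            replace = TRUE)
  expect_lt(at$p.value, 1e-4)
  expect_gt(at$estimate, 0)
})
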