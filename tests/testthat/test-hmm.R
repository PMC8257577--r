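test_that("emission_prob follows the factorised Bernoulli form", {
  p <- hmm_params(1, matrix(1), matrix(c(0.8, 0.2), 1, 2))
  expect_equal(emission_prob(p, 1, c(1, 0)), 0.64)
  p5 <- hmm_params(1, matrix(1), matrix(0.5, 1, 5))
  expect_equal(emission_prob(p5, 1, c(1, 0, 1, 1, 0)), 0.5^5)
  # degenerate emission gives exact zero, no overflow
  pd <- hmm_params(1, matrix(1), matrix(c(1, 0.5), 1, 2))
  expect_equal(emission_prob(pd, 1, c(0, 1)), 0)
  expect_error(emission_prob(p, 1, c(1, 0, 1)), "length")
})

test_that("forward likelihood reproduces the worked two-state example", {
  p <- hmm_params(c(0.5, 0.5), rbind(c(0.9, 0.1), c(0.1, 0.9)),
                  matrix(c(0.9, 0.1), 2, 1))
  # brute force: 0.3645 + 3 * 0.0045 = 0.378
  expect_equal(exp(hmm_loglik(p, matrix(c(1, 1), 2, 1))), 0.378, tolerance = 1e-4)
  # K = 1: plain product of Bernoullis
  p1 <- hmm_params(1, matrix(1), matrix(0.5, 1, 1))
  expect_equal(exp(hmm_loglik(p1, matrix(c(1, 0, 1), 3, 1))), 0.125, tolerance = 1e-6)
})

test_that("forward and posterior agree with exhaustive enumeration", {
  withr::with_seed(42, {
    for (i in 1:25) {
      K <- sample(2:3, 1); M <- sample(1:3, 1); T_ <- sample(2:6, 1)
      d <- random_hmm_draw(K, M)
      X <- matrix(rbinom(T_ * M, 1, 0.5), T_, M)
      p <- hmm_params(d$initial, d$transitions, d$emissions)
      expect_equal(hmm_loglik(p, X),
                   log(oracle_likelihood(d$initial, d$transitions, d$emissions, X)),
                   tolerance = 1e-10)
      seg <- decode_states(p, X)
      expect_equal(unname(seg$posterior),
                   oracle_posterior(d$initial, d$transitions, d$emissions, X),
                   tolerance = 1e-10)
      expect_equal(rowSums(seg$posterior), rep(1, T_), tolerance = 1e-12)
    }
  })
})

test_that("separable emissions decode to the observation pattern", {
  p <- hmm_params(c(0.5, 0.5), rbind(c(0.95, 0.05), c(0.05, 0.95)),
                  rbind(rep(1, 3), rep(0, 3)))
  X2 <- rbind(matrix(1, 4, 3), matrix(0, 3, 3), matrix(1, 2, 3))
  seg <- decode_states(p, X2)
  expect_equal(seg$labels, c(1, 1, 1, 1, 2, 2, 2, 1, 1))
})

test_that("EM fits deterministically, monotonically, and solves K = 1 in closed form", {
  withr::with_seed(9, {
    X <- matrix(rbinom(400 * 3, 1, rep(c(0.2, 0.6, 0.8), each = 400)), 400, 3,
                dimnames = list(NULL, c("a", "b", "c")))
  })
  f1 <- fit_hmm(X, K = 1, seed = 2)
  expect_equal(unname(f1$params$emissions[1, ]), unname(colMeans(X)), tolerance = 1e-6)
  expect_true(f1$converged)

  f2a <- fit_hmm(X, K = 2, seed = 7, max_iter = 50)
  f2b <- fit_hmm(X, K = 2, seed = 7, max_iter = 50)
  expect_identical(f2a$params$emissions, f2b$params$emissions)
  expect_true(all(diff(f2a$trace$loglik) > -1e-8))

  expect_warning(fit_hmm(matrix(1, 10, 1), K = 3, seed = 1, max_iter = 5),
                 "distinct observation patterns")
})

test_that("relabelling permutes parameters consistently", {
  withr::with_seed(31, {
    d <- random_hmm_draw(3, 2)
    p <- hmm_params(d$initial, d$transitions, d$emissions)
    X <- matrix(rbinom(40, 1, 0.5), 20, 2)
    seg <- decode_states(p, X)
    perm <- c(3L, 1L, 2L)
    pp <- hmm_params(d$initial[perm], d$transitions[perm, perm],
                     d$emissions[perm, , drop = FALSE])
    seg_p <- decode_states(pp, X)
    # relabelled model assigns the same underlying state to every bin
    expect_equal(perm[seg_p$labels], seg$labels)
    expect_equal(hmm_loglik(p, X), hmm_loglik(pp, X), tolerance = 1e-12)
  })
})

test_that("states rich in open-chromatin marks are listed first after fitting", {
  cfg <- recovery_config(seed = 13, n_bins = 6000)
  tr <- simulate_tracks(cfg)
  fit <- fit_hmm(tr$track, K = 3, seed = 5)
  em <- fit$params$emissions
  active_score <- rowMeans(em[, c("ATAC", "H3K4me3", "H2AZ")])
  expect_equal(order(-active_score), 1:3)
})

test_that("genome fractions are bp-weighted and sum to one", {
  seg1 <- manual_segmentation(rep(1L, 5), states = c("S1", "S2"))
  gf1 <- genome_fraction(seg1)
  expect_equal(gf1$fraction, c(1, 0))
  seg2 <- manual_segmentation(rep(c(1L, 2L), 5), states = c("S1", "S2"))
  expect_equal(genome_fraction(seg2)$fraction, c(0.5, 0.5))
  # short terminal bin weighs by true length: 3 bins of 1000 but genome 2500
  seg3 <- manual_segmentation(c(1L, 2L, 2L), states = c("S1", "S2"), genome_len = 2500)
  gf3 <- genome_fraction(seg3)
  expect_equal(sum(gf3$bp), 2500)
  expect_equal(gf3$fraction, c(1000, 1500) / 2500)
})

test_that("truth-state fractions sit near the chain's stationary distribution", {
  cfg <- simulation_config(seed = 2)
  tr <- simulate_tracks(cfg)
  seg <- truth_segmentation(structure(
    list(config = cfg, grid = tr$grid, truth = tr$truth),
    class = "synthetic_epigenome"
  ))
  frac <- genome_fraction(seg)$fraction
  pi0 <- unname(cfg$true_initial)
  # 3 SE binomial bound per state (dependent draws, so this is generous for
  # the big state and indicative for the rare ones at 50k bins)
  se <- sqrt(pi0 * (1 - pi0) / cfg$n_bins)
  expect_true(all(abs(frac - pi0) < pmax(3 * se, 0.02)))
})

test_that("log-likelihood is non-decreasing in K and select_k tabulates BIC", {
  cfg <- recovery_config(seed = 23, n_bins = 1500)
  tr <- simulate_tracks(cfg)
  tab <- select_k(tr$track, 1:4, seed = 3, n_restarts = 2, max_iter = 50, tol = 1e-3)
  expect_equal(tab$K, 1:4)
  expect_true(all(diff(tab$loglik) > -1e-6))
  expect_equal(tab$n_params, (tab$K - 1) + tab$K * (tab$K - 1) + tab$K * 5)
  expect_equal(tab$bic, -2 * tab$loglik + tab$n_params * log(1500))
  # K = 1 matches the closed-form independent-Bernoulli likelihood
  ml <- colMeans(tr$track$values)
  p1 <- hmm_params(1, matrix(1), matrix(ml, 1), marks = colnames(tr$track$values))
  expect_equal(tab$loglik[1], hmm_loglik(p1, tr$track), tolerance = 1e-4)
})

test_that("viterbi decoding matches posterior decoding on well-separated data", {
  cfg <- recovery_config(seed = 3, n_bins = 2000)
  tr <- simulate_tracks(cfg)
  p <- hmm_params(cfg$true_initial, cfg$true_transitions, cfg$true_emissions)
  post <- decode_states(p, tr$track, method = "posterior", keep_posterior = FALSE)
  vit <- decode_states(p, tr$track, method = "viterbi")
  expect_gt(mean(post$labels == vit$labels), 0.98)
  expect_gt(mean(post$labels == tr$truth), 0.95)
})

test_that("segmentation exports merge runs and round-trip through BED", {
  seg <- manual_segmentation(c(1L, 1L, 2L, 2L, 1L), states = c("S1", "S2"))
  si <- state_intervals(seg)
  expect_equal(nrow(si), 3)
  expect_equal(as.character(si$state), c("S1", "S2", "S1"))
  expect_equal(si$end - si$start, c(2000, 2000, 1000))
  f <- withr::local_tempfile(fileext = ".bed")
  write_segmentation(seg, f)
  back <- read_bed(f)
  expect_equal(nrow(back), 3)
  expect_equal(back$name, c("S1", "S2", "S1"))
})

test_that("tidy, glance and autoplot summarise a fit", {
  cfg <- recovery_config(seed = 17, n_bins = 800)
  tr <- simulate_tracks(cfg)
  fit <- fit_hmm(tr$track, K = 2, seed = 1, max_iter = 30)
  td <- tidy(fit)
  expect_equal(nrow(td), 2 * 5)
  expect_true(all(td$emission >= 0 & td$emission <= 1))
  gl <- glance(fit)
  expect_equal(gl$K, 2)
  expect_equal(gl$bic, -2 * gl$loglik + gl$n_params * log(800))
  expect_s3_class(autoplot(fit), "ggplot")
})
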