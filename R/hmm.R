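EMISSION_FLOOR <- 1e-6
STOCHASTIC_TOL <- 1e-8

#' Parameters of a multivariate Bernoulli-emission HMM
#'
#' `K` chromatin states emit `M` conditionally independent binary marks;
#' `emissions[k, m]` is the probability that mark `m` is present in a bin of
#' state `k` (the "emission parameters" displayed as a state-by-mark
#' heatmap). `initial` must sum to 1 and every row of `transitions` must sum
#' to 1 (tolerance 1e-8).
#'
#' @param initial Length-`K` initial state distribution.
#' @param transitions `K x K` row-stochastic transition matrix.
#' @param emissions `K x M` matrix of Bernoulli presence probabilities.
#' @param marks Mark names (default from `emissions` column names).
#' @param states State labels (default `S1..SK`).
#' @return An object of class `hmm_params`.
#' @export
hmm_params <- function(initial, transitions, emissions,
                       marks = colnames(emissions), states = NULL) {
  emissions <- as.matrix(emissions)
  transitions <- as.matrix(transitions)
  K <- length(initial)
  M <- ncol(emissions)
  if (!all(dim(transitions) == c(K, K)) || nrow(emissions) != K) {
    abort("inconsistent parameter dimensions")
  }
  if (abs(sum(initial) - 1) > STOCHASTIC_TOL) abort("`initial` must sum to 1")
  if (any(abs(rowSums(transitions) - 1) > STOCHASTIC_TOL)) {
    abort("`transitions` rows must sum to 1")
  }
  if (any(initial < 0) || any(transitions < 0)) abort("negative probabilities")
  if (any(emissions < 0) || any(emissions > 1)) abort("emissions must lie in [0, 1]")
  if (is.null(marks)) marks <- paste0("M", seq_len(M))
  if (is.null(states)) states <- state_labels(K)
  dimnames(emissions) <- list(states, marks)
  dimnames(transitions) <- list(states, states)
  structure(
    list(initial = setNames(as.numeric(initial), states),
         transitions = transitions, emissions = emissions,
         states = states, marks = marks, K = K, M = M),
    class = "hmm_params"
  )
}

#' @export
print.hmm_params <- function(x, ...) {
  cat("<hmm_params> ", x$K, " states, ", x$M, " marks\n", sep = "")
  cat("emissions:\n")
  print(round(x$emissions, 3))
  invisible(x)
}

#' Probability of one observation under one state
#'
#' `prod_m p[k,m]^x_m (1 - p[k,m])^(1 - x_m)`, evaluated in log space.
#' Degenerate emissions (0 or 1) are honoured exactly, so an impossible
#' observation returns probability 0.
#'
#' @param params An `hmm_params`.
#' @param state State index or label.
#' @param x Binary observation vector of length `M`.
#' @return Probability in `[0, 1]`.
#' @export
emission_prob <- function(params, state, x) {
  stopifnot(inherits(params, "hmm_params"))
  if (is.character(state)) state <- match(state, params$states)
  if (length(x) != params$M) abort("observation length must equal the mark count")
  if (!all(x %in% c(0, 1))) abort("observation must be binary")
  p <- params$emissions[state, ]
  lg <- sum(ifelse(x == 1, log(p), log1p(-p)))
  exp(lg)
}

floored_emissions <- function(emissions) {
  pmin(pmax(emissions, EMISSION_FLOOR), 1 - EMISSION_FLOOR)
}

# T x K matrix of emission probabilities for a binary observation matrix
emission_matrix <- function(params, X) {
  p <- floored_emissions(params$emissions)
  exp(X %*% t(log(p)) + (1 - X) %*% t(log1p(-p)))
}

# split observations into per-chromosome matrices (chain restarts at pi)
track_sequences <- function(track) {
  if (inherits(track, "track_matrix")) {
    cb <- track$grid$chrom_bins
    lapply(seq_len(nrow(cb)), function(i) {
      track$values[cb$offset[i] + seq_len(cb$n_bins[i]), , drop = FALSE]
    })
  } else {
    list(as.matrix(track))
  }
}

track_values <- function(track) {
  if (inherits(track, "track_matrix")) track$values else as.matrix(track)
}

check_binary_obs <- function(track) {
  v <- track_values(track)
  if (!all(v %in% c(0, 1))) abort("observations must be binary; binarize first")
  invisible(v)
}

#' Log-likelihood of a binary track under HMM parameters
#'
#' Scaled forward recursion; chromosomes are independent sequences that each
#' restart at the initial distribution. Emission probabilities are floored
#' at 1e-6 away from 0/1 so degenerate parameters cannot produce `-Inf`.
#'
#' @param params An `hmm_params`.
#' @param track A binary `track_matrix`, or a plain bins-x-marks 0/1 matrix
#'   (treated as a single sequence).
#' @return Scalar log-likelihood.
#' @export
hmm_loglik <- function(params, track) {
  stopifnot(inherits(params, "hmm_params"))
  check_binary_obs(track)
  seqs <- track_sequences(track)
  sum(vapply(seqs, function(X) {
    forward_loglik(emission_matrix(params, X), params$transitions, params$initial)
  }, numeric(1)))
}

random_init <- function(K, M, marks) {
  emissions <- matrix(runif(K * M, 0.1, 0.9), K, M)
  transitions <- matrix(1 / K, K, K) + matrix(rgamma(K * K, shape = 2), K, K) * 0.1
  transitions <- transitions / rowSums(transitions)
  hmm_params(rep(1 / K, K), transitions, emissions, marks = marks)
}

em_once <- function(seqs, params, tol, max_iter) {
  K <- params$K
  trace <- numeric(0)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    ll <- 0
    xi_tot <- matrix(0, K, K)
    emis_num <- matrix(0, K, params$M)
    gamma_sum <- numeric(K)
    pi_rows <- matrix(0, length(seqs), K)
    for (s in seq_along(seqs)) {
      X <- seqs[[s]]
      fb <- fb_pass(emission_matrix(params, X), params$transitions, params$initial)
      ll <- ll + fb$loglik
      xi_tot <- xi_tot + fb$xi_sum
      emis_num <- emis_num + crossprod(fb$gamma, X)
      gamma_sum <- gamma_sum + colSums(fb$gamma)
      pi_rows[s, ] <- fb$gamma[1, ]
    }
    trace <- c(trace, ll)
    if (iter > 1 && (ll - trace[iter - 1]) < tol) {
      converged <- TRUE
      break
    }
    new_pi <- pmax(colMeans(pi_rows), 1e-10)
    new_pi <- new_pi / sum(new_pi)
    rs <- rowSums(xi_tot)
    new_A <- params$transitions
    ok <- rs > 0
    new_A[ok, ] <- xi_tot[ok, , drop = FALSE] / rs[ok]
    new_A <- pmax(new_A, 1e-10)
    new_A <- new_A / rowSums(new_A)
    new_p <- params$emissions
    okg <- gamma_sum > 0
    new_p[okg, ] <- emis_num[okg, , drop = FALSE] / gamma_sum[okg]
    new_p <- floored_emissions(new_p)
    params <- hmm_params(new_pi, new_A, new_p, marks = params$marks,
                         states = params$states)
  }
  list(params = params, trace = trace, converged = converged)
}

# order states so that open-chromatin-heavy states come first; falls back to
# overall emission weight when no active mark is recognisable by name
state_display_order <- function(emissions, marks) {
  active <- grepl("ATAC|H3K4|H2A", marks, ignore.case = TRUE)
  score <- if (any(active)) rowMeans(emissions[, active, drop = FALSE]) else rowMeans(emissions)
  order(-score, -rowMeans(emissions))
}

permute_params <- function(params, perm) {
  hmm_params(
    initial = unname(params$initial[perm]),
    transitions = params$transitions[perm, perm, drop = FALSE],
    emissions = params$emissions[perm, , drop = FALSE],
    marks = params$marks, states = state_labels(params$K)
  )
}

#' Fit a Bernoulli-emission HMM by Baum-Welch EM
#'
#' Seeded random initialisation (emissions ~ Uniform(0.1, 0.9), transition
#' rows uniform plus Dirichlet-style jitter), expectation-maximisation until
#' the log-likelihood gain drops below `tol` or `max_iter` is reached. The
#' log-likelihood is non-decreasing across iterations (recorded in the fit
#' trace). States are relabelled for display so that states rich in
#' open-chromatin marks come first.
#'
#' @param track Binary `track_matrix` or 0/1 matrix.
#' @param K Number of states (>= 1).
#' @param seed Integer seed; the same seed reproduces the fit exactly.
#' @param tol Log-likelihood gain below which EM stops (default 1e-4).
#' @param max_iter Maximum EM iterations (default 200).
#' @param n_restarts Number of seeded random restarts; the best final
#'   log-likelihood wins (default 1).
#' @param relabel Reorder states for display (default TRUE).
#' @return An object of class `hmm_fit` with elements `params`, `loglik`,
#'   `trace` (tibble `iteration`, `loglik`), `converged`, `iterations`,
#'   `seed`, `n_obs`, `n_params`.
#' @export
fit_hmm <- function(track, K, seed = 1, tol = 1e-4, max_iter = 200,
                    n_restarts = 1, relabel = TRUE) {
  check_number(K, "K", lower = 1)
  V <- check_binary_obs(track)
  seqs <- track_sequences(track)
  M <- ncol(V)
  marks <- colnames(V) %||% paste0("M", seq_len(M))
  n_pat <- nrow(unique(as.data.frame(V)))
  if (K > n_pat) {
    warn(paste0("K = ", K, " exceeds the ", n_pat,
                " distinct observation patterns; degenerate states are possible"))
  }
  best <- NULL
  for (r in seq_len(n_restarts)) {
    res <- withr::with_seed(as.integer(seed) + r - 1L, {
      init <- random_init(K, M, marks)
      em_once(seqs, init, tol = tol, max_iter = max_iter)
    })
    if (is.null(best) || tail(res$trace, 1) > tail(best$trace, 1)) best <- res
  }
  params <- best$params
  if (relabel) {
    params <- permute_params(params, state_display_order(params$emissions, marks))
  }
  n_obs <- nrow(V)
  n_params <- (K - 1) + K * (K - 1) + K * M
  structure(
    list(params = params, loglik = tail(best$trace, 1),
         trace = tibble(iteration = seq_along(best$trace), loglik = best$trace),
         converged = best$converged, iterations = length(best$trace),
         seed = seed, n_obs = n_obs, n_params = n_params, K = K, M = M),
    class = "hmm_fit"
  )
}

#' @export
print.hmm_fit <- function(x, ...) {
  cat("<hmm_fit> K = ", x$K, ", M = ", x$M, ", loglik = ",
      format(x$loglik, digits = 8), ", ", x$iterations, " EM iterations (",
      if (x$converged) "converged" else "max_iter reached", ")\n", sep = "")
  print(x$params)
  invisible(x)
}

as_params <- function(object) {
  if (inherits(object, "hmm_fit")) object$params
  else if (inherits(object, "hmm_params")) object
  else abort("expected an `hmm_fit` or `hmm_params`")
}

#' Decode a binary track into per-bin states
#'
#' Default decoding assigns each bin the state with maximal
#' forward-backward posterior probability; Viterbi (jointly most probable
#' path) is available via `method = "viterbi"`.
#'
#' @param object An `hmm_fit` or `hmm_params`.
#' @param track Binary `track_matrix` or 0/1 matrix.
#' @param method `"posterior"` (default) or `"viterbi"`.
#' @param keep_posterior Keep the bins-x-K posterior matrix (default TRUE
#'   for posterior decoding).
#' @return An object of class `state_segmentation`: per-bin integer labels,
#'   state names, the bin grid, and optionally the posterior matrix.
#' @export
decode_states <- function(object, track, method = c("posterior", "viterbi"),
                          keep_posterior = TRUE) {
  params <- as_params(object)
  method <- match.arg(method)
  check_binary_obs(track)
  seqs <- track_sequences(track)
  grid <- if (inherits(track, "track_matrix")) track$grid else {
    bin_grid(tibble(chrom = "seq1", length = nrow(track_values(track))), bin_size = 1)
  }
  labels <- integer(0)
  post <- if (method == "posterior" && keep_posterior) NULL else NA
  post_rows <- list()
  for (X in seqs) {
    if (method == "posterior") {
      fb <- fb_pass(emission_matrix(params, X), params$transitions, params$initial)
      labels <- c(labels, max.col(fb$gamma, ties.method = "first"))
      if (keep_posterior) post_rows[[length(post_rows) + 1]] <- fb$gamma
    } else {
      p <- floored_emissions(params$emissions)
      logemis <- X %*% t(log(p)) + (1 - X) %*% t(log1p(-p))
      labels <- c(labels, viterbi_path(logemis, log(pmax(params$transitions, 1e-300)),
                                       log(pmax(params$initial, 1e-300))))
    }
  }
  posterior <- if (method == "posterior" && keep_posterior) {
    m <- do.call(rbind, post_rows)
    colnames(m) <- params$states
    m
  } else NULL
  structure(
    list(grid = grid, labels = labels, states = params$states,
         posterior = posterior, method = method),
    class = "state_segmentation"
  )
}

#' @export
print.state_segmentation <- function(x, ...) {
  cat("<state_segmentation> ", length(x$labels), " bins, states: ",
      paste(x$states, collapse = ", "), " (", x$method, " decoding)\n", sep = "")
  invisible(x)
}

#' @method as_tibble state_segmentation
#' @export
as_tibble.state_segmentation <- function(x, ...) {
  out <- bin_intervals(x$grid)
  out$state <- factor(x$states[x$labels], levels = x$states)
  out
}

#' Merge a segmentation into per-state genomic intervals
#' @param seg A `state_segmentation`.
#' @return Tibble `chrom`, `start`, `end`, `state` (runs of equal state
#'   merged), the dense-BED form of the segmentation.
#' @export
state_intervals <- function(seg) {
  stopifnot(inherits(seg, "state_segmentation"))
  tb <- as_tibble(seg)
  tb |>
    group_by(.data$chrom) |>
    mutate(run = cumsum(c(1L, diff(as.integer(.data$state)) != 0L))) |>
    group_by(.data$chrom, .data$run) |>
    summarise(start = min(.data$start), end = max(.data$end),
              state = .data$state[1], .groups = "drop") |>
    select("chrom", "start", "end", "state") |>
    arrange(.data$chrom, .data$start)
}

#' Write a segmentation as dense BED (chrom, start, end, state)
#' @param seg A `state_segmentation`.
#' @param path Output path.
#' @export
write_segmentation <- function(seg, path) {
  si <- state_intervals(seg)
  si$name <- as.character(si$state)
  write_bed(si[, c("chrom", "start", "end", "name")], path)
}

#' Fraction of the genome covered by each state
#'
#' Bp-weighted: short terminal bins contribute their true length.
#'
#' @param seg A `state_segmentation`.
#' @return Tibble `state`, `bp`, `fraction` (fractions sum to 1).
#' @export
genome_fraction <- function(seg) {
  stopifnot(inherits(seg, "state_segmentation"))
  tb <- as_tibble(seg)
  out <- tb |>
    mutate(width = .data$end - .data$start) |>
    group_by(.data$state, .drop = FALSE) |>
    summarise(bp = sum(as.numeric(.data$width)), .groups = "drop")
  out$fraction <- out$bp / sum(out$bp)
  out
}

#' Fit a range of state counts and compare by BIC
#'
#' One fit per `K`; `BIC = -2 LL + n_params log(n_bins)` with
#' `n_params = (K - 1) + K (K - 1) + K M`. Chromatin-state maps of adult
#' tissues are typically built with a state count chosen by an unstated
#' optimisation; BIC is this package's documented criterion.
#'
#' @param track Binary `track_matrix` or 0/1 matrix.
#' @param K_range Integer vector of candidate state counts.
#' @param seed Seed (each K uses the same root seed).
#' @param n_restarts Restarts per K (default 2).
#' @inheritParams fit_hmm
#' @return Tibble `K`, `loglik`, `n_params`, `bic`, `converged`.
#' @export
select_k <- function(track, K_range, seed = 1, tol = 1e-4, max_iter = 200,
                     n_restarts = 2) {
  if (length(K_range) == 0) abort("`K_range` must be non-empty")
  rows <- map(sort(unique(as.integer(K_range))), function(K) {
    fit <- fit_hmm(track, K, seed = seed, tol = tol, max_iter = max_iter,
                   n_restarts = n_restarts, relabel = FALSE)
    tibble(K = K, loglik = fit$loglik, n_params = fit$n_params,
           bic = -2 * fit$loglik + fit$n_params * log(fit$n_obs),
           converged = fit$converged)
  })
  bind_rows(rows)
}

perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    for (p in perms(n - 1)) {
      rest <- setdiff(seq_len(n), i)
      out[[length(out) + 1]] <- c(i, rest[p])
    }
  }
  out
}

#' Best state permutation matching estimated to true emissions
#'
#' Label switching is inherent to EM; this finds the permutation of
#' estimated states minimising the mean absolute emission difference to a
#' reference parameterisation.
#'
#' @param estimated,truth `K x M` emission matrices (same dimensions).
#' @return List with `perm` (estimated state `perm[k]` corresponds to true
#'   state `k`) and `mae` (mean absolute emission error after matching).
#' @export
match_state_permutation <- function(estimated, truth) {
  estimated <- as.matrix(estimated); truth <- as.matrix(truth)
  if (!all(dim(estimated) == dim(truth))) abort("dimension mismatch")
  K <- nrow(truth)
  if (K > 8) abort("permutation matching supported for K <= 8")
  best <- NULL
  for (p in perms(K)) {
    mae <- mean(abs(estimated[p, , drop = FALSE] - truth))
    if (is.null(best) || mae < best$mae) best <- list(perm = p, mae = mae)
  }
  best
}
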