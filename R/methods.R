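#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an HMM fit into a long emission table
#'
#' @param x An `hmm_fit`.
#' @param ... Unused.
#' @return Tibble `state`, `mark`, `emission`.
#' @method tidy hmm_fit
#' @export
tidy.hmm_fit <- function(x, ...) {
  em <- x$params$emissions
  tibble(
    state = factor(rep(rownames(em), ncol(em)), levels = x$params$states),
    mark = rep(colnames(em), each = nrow(em)),
    emission = as.numeric(em)
  ) |> arrange(.data$state, .data$mark)
}

#' One-row summary of an HMM fit
#'
#' @param x An `hmm_fit`.
#' @param ... Unused.
#' @return Tibble with `K`, `M`, `loglik`, `n_params`, `bic`, `iterations`,
#'   `converged`, `seed`.
#' @method glance hmm_fit
#' @export
glance.hmm_fit <- function(x, ...) {
  tibble(
    K = x$K, M = x$M, loglik = x$loglik, n_params = x$n_params,
    bic = -2 * x$loglik + x$n_params * log(x$n_obs),
    iterations = x$iterations, converged = x$converged, seed = x$seed
  )
}

#' One-row summary of a subsampled age test
#' @param x An `age_test`.
#' @param ... Unused.
#' @method glance age_test
#' @export
glance.age_test <- function(x, ...) tidy.age_test(x)
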