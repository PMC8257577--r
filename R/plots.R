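#' Emission-parameter heatmap for a fitted HMM
#'
#' The state-by-mark probability heatmap conventionally used to read a
#' chromatin-state model.
#'
#' @param object An `hmm_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot hmm_fit
#' @export
autoplot.hmm_fit <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mark, y = .data$state,
                                   fill = .data$emission)) +
    ggplot2::geom_tile(colour = "grey60") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$emission)),
                       size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "#1c4f9c",
                                 limits = c(0, 1)) +
    ggplot2::scale_y_discrete(limits = rev(levels(df$state))) +
    ggplot2::labs(x = NULL, y = NULL, fill = "P(present)",
                  title = "Emission parameters") +
    ggplot2::theme_minimal()
}

#' Genome-fraction bar chart for a segmentation
#'
#' @param object A `state_segmentation`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot state_segmentation
#' @export
autoplot.state_segmentation <- function(object, ...) {
  df <- genome_fraction(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$state, y = .data$fraction,
                                   fill = .data$state)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_y_continuous(labels = function(v) sprintf("%.0f%%", 100 * v)) +
    ggplot2::labs(x = NULL, y = "fraction of genome") +
    ggplot2::theme_minimal()
}

#' Methylation category fractions per state
#'
#' @param summary Output of [state_methylation_summary()].
#' @return A ggplot (stacked category fractions by state).
#' @export
plot_methylation_by_state <- function(summary) {
  df <- summary |>
    select("state", "n_methylated", "n_unmethylated", "n_intermediate") |>
    tidyr::pivot_longer(-"state", names_to = "category", values_to = "n") |>
    mutate(category = sub("^n_", "", .data$category))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$state, y = .data$n,
                                   fill = .data$category)) +
    ggplot2::geom_col(position = "fill") +
    ggplot2::scale_fill_manual(values = c(methylated = "black",
                                          unmethylated = "#c23b22",
                                          intermediate = "grey70")) +
    ggplot2::labs(x = NULL, y = "fraction of CpGs", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Mean expression trajectories per bivalency cluster
#'
#' @param trajectories Output of [cluster_expression_trajectories()].
#' @return A ggplot (mean log(FPKM+1) against timepoint, one line per
#'   cluster).
#' @export
plot_trajectories <- function(trajectories) {
  ggplot2::ggplot(trajectories,
                  ggplot2::aes(x = .data$timepoint, y = .data$mean_log_fpkm,
                               colour = .data$cluster,
                               group = .data$cluster)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_point(size = 1.6) +
    ggplot2::labs(x = NULL, y = "mean log(FPKM + 1)", colour = "cluster") +
    ggplot2::theme_minimal()
}

#' Mean TSS profile per cluster for one mark
#'
#' @param m A `tss_matrix`.
#' @param clusters Optional `bivalent_clusters` (or tibble `gene_id`,
#'   `cluster`) to facet the mean profile by cluster.
#' @return A ggplot.
#' @export
plot_tss_profile <- function(m, clusters = NULL) {
  stopifnot(inherits(m, "tss_matrix"))
  df <- tibble(
    gene_id = rep(m$gene_id, each = length(m$positions)),
    position = rep(m$positions, nrow(m$values)),
    value = as.numeric(t(m$values))
  )
  if (!is.null(clusters)) {
    cl <- if (inherits(clusters, "bivalent_clusters")) clusters$clusters else as_tibble(clusters)
    df <- dplyr::inner_join(df, cl, by = "gene_id") |>
      group_by(.data$cluster, .data$position)
  } else {
    df <- group_by(df, .data$position)
  }
  df <- summarise(df, mean_signal = mean(.data$value, na.rm = TRUE), .groups = "drop")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$mean_signal))
  if ("cluster" %in% names(df)) {
    p <- p + ggplot2::aes(colour = .data$cluster)
  }
  p + ggplot2::geom_line() +
    ggplot2::labs(x = "position relative to TSS (bp)",
                  y = paste0("mean ", m$mark, " signal")) +
    ggplot2::theme_minimal()
}
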