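# ggplot2 helpers for the main result types.

#' QQ plot of burden-test p-values by mask
#'
#' @param object A `mask_scan`.
#' @param maf_bin Which bin to plot (default: the widest).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mask_scan <- function(object, maf_bin = max(object$config$aaf_bins), ...) {
  df <- object$results |>
    dplyr::filter(.data$maf_bin == !!maf_bin) |>
    dplyr::group_by(.data$mask_id) |>
    dplyr::arrange(.data$p, .by_group = TRUE) |>
    dplyr::mutate(
      expected = -log10(stats::ppoints(dplyr::n())),
      observed = -log10(.data$p)
    ) |>
    dplyr::ungroup()
  ggplot2::ggplot(df, ggplot2::aes(.data$expected, .data$observed,
    color = .data$mask_id
  )) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::labs(
      x = expression(Expected ~ -log[10](p)),
      y = expression(Observed ~ -log[10](p)),
      color = "mask",
      title = sprintf("Burden-test calibration (aaf bin %g)", maf_bin)
    ) +
    ggplot2::theme_minimal()
}

#' Cluster map of masks in component space
#'
#' @param object A `mask_clustering`.
#' @param ... Unused.
#' @return A ggplot of the first two component scores colored by cluster.
#' @export
autoplot.mask_clustering <- function(object, ...) {
  sc <- object$scores
  df <- object$assignments |>
    dplyr::mutate(
      pc1 = sc[, 1],
      pc2 = if (ncol(sc) >= 2) sc[, 2] else 0
    )
  ggplot2::ggplot(df, ggplot2::aes(.data$pc1, .data$pc2,
    color = factor(.data$cluster), label = .data$mask_id
  )) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = "component 1", y = "component 2", color = "cluster",
      title = "Mask clustering on variant-membership components"
    ) +
    ggplot2::theme_minimal()
}

#' Greedy covering trace: coverage and marginal gain by strategy size
#'
#' @param search An [optimal_strategy_search()] result.
#' @return A ggplot of the covered-association count against strategy size,
#'   with the chosen size marked.
#' @export
plot_greedy_search <- function(search) {
  ggplot2::ggplot(search$by_m, ggplot2::aes(.data$m, .data$count)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = search$m, linetype = 2, color = "red") +
    ggplot2::labs(
      x = "strategy size m",
      y = "significant associations after Bonferroni",
      title = "Greedy covering: cross-size comparison"
    ) +
    ggplot2::theme_minimal()
}

#' Per-strategy significant-association counts
#'
#' @param summary_table The `table` element of
#'   [summarize_catalog_strategies()].
#' @return A ggplot bar chart.
#' @export
plot_strategy_counts <- function(summary_table) {
  ggplot2::ggplot(
    summary_table,
    ggplot2::aes(
      stats::reorder(.data$strategy_id, .data$count), .data$count
    )
  ) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL, y = "significant associations",
      title = "Masking strategies: Bonferroni-corrected yield"
    ) +
    ggplot2::theme_minimal()
}
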