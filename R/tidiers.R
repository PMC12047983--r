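# broom-style tidiers.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a mask scan
#'
#' @param x A `mask_scan` from [run_mask_scan()].
#' @param ... Unused.
#' @return The burden-test results tibble.
#' @export
tidy.mask_scan <- function(x, ...) x$results

#' @rdname tidy.mask_scan
#' @return `glance()` returns a one-row summary: tests, masks, traits, genes,
#'   masks excluded, and the median lambda at the widest bin.
#' @export
glance.mask_scan <- function(x, ...) {
  wide <- max(x$config$aaf_bins)
  lam <- x$calibration$lambda |> dplyr::filter(.data$maf_bin == wide)
  tibble::tibble(
    n_tests = nrow(x$results),
    n_masks = dplyr::n_distinct(x$results$mask_id),
    n_traits = dplyr::n_distinct(x$results$trait),
    n_genes = dplyr::n_distinct(x$results$gene),
    n_masks_excluded = length(x$dropped_masks),
    median_lambda = stats::median(lam$lambda)
  )
}

#' Tidy a mask clustering
#'
#' @param x A `mask_clustering` from [cluster_and_subcluster()].
#' @param ... Unused.
#' @return The assignments tibble (mask_id, cluster, subcluster).
#' @export
tidy.mask_clustering <- function(x, ...) x$assignments

#' @rdname tidy.mask_clustering
#' @export
glance.mask_clustering <- function(x, ...) {
  tibble::tibble(
    n_masks = nrow(x$assignments), k = x$k,
    n_subclusters = dplyr::n_distinct(x$assignments$subcluster),
    n_components = x$n_components, explained = x$explained,
    silhouette_round1 = x$silhouette_round1,
    silhouette_round2 = x$silhouette_round2
  )
}

#' Tidy a strategy
#'
#' @param x A `strategy` from [new_strategy()].
#' @param ... Unused.
#' @return Tibble strategy_id, rank, mask_id, m, threshold.
#' @export
tidy.strategy <- function(x, ...) {
  tibble::tibble(
    strategy_id = x$strategy_id, rank = seq_len(x$m), mask_id = x$mask_ids,
    m = x$m, threshold = x$threshold
  )
}

#' Tidy a composite model
#'
#' @param x A `composite_model`.
#' @param ... Unused.
#' @return Tibble component, weight, orientation (component models) or
#'   algorithm weights (`og`).
#' @export
tidy.composite_model <- function(x, ...) {
  if (x$method == "og") {
    return(tibble::tibble(
      component = seq_along(x$weights), weight = x$weights, orientation = 1
    ))
  }
  tibble::tibble(
    component = seq_along(x$weights), weight = x$weights,
    orientation = x$orientation
  )
}
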