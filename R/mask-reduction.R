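# Two-round clustering of masks: variant membership, then variant MAF.
#
# Round 1 treats each mask as a binary vector of variant inclusions, reduces
# it with PCA to the smallest number of components explaining at least the
# variance target (default 90%), and k-means-clusters the component scores
# with k chosen by an elbow rule on the cost function. Round 2 repeats the
# construction within each cluster using the masked variants' MAFs as
# features (MAF where the mask includes the variant, 0 otherwise), splitting
# each cluster into subclusters. One representative mask per (sub)cluster —
# the one with the most significant associations — forms a reduced strategy.

#' Reduce a mask feature matrix to principal component scores
#'
#' Retains the smallest number of components whose cumulative explained
#' variance reaches `variance_target`. Component signs follow a
#' deterministic convention: the largest-magnitude loading of each component
#' is positive.
#'
#' @param features Masks x features numeric matrix.
#' @param variance_target Cumulative explained-variance fraction in (0, 1\].
#' @return List with `scores` (masks x retained components), `n_components`,
#'   `explained` (cumulative fraction at the retained count), and
#'   `explained_ratios` (all components).
#' @export
reduce_dimensions <- function(features, variance_target = 0.90) {
  stopifnot(nrow(features) >= 2, variance_target > 0, variance_target <= 1)
  fit <- stats::prcomp(features, center = TRUE, scale. = FALSE)
  vars <- fit$sdev^2
  if (sum(vars) < .Machine$double.eps) {
    stop("feature matrix is constant; nothing to reduce", call. = FALSE)
  }
  ratios <- vars / sum(vars)
  ncomp <- which(cumsum(ratios) >= variance_target - 1e-12)[1]
  scores <- fit$x[, seq_len(ncomp), drop = FALSE]
  for (j in seq_len(ncomp)) {
    lead <- which.max(abs(fit$rotation[, j]))
    if (fit$rotation[lead, j] < 0) scores[, j] <- -scores[, j]
  }
  list(
    scores = scores, n_components = ncomp,
    explained = sum(ratios[seq_len(ncomp)]), explained_ratios = ratios
  )
}

kmeans_cost <- function(scores, k, nstart, seed) {
  if (k == 1) {
    return(list(
      cost = sum(scale(scores, scale = FALSE)^2),
      labels = rep(1L, nrow(scores))
    ))
  }
  # k-means on the distinct rows (stats::kmeans rejects k >= nrow and
  # duplicate centers), then map labels back to all rows
  key <- apply(scores, 1, paste, collapse = "\r")
  ux <- scores[!duplicated(key), , drop = FALSE]
  ukey <- key[!duplicated(key)]
  if (k >= nrow(ux)) {
    ulab <- seq_len(nrow(ux))
    centers <- ux
  } else {
    fit <- withr_seed(seed, stats::kmeans(ux, centers = k, nstart = nstart))
    ulab <- fit$cluster
    centers <- fit$centers
  }
  labels <- ulab[match(key, ukey)]
  cost <- sum((scores - centers[labels, , drop = FALSE])^2)
  list(cost = cost, labels = as.integer(labels))
}

#' Choose the number of clusters by the elbow rule
#'
#' Runs k-means (multiple restarts, fixed seed) across `k_range` and returns
#' the smallest k whose cost decrease to k+1, as a fraction of the total
#' cost at the smallest candidate k, falls below `drop_threshold` ("the cost
#' function reduced minimally beyond this k").
#'
#' @param scores Observations x features matrix (component scores).
#' @param k_range Candidate cluster counts (default `1:10`, capped at the
#'   number of distinct observations).
#' @param drop_threshold Relative cost-decrease threshold (default 0.05).
#' @param nstart k-means restarts (default 10).
#' @param seed Seed for the stochastic fits.
#' @return The chosen k.
#' @export
choose_k_elbow <- function(scores, k_range = 1:10, drop_threshold = 0.05,
                           nstart = 10, seed = 1L) {
  n_distinct_rows <- nrow(unique(as.data.frame(scores)))
  k_range <- sort(unique(pmin(k_range, n_distinct_rows)))
  if (length(k_range) == 1) {
    return(k_range)
  }
  costs <- vapply(
    k_range,
    function(k) kmeans_cost(scores, k, nstart, seed + k)$cost, 0
  )
  total <- costs[1]
  if (total < .Machine$double.eps) {
    return(k_range[1])
  }
  for (i in seq_len(length(k_range) - 1)) {
    drop <- (costs[i] - costs[i + 1]) / total
    if (drop < drop_threshold) {
      return(k_range[i])
    }
  }
  k_range[length(k_range)]
}

mean_silhouette <- function(scores, labels) {
  if (length(unique(labels)) < 2) {
    return(NA_real_)
  }
  sil <- cluster::silhouette(as.integer(factor(labels)), stats::dist(scores))
  if (!is.matrix(sil)) {
    return(NA_real_)
  }
  mean(sil[, "sil_width"])
}

#' Two-round clustering of a mask catalog
#'
#' Round 1 clusters masks on binary variant membership (PCA to the variance
#' target, then k-means with elbow-chosen k). Round 2 reruns PCA + k-means
#' within each round-1 cluster on MAF features (variant MAF where included,
#' 0 otherwise); singleton clusters are not split. Silhouette scores are
#' computed per round (round 2 as the mean over subclustered clusters).
#'
#' @param membership Logical/0-1 masks x variants matrix from
#'   [evaluate_catalog()].
#' @param mafs Per-variant MAF vector aligned to the membership columns.
#' @param config A [pipeline_config()] (supplies the variance target, elbow
#'   threshold, restarts and seed).
#' @param k_range Candidate k values for both rounds.
#' @return A `mask_clustering` object: list with `assignments` (tibble
#'   mask_id, cluster, subcluster), `k`, `n_components`, `explained`,
#'   `silhouette_round1`, `silhouette_round2` (mean over subclustered
#'   clusters), and `scores` (round-1 component scores).
#' @export
cluster_and_subcluster <- function(membership, mafs, config = pipeline_config(),
                                   k_range = 1:10) {
  stopifnot(ncol(membership) == length(mafs))
  mem <- membership * 1
  red <- reduce_dimensions(mem, config$variance_target)
  k <- choose_k_elbow(red$scores, k_range, config$elbow_drop,
    nstart = config$kmeans_restarts, seed = config$seed
  )
  labels <- kmeans_cost(red$scores, k, config$kmeans_restarts, config$seed)$labels
  sil1 <- mean_silhouette(red$scores, labels)

  maf_features <- sweep(mem, 2, mafs, `*`)
  assignments <- tibble::tibble(
    mask_id = rownames(membership), cluster = as.integer(labels),
    subcluster = NA_character_
  )
  sub_sils <- c()
  for (cl in sort(unique(labels))) {
    members <- which(labels == cl)
    if (length(members) < 2) {
      assignments$subcluster[members] <- paste0(cl, ".1")
      next
    }
    feats <- maf_features[members, , drop = FALSE]
    if (sum(apply(feats, 2, stats::var)) < .Machine$double.eps) {
      assignments$subcluster[members] <- paste0(cl, ".1")
      next
    }
    red2 <- reduce_dimensions(feats, config$variance_target)
    k2 <- choose_k_elbow(
      red2$scores, seq_len(min(max(k_range), length(members))),
      config$elbow_drop,
      nstart = config$kmeans_restarts, seed = config$seed + cl
    )
    lab2 <- kmeans_cost(
      red2$scores, k2, config$kmeans_restarts, config$seed + cl
    )$labels
    assignments$subcluster[members] <- paste0(cl, ".", lab2)
    s <- mean_silhouette(red2$scores, lab2)
    if (!is.na(s)) sub_sils <- c(sub_sils, s)
  }
  structure(
    list(
      assignments = assignments, k = k, n_components = red$n_components,
      explained = red$explained, silhouette_round1 = sil1,
      silhouette_round2 = if (length(sub_sils)) mean(sub_sils) else NA_real_,
      scores = red$scores
    ),
    class = "mask_clustering"
  )
}

#' @export
print.mask_clustering <- function(x, ...) {
  cat(
    "<mask_clustering> ", nrow(x$assignments), " masks | ",
    x$k, " clusters / ", dplyr::n_distinct(x$assignments$subcluster),
    " subclusters | ", x$n_components, " components (",
    round(100 * x$explained, 1), "% variance)\n",
    sep = ""
  )
  invisible(x)
}

#' Select one representative mask per cluster
#'
#' Picks, within each cluster (or subcluster), the mask with the largest
#' number of significant associations; ties go to the lexicographically
#' smallest mask id. The representatives form a strategy of size equal to
#' the number of (sub)clusters.
#'
#' @param clustering A `mask_clustering` (or its `assignments` tibble).
#' @param mask_counts Tibble `mask_id`, `count`: per-mask significant
#'   association counts at the relevant frequency class.
#' @param level `"cluster"` or `"subcluster"`.
#' @param strategy_id Identifier for the resulting strategy.
#' @param alpha0 Mask-level threshold for the strategy object.
#' @return A [new_strategy()] of the representatives (ordered by cluster).
#' @export
select_representatives <- function(clustering, mask_counts,
                                   level = c("cluster", "subcluster"),
                                   strategy_id = NULL, alpha0 = 2.5e-6) {
  level <- match.arg(level)
  assignments <- if (inherits(clustering, "mask_clustering")) {
    clustering$assignments
  } else {
    clustering
  }
  missing <- setdiff(assignments$mask_id, mask_counts$mask_id)
  if (length(missing)) {
    stop(
      "no significant-association counts for mask(s): ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  reps <- assignments |>
    dplyr::left_join(mask_counts, by = "mask_id") |>
    dplyr::group_by(.data[[level]]) |>
    dplyr::arrange(dplyr::desc(.data$count), .data$mask_id, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data[[level]])
  new_strategy(
    reps$mask_id,
    strategy_id %||% paste0("representatives_", level),
    alpha0 = alpha0
  )
}

#' Per-mask significant association counts
#'
#' Convenience: counts distinct (gene, trait) pairs per mask with p below
#' `alpha0` at the bin matching `freq_class`. Masks present in the results
#' but with no significant association get count 0.
#'
#' @inheritParams count_strategy_significant
#' @param alpha0 Mask-level threshold.
#' @param masks Mask universe to report (default: the masks appearing in the
#'   results); masks with no tests at the class bin get count 0.
#' @return Tibble `mask_id`, `count`.
#' @export
mask_significant_counts <- function(results, freq_class = c("total", "low-frequency", "rare"),
                                    alpha0 = 2.5e-6,
                                    aaf_bins = c(0.5, 0.01, 0.001),
                                    masks = NULL) {
  freq_class <- match.arg(freq_class)
  bin <- class_bin(freq_class, aaf_bins)
  counts <- results |>
    dplyr::filter(.data$maf_bin == bin, .data$p < alpha0) |>
    dplyr::distinct(.data$mask_id, .data$gene, .data$trait) |>
    dplyr::count(.data$mask_id, name = "count")
  tibble::tibble(mask_id = sort(masks %||% unique(results$mask_id))) |>
    dplyr::left_join(counts, by = "mask_id") |>
    dplyr::mutate(count = tidyr::replace_na(.data$count, 0L))
}
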