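# LD clumping of single-variant results and conditional burden tests.

#' Greedy LD clumping of single-variant association results
#'
#' Classic index-variant selection: variants are sorted by p-value; the best
#' remaining variant with `p < p1` becomes an index, and all remaining
#' variants on the same chromosome within `window_kb` whose squared genotype
#' correlation with the index is at least `r2` are removed; repeat until no
#' variant below `p1` remains.
#'
#' @param stats Tibble with columns `variant_id`, `chrom`, `pos`, `p`.
#' @param genotypes Samples x variants dosage matrix with the variants of
#'   `stats` among its column names.
#' @param p1 Index-variant p-value threshold (default 1e-4).
#' @param r2 Squared-correlation threshold (default 0.5).
#' @param window_kb Window in kilobases (default 250).
#' @return Character vector of index variant ids (possibly empty), in
#'   selection order.
#' @export
ld_clump <- function(stats, genotypes, p1 = 1e-4, r2 = 0.5, window_kb = 250) {
  stopifnot(all(stats$variant_id %in% colnames(genotypes)))
  pool <- stats |> dplyr::arrange(.data$p, .data$variant_id)
  indices <- character()
  while (nrow(pool) > 0 && pool$p[1] < p1) {
    idx <- pool[1, ]
    indices <- c(indices, idx$variant_id)
    pool <- pool[-1, ]
    if (nrow(pool) == 0) break
    near <- pool$chrom == idx$chrom &
      abs(pool$pos - idx$pos) <= window_kb * 1000
    if (any(near)) {
      gi <- genotypes[, idx$variant_id]
      r <- suppressWarnings(
        stats::cor(genotypes[, pool$variant_id[near], drop = FALSE], gi)
      )
      r[is.na(r)] <- 0
      drop_ids <- pool$variant_id[near][r^2 >= r2]
      pool <- dplyr::filter(pool, !.data$variant_id %in% drop_ids)
    }
  }
  indices
}

#' Burden test conditional on index-variant dosages
#'
#' Reruns [fit_burden_test()] with the dosages of LD-clumped index variants
#' appended to the covariates. Index columns that are collinear with the
#' existing design are dropped (with a message).
#'
#' @inheritParams fit_burden_test
#' @param index_genotypes Samples x index-variants dosage matrix (may have
#'   zero columns, in which case the unconditional test is returned).
#' @return One-row tibble as in [fit_burden_test()].
#' @export
conditional_burden_test <- function(burden, trait, covariates = NULL,
                                    index_genotypes = NULL) {
  if (is.null(index_genotypes) || ncol(index_genotypes) == 0) {
    return(fit_burden_test(burden, trait, covariates))
  }
  index_genotypes <- as.matrix(index_genotypes)
  base <- if (is.null(covariates)) {
    matrix(1, nrow(index_genotypes), 1)
  } else {
    cbind(1, as.matrix(covariates))
  }
  q <- qr(cbind(base, index_genotypes))
  kept <- sort(q$pivot[seq_len(q$rank)])
  dropped <- setdiff(seq_len(ncol(base) + ncol(index_genotypes)), kept)
  dropped <- dropped[dropped > ncol(base)] - ncol(base)
  if (length(dropped)) {
    message(
      "dropping ", length(dropped),
      " collinear index-variant column(s) from the conditional model"
    )
    index_genotypes <- index_genotypes[, -dropped, drop = FALSE]
  }
  extra <- cbind(
    if (is.null(covariates)) NULL else as.matrix(covariates),
    index_genotypes
  )
  if (ncol(extra) == 0) extra <- NULL
  fit_burden_test(burden, trait, extra)
}
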