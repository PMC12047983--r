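# Scanning a mask catalog across genes, traits, and allele-frequency bins.

#' Pipeline configuration defaults
#'
#' All thresholds of the analysis in one object: the mask-level significance
#' threshold `alpha0` (strategy-level threshold is `alpha0 / m`), the
#' genomic-inflation exclusion cutoff, the minimum cumulative minor-allele
#' count, the allele-frequency bins, the composite damaging-call threshold,
#' and LD-clumping defaults.
#'
#' @param alpha0 Mask-level significance threshold (default 2.5e-6).
#' @param lambda_max Masks whose mean lambda across traits exceeds this are
#'   excluded (default 1.2).
#' @param cmac_min Tests with cumulative MAC `<= cmac_min` are removed
#'   (default 10).
#' @param aaf_bins Allele-frequency bins at which burdens are recomputed
#'   (default `c(0.5, 0.01, 0.001)`).
#' @param composite_threshold Damaging-call threshold on rank scores
#'   (default 0.67).
#' @param clump_p1,clump_r2,clump_kb LD-clumping defaults (1e-4, 0.5, 250).
#' @param elbow_drop Relative cost-decrease threshold of the k-means elbow
#'   rule (default 0.05).
#' @param variance_target Cumulative explained-variance target of the
#'   clustering PCA (default 0.90).
#' @param kmeans_restarts Random restarts of each k-means fit (default 10).
#' @param seed Seed for stochastic steps.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(alpha0 = 2.5e-6, lambda_max = 1.2, cmac_min = 10,
                            aaf_bins = c(0.5, 0.01, 0.001),
                            composite_threshold = 0.67,
                            clump_p1 = 1e-4, clump_r2 = 0.5, clump_kb = 250,
                            elbow_drop = 0.05, variance_target = 0.90,
                            kmeans_restarts = 10, seed = 1L) {
  structure(
    list(
      alpha0 = alpha0, lambda_max = lambda_max, cmac_min = cmac_min,
      aaf_bins = aaf_bins, composite_threshold = composite_threshold,
      clump_p1 = clump_p1, clump_r2 = clump_r2, clump_kb = clump_kb,
      elbow_drop = elbow_drop, variance_target = variance_target,
      kmeans_restarts = kmeans_restarts, seed = seed
    ),
    class = "pipeline_config"
  )
}

#' Run gene-level burden tests for every mask, trait, gene, and bin
#'
#' For each (mask, gene, allele-frequency bin) the mask's variants are
#' collapsed into a per-sample burden and tested against every trait with
#' covariate-adjusted OLS. Tests with cumulative MAC `<= cmac_min` are
#' removed. Calibration then computes the genomic inflation factor lambda per
#' (mask, trait, bin); masks with no variants and masks whose mean lambda
#' across traits (at the widest bin) exceeds `lambda_max` are dropped from
#' the results and flagged in the report.
#'
#' @param catalog Mask catalog tibble (`mask_id`, `expression`).
#' @param variants Variant annotation tibble aligned to `genotypes` columns.
#' @param genotypes Samples x variants dosage matrix; column names must match
#'   `variants$variant_id`.
#' @param phenotypes Tibble with `sample_id` and one numeric column per
#'   trait (already inverse-normalized; see [inverse_normal()]).
#' @param covariates Tibble with `sample_id` and numeric covariate columns,
#'   or NULL.
#' @param config A [pipeline_config()].
#' @param membership Optional precomputed membership matrix from
#'   [evaluate_catalog()].
#' @return A `mask_scan` object: list with `results` (tibble gene, trait,
#'   mask_id, maf_bin, n_variants, cmac, beta, se, statistic, p),
#'   `calibration` (lambda per mask/trait/bin plus per-mask mean lambda and
#'   exclusion flags), `dropped_masks`, and `config`.
#' @export
run_mask_scan <- function(catalog, variants, genotypes, phenotypes,
                          covariates = NULL, config = pipeline_config(),
                          membership = NULL) {
  stopifnot(identical(colnames(genotypes), variants$variant_id))
  if (is.null(membership)) membership <- evaluate_catalog(catalog, variants)
  traits <- setdiff(names(phenotypes), "sample_id")
  cov_m <- NULL
  if (!is.null(covariates)) {
    stopifnot(identical(covariates$sample_id, phenotypes$sample_id))
    cov_m <- as.matrix(covariates[setdiff(names(covariates), "sample_id")])
  }
  genes <- sort(unique(variants$gene))
  gene_cols <- split(seq_len(nrow(variants)), variants$gene)

  # Frisch-Waugh fast path: residualize traits on [1, covariates] once, then
  # each burden once, and form the OLS t-test from the residual cross
  # products — algebraically identical to fit_burden_test (verified in the
  # test suite), vectorized over traits.
  n <- nrow(genotypes)
  cmat <- if (is.null(cov_m)) matrix(1, n, 1) else cbind(1, cov_m)
  trait_m <- as.matrix(phenotypes[traits])
  use_fast <- !anyNA(trait_m) && !anyNA(cmat)
  if (use_fast) {
    qrc <- qr(cmat)
    ry <- qr.resid(qrc, trait_m)
    syy <- colSums(ry^2)
    df <- n - qrc$rank - 1L
  }

  mask_ids <- rownames(membership)
  rows <- list()
  for (gene in genes) {
    cols <- gene_cols[[gene]]
    g <- genotypes[, cols, drop = FALSE]
    if (anyNA(g)) g[is.na(g)] <- 0
    vmaf <- variants$maf[cols]
    vmac <- variants$mac[cols]
    mem_g <- membership[, cols, drop = FALSE]
    # indicator columns: one per (mask, bin) passing the cMAC gate
    combos <- tidyr::expand_grid(mask_id = mask_ids, maf_bin = config$aaf_bins)
    keep_m <- vapply(seq_len(nrow(combos)), function(i) {
      mem_g[combos$mask_id[i], ] & vmaf < combos$maf_bin[i]
    }, logical(length(cols)))
    if (length(cols) == 1) keep_m <- matrix(keep_m, nrow = 1)
    combos$cmac <- as.vector(vmac %*% keep_m)
    combos$n_variants <- colSums(keep_m)
    pass <- combos$cmac > config$cmac_min
    if (!any(pass)) next
    combos <- combos[pass, , drop = FALSE]
    burdens <- g %*% (keep_m[, pass, drop = FALSE] * 1)
    if (use_fast) {
      rb <- qr.resid(qrc, burdens)
      sxx <- colSums(rb^2)
      ok <- sxx > n * .Machine$double.eps
      if (!any(ok)) next
      beta_m <- crossprod(rb[, ok, drop = FALSE], ry) / sxx[ok] # k x T
      rss <- pmax(-(beta_m^2 * sxx[ok]) + rep(syy, each = sum(ok)), 0)
      se_m <- sqrt(rss / df / sxx[ok])
      stat_m <- beta_m / se_m
      k <- sum(ok)
      nt <- length(traits)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        gene = gene,
        trait = rep(traits, each = k),
        mask_id = rep(combos$mask_id[ok], nt),
        maf_bin = rep(combos$maf_bin[ok], nt),
        n_variants = rep(combos$n_variants[ok], nt),
        cmac = rep(combos$cmac[ok], nt),
        beta = as.vector(beta_m), se = as.vector(se_m),
        statistic = as.vector(stat_m),
        p = 2 * stats::pt(abs(as.vector(stat_m)), df = df, lower.tail = FALSE)
      )
    } else {
      for (i in seq_len(nrow(combos))) {
        for (trait in traits) {
          ft <- fit_burden_test(burdens[, i], phenotypes[[trait]], cov_m)
          if (nrow(ft) == 0) next
          rows[[length(rows) + 1L]] <- tibble::tibble(
            gene = gene, trait = trait, mask_id = combos$mask_id[i],
            maf_bin = combos$maf_bin[i],
            n_variants = combos$n_variants[i], cmac = combos$cmac[i],
            beta = ft$beta, se = ft$se, statistic = ft$statistic, p = ft$p
          )
        }
      }
    }
  }
  results <- if (length(rows)) {
    purrr::list_rbind(rows) |>
      dplyr::arrange(
        .data$mask_id, .data$trait, .data$gene, dplyr::desc(.data$maf_bin)
      )
  } else {
    tibble::tibble(
      gene = character(), trait = character(), mask_id = character(),
      maf_bin = double(), n_variants = integer(), cmac = double(),
      beta = double(), se = double(), statistic = double(), p = double()
    )
  }

  no_variant_masks <- rownames(membership)[rowSums(membership) == 0]
  calibration <- calibrate_scan(results, config,
    all_masks = catalog$mask_id, no_variant_masks = no_variant_masks
  )
  dropped <- calibration$mask_summary |>
    dplyr::filter(.data$excluded) |>
    dplyr::pull("mask_id")
  results <- dplyr::filter(results, !.data$mask_id %in% dropped)
  structure(
    list(
      results = results, calibration = calibration,
      dropped_masks = dropped, config = config
    ),
    class = "mask_scan"
  )
}

calibrate_scan <- function(results, config, all_masks, no_variant_masks) {
  wide_bin <- max(config$aaf_bins)
  lambda_tbl <- results |>
    dplyr::group_by(.data$mask_id, .data$trait, .data$maf_bin) |>
    dplyr::summarise(
      n_tests = dplyr::n(), lambda = genomic_lambda(.data$p), .groups = "drop"
    )
  mean_lambda <- lambda_tbl |>
    dplyr::filter(.data$maf_bin == wide_bin) |>
    dplyr::group_by(.data$mask_id) |>
    dplyr::summarise(mean_lambda = mean(.data$lambda), .groups = "drop")
  mask_summary <- tibble::tibble(mask_id = all_masks) |>
    dplyr::left_join(mean_lambda, by = "mask_id") |>
    dplyr::mutate(
      no_variants = .data$mask_id %in% no_variant_masks,
      inflated = !is.na(.data$mean_lambda) &
        .data$mean_lambda > config$lambda_max,
      excluded = .data$no_variants | .data$inflated
    )
  list(lambda = lambda_tbl, mask_summary = mask_summary)
}

#' @export
print.mask_scan <- function(x, ...) {
  cat(
    "<mask_scan> ", nrow(x$results), " burden tests | ",
    dplyr::n_distinct(x$results$mask_id), " masks | ",
    dplyr::n_distinct(x$results$trait), " traits | ",
    length(x$dropped_masks), " masks excluded\n",
    sep = ""
  )
  invisible(x)
}

#' Classify significant associations by allele-frequency class
#'
#' An association (gene, trait, mask) is `total` when its widest-bin p-value
#' is below the threshold, `low-frequency` when the 1%-bin p-value is, and
#' `rare` when the 0.1%-bin p-value is.
#'
#' @param results Burden-test results tibble (as in [run_mask_scan()]).
#' @param threshold Significance threshold (mask level: `alpha0`; strategy
#'   level: `alpha0 / m`).
#' @param aaf_bins The three bins, widest first.
#' @return Tibble gene, trait, mask_id with logical `total`, `low_frequency`,
#'   `rare` columns.
#' @export
classify_association_frequency <- function(results, threshold = 2.5e-6,
                                           aaf_bins = c(0.5, 0.01, 0.001)) {
  flag_bin <- function(bin, nm) {
    results |>
      dplyr::filter(.data$maf_bin == bin) |>
      dplyr::mutate("{nm}" := .data$p < threshold) |>
      dplyr::select("gene", "trait", "mask_id", dplyr::all_of(nm))
  }
  flag_bin(aaf_bins[1], "total") |>
    dplyr::full_join(flag_bin(aaf_bins[2], "low_frequency"),
      by = c("gene", "trait", "mask_id")
    ) |>
    dplyr::full_join(flag_bin(aaf_bins[3], "rare"),
      by = c("gene", "trait", "mask_id")
    ) |>
    dplyr::mutate(dplyr::across(
      c("total", "low_frequency", "rare"), ~ tidyr::replace_na(.x, FALSE)
    ))
}

#' Map an association frequency class to its allele-frequency bin
#' @param freq_class `"total"`, `"low-frequency"` or `"rare"`.
#' @param aaf_bins The three bins, widest first.
#' @return The matching bin.
#' @keywords internal
class_bin <- function(freq_class, aaf_bins = c(0.5, 0.01, 0.001)) {
  switch(freq_class,
    total = aaf_bins[1],
    `low-frequency` = aaf_bins[2],
    rare = aaf_bins[3],
    stop("unknown frequency class: ", freq_class, call. = FALSE)
  )
}
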