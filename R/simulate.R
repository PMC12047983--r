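# Synthetic cohorts with recorded ground truth.
#
# The generator emulates the statistical structure the analysis assumes:
# a rare-skewed site-frequency spectrum; a latent per-variant pathogenicity
# indicator whose prevalence decreases with log-MAF (rarer variants are more
# likely to be damaging); an ensemble of pathogenicity predictors that track
# the latent signal through a single noisy factor (reproducing the high
# inter-algorithm correlation real rank scores show); Hardy-Weinberg
# genotypes; and quantitative phenotypes built from planted per-gene burden
# effects acting through the truly damaging variants, plus covariates and
# noise, then rank-inverse-normalized. What it deliberately does not emulate:
# linkage disequilibrium beyond optional paired common/rare variants,
# relatedness, and population stratification.

#' Simulation configuration
#'
#' @param n_samples Cohort size.
#' @param n_genes Number of genes.
#' @param mean_variants_per_gene Mean of the (zero-truncated) Poisson variant
#'   count per gene.
#' @param prop_common Fraction of variants drawn from the common component of
#'   the MAF mixture (default 0.1); the rest come from a rare-skewed Beta.
#' @param rare_shape1,rare_shape2 Beta parameters of the rare component
#'   (default 0.2, 50: heavily weighted near 0, so a typical gene carries
#'   enough sub-0.1%-MAF variants for the rare bin to clear the cMAC gate).
#' @param prevalence Target mean of the latent damaging indicator
#'   (default 0.3).
#' @param maf_slope Slope of the decreasing logit-linear link between
#'   log10(MAF) and the damaging probability (default 0.7).
#' @param n_algorithms Number of predictor algorithms (default 39).
#' @param noise_sd Per-algorithm noise added to the latent pathogenicity
#'   factor before rank transformation (default 0.8).
#' @param score_missingness Fraction of rank-score entries set missing
#'   (default 0.05).
#' @param causal_fraction Fraction of genes with a planted burden effect
#'   (default 0.02, so genomic-inflation estimates stay dominated by null
#'   genes, as they are in exome-wide scans).
#' @param beta Effect size per causal gene, applied to the sum of dosages
#'   over that gene's truly damaging variants below `causal_max_maf`
#'   (default 2.5; sign alternates across causal genes).
#' @param causal_max_maf Planted effects act only on damaging variants with
#'   MAF below this cap (default 0.01): the planted architecture is a
#'   rare-variant allelic series, leaving common-variant signal to
#'   single-variant methods.
#' @param n_traits Number of quantitative traits (default 6); every trait
#'   shares the causal genes but has independent noise. Several traits keep
#'   the mean-lambda mask filter stable, mirroring multi-phenotype scans.
#' @param h2_noise_sd Residual noise standard deviation (default 1).
#' @param seed Mandatory seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_samples = 2500, n_genes = 300,
                       mean_variants_per_gene = 50, prop_common = 0.1,
                       rare_shape1 = 0.2, rare_shape2 = 50,
                       prevalence = 0.3, maf_slope = 0.7,
                       n_algorithms = 39, noise_sd = 0.8,
                       score_missingness = 0.05,
                       causal_fraction = 0.02, beta = 2.5,
                       causal_max_maf = 0.01, n_traits = 6,
                       h2_noise_sd = 1, seed) {
  stopifnot(
    !missing(seed),
    prop_common >= 0, prop_common <= 1,
    prevalence > 0, prevalence < 1,
    score_missingness >= 0, score_missingness < 1,
    causal_fraction >= 0, causal_fraction <= 1
  )
  structure(
    list(
      n_samples = n_samples, n_genes = n_genes,
      mean_variants_per_gene = mean_variants_per_gene,
      prop_common = prop_common, rare_shape1 = rare_shape1,
      rare_shape2 = rare_shape2, prevalence = prevalence,
      maf_slope = maf_slope, n_algorithms = n_algorithms,
      noise_sd = noise_sd, score_missingness = score_missingness,
      causal_fraction = causal_fraction, beta = beta,
      causal_max_maf = causal_max_maf, n_traits = n_traits,
      h2_noise_sd = h2_noise_sd, seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

sim_algorithm_names <- function(n) {
  named <- c(
    "REVEL", "CADD", "SIFT", "Polyphen2_HDIV", "Polyphen2_HVAR",
    "MutationTaster", "PROVEAN", "FATHMM", "VEST4", "MetaSVM"
  )
  if (n <= length(named)) {
    return(named[seq_len(n)])
  }
  c(named, sprintf("ALG%02d", seq_len(n - length(named))))
}

#' Simulate an annotated variant table with latent ground truth
#'
#' Per gene, a zero-truncated Poisson number of variants is drawn; MAFs come
#' from the configured rare/common mixture (truncated below at `1/(2n)`).
#' The latent damaging indicator is Bernoulli with a logit that decreases in
#' log10(MAF) and is calibrated so the mean damaging rate equals
#' `prevalence`. Consequences are drawn so damaging variants are enriched
#' for pLoF and missense labels; each predictor's rank score is the rank
#' transform of (latent factor + independent noise); categorical calls use
#' the 0.67 rank cut. An `ORACLE_score` column (the damaging indicator
#' itself) supports planted-oracle recovery experiments.
#'
#' @param config A [sim_config()].
#' @return List with `variants` (annotation tibble) and `truth` (tibble
#'   variant_id, gene, damaging).
#' @export
simulate_variants <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr_seed(config$seed, {
    n_per_gene <- pmax(1L, stats::rpois(config$n_genes, config$mean_variants_per_gene))
    gene <- rep(sprintf("gene%03d", seq_len(config$n_genes)), n_per_gene)
    n <- length(gene)
    common <- stats::runif(n) < config$prop_common
    maf <- ifelse(
      common,
      stats::runif(n, 0.05, 0.5),
      stats::rbeta(n, config$rare_shape1, config$rare_shape2)
    )
    maf <- pmin(pmax(maf, 1 / (2 * config$n_samples)), 0.5)

    lmaf <- log10(maf)
    eta <- stats::qlogis(config$prevalence) -
      config$maf_slope * (lmaf - mean(lmaf))
    damaging <- stats::runif(n) < stats::plogis(eta)

    consequence <- character(n)
    plof_csq <- c("stop_gained", "frameshift", "splice_donor", "splice_acceptor")
    for (i in seq_len(n)) {
      consequence[i] <- if (damaging[i]) {
        sample(
          c(plof_csq, "missense", "inframe_indel"),
          1,
          prob = c(rep(0.075, 4), 0.6, 0.1)
        )
      } else {
        sample(
          c("missense", "synonymous", "splice_region", "inframe_indel", "other"),
          1,
          prob = c(0.5, 0.3, 0.1, 0.05, 0.05)
        )
      }
    }
    is_indel <- consequence %in% c("frameshift", "inframe_indel")
    lof_confidence <- ifelse(
      consequence %in% plof_csq,
      ifelse(stats::runif(n) < 0.85, "HC", "LC"), "none"
    )
    impact <- dplyr::case_when(
      consequence %in% plof_csq ~ "HIGH",
      consequence %in% c("missense", "inframe_indel") ~ "MODERATE",
      consequence %in% c("synonymous", "splice_region") ~ "LOW",
      TRUE ~ "MODIFIER"
    )

    latent <- 1.5 * damaging + stats::rnorm(n)
    algs <- sim_algorithm_names(config$n_algorithms)
    ranks <- matrix(NA_real_, n, length(algs), dimnames = list(NULL, algs))
    for (j in seq_along(algs)) {
      ranks[, j] <- rank_score(latent + stats::rnorm(n, sd = config$noise_sd))
    }
    if (config$score_missingness > 0) {
      miss <- matrix(
        stats::runif(n * length(algs)) < config$score_missingness,
        n, length(algs)
      )
      # keep at least one observed score per variant
      miss[rowSums(!miss) == 0, 1] <- FALSE
      ranks[miss] <- NA_real_
    }

    variants <- tibble::tibble(
      variant_id = sprintf("var%05d", seq_len(n)),
      chrom = "chr1",
      pos = seq_len(n) * 1000L,
      ref = "A", alt = ifelse(is_indel, "AT", "G"),
      gene = gene, consequence = consequence, is_indel = is_indel,
      lof_confidence = lof_confidence, impact = impact,
      maf = maf, mac = as.integer(round(2 * config$n_samples * maf))
    )
    rank_tbl <- tibble::as_tibble(ranks)
    names(rank_tbl) <- paste0(algs, "_rankscore")
    variants <- dplyr::bind_cols(variants, rank_tbl)
    variants$REVEL_score <- variants$REVEL_rankscore
    variants$CADD_phred <- variants$CADD_rankscore * 50
    for (a in intersect(c("SIFT", "Polyphen2_HDIV", "Polyphen2_HVAR"), algs)) {
      rs <- variants[[paste0(a, "_rankscore")]]
      variants[[paste0(a, "_pred")]] <- ifelse(is.na(rs), NA_character_,
        ifelse(rs > 0.67, "D", "B")
      )
    }
    variants$ORACLE_score <- as.numeric(damaging)

    list(
      variants = variants,
      truth = tibble::tibble(
        variant_id = variants$variant_id, gene = gene, damaging = damaging,
        maf = variants$maf
      )
    )
  })
}

#' Simulate Hardy-Weinberg genotype dosages
#'
#' Dosage ~ Binomial(2, maf) independently per sample. Realized MAF and MAC
#' are written back onto the variant table.
#'
#' @param variants Variant annotation tibble with a `maf` column.
#' @param n_samples Number of samples.
#' @param seed Seed.
#' @return List with `genotypes` (samples x variants integer matrix, sample
#'   ids `s00001`, ... as rownames) and `variants` (realized `maf`/`mac`
#'   updated).
#' @export
simulate_genotypes <- function(variants, n_samples, seed) {
  withr_seed(seed, {
    n_var <- nrow(variants)
    g <- matrix(
      stats::rbinom(n_samples * n_var, 2, rep(variants$maf, each = n_samples)),
      nrow = n_samples, ncol = n_var,
      dimnames = list(
        sprintf("s%05d", seq_len(n_samples)), variants$variant_id
      )
    )
    ac <- colSums(g)
    # fold onto the minor allele if the alternate allele drifts past 0.5
    variants$mac <- as.integer(pmin(ac, 2 * n_samples - ac))
    variants$maf <- variants$mac / (2 * n_samples)
    list(genotypes = g, variants = variants)
  })
}

#' Simulate quantitative phenotypes with planted gene-burden effects
#'
#' A causal subset of genes is drawn; each causal gene g contributes
#' `beta_g * (sum of dosages over g's truly damaging variants below the
#' `causal_max_maf` cap)` with `|beta_g| = beta` and alternating sign. Covariates (sex, array, 5 PCs)
#' receive small fixed effects; residual noise is normal. Each trait is then
#' rank-inverse-normal transformed (Blom offset).
#'
#' @param genotypes Samples x variants dosage matrix.
#' @param truth Truth tibble from [simulate_variants()] (variant_id, gene,
#'   damaging).
#' @param config A [sim_config()].
#' @return List with `phenotypes` (tibble sample_id, trait_1, ...),
#'   `covariates` (tibble sample_id, sex, array, PC1..PC5), and `truth`
#'   (tibble gene, beta of the causal genes).
#' @export
simulate_phenotypes <- function(genotypes, truth, config) {
  stopifnot(inherits(config, "sim_config"))
  withr_seed(config$seed + 1L, {
    n <- nrow(genotypes)
    genes <- sort(unique(truth$gene))
    n_causal <- round(config$causal_fraction * length(genes))
    causal <- sort(sample(genes, n_causal))
    betas <- config$beta * rep_len(c(1, -1), n_causal)

    covars <- tibble::tibble(
      sample_id = rownames(genotypes),
      sex = stats::rbinom(n, 1, 0.5),
      array = stats::rbinom(n, 1, 0.3)
    )
    pcs <- matrix(stats::rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("PC", 1:5)))
    covars <- dplyr::bind_cols(covars, tibble::as_tibble(pcs))
    cov_effect <- 0.1 * covars$sex + 0.05 * covars$array +
      drop(pcs %*% c(0.05, 0.04, 0.03, 0.02, 0.01))

    genetic <- numeric(n)
    for (i in seq_along(causal)) {
      vids <- truth$variant_id[
        truth$gene == causal[i] & truth$damaging &
          truth$maf < config$causal_max_maf
      ]
      vids <- intersect(vids, colnames(genotypes))
      if (length(vids) == 0) next
      genetic <- genetic +
        betas[i] * rowSums(genotypes[, vids, drop = FALSE])
    }

    phen <- tibble::tibble(sample_id = rownames(genotypes))
    for (t in seq_len(config$n_traits)) {
      y <- genetic + cov_effect + stats::rnorm(n, sd = config$h2_noise_sd)
      phen[[paste0("trait_", t)]] <- inverse_normal(y)
    }
    list(
      phenotypes = phen, covariates = covars,
      truth = tibble::tibble(gene = causal, beta = betas)
    )
  })
}

#' Simulate a mask catalog spanning all annotation and MAF categories
#'
#' Emits one mask per annotation class (pLoF, damMis, pLoFdamMis, pLoFmis,
#' misIndels, coding) crossed with the four maximum-MAF classes (no token,
#' `maf1`, `maf0_1`, `maf0_01`), plus planted near-duplicates (reordered and
#' alias-spelled variants of existing masks) and, optionally, a planted
#' "oracle" mask selecting exactly the truly damaging rare variants via the
#' `ORACLE_score` column of [simulate_variants()].
#'
#' @param include_oracle Include the planted oracle mask (default `TRUE`).
#' @param include_duplicates Include the planted duplicates (default `TRUE`).
#' @return Mask catalog tibble (`mask_id`, `expression`, `source`).
#' @export
simulate_mask_catalog <- function(include_oracle = TRUE,
                                  include_duplicates = TRUE) {
  templates <- c(
    pLoF = "stop_gained | stop_lost | frameshift | splice_donor | splice_acceptor",
    damMis = "missense & REVEL_score_0_55",
    pLoFdamMis = "LoF_HC | (missense & CADD_phred_25)",
    pLoFmis = "stop_gained | frameshift | essential_splice | missense",
    misIndels = "missense | inframe_indel | LoF_LC",
    coding = "missense | synonymous | inframe_indel | stop_gained | frameshift"
  )
  maf_tokens <- c(all = NA, maf1 = "maf1", maf0_1 = "maf0_1", maf0_01 = "maf0_01")
  grid <- tidyr::expand_grid(
    class = names(templates), maf = names(maf_tokens)
  )
  cat <- grid |>
    dplyr::mutate(
      tok = maf_tokens[.data$maf],
      expression = dplyr::if_else(
        is.na(.data$tok), templates[.data$class],
        sprintf("(%s) & %s", templates[.data$class], .data$tok)
      ),
      mask_id = paste0("sim_", .data$class, "_", .data$maf),
      source = "simulated"
    ) |>
    dplyr::select("mask_id", "expression", "source")
  if (include_duplicates) {
    dups <- tibble::tibble(
      mask_id = c("sim_dup_plof", "sim_dup_mis"),
      expression = c(
        # reordered copy of sim_pLoF_maf1
        "(splice_acceptor | splice_donor | frameshift | stop_lost | stop_gained) & maf_le_1",
        # alias-spelled copy of sim_damMis_all
        "nonsynonymous & REVEL_score_0_55"
      ),
      source = "simulated-duplicate"
    )
    cat <- dplyr::bind_rows(cat, dups)
  }
  if (include_oracle) {
    cat <- dplyr::bind_rows(
      cat,
      tibble::tibble(
        mask_id = "sim_oracle",
        expression = "ORACLE_score_0_5 & maf0_1",
        source = "simulated-oracle"
      )
    )
  }
  cat
}

#' Simulate a complete cohort
#'
#' Convenience wrapper: variants, genotypes (realized frequencies written
#' back), phenotypes, covariates, truth, and a mask catalog.
#'
#' @param config A [sim_config()].
#' @param include_oracle Passed to [simulate_mask_catalog()].
#' @return List with `variants`, `genotypes`, `phenotypes`, `covariates`,
#'   `catalog`, `truth` (list of `variants` and `genes` tibbles), `config`.
#' @export
simulate_cohort <- function(config, include_oracle = TRUE) {
  sv <- simulate_variants(config)
  sg <- simulate_genotypes(sv$variants, config$n_samples, config$seed + 2L)
  sp <- simulate_phenotypes(sg$genotypes, sv$truth, config)
  list(
    variants = sg$variants, genotypes = sg$genotypes,
    phenotypes = sp$phenotypes, covariates = sp$covariates,
    catalog = simulate_mask_catalog(include_oracle = include_oracle),
    truth = list(variants = sv$truth, genes = sp$truth),
    config = config
  )
}
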