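# Gene-level burden testing primitives.

#' Rank-based inverse normal transform
#'
#' Blom-offset (k = 3/8) rank inverse normal transform; ties receive average
#' ranks, NAs are preserved.
#'
#' @param x Numeric vector.
#' @param offset Blom offset (default 3/8).
#' @return Transformed vector, approximately standard normal.
#' @export
inverse_normal <- function(x, offset = 3 / 8) {
  out <- rep(NA_real_, length(x))
  ok <- !is.na(x)
  n <- sum(ok)
  r <- rank(x[ok], ties.method = "average")
  out[ok] <- stats::qnorm((r - offset) / (n - 2 * offset + 1))
  out
}

#' Collapse mask variants into a per-sample burden
#'
#' The burden of a sample is the sum of its dosages over the mask's variants
#' whose MAF is below the allele-frequency bin. Missing dosages contribute 0
#' (pre-impute if another rule is wanted).
#'
#' @param genotypes Samples x variants dosage matrix (0/1/2, NAs allowed)
#'   with variant ids as column names.
#' @param membership Logical vector over the genotype columns: which variants
#'   belong to the mask (within the gene under test).
#' @param maf Per-variant MAF vector aligned to the genotype columns.
#' @param mac Per-variant minor-allele-count vector aligned to the columns.
#' @param maf_bin Allele-frequency bin; only variants with `maf < maf_bin`
#'   are collapsed. Default 0.5 (all variants).
#' @return List with `burden` (per-sample vector), `cmac` (cumulative minor
#'   allele count over included variants) and `n_variants`.
#' @examples
#' g <- matrix(c(1, 0, 0, 2, 1, 1), nrow = 3, byrow = TRUE)
#' collapse_burden(g, c(TRUE, TRUE), maf = c(0.001, 0.002), mac = c(2, 3))
#' @export
collapse_burden <- function(genotypes, membership, maf, mac, maf_bin = 0.5) {
  stopifnot(
    length(membership) == ncol(genotypes),
    length(maf) == ncol(genotypes), length(mac) == ncol(genotypes)
  )
  keep <- membership & maf < maf_bin
  if (!any(keep)) {
    return(list(
      burden = numeric(nrow(genotypes)), cmac = 0, n_variants = 0L
    ))
  }
  g <- genotypes[, keep, drop = FALSE]
  g[is.na(g)] <- 0
  list(
    burden = rowSums(g), cmac = sum(mac[keep]), n_variants = sum(keep)
  )
}

#' Covariate-adjusted burden test
#'
#' Ordinary least squares of the trait on `[intercept, burden, covariates]`
#' with a two-sided t-test on the burden coefficient.
#'
#' @param burden Per-sample burden vector.
#' @param trait Per-sample quantitative trait (NAs dropped pairwise).
#' @param covariates Optional numeric matrix or data frame of covariates.
#' @return One-row tibble: `beta`, `se`, `statistic`, `df`, `p`; or a
#'   zero-row tibble when the test is degenerate (constant burden after
#'   NA removal).
#' @export
fit_burden_test <- function(burden, trait, covariates = NULL) {
  x <- cbind(`(Intercept)` = 1, burden = burden)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    stopifnot(nrow(covariates) == length(burden))
    x <- cbind(x, covariates)
  }
  ok <- stats::complete.cases(x) & !is.na(trait)
  x <- x[ok, , drop = FALSE]
  y <- trait[ok]
  empty <- tibble::tibble(
    beta = double(), se = double(), statistic = double(),
    df = double(), p = double()
  )
  if (nrow(x) <= ncol(x) + 1 || stats::var(x[, "burden"]) == 0) {
    return(empty)
  }
  fit <- stats::lm.fit(x, y)
  if (is.na(fit$coefficients["burden"])) {
    return(empty)
  }
  df <- fit$df.residual
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / df
  r <- fit$qr
  # (X'X)^-1 diagonal via the R factor of the pivoted QR
  xtx_inv <- chol2inv(r$qr[seq_len(r$rank), seq_len(r$rank), drop = FALSE])
  pivot <- r$pivot[seq_len(r$rank)]
  jb <- which(pivot == 2L) # burden is column 2 of x
  beta <- unname(fit$coefficients["burden"])
  se <- sqrt(sigma2 * xtx_inv[jb, jb])
  stat <- beta / se
  tibble::tibble(
    beta = beta, se = se, statistic = stat, df = df,
    p = 2 * stats::pt(abs(stat), df = df, lower.tail = FALSE)
  )
}

#' Genomic inflation factor of a set of p-values
#'
#' `lambda = median(qchisq(p, df = 1, lower.tail = FALSE)) / qchisq(0.5, 1)`.
#'
#' @param p Vector of p-values in (0, 1].
#' @return The genomic inflation factor (lambda GC).
#' @examples
#' genomic_lambda(runif(1000)) # ~ 1
#' @export
genomic_lambda <- function(p) {
  if (length(p) == 0) stop("no p-values supplied", call. = FALSE)
  stopifnot(all(p > 0 & p <= 1))
  stats::median(stats::qchisq(p, df = 1, lower.tail = FALSE)) /
    stats::qchisq(0.5, df = 1)
}
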