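# Composite damaging scores from ensembles of predictor rank scores.
#
# Pathogenicity predictors are summarized as rank scores in (0, 1] (rank of
# the variant's native score among all scored variants, higher = more
# damaging). Three composite scores aggregate an algorithm panel:
#
#   og — the fraction of algorithms whose rank score exceeds a threshold
#        (default 0.67, chosen so that roughly a third of variants are
#        called damaging, matching what categorical predictors typically do);
#   pc — principal components of the rank-score matrix, each converted back
#        to a rank score, oriented against MAF, thresholded, and combined as
#        a vote weighted by explained-variance ratio;
#   ic — same construction on independent components, weighted by the L2
#        norms of the mixing-matrix columns (independent components have no
#        variance decomposition; the mixing norm is the closest analogue).
#
# Orientation: damaging scores should be higher for rarer variants. Each
# component's rank score is tested for Pearson correlation with MAF; a
# significantly positive correlation (P < 0.01) flips the component
# (rank -> 1 - rank + 1/N) so that, post-orientation, no component is
# significantly positively correlated with MAF.

#' Rank-transform a numeric vector to (0, 1]
#'
#' Average ranks for ties, divided by the number of non-missing values; the
#' dbNSFP rank-score convention.
#'
#' @param x Numeric vector (NAs preserved).
#' @return Numeric vector in (0, 1] with NAs where `x` is NA.
#' @export
rank_score <- function(x) {
  out <- rep(NA_real_, length(x))
  ok <- !is.na(x)
  out[ok] <- rank(x[ok], ties.method = "average") / sum(ok)
  out
}

#' Impute missing rank scores by round-robin conditional regression
#'
#' Missing entries are initialized at column means, then each column with
#' missing values is regressed (OLS with intercept) on all other columns over
#' its observed rows and its missing entries replaced by predictions,
#' sweeping columns repeatedly until the largest change falls below `tol` or
#' `max_iter` sweeps. Observed entries are never modified; imputed values are
#' clipped to (0, 1].
#'
#' @param x Numeric matrix of rank scores in (0, 1] with NAs for missing.
#' @param max_iter Maximum number of sweeps (default 10).
#' @param tol Convergence tolerance on the largest absolute change.
#' @return A complete numeric matrix.
#' @export
impute_rank_scores <- function(x, max_iter = 10, tol = 1e-4) {
  stopifnot(is.matrix(x), is.numeric(x))
  miss <- is.na(x)
  if (!any(miss)) {
    return(x)
  }
  all_missing <- colSums(!miss) == 0
  if (any(all_missing)) {
    stop(
      "cannot impute: no observed values for algorithm(s) ",
      paste(colnames(x)[all_missing] %||% which(all_missing), collapse = ", "),
      call. = FALSE
    )
  }
  if (any(rowSums(!miss) == 0)) {
    stop("cannot impute: some variants have no observed rank score", call. = FALSE)
  }
  eps <- 1e-9
  filled <- x
  mu <- colMeans(x, na.rm = TRUE)
  for (j in seq_len(ncol(x))) filled[miss[, j], j] <- mu[j]
  cols <- which(colSums(miss) > 0)
  for (iter in seq_len(max_iter)) {
    delta <- 0
    for (j in cols) {
      obs <- !miss[, j]
      X <- cbind(1, filled[, -j, drop = FALSE])
      fit <- stats::lm.fit(X[obs, , drop = FALSE], filled[obs, j])
      beta <- fit$coefficients
      beta[is.na(beta)] <- 0
      pred <- drop(X[!obs, , drop = FALSE] %*% beta)
      pred <- pmin(1, pmax(eps, pred))
      delta <- max(delta, max(abs(pred - filled[!obs, j])))
      filled[!obs, j] <- pred
    }
    if (delta < tol) break
  }
  filled
}

# Symmetric fixed-point ICA with the logcosh contrast on whitened data.
# Returns the estimated unmixing applied to the centered data (source
# estimates S, n x k) and the mixing matrix A (p x k) with X_centered = S A^T.
fast_ica <- function(x, n_comp = ncol(x), max_iter = 200, tol = 1e-6) {
  n <- nrow(x)
  xc <- scale(x, center = TRUE, scale = FALSE)
  cv <- crossprod(xc) / (n - 1)
  e <- eigen(cv, symmetric = TRUE)
  pos <- e$values > max(e$values) * 1e-10
  k <- min(n_comp, sum(pos))
  # whitening: z = xc %*% K, cov(z) = I
  K <- e$vectors[, seq_len(k), drop = FALSE] %*% diag(1 / sqrt(e$values[seq_len(k)]), k)
  z <- xc %*% K
  w <- matrix(stats::rnorm(k * k), k, k)
  sym_decorrelate <- function(w) {
    s <- w %*% t(w)
    es <- eigen(s, symmetric = TRUE)
    es$vectors %*% diag(1 / sqrt(pmax(es$values, 1e-12)), k) %*% t(es$vectors) %*% w
  }
  w <- sym_decorrelate(w)
  for (i in seq_len(max_iter)) {
    wz <- z %*% t(w)
    g <- tanh(wz)
    gp <- 1 - g^2
    w1 <- (t(g) %*% z) / n - diag(colMeans(gp), k) %*% w
    w1 <- sym_decorrelate(w1)
    conv <- max(abs(abs(diag(w1 %*% t(w))) - 1))
    w <- w1
    if (conv < tol) break
  }
  s <- z %*% t(w)
  # X_centered ~= S %*% A^T with A = (pseudo-)inverse of the total unmixing
  unmix <- w %*% t(K) # k x p, s = xc %*% t(unmix)
  a <- t(MASS_ginv(unmix))
  list(S = s, A = a, unmixing = unmix, center = attr(xc, "scaled:center"))
}

# Moore-Penrose pseudoinverse (small matrices only).
MASS_ginv <- function(m, tol = sqrt(.Machine$double.eps)) {
  sv <- svd(m)
  keep <- sv$d > max(tol * sv$d[1], 0)
  sv$v[, keep, drop = FALSE] %*%
    (t(sv$u[, keep, drop = FALSE]) / sv$d[keep])
}

orient_component_ranks <- function(r, maf, p_cut = 0.01) {
  ct <- suppressWarnings(stats::cor.test(r, maf, method = "pearson"))
  flip <- isTRUE(ct$estimate > 0) && isTRUE(ct$p.value < p_cut)
  list(flip = flip, ranks = if (flip) 1 - r + 1 / length(r) else r)
}

#' Derive a composite scoring model from a complete rank-score matrix
#'
#' Fits principal or independent components to the variants-by-algorithms
#' rank-score matrix, converts per-variant component scores to rank scores,
#' orients each component so it is not significantly positively correlated
#' with MAF (Pearson, P < 0.01; positive components are inverted as
#' `1 - rank + 1/N`), and records normalized component weights
#' (explained-variance ratios for `"pc"`, mixing-column L2 norms for
#' `"ic"`).
#'
#' @param x Complete numeric matrix (variants x algorithms) of rank scores.
#' @param maf Per-variant MAF vector used for orientation.
#' @param method `"pc"` or `"ic"`.
#' @param threshold Damaging-call threshold on component rank scores
#'   (default 0.67).
#' @param seed Seed for the stochastic ICA fit (ignored for `"pc"`).
#' @return A `composite_model`: list with `method`, `loadings`, `center`,
#'   `weights` (sum to 1), `orientation` (+1/-1 per component), `threshold`,
#'   and the training component rank scores in `component_ranks`.
#' @export
derive_components <- function(x, maf, method = c("pc", "ic"),
                              threshold = 0.67, seed = 1L) {
  method <- match.arg(method)
  stopifnot(is.matrix(x), !anyNA(x), nrow(x) > ncol(x), ncol(x) >= 2)
  if (all(apply(x, 2, stats::var) < .Machine$double.eps)) {
    stop("rank-score matrix has zero variance; cannot derive components",
      call. = FALSE
    )
  }
  if (method == "pc") {
    fit <- stats::prcomp(x, center = TRUE, scale. = FALSE)
    scores <- fit$x
    loadings <- fit$rotation
    center <- fit$center
    raw_w <- fit$sdev^2
  } else {
    fit <- withr_seed(seed, fast_ica(x))
    scores <- fit$S
    loadings <- t(fit$unmixing) # so that new scores = (x - center) %*% loadings
    center <- fit$center
    raw_w <- sqrt(colSums(fit$A^2))
  }
  keep <- raw_w > max(raw_w) * 1e-12
  scores <- scores[, keep, drop = FALSE]
  loadings <- loadings[, keep, drop = FALSE]
  raw_w <- raw_w[keep]
  oriented <- apply(scores, 2, rank_score)
  orientation <- rep(1, ncol(scores))
  for (j in seq_len(ncol(scores))) {
    o <- orient_component_ranks(oriented[, j], maf)
    orientation[j] <- if (o$flip) -1 else 1
    oriented[, j] <- o$ranks
  }
  structure(
    list(
      method = method, loadings = loadings, center = center,
      weights = raw_w / sum(raw_w), orientation = orientation,
      threshold = threshold, component_ranks = oriented
    ),
    class = "composite_model"
  )
}

# run expr with a private RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  )
  set.seed(seed)
  expr
}

#' @export
print.composite_model <- function(x, ...) {
  cat(
    "<composite_model> method =", x$method, "|", ncol(x$loadings),
    "components | threshold", x$threshold, "\n"
  )
  invisible(x)
}

#' Composite damaging score of variants
#'
#' For an `og` model the score is the fraction of algorithms whose rank
#' score exceeds the threshold. For `pc`/`ic` models the score is the
#' weighted vote `sum_j w_j * [oriented component-j rank score > threshold]`.
#' Scores lie in `[0, 1]`.
#'
#' @param model A `composite_model` from [derive_components()] or
#'   [og_model()].
#' @param x Complete rank-score matrix; must match the matrix the model was
#'   fitted on column-for-column. For component models the training
#'   component rank scores are reused when `x` has the training row count;
#'   otherwise new component scores are projected and re-ranked.
#' @return Numeric vector of per-variant composite scores in `[0, 1]`.
#' @export
composite_score <- function(model, x) {
  stopifnot(inherits(model, "composite_model"), is.matrix(x), !anyNA(x))
  if (model$method == "og") {
    if (ncol(x) != length(model$weights)) {
      stop("rank-score matrix does not match the model's algorithm count",
        call. = FALSE
      )
    }
    calls <- x > model$threshold
    return(drop(calls %*% model$weights))
  }
  if (ncol(x) != nrow(model$loadings)) {
    stop("rank-score matrix does not match the model's algorithm count",
      call. = FALSE
    )
  }
  if (nrow(x) == nrow(model$component_ranks)) {
    oriented <- model$component_ranks
  } else {
    scores <- sweep(x, 2, model$center) %*% model$loadings
    oriented <- apply(scores, 2, rank_score)
    n <- nrow(x)
    for (j in seq_len(ncol(oriented))) {
      if (model$orientation[j] < 0) oriented[, j] <- 1 - oriented[, j] + 1 / n
    }
  }
  calls <- oriented > model$threshold
  drop(calls %*% model$weights)
}

#' Original-ensemble composite model
#'
#' The `og` composite calls a variant damaging by an algorithm when that
#' algorithm's rank score exceeds `threshold`; the composite score is the
#' fraction of algorithms calling damaging (equal weights).
#'
#' @param n_algorithms Number of algorithms in the panel.
#' @param threshold Damaging-call threshold (default 0.67).
#' @return A `composite_model` with method `"og"`.
#' @export
og_model <- function(n_algorithms, threshold = 0.67) {
  structure(
    list(
      method = "og", weights = rep(1 / n_algorithms, n_algorithms),
      threshold = threshold
    ),
    class = "composite_model"
  )
}

#' Attach composite scores to a variant table
#'
#' Builds the rank-score matrix from the `*_rankscore` columns, imputes
#' missing entries, fits the `pc` and `ic` models, and appends `combo_og`,
#' `combo_pc`, `combo_ic` columns.
#'
#' @param variants Variant annotation tibble with `*_rankscore` columns.
#' @param threshold Damaging-call threshold (default 0.67).
#' @param seed Seed for the ICA fit.
#' @return List with `variants` (scores appended), `models` (named list of
#'   the three `composite_model`s) and `rank_matrix` (the imputed matrix).
#' @export
add_composite_scores <- function(variants, threshold = 0.67, seed = 1L) {
  cols <- grep("_rankscore$", names(variants), value = TRUE)
  if (length(cols) < 2) {
    stop("need at least two *_rankscore columns to build composite scores",
      call. = FALSE
    )
  }
  m <- as.matrix(variants[cols])
  m <- impute_rank_scores(m)
  models <- list(
    og = og_model(ncol(m), threshold),
    pc = derive_components(m, variants$maf, "pc", threshold),
    ic = derive_components(m, variants$maf, "ic", threshold, seed = seed)
  )
  variants$combo_og <- composite_score(models$og, m)
  variants$combo_pc <- composite_score(models$pc, m)
  variants$combo_ic <- composite_score(models$ic, m)
  list(variants = variants, models = models, rank_matrix = m)
}

#' Generate the combined pLoF + composite-damaging-missense masks
#'
#' Emits masks of the form
#' `(LoF_HC | (missense & combo_<method><cut>)) [& <maf token>]` for every
#' combination of composite method, vote cut, and MAF token: by default 3
#' methods x 4 cuts (25/50/75/90%) x 3 MAF tokens (none, `maf1`, `maf0_1`)
#' = 36 masks.
#'
#' @param methods Composite methods to use.
#' @param cuts Vote-fraction cuts.
#' @param maf_tokens MAF tokens; `NA` means no MAF filter.
#' @return Mask catalog tibble (`mask_id`, `expression`, `source`).
#' @export
build_composite_masks <- function(methods = c("og", "pc", "ic"),
                                  cuts = c(0.25, 0.50, 0.75, 0.90),
                                  maf_tokens = c(NA, "maf1", "maf0_1")) {
  grid <- tidyr::expand_grid(
    method = methods, cut = cuts, maf_token = maf_tokens
  )
  grid |>
    dplyr::mutate(
      core = sprintf(
        "(LoF_HC | (missense & combo_%s%d))", .data$method,
        as.integer(round(.data$cut * 100))
      ),
      expression = dplyr::if_else(
        is.na(.data$maf_token), .data$core,
        paste0(.data$core, " & ", .data$maf_token)
      ),
      maf_suffix = dplyr::case_when(
        is.na(.data$maf_token) ~ "",
        .data$maf_token == "maf1" ~ ".0_01",
        .data$maf_token == "maf0_1" ~ ".0_001",
        TRUE ~ paste0(".", .data$maf_token)
      ),
      mask_id = sprintf(
        "new_damaging_%s%d%s", .data$method,
        as.integer(round(.data$cut * 100)), .data$maf_suffix
      ),
      source = "composite"
    ) |>
    dplyr::select("mask_id", "expression", "source")
}
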