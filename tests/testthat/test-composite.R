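make_rank_matrix <- function(n, k, seed, missing = 0) {
  set.seed(seed)
  latent <- rnorm(n)
  m <- vapply(seq_len(k), function(j) rank_score(latent + rnorm(n, sd = 0.5)),
    numeric(n)
  )
  colnames(m) <- sprintf("alg%02d", seq_len(k))
  if (missing > 0) {
    idx <- which(matrix(runif(n * k) < missing, n, k))
    m[idx] <- NA
  }
  list(m = m, latent = latent)
}

test_that("imputation returns complete matrices unchanged", {
  m <- make_rank_matrix(50, 4, seed = 1)$m
  expect_identical(impute_rank_scores(m), m)
})

test_that("imputation recovers a perfectly collinear column exactly", {
  set.seed(2)
  col1 <- rank_score(rnorm(40))
  m <- cbind(a = col1, b = col1, c = rank_score(rnorm(40)))
  m[5, "b"] <- NA
  out <- impute_rank_scores(m, max_iter = 25, tol = 1e-10)
  expect_equal(unname(out[5, "b"]), col1[5], tolerance = 1e-6)
  # observed entries untouched
  expect_identical(out[-5, ], m[-5, ])
})

test_that("regression imputation beats column-mean imputation", {
  mk <- make_rank_matrix(100, 5, seed = 3)
  truth <- mk$m
  m <- truth
  set.seed(4)
  miss <- matrix(runif(500) < 0.1, 100, 5)
  miss[rowSums(!miss) == 0, 1] <- FALSE
  m[miss] <- NA
  imp <- impute_rank_scores(m, max_iter = 20)
  mean_imp <- m
  for (j in 1:5) mean_imp[is.na(m[, j]), j] <- mean(m[, j], na.rm = TRUE)
  rmse <- function(x) sqrt(mean((x[miss] - truth[miss])^2))
  expect_lt(rmse(imp), rmse(mean_imp))
})

test_that("imputation rejects degenerate missingness patterns", {
  m <- make_rank_matrix(20, 3, seed = 5)$m
  m[, 2] <- NA
  expect_error(impute_rank_scores(m), "alg02")
  m2 <- make_rank_matrix(20, 3, seed = 6)$m
  m2[7, ] <- NA
  expect_error(impute_rank_scores(m2), "no observed rank score")
})

test_that("two identical columns put all PC weight on one component", {
  set.seed(7)
  col <- rank_score(rnorm(60))
  m <- cbind(a = col, b = col)
  maf <- runif(60, 0, 0.01)
  mod <- derive_components(m, maf, "pc")
  expect_equal(sum(mod$weights), 1)
  expect_gt(mod$weights[1], 1 - 1e-8)
  # component-1 rank score matches the shared column's ranks up to
  # orientation
  r1 <- mod$component_ranks[, 1]
  expect_equal(abs(cor(r1, col, method = "spearman")), 1, tolerance = 1e-8)
})

test_that("components positively correlated with MAF are inverted", {
  set.seed(8)
  n <- 300
  maf <- rbeta(n, 0.5, 5)
  # single dominant factor strongly aligned with MAF
  factor1 <- scale(maf) + rnorm(n, sd = 0.2)
  m <- vapply(1:4, function(j) rank_score(factor1 + rnorm(n, sd = 0.1)),
    numeric(n)
  )
  colnames(m) <- paste0("a", 1:4)
  mod <- derive_components(m, maf, "pc")
  # raw (pre-orientation) component-1 ranks
  raw <- rank_score((sweep(m, 2, mod$center) %*% mod$loadings)[, 1])
  raw_ct <- cor.test(raw, maf)
  expect_identical(
    mod$orientation[1] == -1,
    unname(raw_ct$estimate > 0 && raw_ct$p.value < 0.01)
  )
  # the dominant component tracks MAF strongly here, so one arm must flip:
  # post-orientation correlation is non-positive either way
  ct <- cor.test(mod$component_ranks[, 1], maf)
  expect_lte(unname(ct$estimate), 0)
  # post-orientation no component is significantly positively correlated
  for (j in seq_len(ncol(mod$component_ranks))) {
    ct <- cor.test(mod$component_ranks[, j], maf)
    expect_false(ct$estimate > 0 && ct$p.value < 0.01)
  }
})

test_that("a single latent factor is recovered by the leading component", {
  mk <- make_rank_matrix(400, 6, seed = 9)
  maf <- runif(400, 0, 0.01)
  mod <- derive_components(mk$m, maf, "pc")
  cors <- abs(apply(
    mod$component_ranks, 2, function(r) cor(r, rank(mk$latent))
  ))
  # the top-weighted component carries the factor
  expect_gt(cors[which.max(mod$weights)], 0.9)
  expect_equal(sum(mod$weights), 1)
  expect_true(all(mod$weights >= 0))

  # independent components of a Gaussian single-factor model are not
  # identifiable, so only structural properties are required of "ic"
  ic <- derive_components(mk$m, maf, "ic", seed = 99)
  expect_equal(sum(ic$weights), 1)
  expect_true(all(ic$weights >= 0))
  expect_true(all(ic$component_ranks > 0 & ic$component_ranks <= 1 + 1e-12))
})

test_that("composite scores are weighted votes in [0, 1]", {
  # hand-built two-component model: weights (0.75, 0.25)
  mod <- structure(
    list(
      method = "pc", loadings = diag(2), center = c(0, 0),
      weights = c(0.75, 0.25), orientation = c(1, 1), threshold = 0.67,
      component_ranks = matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2)
    ),
    class = "composite_model"
  )
  s <- composite_score(mod, matrix(0, 2, 2))
  expect_equal(s, c(0.75, 0.25))

  # one-component model gives only 0/1
  mod1 <- structure(
    list(
      method = "pc", loadings = matrix(1, 1, 1), center = 0, weights = 1,
      orientation = 1, threshold = 0.67,
      component_ranks = matrix(c(0.9, 0.3, 0.7), 3, 1)
    ),
    class = "composite_model"
  )
  expect_setequal(composite_score(mod1, matrix(0, 3, 1)), c(1, 0, 1))

  # og: unanimous high rank scores give 1
  og <- og_model(39)
  m <- matrix(0.9, 5, 39)
  expect_equal(composite_score(og, m), rep(1, 5))
  expect_error(composite_score(og, m[, 1:10]), "algorithm count")
})

test_that("the combo mask grid is complete and nested", {
  masks <- build_composite_masks()
  expect_identical(nrow(masks), 36L)
  expect_true(
    "(LoF_HC | (missense & combo_og25)) & maf1" %in% masks$expression
  )
  expect_true("new_damaging_og25.0_01" %in% masks$mask_id)

  variants <- random_variants(100, seed = 10)
  set.seed(11)
  variants$combo_og <- runif(100)
  variants$lof_confidence <- "none" # isolate the missense arm
  for (tok in c("", " & maf1")) {
    prev <- NULL
    for (cut in c(25, 50, 75, 90)) {
      e <- sprintf("(LoF_HC | (missense & combo_og%d))%s", cut, tok)
      cur <- evaluate_mask(normalize_mask(parse_mask(e)), variants)
      if (!is.null(prev)) expect_true(all(!cur | prev))
      prev <- cur
    }
  }

  # threshold comparison on a single variant
  v <- toy_variant("missense", combo_og = 0.30)
  expect_true(evaluate_mask(parse_mask("combo_og25"), v))
  expect_false(evaluate_mask(parse_mask("combo_og50"), v))
})

test_that("add_composite_scores attaches the three score columns", {
  co <- simulate_variants(sim_config(
    n_samples = 400, n_genes = 10, mean_variants_per_gene = 20,
    n_algorithms = 6, seed = 12
  ))
  out <- add_composite_scores(co$variants, seed = 12)
  expect_true(all(c("combo_og", "combo_pc", "combo_ic") %in% names(out$variants)))
  for (cn in c("combo_og", "combo_pc", "combo_ic")) {
    expect_true(all(out$variants[[cn]] >= 0 & out$variants[[cn]] <= 1))
  }
  expect_identical(names(out$models), c("og", "pc", "ic"))
})
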