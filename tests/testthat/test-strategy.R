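res_row <- function(gene, trait, mask, p, bin = 0.001) {
  tibble::tibble(
    gene = gene, trait = trait, mask_id = mask, maf_bin = bin, p = p
  )
}

test_that("the Bonferroni threshold scales with strategy size", {
  res <- dplyr::bind_rows(
    res_row("g1", "t", "m1", 2.4e-6),
    res_row("g9", "t", "m2", 0.5)
  )
  s1 <- new_strategy("m1", "solo")
  expect_identical(count_strategy_significant(res, s1, "rare")$count, 1L)
  s2 <- new_strategy(c("m1", "m2"), "pair")
  expect_identical(count_strategy_significant(res, s2, "rare")$count, 0L)
})

test_that("an association found by several member masks counts once", {
  res <- dplyr::bind_rows(
    res_row("g1", "t", "m1", 1e-9),
    res_row("g1", "t", "m2", 1e-9),
    res_row("g1", "t", "m3", 1e-9)
  )
  s <- new_strategy(c("m1", "m2", "m3"), "trio")
  out <- count_strategy_significant(res, s, "rare")
  expect_identical(out$count, 1L)
  expect_identical(out$associations$gene, "g1")
})

test_that("counts are invariant to mask order and match brute force", {
  set.seed(50)
  masks <- sprintf("m%02d", 1:20)
  genes <- sprintf("g%02d", 1:10)
  traits <- c("t1", "t2", "t3", "t4", "t5")
  res <- tidyr::expand_grid(gene = genes, trait = traits, mask_id = masks) |>
    dplyr::slice_sample(n = 500) |>
    dplyr::mutate(maf_bin = 0.001, p = 10^runif(500, -9, -0.1))
  s <- new_strategy(sample(masks, 8), "big")
  out <- count_strategy_significant(res, s, "rare")

  # brute-force double loop
  hits <- character()
  for (m in s$mask_ids) {
    for (i in seq_len(nrow(res))) {
      if (res$mask_id[i] == m && res$p[i] < 2.5e-6 / 8) {
        hits <- c(hits, paste(res$gene[i], res$trait[i]))
      }
    }
  }
  expect_identical(out$count, length(unique(hits)))

  s_rev <- new_strategy(rev(s$mask_ids), "big_rev")
  expect_identical(count_strategy_significant(res, s_rev, "rare")$count, out$count)
})

test_that("unknown mask ids in a strategy are an error", {
  res <- res_row("g1", "t", "m1", 1e-9)
  expect_error(
    count_strategy_significant(res, new_strategy(c("m1", "zz"), "bad"), "rare"),
    "zz"
  )
})

test_that("appending masks grows coverage at fixed threshold but can shrink counts under Bonferroni", {
  # two masks: m1 carries 3 borderline associations, m2 carries 1 strong one
  res <- dplyr::bind_rows(
    res_row("g1", "t", "m1", 2e-6),
    res_row("g2", "t", "m1", 2e-6),
    res_row("g3", "t", "m1", 2e-6),
    res_row("g4", "t", "m2", 1e-12)
  )
  fixed_thr <- 2.5e-6
  sig_fixed <- function(mask_ids) {
    length(unique(res$gene[res$mask_id %in% mask_ids & res$p < fixed_thr]))
  }
  # fixed threshold: monotone non-decreasing as masks are appended
  expect_gte(sig_fixed(c("m1", "m2")), sig_fixed("m1"))
  # m-dependent threshold: the 3 borderline hits die at alpha0/2
  c1 <- count_strategy_significant(res, new_strategy("m1", "s1"), "rare")$count
  c2 <- count_strategy_significant(
    res, new_strategy(c("m1", "m2"), "s2"), "rare"
  )$count
  expect_identical(c1, 3L)
  expect_identical(c2, 1L)
  expect_lt(c2, c1)
})

test_that("catalog summaries report per-strategy counts, average, and best", {
  res <- dplyr::bind_rows(
    res_row("g1", "t", "m1", 1e-9),
    res_row("g2", "t", "m1", 1e-9),
    res_row("g3", "t", "m2", 1e-9)
  )
  s_a <- new_strategy("m1", "a")
  s_b <- new_strategy("m2", "b")
  out <- summarize_catalog_strategies(list(s_a, s_b), res, "rare")
  expect_equal(out$average, 1.5)
  expect_identical(out$best$strategy_id, "a")
  expect_identical(out$table$count, c(2L, 1L))

  # single strategy: average = best = its count
  out1 <- summarize_catalog_strategies(list(s_a), res, "rare")
  expect_equal(out1$average, 2)
  expect_identical(out1$best$strategy_id, "a")

  # deterministic lexicographic tie-break
  s_c <- new_strategy("m2", "0_first")
  res_tie <- dplyr::bind_rows(
    res_row("g1", "t", "m1", 1e-9), res_row("g1", "t", "m2", 1e-9)
  )
  tie <- summarize_catalog_strategies(list(s_a, s_c), res_tie, "rare")
  expect_identical(tie$best$strategy_id, "0_first")

  expect_error(summarize_catalog_strategies(list(), res, "rare"), "no strategies")
})

test_that("fifteen-strategy fixture: average/best agree with recomputation", {
  set.seed(51)
  masks <- sprintf("m%02d", 1:12)
  res <- tidyr::expand_grid(
    gene = sprintf("g%02d", 1:8), trait = c("t1", "t2"), mask_id = masks
  ) |>
    dplyr::mutate(maf_bin = 0.001, p = 10^runif(dplyr::n(), -10, -0.1))
  strategies <- lapply(1:15, function(i) {
    new_strategy(sample(masks, sample(1:5, 1)), sprintf("s%02d", i))
  })
  out <- summarize_catalog_strategies(strategies, res, "rare")
  counts <- vapply(
    strategies,
    function(s) count_strategy_significant(res, s, "rare")$count, 0L
  )
  expect_equal(out$average, mean(counts))
  expect_identical(out$best$strategy_id, out$table$strategy_id[
    order(-out$table$count, out$table$strategy_id)[1]
  ])
})

test_that("jaccard similarity follows set arithmetic", {
  expect_equal(jaccard_similarity(c("a", "b"), c("a", "b")), 1)
  expect_equal(jaccard_similarity(c("a"), c("b")), 0)
  expect_equal(jaccard_similarity(c("a", "b", "c"), c("b", "c", "d")), 0.5)
  expect_equal(jaccard_similarity(character(0), character(0)), 0)
  s1 <- new_strategy(c("a", "b", "c"), "x")
  s2 <- new_strategy(c("b", "c", "d"), "y")
  expect_equal(jaccard_similarity(s1, s2), 0.5)
})

test_that("strategy catalogs round-trip through TSV", {
  strategies <- list(
    new_strategy(c("m1", "m2"), "s1"), new_strategy("m3", "s2")
  )
  p <- withr::local_tempfile(fileext = ".tsv")
  write_strategy_catalog(strategies, p)
  back <- read_strategy_catalog(p)
  expect_identical(back$s1$mask_ids, c("m1", "m2"))
  expect_identical(back$s2$m, 1L)
  expect_equal(back$s1$threshold, 2.5e-6 / 2)
})
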