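test_that("m = 1 returns the single best mask", {
  inst <- inst_from_sets(list(
    a = c("x", "y"), b = c("x", "y", "z"), c = "q"
  ))
  out <- greedy_cover_fixed_m(inst, 1)
  expect_identical(out$strategy$mask_ids, "b")
  expect_identical(out$count, 3L)
})

test_that("hand-enumerable trace: A={1,2,3}, B={3,4}, C={5}", {
  inst <- inst_from_sets(list(
    A = c("1", "2", "3"), B = c("3", "4"), C = "5"
  ))
  out <- greedy_cover_fixed_m(inst, 2)
  # A first (gain 3); then B and C both add 2... B adds {4} only (3 is
  # covered), C adds {5}: gains 1 vs 1, tie broken lexicographically -> B
  expect_identical(out$trace$mask_id, c("A", "B"))
  expect_identical(out$trace$gain, c(3L, 1L))
  expect_identical(out$count, 4L)
  out3 <- greedy_cover_fixed_m(inst, 3)
  expect_identical(out3$count, 5L)
})

test_that("greedy marginal gains never increase along the trace", {
  for (seed in 1:10) {
    inst <- random_instance(seed + 70)
    m <- min(4, length(inst$masks))
    tr <- greedy_cover_fixed_m(inst, m)$trace
    expect_true(all(diff(tr$gain) <= 0), info = seed)
  }
})

test_that("coverage sets shrink as m grows (threshold monotonicity)", {
  for (seed in 1:5) {
    inst <- random_instance(seed + 80)
    s1 <- maskcover:::instance_sets(inst, 1)
    s4 <- maskcover:::instance_sets(inst, 4)
    for (id in names(s1)) {
      expect_true(all(s4[[id]] %in% s1[[id]]))
    }
  }
})

test_that("greedy respects the (1 - 1/e) bound against exhaustive search", {
  n_opt_matched <- 0
  n_inst <- 40
  for (seed in seq_len(n_inst)) {
    inst <- random_instance(seed + 200)
    m <- sample(seq_len(min(4, length(inst$masks))), 1)
    g <- greedy_cover_fixed_m(inst, m)$count
    opt <- exhaustive_cover(inst, m)
    expect_gte(g, (1 - exp(-1)) * opt)
    if (g == opt) n_opt_matched <- n_opt_matched + 1
  }
  expect_gt(n_opt_matched / n_inst, 0.5)
})

test_that("greedy output is invariant to mask input order", {
  inst <- random_instance(999)
  perm <- sample(names(inst$masks))
  inst_perm <- maskcover:::new_coverage_instance(
    inst$masks[perm],
    alpha0 = inst$alpha0
  )
  m <- min(3, length(inst$masks))
  expect_identical(
    greedy_cover_fixed_m(inst, m)$strategy$mask_ids,
    greedy_cover_fixed_m(inst_perm, m)$strategy$mask_ids
  )
})

test_that("exhausted gains fill remaining slots with zero-gain masks", {
  inst <- inst_from_sets(list(a = c("x"), b = c("x"), c = character(0)))
  out <- greedy_cover_fixed_m(inst, 3)
  expect_identical(out$strategy$m, 3L)
  expect_identical(out$count, 1L)
  expect_identical(out$trace$gain, c(1L, 0L, 0L))
})

test_that("cross-size search prefers fewer masks on ties and finds trade-offs", {
  # one mask covers everything at alpha0: m = 1 wins
  inst <- inst_from_sets(list(all = c("x", "y", "z"), some = "x"))
  out <- optimal_strategy_search(inst)
  expect_identical(out$m, 1L)
  expect_identical(out$best$strategy$mask_ids, "all")

  # borderline p-values: alpha0/2 kills three associations while a second
  # mask only adds one -> m = 1 beats m = 2 (the Bonferroni trade-off)
  a0 <- 2.5e-6
  inst2 <- maskcover:::new_coverage_instance(
    list(
      m1 = tibble::tibble(key = c("a", "b", "c"), p = a0 * 0.9),
      m2 = tibble::tibble(key = "d", p = a0 / 10)
    ),
    alpha0 = a0
  )
  out2 <- optimal_strategy_search(inst2)
  expect_identical(out2$m, 1L)
  expect_identical(out2$best$count, 3L)

  # disjoint strong sets: all three masks survive alpha0/3 and m = 3 wins
  inst3 <- maskcover:::new_coverage_instance(
    list(
      m1 = tibble::tibble(key = c("a", "b"), p = a0 / 100),
      m2 = tibble::tibble(key = c("c", "d"), p = a0 / 100),
      m3 = tibble::tibble(key = c("e", "f"), p = a0 / 100)
    ),
    alpha0 = a0
  )
  out3 <- optimal_strategy_search(inst3)
  expect_identical(out3$m, 3L)
  expect_identical(out3$best$count, 6L)

  expect_error(
    optimal_strategy_search(maskcover:::new_coverage_instance(list())),
    "empty"
  )
})

test_that("truncation re-thresholds and recounts the leading picks", {
  inst <- random_instance(501)
  m <- min(4, length(inst$masks))
  g <- greedy_cover_fixed_m(inst, m)
  full <- truncate_strategy(inst, g, m)
  expect_identical(full$count, g$count)
  expect_identical(full$strategy$mask_ids, g$strategy$mask_ids)

  for (s in seq_len(m)) {
    tr <- truncate_strategy(inst, g, s)
    # brute-force recount at threshold alpha0/s
    sets <- maskcover:::instance_sets(inst, s)
    want <- length(unique(unlist(sets[tr$strategy$mask_ids], use.names = FALSE)))
    expect_identical(tr$count, want)
  }
  # size 1 is greedy's first pick at the full alpha0 threshold
  t1 <- truncate_strategy(inst, g, 1)
  expect_identical(t1$strategy$mask_ids, g$trace$mask_id[1])
})

test_that("leave-one-trait-out returns full coverage for identical traits", {
  res <- tidyr::expand_grid(
    trait = c("t1", "t2", "t3"),
    tibble::tibble(
      gene = c("g1", "g2", "g3"), mask_id = c("m1", "m1", "m2"),
      p = c(1e-9, 1e-9, 1e-8)
    )
  ) |>
    dplyr::mutate(maf_bin = 0.001)
  out <- leave_one_trait_out(res, "rare")
  expect_equal(out$fraction, rep(1, 3))
})

test_that("traits without associations report an undefined fraction", {
  res <- dplyr::bind_rows(
    tibble::tibble(
      trait = "t1", gene = c("g1", "g2"), mask_id = "m1",
      maf_bin = 0.001, p = 1e-9
    ),
    tibble::tibble(
      trait = "t2", gene = "g1", mask_id = "m1",
      maf_bin = 0.001, p = 0.9
    )
  )
  out <- leave_one_trait_out(res, "rare")
  expect_true(is.nan(out$fraction[out$trait == "t2"]))
  expect_false(is.nan(out$fraction[out$trait == "t1"]))
})

test_that("cross-trait strategies beat random same-size strategies on shared structure", {
  set.seed(90)
  masks <- sprintf("m%02d", 1:10)
  shared <- c("m03", "m07") # informative masks shared across traits
  res <- purrr::map(paste0("t", 1:6), function(tr) {
    tibble::tibble(
      trait = tr,
      gene = sprintf("g%02d", 1:30),
      mask_id = sample(masks, 30, replace = TRUE),
      maf_bin = 0.001,
      p = ifelse(runif(30) < 0.1, 1e-9, runif(30, 0.01, 1))
    ) |>
      dplyr::mutate(p = ifelse(.data$mask_id %in% shared & runif(30) < 0.8,
        1e-9, .data$p
      ))
  }) |> purrr::list_rbind()
  out <- leave_one_trait_out(res, "rare", m_max = 4)
  loto_mean <- mean(out$fraction, na.rm = TRUE)

  # random baseline: same sizes, random mask sets
  base <- purrr::map_dbl(unique(res$trait), function(tr) {
    m <- out$m[out$trait == tr]
    inst_tr <- coverage_instance(
      dplyr::filter(res, .data$trait == tr), "rare"
    )
    sets <- maskcover:::instance_sets(inst_tr, m)
    reps <- purrr::map_int(1:30, function(i) {
      length(unique(unlist(sets[sample(masks, m)], use.names = FALSE)))
    })
    mx <- optimal_strategy_search(inst_tr)$best$count
    if (mx == 0) NaN else mean(reps) / mx
  })
  expect_gt(loto_mean, mean(base, na.rm = TRUE))
})
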