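test_that("published-style mask definitions include and exclude as expected", {
  m4 <- normalize_mask(parse_mask(
    "(stop_gained | stop_lost | frameshift | essential_splice | (missense & REVEL_score_0_55)) & maf0_1",
    mask_id = "ptv_revel_rare"
  ))
  inc <- toy_variant("missense", maf = 5e-4, REVEL_score = 0.60)
  exc <- toy_variant("synonymous", maf = 5e-4, REVEL_score = NA_real_)
  expect_true(evaluate_mask(m4, inc))
  expect_false(evaluate_mask(m4, exc))
  # splice donor counts as essential splice; splice region does not
  expect_true(evaluate_mask(
    m4, toy_variant("splice_donor", maf = 5e-4, REVEL_score = NA_real_)
  ))
  expect_false(evaluate_mask(
    m4, toy_variant("splice_region", maf = 5e-4, REVEL_score = NA_real_)
  ))
  # the MAF gate dominates annotation
  expect_false(evaluate_mask(
    m4, toy_variant("stop_gained", maf = 0.01, REVEL_score = NA_real_)
  ))
})

test_that("missing predictor values never satisfy an atom", {
  m <- normalize_mask(parse_mask("missense & REVEL_score_0_55"))
  v <- toy_variant("missense", REVEL_score = NA_real_)
  expect_false(evaluate_mask(m, v))
  mp <- normalize_mask(parse_mask("missense & Polyphen2_HDIV_pred_D"))
  vp <- toy_variant("missense", Polyphen2_HDIV_pred = NA_character_)
  expect_false(evaluate_mask(mp, vp))
})

test_that("atoms referencing absent predictor columns raise an error", {
  m <- normalize_mask(parse_mask("missense & MutScore_score_0_5"))
  expect_error(
    evaluate_mask(m, toy_variant("missense")),
    "MutScore_score"
  )
})

test_that("evaluate_mask agrees with the naive recursive interpreter", {
  variants <- random_variants(200, seed = 42)
  for (seed in 1:10) {
    m <- normalize_mask(parse_mask(random_mask_expression(seed + 500)))
    expect_identical(
      evaluate_mask(m, variants), naive_eval_mask(m, variants),
      info = m$expression
    )
  }
})

test_that("MAF-token tightening never adds variants (monotonicity)", {
  variants <- random_variants(200, seed = 7)
  base <- "stop_gained | missense | (synonymous & CADD_phred_20)"
  tokens <- c("maf10", "maf1", "maf0_1", "maf0_01")
  prev <- evaluate_mask(normalize_mask(parse_mask(base)), variants)
  for (tok in tokens) {
    cur <- evaluate_mask(
      normalize_mask(parse_mask(sprintf("(%s) & %s", base, tok))), variants
    )
    expect_true(all(!cur | prev), info = tok)
    prev <- cur
  }
})

test_that("dedupe_catalog collapses canonical duplicates and keeps provenance", {
  catalog <- tibble::tibble(
    mask_id = c("a1", "a2", "b1"),
    expression = c(
      "stop_gained | frameshift", "frameshift | stop_gained", "missense"
    ),
    source = c("study1", "study2", "study3")
  )
  ded <- dedupe_catalog(catalog)
  expect_identical(nrow(ded), 2L)
  expect_identical(ded$n_merged[ded$mask_id == "a1"], 2L)
  expect_match(ded$source[ded$mask_id == "a1"], "study1;study2")
})

test_that("unique mask count matches pairwise truth-table equivalence", {
  set.seed(3)
  exprs <- vapply(1:20, function(s) random_mask_expression(s + 900), "")
  # plant textual duplicates with reordered operands
  exprs <- c(exprs, "(maf1 & missense)", "missense & maf1",
    "stop_gained | missense", "missense | stop_gained")
  catalog <- tibble::tibble(
    mask_id = sprintf("m%02d", seq_along(exprs)), expression = exprs,
    source = NA_character_
  )
  ded <- dedupe_catalog(catalog)

  masks <- lapply(seq_along(exprs), function(i) {
    normalize_mask(parse_mask(exprs[i], mask_id = catalog$mask_id[i]))
  })
  n <- length(masks)
  classes <- seq_len(n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (classes[j] != j) next
      if (truth_table_equal(masks[[i]], masks[[j]])) {
        classes[j] <- classes[i]
      }
    }
  }
  # canonical dedup may not merge equivalences beyond syntactic
  # normalization, but must never exceed the truth-table class count and
  # must merge the planted syntactic duplicates
  expect_gte(nrow(ded), length(unique(classes)))
  expect_lt(nrow(ded), length(exprs))
})

test_that("mask categories follow the annotation/maxMAF precedence", {
  cases <- list(
    list("stop_gained | frameshift", "pLoF", "common"),
    list("(LoF_HC | (missense & combo_og25)) & maf1", "pLoFdamMis", "low-frequency"),
    list("synonymous & maf0_1", "coding", "rare"),
    list("missense & REVEL_score_0_55", "damMis", "common"),
    list("stop_gained | frameshift | missense", "pLoFmis", "common"),
    list("(missense | inframe_indel | LoF_LC) & maf1", "misIndels", "low-frequency"),
    list("(stop_gained | frameshift) & maf0_01", "pLoF", "ultra-rare"),
    list("missense & maf5", "misIndels", "common"),
    list("CADD_phred_20 & maf1", "damMis", "low-frequency")
  )
  for (cs in cases) {
    got <- categorize_mask(parse_mask(cs[[1]]))
    expect_identical(got$annotation_class, cs[[2]], info = cs[[1]])
    expect_identical(got$maxmaf_class, cs[[3]], info = cs[[1]])
  }
})

test_that("evaluate_catalog builds an aligned membership matrix", {
  variants <- random_variants(50, seed = 11)
  catalog <- tibble::tibble(
    mask_id = c("ptv", "mis"),
    expression = c("stop_gained | frameshift", "missense"),
    source = NA_character_
  )
  mem <- evaluate_catalog(catalog, variants)
  expect_identical(dim(mem), c(2L, 50L))
  expect_identical(rownames(mem), catalog$mask_id)
  expect_identical(
    unname(mem["mis", ]), variants$consequence == "missense"
  )
})

test_that("catalog and annotation TSVs round-trip", {
  catalog <- simulate_mask_catalog()
  p <- withr::local_tempfile(fileext = ".tsv")
  write_mask_catalog(catalog, p)
  expect_identical(as.data.frame(read_mask_catalog(p)), as.data.frame(catalog))

  variants <- random_variants(20, seed = 5)
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_annotation_table(variants, p2)
  back <- read_annotation_table(p2)
  expect_equal(as.data.frame(back), as.data.frame(variants))
})
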