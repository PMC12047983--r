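# Independent oracles used across the suite. These deliberately do not share
# code paths with the package internals they check.

# --- naive per-variant recursive mask interpreter ---------------------------
# Evaluates one variant (a one-row data frame) at a time, with its own atom
# semantics written from scratch.
naive_eval_ast <- function(node, v) {
  if (node$op == "and") {
    return(all(vapply(node$args, naive_eval_ast, TRUE, v = v)))
  }
  if (node$op == "or") {
    return(any(vapply(node$args, naive_eval_ast, TRUE, v = v)))
  }
  tok <- node$token
  na_false <- function(x) !is.na(x) && x
  if (tok %in% c(
    "stop_gained", "stop_lost", "frameshift", "splice_donor",
    "splice_acceptor", "splice_region", "missense", "synonymous",
    "inframe_indel", "start_retained", "stop_retained",
    "incomplete_terminal_codon", "other"
  )) {
    return(v$consequence == tok)
  }
  if (tok == "essential_splice") {
    return(v$consequence %in% c("splice_donor", "splice_acceptor"))
  }
  if (tok == "indel") {
    return(isTRUE(v$is_indel))
  }
  if (tok %in% c("LoF_HC", "LoF_LC")) {
    return(v$lof_confidence == sub("LoF_", "", tok))
  }
  if (grepl("^IMPACT_", tok)) {
    return(v$impact == sub("IMPACT_", "", tok))
  }
  m <- regmatches(tok, regexec("^maf_gt_([0-9_]+)$", tok))[[1]]
  if (length(m)) {
    return(v$maf > as.numeric(gsub("_", ".", m[2])) / 100)
  }
  m <- regmatches(tok, regexec("^maf([0-9_]+)$", tok))[[1]]
  if (length(m)) {
    return(v$maf < as.numeric(gsub("_", ".", m[2])) / 100)
  }
  m <- regmatches(tok, regexec("^combo_(og|pc|ic)([0-9]+)$", tok))[[1]]
  if (length(m)) {
    return(na_false(v[[paste0("combo_", m[2])]] >= as.numeric(m[3]) / 100))
  }
  m <- regmatches(
    tok, regexec("^(.+)_(score|phred|rankscore)_([0-9]+(?:_[0-9]+)?)$", tok)
  )[[1]]
  if (length(m)) {
    col <- paste0(m[2], "_", m[3])
    return(na_false(v[[col]] >= as.numeric(gsub("_", ".", m[4]))))
  }
  m <- regmatches(tok, regexec("^(.+)_pred_([A-Za-z]+)$", tok))[[1]]
  if (length(m)) {
    return(na_false(v[[paste0(m[2], "_pred")]] == m[3]))
  }
  m <- regmatches(tok, regexec("^ClinVar_([A-Z]+)$", tok))[[1]]
  if (length(m)) {
    return(na_false(v[["ClinVar_pred"]] == m[2]))
  }
  stop("naive interpreter: unhandled token ", tok)
}

naive_eval_mask <- function(mask, variants) {
  vapply(
    seq_len(nrow(variants)),
    function(i) naive_eval_ast(mask$ast, variants[i, , drop = FALSE]),
    TRUE
  )
}

# --- truth-table equivalence over the atom vocabulary -----------------------
eval_ast_assignment <- function(node, env) {
  if (node$op == "atom") {
    return(env[[node$token]])
  }
  vals <- vapply(node$args, eval_ast_assignment, TRUE, env = env)
  if (node$op == "and") all(vals) else any(vals)
}

truth_table_equal <- function(a, b) {
  if (inherits(a, "mask_definition")) a <- a$ast
  if (inherits(b, "mask_definition")) b <- b$ast
  atoms <- union(maskcover:::mask_atoms(a), maskcover:::mask_atoms(b))
  stopifnot(length(atoms) <= 20)
  for (bits in 0:(2^length(atoms) - 1)) {
    env <- as.list(stats::setNames(
      as.logical(bitwAnd(bits, 2^(seq_along(atoms) - 1))), atoms
    ))
    if (eval_ast_assignment(a, env) != eval_ast_assignment(b, env)) {
      return(FALSE)
    }
  }
  TRUE
}

# --- OLS normal-equations + t-distribution oracle ---------------------------
ols_oracle <- function(y, burden, covariates = NULL) {
  X <- cbind(1, burden)
  if (!is.null(covariates)) X <- cbind(X, as.matrix(covariates))
  xtx <- t(X) %*% X
  beta_hat <- solve(xtx, t(X) %*% y)
  res <- y - X %*% beta_hat
  df <- nrow(X) - ncol(X)
  sigma2 <- sum(res^2) / df
  vb <- sigma2 * solve(xtx)[2, 2]
  tibble::tibble(
    beta = beta_hat[2], se = sqrt(vb),
    statistic = beta_hat[2] / sqrt(vb), df = df,
    p = 2 * stats::pt(abs(beta_hat[2] / sqrt(vb)), df, lower.tail = FALSE)
  )
}

# --- reference greedy LD-clump trace ----------------------------------------
reference_clump <- function(stats_tbl, genotypes, p1, r2, window_kb) {
  remaining <- stats_tbl[order(stats_tbl$p, stats_tbl$variant_id), ]
  out <- character()
  while (nrow(remaining) > 0) {
    if (remaining$p[1] >= p1) break
    top <- remaining[1, ]
    out <- c(out, top$variant_id)
    remaining <- remaining[-1, ]
    keep <- rep(TRUE, nrow(remaining))
    for (i in seq_len(nrow(remaining))) {
      if (remaining$chrom[i] == top$chrom &&
        abs(remaining$pos[i] - top$pos) <= window_kb * 1000) {
        rr <- suppressWarnings(stats::cor(
          genotypes[, remaining$variant_id[i]], genotypes[, top$variant_id]
        ))
        if (!is.na(rr) && rr^2 >= r2) keep[i] <- FALSE
      }
    }
    remaining <- remaining[keep, , drop = FALSE]
  }
  out
}

# --- adjusted Rand index (for planted-label recovery) -----------------------
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  exp_idx <- sum_a * sum_b / n
  max_idx <- (sum_a + sum_b) / 2
  (sum_ij - exp_idx) / (max_idx - exp_idx)
}

# --- small variant-table builder --------------------------------------------
toy_variant <- function(consequence = "missense", maf = 1e-4, mac = 1,
                        lof_confidence = "none", impact = "MODERATE",
                        is_indel = FALSE, ...) {
  extra <- list(...)
  base <- tibble::tibble(
    variant_id = "v", chrom = "chr1", pos = 1L, ref = "A", alt = "G",
    gene = "g", consequence = consequence, is_indel = is_indel,
    lof_confidence = lof_confidence, impact = impact, maf = maf,
    mac = mac
  )
  for (nm in names(extra)) base[[nm]] <- extra[[nm]]
  base
}

# random variant fixture with predictor columns, for interpreter-equivalence
# property tests
random_variants <- function(n, seed) {
  set.seed(seed)
  csq <- c(
    "stop_gained", "stop_lost", "frameshift", "splice_donor",
    "splice_acceptor", "splice_region", "missense", "synonymous",
    "inframe_indel", "other"
  )
  tibble::tibble(
    variant_id = sprintf("v%03d", seq_len(n)),
    chrom = "chr1", pos = seq_len(n), ref = "A", alt = "G",
    gene = sample(c("g1", "g2", "g3"), n, replace = TRUE),
    consequence = sample(csq, n, replace = TRUE),
    is_indel = sample(c(TRUE, FALSE), n, replace = TRUE),
    lof_confidence = sample(c("HC", "LC", "none"), n, replace = TRUE),
    impact = sample(c("HIGH", "MODERATE", "LOW", "MODIFIER"), n, replace = TRUE),
    maf = stats::runif(n, 0, 0.5),
    mac = sample(0:50, n, replace = TRUE),
    REVEL_score = ifelse(stats::runif(n) < 0.2, NA, stats::runif(n)),
    CADD_phred = ifelse(stats::runif(n) < 0.2, NA, stats::runif(n, 0, 50)),
    SIFT_pred = sample(c("D", "T", NA), n, replace = TRUE),
    Polyphen2_HDIV_pred = sample(c("D", "P", "B", NA), n, replace = TRUE),
    Polyphen2_HVAR_pred = sample(c("D", "P", "B", NA), n, replace = TRUE),
    combo_og = stats::runif(n)
  )
}

random_mask_expression <- function(seed) {
  set.seed(seed)
  atoms <- c(
    "stop_gained", "frameshift", "missense", "synonymous", "essential_splice",
    "LoF_HC", "IMPACT_HIGH", "REVEL_score_0_55", "CADD_phred_20",
    "SIFT_pred_D", "Polyphen2_HDIV_pred_D", "combo_og25", "maf1", "maf0_1",
    "maf5", "maf_gt_0_01", "is_indel_placeholder"
  )
  atoms <- setdiff(atoms, "is_indel_placeholder")
  pick <- function() sample(atoms, 1)
  grp <- function(depth) {
    if (depth <= 0 || stats::runif(1) < 0.4) {
      return(pick())
    }
    k <- sample(2:3, 1)
    parts <- vapply(seq_len(k), function(i) grp(depth - 1), "")
    op <- sample(c(" & ", " | "), 1)
    paste0("(", paste(parts, collapse = op), ")")
  }
  grp(3)
}
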