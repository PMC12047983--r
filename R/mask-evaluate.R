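# Evaluating masks against an annotated variant table.
#
# Variant tables are tibbles with one row per variant. Required columns:
# variant_id, chrom, pos, ref, alt, gene, consequence, is_indel,
# lof_confidence ("HC", "LC" or "none"), impact, maf, mac. Predictor columns
# follow the naming scheme <Algorithm>_score / <Algorithm>_phred /
# <Algorithm>_rankscore (numeric, native scale) and <Algorithm>_pred
# (categorical call). Composite scores live in combo_og / combo_pc / combo_ic.
# Missing predictor values are permitted and never satisfy an atom.

atom_column <- function(info) {
  switch(info$kind,
    pred = paste0(info$algorithm, "_pred"),
    score = paste0(info$algorithm, "_", info$scale),
    combo = paste0("combo_", info$method),
    NULL
  )
}

eval_atom <- function(token, variants) {
  info <- atom_info(token)
  if (is.null(info)) {
    stop("unknown mask atom: '", token, "'", call. = FALSE)
  }
  n <- nrow(variants)
  col <- atom_column(info)
  if (!is.null(col) && !col %in% names(variants)) {
    stop(
      "mask atom '", token, "' needs variant column '", col,
      "', which is absent from the annotation table",
      call. = FALSE
    )
  }
  out <- switch(info$kind,
    consequence = variants$consequence == info$value,
    essential_splice = variants$consequence %in% c("splice_donor", "splice_acceptor"),
    indel = variants$is_indel,
    lof = variants$lof_confidence == info$value,
    impact = variants$impact == info$value,
    pred = variants[[col]] == info$category,
    score = variants[[col]] >= info$threshold,
    combo = variants[[col]] >= info$cut,
    maf = if (info$op == "<") variants$maf < info$value else variants$maf > info$value,
    alias = stop(
      "mask atom '", token, "' must be normalized before evaluation ",
      "(see normalize_mask())",
      call. = FALSE
    )
  )
  out[is.na(out)] <- FALSE
  out
}

#' Evaluate a mask against a variant table
#'
#' Returns the per-variant inclusion flag of a mask. Score and categorical
#' atoms on variants with missing predictor values evaluate `FALSE`
#' (an unscored variant cannot satisfy a score threshold); MAF tokens compare
#' against the cohort `maf` column.
#'
#' @param mask A `mask_definition` (normalized; alias atoms such as `splice`
#'   must have been rewritten by [normalize_mask()]).
#' @param variants Variant annotation tibble (see package vignette).
#' @return Logical vector of length `nrow(variants)`.
#' @examples
#' v <- tibble::tibble(
#'   variant_id = c("a", "b"), consequence = c("missense", "synonymous"),
#'   is_indel = FALSE, lof_confidence = "none", impact = "MODERATE",
#'   maf = c(5e-4, 5e-4), REVEL_score = c(0.6, NA)
#' )
#' m <- parse_mask("missense & REVEL_score_0_55 & maf0_1")
#' evaluate_mask(m, v)
#' @export
evaluate_mask <- function(mask, variants) {
  stopifnot(inherits(mask, "mask_definition"))
  ev <- function(node) {
    if (node$op == "atom") {
      return(eval_atom(node$token, variants))
    }
    vals <- lapply(node$args, ev)
    if (node$op == "and") Reduce(`&`, vals) else Reduce(`|`, vals)
  }
  ev(mask$ast)
}

#' Build the mask-by-variant membership matrix of a catalog
#'
#' @param catalog Mask catalog tibble with columns `mask_id`, `expression`
#'   (and optionally `source`), as read by [read_mask_catalog()] or built by
#'   [simulate_mask_catalog()].
#' @param variants Variant annotation tibble.
#' @param normalize Normalize each mask before evaluation (default `TRUE`).
#' @return Logical matrix, rows = masks (rownames `mask_id`), columns =
#'   variants (colnames `variant_id`).
#' @export
evaluate_catalog <- function(catalog, variants, normalize = TRUE) {
  stopifnot(!anyDuplicated(catalog$mask_id))
  masks <- purrr::map2(catalog$expression, catalog$mask_id, parse_mask)
  if (normalize) masks <- purrr::map(masks, normalize_mask)
  mem <- vapply(masks, evaluate_mask, logical(nrow(variants)), variants = variants)
  mem <- matrix(mem,
    nrow = nrow(catalog), ncol = nrow(variants), byrow = TRUE,
    dimnames = list(catalog$mask_id, variants$variant_id)
  )
  mem
}

#' Deduplicate a mask catalog by canonical form
#'
#' Masks whose normalized canonical expressions coincide are merged into one
#' representative (the lexicographically smallest `mask_id`); the merged
#' provenance strings are joined with `";"`.
#'
#' @param catalog Mask catalog tibble (`mask_id`, `expression`, optional
#'   `source`).
#' @return Catalog tibble with one row per canonical form, columns `mask_id`,
#'   `expression` (canonical), `source`, `n_merged`, `merged_ids`.
#' @export
dedupe_catalog <- function(catalog) {
  if (!"source" %in% names(catalog)) catalog$source <- NA_character_
  canon <- purrr::map_chr(
    purrr::map2(catalog$expression, catalog$mask_id, parse_mask),
    ~ normalize_mask(.x)$expression
  )
  catalog |>
    dplyr::mutate(expression = canon) |>
    dplyr::arrange(.data$mask_id) |>
    dplyr::group_by(.data$expression) |>
    dplyr::summarise(
      merged_ids = paste(.data$mask_id, collapse = ";"),
      mask_id = dplyr::first(.data$mask_id),
      source = paste(unique(stats::na.omit(.data$source)), collapse = ";"),
      n_merged = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::select(
      "mask_id", "expression", "source", "n_merged", "merged_ids"
    ) |>
    dplyr::arrange(.data$mask_id)
}

# -- categorization -----------------------------------------------------------

PLOF_ATOM_TOKENS <- c(
  "stop_gained", "stop_lost", "frameshift", "splice_donor", "splice_acceptor",
  "essential_splice", "LoF_HC", "IMPACT_HIGH"
)
MISINDEL_ATOM_TOKENS <- c("inframe_indel", "indel", "LoF_LC")
CODING_ATOM_TOKENS <- c(
  "synonymous", "splice_region", "start_retained", "stop_retained",
  "incomplete_terminal_codon", "other", "IMPACT_MODERATE", "IMPACT_LOW",
  "IMPACT_MODIFIER"
)

atom_annotation_class <- function(token) {
  if (token %in% PLOF_ATOM_TOKENS) {
    return("plof")
  }
  if (token == "missense") {
    return("mis")
  }
  if (token %in% MISINDEL_ATOM_TOKENS) {
    return("indel")
  }
  if (token %in% CODING_ATOM_TOKENS) {
    return("coding")
  }
  info <- atom_info(token)
  if (info$kind %in% c("pred", "score", "combo")) {
    return("pred")
  }
  if (info$kind == "maf") {
    return(character(0))
  }
  "coding"
}

ast_annotation_classes <- function(node) {
  if (node$op == "atom") {
    return(atom_annotation_class(node$token))
  }
  u <- unique(unlist(lapply(node$args, ast_annotation_classes)))
  if (node$op == "and" && all(c("mis", "pred") %in% u)) {
    # a predictor constraint conjoined with missense makes damaging missense
    u <- c(setdiff(u, c("mis", "pred")), "dammis")
  }
  u
}

maf_upper_bounds <- function(ast) {
  toks <- mask_atoms(ast)
  vals <- purrr::map(toks, atom_info)
  unlist(purrr::map2(toks, vals, function(t, i) {
    if (!is.null(i) && i$kind == "maf" && i$op == "<") i$value else NULL
  }))
}

#' Categorize a mask by annotation class and maximum-MAF class
#'
#' The maximum-MAF class comes from the tightest upper-bound MAF token:
#' none or > 1% is `common`, <= 1% is `low-frequency`, <= 0.1% is `rare`,
#' <= 0.01% is `ultra-rare`. The annotation class summarizes the non-MAF
#' leaves: pLoF-only atoms give `pLoF`; damaging-missense-only gives
#' `damMis`; pLoF plus damaging missense gives `pLoFdamMis`; pLoF plus
#' unqualified missense (or indel-class atoms) gives `pLoFmis`;
#' missense/indel atoms without pLoF give `misIndels`; anything containing
#' broader coding atoms (synonymous etc.) is `coding`.
#'
#' @param mask A `mask_definition`; normalized internally.
#' @return A tibble with one row: `mask_id`, `annotation_class`,
#'   `maxmaf_class`.
#' @examples
#' categorize_mask(parse_mask("stop_gained | frameshift"))
#' categorize_mask(parse_mask("(LoF_HC | (missense & combo_og25)) & maf1"))
#' @export
categorize_mask <- function(mask) {
  stopifnot(inherits(mask, "mask_definition"))
  mask <- normalize_mask(mask)
  bounds <- maf_upper_bounds(mask$ast)
  t <- if (length(bounds)) min(bounds) else Inf
  maxmaf_class <- dplyr::case_when(
    t <= 1e-4 ~ "ultra-rare",
    t <= 1e-3 ~ "rare",
    t <= 1e-2 ~ "low-frequency",
    TRUE ~ "common"
  )
  cls <- ast_annotation_classes(mask$ast)
  if ("pred" %in% cls) cls <- unique(c(setdiff(cls, "pred"), "dammis"))
  has <- function(x) x %in% cls
  annotation_class <-
    if (has("coding")) {
      "coding"
    } else if (has("plof") && (has("mis") || has("indel"))) {
      "pLoFmis"
    } else if (has("plof") && has("dammis")) {
      "pLoFdamMis"
    } else if (has("plof")) {
      "pLoF"
    } else if (has("dammis") && !has("mis") && !has("indel")) {
      "damMis"
    } else if (has("mis") || has("indel") || has("dammis")) {
      "misIndels"
    } else {
      "coding"
    }
  tibble::tibble(
    mask_id = mask$mask_id,
    annotation_class = annotation_class,
    maxmaf_class = maxmaf_class
  )
}

#' Categorize every mask in a catalog
#'
#' @inheritParams dedupe_catalog
#' @return The catalog with `annotation_class` and `maxmaf_class` columns
#'   appended.
#' @export
categorize_catalog <- function(catalog) {
  cats <- purrr::map2(
    catalog$expression, catalog$mask_id,
    ~ categorize_mask(parse_mask(.x, mask_id = .y))
  ) |> purrr::list_rbind()
  dplyr::left_join(catalog, cats, by = "mask_id")
}

# -- catalog I/O --------------------------------------------------------------

#' Read / write a mask catalog TSV
#'
#' The catalog format is a tab-separated file with header columns `mask_id`,
#' `expression`, `source`.
#'
#' @param path File path.
#' @return `read_mask_catalog()` returns the catalog tibble.
#' @export
read_mask_catalog <- function(path) {
  readr::read_tsv(path,
    col_types = readr::cols(
      mask_id = readr::col_character(),
      expression = readr::col_character(),
      source = readr::col_character()
    )
  )
}

#' @rdname read_mask_catalog
#' @param catalog Catalog tibble.
#' @export
write_mask_catalog <- function(catalog, path) {
  readr::write_tsv(catalog, path)
  invisible(path)
}

#' Read a variant annotation TSV
#'
#' One row per variant; the fixed columns are typed, predictor columns are
#' guessed.
#'
#' @param path File path.
#' @return Variant annotation tibble.
#' @export
read_annotation_table <- function(path) {
  readr::read_tsv(path,
    col_types = readr::cols(
      variant_id = readr::col_character(),
      chrom = readr::col_character(),
      pos = readr::col_integer(),
      ref = readr::col_character(),
      alt = readr::col_character(),
      gene = readr::col_character(),
      consequence = readr::col_character(),
      is_indel = readr::col_logical(),
      lof_confidence = readr::col_character(),
      impact = readr::col_character(),
      maf = readr::col_double(),
      mac = readr::col_integer(),
      .default = readr::col_guess()
    )
  )
}

#' @rdname read_annotation_table
#' @param variants Variant annotation tibble.
#' @export
write_annotation_table <- function(variants, path) {
  readr::write_tsv(variants, path)
  invisible(path)
}
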