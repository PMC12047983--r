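# Mask expression language
#
# A mask is a boolean predicate over annotation atoms and allele-frequency
# tokens, written infix with `&`, `|` and parentheses; `&` binds tighter
# than `|`. Atoms come from a fixed vocabulary:
#
#   * consequence tokens:  stop_gained, stop_lost, frameshift, splice_donor,
#     splice_acceptor, splice_region, missense, synonymous, inframe_indel,
#     start_retained, stop_retained, incomplete_terminal_codon, other,
#     plus essential_splice (= splice_donor | splice_acceptor) and indel;
#   * LOFTEE confidence:   LoF_HC, LoF_LC;
#   * VEP impact:          IMPACT_HIGH, IMPACT_MODERATE, IMPACT_LOW,
#     IMPACT_MODIFIER;
#   * categorical predictors:  <Algorithm>_pred_<CAT>, e.g.
#     Polyphen2_HDIV_pred_D, SIFT_pred_D, ClinVar_P / ClinVar_LP;
#   * score thresholds:    <Algorithm>_score_<x>[_<y>] meaning native score
#     >= x.y (REVEL_score_0_55 is REVEL >= 0.55), <Algorithm>_phred_<x>
#     (CADD_phred_20 is CADD phred >= 20), <Algorithm>_rankscore_<x>_<y>,
#     and combo_<og|pc|ic><NN> meaning composite score >= NN/100;
#   * MAF tokens:          maf<X> is maf < X% (maf1 -> < 1%, maf0_1 ->
#     < 0.1%, maf0_01 -> < 0.01%, maf10 -> < 10%), maf_gt_<X> is maf > X%,
#     and maf_le_<X> (maf <= X%) which normalization rewrites to maf<X>;
#   * harmonization aliases accepted by the parser and rewritten by
#     `normalize_mask()`: nonsynonymous, splice, polyphen2,
#     Polyphen2_pred_<CAT>, and reference-panel MAF tokens such as
#     gnomad_maf1 which are mapped to cohort MAF tokens.

CONSEQUENCE_VOCAB <- c(
  "stop_gained", "stop_lost", "frameshift", "splice_donor", "splice_acceptor",
  "splice_region", "missense", "synonymous", "inframe_indel", "start_retained",
  "stop_retained", "incomplete_terminal_codon", "other"
)

MAF_PANEL_PREFIXES <- c("gnomad", "exac", "kg1000", "topmed", "esp", "internal")

re_match1 <- function(x, pattern) {
  m <- regmatches(x, regexec(pattern, x))[[1]]
  if (length(m) == 0) NULL else m
}

# numeric value of the X[_Y] percentage suffix, e.g. "0_55" -> 0.0055
maf_suffix_value <- function(s) as.numeric(gsub("_", ".", s)) / 100

#' Classify a token of the mask language
#'
#' @param token A single token string.
#' @return A list with `kind` (one of `"consequence"`, `"essential_splice"`,
#'   `"indel"`, `"lof"`, `"impact"`, `"pred"`, `"score"`, `"combo"`, `"maf"`,
#'   `"alias"`) plus kind-specific fields, or `NULL` if the token is not in
#'   the vocabulary.
#' @keywords internal
atom_info <- function(token) {
  if (token %in% CONSEQUENCE_VOCAB) {
    return(list(kind = "consequence", value = token))
  }
  if (token == "essential_splice") return(list(kind = "essential_splice"))
  if (token == "indel") return(list(kind = "indel"))
  if (token %in% c("LoF_HC", "LoF_LC")) {
    return(list(kind = "lof", value = sub("LoF_", "", token)))
  }
  if (grepl("^IMPACT_(HIGH|MODERATE|LOW|MODIFIER)$", token)) {
    return(list(kind = "impact", value = sub("IMPACT_", "", token)))
  }
  if (token %in% c("nonsynonymous", "splice", "polyphen2")) {
    return(list(kind = "alias", value = token))
  }
  m <- re_match1(token, "^Polyphen2_pred_([A-Za-z]+)$")
  if (!is.null(m)) return(list(kind = "alias", value = "polyphen2_pred", category = m[2]))
  m <- re_match1(token, "^ClinVar_([A-Z]+)$")
  if (!is.null(m)) {
    return(list(kind = "pred", algorithm = "ClinVar", category = m[2]))
  }
  m <- re_match1(token, "^([A-Za-z][A-Za-z0-9.]*(?:_[A-Za-z0-9.]+)*)_pred_([A-Za-z]+)$")
  if (!is.null(m)) return(list(kind = "pred", algorithm = m[2], category = m[3]))
  m <- re_match1(token, "^combo_(og|pc|ic)([0-9]+)$")
  if (!is.null(m)) {
    return(list(kind = "combo", method = m[2], cut = as.numeric(m[3]) / 100))
  }
  m <- re_match1(token, "^([A-Za-z][A-Za-z0-9.]*(?:_[A-Za-z0-9.]+)*?)_(score|phred|rankscore)_([0-9]+(?:_[0-9]+)?)$")
  if (!is.null(m)) {
    return(list(
      kind = "score", algorithm = m[2], scale = m[3],
      threshold = as.numeric(gsub("_", ".", m[4]))
    ))
  }
  m <- re_match1(token, "^maf_gt_([0-9]+(?:_[0-9]+)?)$")
  if (!is.null(m)) return(list(kind = "maf", op = ">", value = maf_suffix_value(m[2])))
  m <- re_match1(token, "^maf_le_([0-9]+(?:_[0-9]+)?)$")
  if (!is.null(m)) {
    return(list(kind = "alias", value = "maf_le", suffix = m[2]))
  }
  m <- re_match1(token, "^maf([0-9]+(?:_[0-9]+)?)$")
  if (!is.null(m)) return(list(kind = "maf", op = "<", value = maf_suffix_value(m[2])))
  m <- re_match1(token, paste0(
    "^(", paste(MAF_PANEL_PREFIXES, collapse = "|"), ")_(maf(?:_le_|_gt_)?[0-9]+(?:_[0-9]+)?)$"
  ))
  if (!is.null(m)) return(list(kind = "alias", value = "panel_maf", cohort_token = m[3]))
  NULL
}

atom_node <- function(token) structure(list(op = "atom", token = token), class = "mask_ast")
op_node <- function(op, args) structure(list(op = op, args = args), class = "mask_ast")

tokenize_mask <- function(expression) {
  pos <- gregexpr("[()&|]|[A-Za-z0-9._]+|\\S", expression)[[1]]
  toks <- regmatches(expression, gregexpr("[()&|]|[A-Za-z0-9._]+|\\S", expression))[[1]]
  list(tokens = toks, positions = as.integer(pos))
}

#' Parse a mask expression into a mask definition
#'
#' Parses the infix boolean mask language (see the package vignette for the
#' grammar). `&` takes precedence over `|`; parentheses group. Unknown atoms
#' and unbalanced parentheses are errors.
#'
#' @param expression Mask expression string, e.g.
#'   `"(LoF_HC | (missense & combo_og25)) & maf1"`.
#' @param mask_id Identifier for the mask; defaults to the expression itself.
#' @param source Free-text provenance string.
#' @return A `mask_definition` object: a list with `mask_id`, `ast`,
#'   `expression` (the serialized AST) and `source`.
#' @examples
#' parse_mask("stop_gained | frameshift")
#' parse_mask("(stop_gained | stop_lost) & maf0_1", mask_id = "ptv_rare")
#' @export
parse_mask <- function(expression, mask_id = NULL, source = NA_character_) {
  stopifnot(is.character(expression), length(expression) == 1)
  tk <- tokenize_mask(expression)
  toks <- tk$tokens
  positions <- tk$positions
  i <- 0L

  peek <- function() if (i < length(toks)) toks[i + 1L] else NA_character_
  advance <- function() {
    i <<- i + 1L
    toks[i]
  }
  err_pos <- function() if (i < length(toks)) positions[i + 1L] else nchar(expression) + 1L

  parse_expr <- function() {
    args <- list(parse_term())
    while (!is.na(peek()) && peek() == "|") {
      advance()
      args <- c(args, list(parse_term()))
    }
    if (length(args) == 1) args[[1]] else op_node("or", args)
  }
  parse_term <- function() {
    args <- list(parse_factor())
    while (!is.na(peek()) && peek() == "&") {
      advance()
      args <- c(args, list(parse_factor()))
    }
    if (length(args) == 1) args[[1]] else op_node("and", args)
  }
  parse_factor <- function() {
    tok <- peek()
    if (is.na(tok)) {
      stop("unexpected end of mask expression at position ", err_pos(), call. = FALSE)
    }
    if (tok == "(") {
      advance()
      node <- parse_expr()
      if (is.na(peek()) || peek() != ")") {
        stop("unbalanced parentheses in mask expression at position ", err_pos(),
          call. = FALSE
        )
      }
      advance()
      return(node)
    }
    if (tok %in% c(")", "&", "|")) {
      stop("unexpected '", tok, "' in mask expression at position ", err_pos(),
        call. = FALSE
      )
    }
    advance()
    if (is.null(atom_info(tok))) {
      stop("unknown mask atom: '", tok, "'", call. = FALSE)
    }
    atom_node(tok)
  }

  ast <- parse_expr()
  if (i < length(toks)) {
    stop("unbalanced parentheses in mask expression at position ", err_pos(),
      call. = FALSE
    )
  }
  new_mask_definition(ast, mask_id = mask_id %||% expression, source = source)
}

new_mask_definition <- function(ast, mask_id, source = NA_character_) {
  structure(
    list(
      mask_id = mask_id, ast = ast,
      expression = serialize_mask(ast), source = source
    ),
    class = "mask_definition"
  )
}

#' @export
print.mask_definition <- function(x, ...) {
  cat("<mask_definition> ", x$mask_id, "\n  ", x$expression, "\n", sep = "")
  invisible(x)
}

#' Serialize a mask AST back to its expression string
#'
#' Emits the minimal-parenthesis infix form; parsing the result yields an
#' identical AST (round-trip property).
#'
#' @param ast A mask AST node (or a `mask_definition`).
#' @return A single expression string.
#' @export
serialize_mask <- function(ast) {
  if (inherits(ast, "mask_definition")) ast <- ast$ast
  ser <- function(node, parent_op) {
    if (node$op == "atom") {
      return(node$token)
    }
    sep <- if (node$op == "and") " & " else " | "
    s <- paste(vapply(node$args, ser, "", parent_op = node$op), collapse = sep)
    # only OR under AND needs parentheses
    if (node$op == "or" && identical(parent_op, "and")) paste0("(", s, ")") else s
  }
  ser(ast, parent_op = NA_character_)
}

# -- normalization ------------------------------------------------------------

rewrite_atom <- function(token) {
  info <- atom_info(token)
  if (is.null(info) || info$kind != "alias") {
    return(atom_node(token))
  }
  switch(info$value,
    nonsynonymous = atom_node("missense"),
    splice = op_node("or", list(atom_node("splice_donor"), atom_node("splice_acceptor"))),
    polyphen2 = op_node("or", list(
      atom_node("Polyphen2_HDIV_pred_D"), atom_node("Polyphen2_HVAR_pred_D")
    )),
    polyphen2_pred = op_node("or", list(
      atom_node(paste0("Polyphen2_HDIV_pred_", info$category)),
      atom_node(paste0("Polyphen2_HVAR_pred_", info$category))
    )),
    maf_le = atom_node(paste0("maf", info$suffix)),
    panel_maf = rewrite_atom(info$cohort_token)
  )
}

apply_rewrites <- function(node) {
  if (node$op == "atom") {
    return(rewrite_atom(node$token))
  }
  op_node(node$op, lapply(node$args, apply_rewrites))
}

canonicalize_ast <- function(node) {
  if (node$op == "atom") {
    return(node)
  }
  args <- lapply(node$args, canonicalize_ast)
  # flatten same-op children into an n-ary node
  flat <- list()
  for (a in args) {
    if (a$op == node$op) flat <- c(flat, a$args) else flat <- c(flat, list(a))
  }
  keys <- vapply(flat, serialize_mask, "")
  flat <- flat[!duplicated(keys)]
  keys <- keys[!duplicated(keys)]
  flat <- flat[order(keys, method = "radix")]
  if (length(flat) == 1) {
    return(flat[[1]])
  }
  op_node(node$op, flat)
}

#' Normalize and canonicalize a mask definition
#'
#' Applies the harmonization rewrites used when reconciling mask definitions
#' drawn from heterogeneous sources, then canonicalizes the AST:
#'
#' * `maf_le_X` (MAF <= X%) becomes `mafX` (MAF < X%);
#' * `nonsynonymous` becomes `missense`;
#' * `splice` becomes `splice_donor | splice_acceptor`;
#' * unversioned `polyphen2` (or `Polyphen2_pred_*`) expands to the HDIV and
#'   HVAR variants;
#' * reference-panel MAF tokens (e.g. `gnomad_maf1`) become cohort MAF tokens.
#'
#' Canonical form is the flattened n-ary AND/OR with duplicate children
#' removed and children sorted lexicographically by their serialization; it is
#' idempotent, and two masks with equal canonical expressions are logically
#' equivalent. (The converse is not guaranteed: no full boolean minimization
#' is attempted.)
#'
#' @param mask A `mask_definition` from [parse_mask()].
#' @return A normalized `mask_definition`.
#' @examples
#' normalize_mask(parse_mask("nonsynonymous & maf_le_1"))
#' @export
normalize_mask <- function(mask) {
  stopifnot(inherits(mask, "mask_definition"))
  ast <- canonicalize_ast(apply_rewrites(mask$ast))
  new_mask_definition(ast, mask_id = mask$mask_id, source = mask$source)
}

mask_atoms <- function(ast) {
  if (inherits(ast, "mask_definition")) ast <- ast$ast
  if (ast$op == "atom") {
    return(ast$token)
  }
  unique(unlist(lapply(ast$args, mask_atoms)))
}
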