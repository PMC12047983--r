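# Masking strategies and strategy-level significance counting.
#
# A masking strategy is a set of masks analyzed jointly; its significance
# threshold is Bonferroni-corrected for the set size: alpha0 / m. An
# association (gene, trait) detected by several member masks is counted
# once.

#' Construct a masking strategy
#'
#' @param mask_ids Character vector of member mask ids (must be unique).
#' @param strategy_id Identifier.
#' @param alpha0 Mask-level significance threshold (default 2.5e-6); the
#'   strategy-level threshold is `alpha0 / length(mask_ids)`.
#' @return A `strategy` object with fields `strategy_id`, `mask_ids`, `m`,
#'   `alpha0`, `threshold`.
#' @examples
#' new_strategy(c("ptv", "ptv_missense"), "example")
#' @export
new_strategy <- function(mask_ids, strategy_id = "strategy", alpha0 = 2.5e-6) {
  stopifnot(length(mask_ids) >= 1, !anyDuplicated(mask_ids))
  structure(
    list(
      strategy_id = strategy_id, mask_ids = as.character(mask_ids),
      m = length(mask_ids), alpha0 = alpha0,
      threshold = alpha0 / length(mask_ids)
    ),
    class = "strategy"
  )
}

#' @export
print.strategy <- function(x, ...) {
  cat(
    "<strategy> ", x$strategy_id, ": m = ", x$m,
    ", threshold = ", format(x$threshold, digits = 3), "\n  ",
    paste(x$mask_ids, collapse = ", "), "\n",
    sep = ""
  )
  invisible(x)
}

#' Count the significant associations of a masking strategy
#'
#' The association set is the union over member masks of (gene, trait) pairs
#' whose p-value — at the allele-frequency bin matching `freq_class` — is
#' below the Bonferroni-corrected threshold `alpha0 / m`.
#'
#' @param results Burden-test results tibble (gene, trait, mask_id, maf_bin,
#'   p), e.g. `tidy()` of a [run_mask_scan()] result.
#' @param strategy A [new_strategy()] object.
#' @param freq_class `"total"`, `"low-frequency"` or `"rare"`; selects the
#'   0.5, 0.01 or 0.001 bin.
#' @param aaf_bins The three bins, widest first.
#' @return List with `associations` (tibble gene, trait), `count`, and the
#'   `threshold` applied.
#' @export
count_strategy_significant <- function(results, strategy,
                                       freq_class = c("total", "low-frequency", "rare"),
                                       aaf_bins = c(0.5, 0.01, 0.001)) {
  freq_class <- match.arg(freq_class)
  missing_masks <- setdiff(strategy$mask_ids, unique(results$mask_id))
  if (length(missing_masks)) {
    stop(
      "strategy refers to mask id(s) absent from the results: ",
      paste(missing_masks, collapse = ", "),
      call. = FALSE
    )
  }
  bin <- class_bin(freq_class, aaf_bins)
  assoc <- results |>
    dplyr::filter(
      .data$mask_id %in% strategy$mask_ids,
      .data$maf_bin == bin,
      .data$p < strategy$threshold
    ) |>
    dplyr::distinct(.data$gene, .data$trait) |>
    dplyr::arrange(.data$gene, .data$trait)
  list(associations = assoc, count = nrow(assoc), threshold = strategy$threshold)
}

#' Summarize a catalog of previously employed strategies
#'
#' Computes per-strategy significant-association counts, the average count
#' across strategies (the "average previously employed strategy"), and the
#' best strategy (largest count, ties broken by lexicographic strategy id).
#'
#' @param strategies List of [new_strategy()] objects.
#' @inheritParams count_strategy_significant
#' @return List with `table` (tibble strategy_id, m, count), `average`
#'   (mean count), and `best` (the winning `strategy`).
#' @export
summarize_catalog_strategies <- function(strategies, results,
                                         freq_class = c("total", "low-frequency", "rare"),
                                         aaf_bins = c(0.5, 0.01, 0.001)) {
  freq_class <- match.arg(freq_class)
  if (length(strategies) == 0) {
    stop("no strategies supplied", call. = FALSE)
  }
  tab <- purrr::map(strategies, function(s) {
    tibble::tibble(
      strategy_id = s$strategy_id, m = s$m,
      count = count_strategy_significant(results, s, freq_class, aaf_bins)$count
    )
  }) |> purrr::list_rbind()
  ord <- order(-tab$count, tab$strategy_id)
  list(
    table = tab,
    average = mean(tab$count),
    best = strategies[[ord[1]]]
  )
}

#' Jaccard similarity of two strategies' mask sets
#'
#' `|A intersect B| / |A union B|`; two empty sets have similarity 0.
#'
#' @param a,b [new_strategy()] objects (or character vectors of mask ids).
#' @return A fraction in \[0, 1\].
#' @examples
#' jaccard_similarity(c("a", "b", "c"), c("b", "c", "d")) # 0.5
#' @export
jaccard_similarity <- function(a, b) {
  ids <- function(x) if (inherits(x, "strategy")) x$mask_ids else as.character(x)
  a <- unique(ids(a))
  b <- unique(ids(b))
  u <- length(union(a, b))
  if (u == 0) {
    return(0)
  }
  length(intersect(a, b)) / u
}

#' Read / write a strategy catalog TSV
#'
#' Tab-separated with header columns `strategy_id`, `source`, `mask_ids`
#' (comma-joined).
#'
#' @param path File path.
#' @param alpha0 Mask-level threshold passed to [new_strategy()].
#' @return A list of `strategy` objects (named by strategy id).
#' @export
read_strategy_catalog <- function(path, alpha0 = 2.5e-6) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  out <- purrr::map2(
    strsplit(tab$mask_ids, ","), tab$strategy_id,
    ~ new_strategy(trimws(.x), .y, alpha0 = alpha0)
  )
  stats::setNames(out, tab$strategy_id)
}

#' @rdname read_strategy_catalog
#' @param strategies List of `strategy` objects.
#' @export
write_strategy_catalog <- function(strategies, path) {
  tab <- purrr::map(strategies, function(s) {
    tibble::tibble(
      strategy_id = s$strategy_id,
      source = NA_character_,
      mask_ids = paste(s$mask_ids, collapse = ",")
    )
  }) |> purrr::list_rbind()
  readr::write_tsv(tab, path)
  invisible(path)
}
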