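# Greedy covering: masking strategies that maximize Bonferroni-corrected
# significant associations.
#
# For a candidate strategy size m the significance threshold is alpha0 / m,
# so each mask's set of significant (gene, trait) associations shrinks as m
# grows. For each m the greedy step picks the mask adding the most
# not-yet-covered associations (maximum coverage); strategies across all m
# are then compared and the best count wins. Greedy maximum coverage is the
# classic (1 - 1/e)-approximation of the NP-hard exact problem.

#' Build a coverage instance from burden-test results
#'
#' Precomputes, per candidate mask, the sorted p-value list over association
#' keys at the bin matching `freq_class`, so that the significant set at any
#' threshold alpha0/m is a prefix.
#'
#' @param results Burden-test results tibble (gene, trait, mask_id, maf_bin,
#'   p).
#' @param freq_class `"total"`, `"low-frequency"` or `"rare"`.
#' @param alpha0 Mask-level threshold (default 2.5e-6).
#' @param masks Candidate mask ids (default: all masks in the results).
#' @param aaf_bins The three bins, widest first.
#' @return A `coverage_instance`: list with `masks` (named list of tibbles
#'   `key`, `p`, sorted by p; key is `gene` and `trait` joined by `"\r"`),
#'   `alpha0`.
#' @export
coverage_instance <- function(results, freq_class = c("total", "low-frequency", "rare"),
                              alpha0 = 2.5e-6, masks = NULL,
                              aaf_bins = c(0.5, 0.01, 0.001)) {
  freq_class <- match.arg(freq_class)
  bin <- class_bin(freq_class, aaf_bins)
  masks <- masks %||% sort(unique(results$mask_id))
  sub <- results |>
    dplyr::filter(.data$maf_bin == bin, .data$mask_id %in% masks) |>
    dplyr::mutate(key = paste(.data$gene, .data$trait, sep = "\r")) |>
    dplyr::arrange(.data$p) |>
    dplyr::distinct(.data$mask_id, .data$key, .keep_all = TRUE) |>
    dplyr::select("mask_id", "key", "p")
  lst <- split(sub[c("key", "p")], factor(sub$mask_id, levels = masks))
  structure(list(masks = lst, alpha0 = alpha0), class = "coverage_instance")
}

new_coverage_instance <- function(mask_sets, alpha0 = 2.5e-6) {
  # mask_sets: named list of tibbles (key, p); used by tests/simulations
  lst <- lapply(mask_sets, function(s) s[order(s$p), , drop = FALSE])
  structure(
    list(masks = lst[sort(names(lst))], alpha0 = alpha0),
    class = "coverage_instance"
  )
}

# significant association keys of every mask at threshold alpha0 / m
instance_sets <- function(instance, m) {
  thr <- instance$alpha0 / m
  lapply(instance$masks, function(s) s$key[s$p < thr])
}

#' Greedy maximum-coverage strategy of a fixed size
#'
#' At threshold `alpha0 / m`: (1) compute each mask's significant
#' associations, (2) rank masks by count, (3) pick the top mask (ties by
#' lexicographic mask id), (4) remove its associations from all masks,
#' (5) re-rank, (6) repeat until m masks are picked. If gains reach zero
#' before m picks, the remaining slots are filled with unused masks in id
#' order at zero gain so the strategy has exactly m members and the
#' `alpha0/m` threshold remains honest.
#'
#' @param instance A [coverage_instance()].
#' @param m Strategy size, between 1 and the number of candidate masks.
#' @param alpha0 Optional override of the instance threshold.
#' @return List with `strategy` (a [new_strategy()]), `covered` (character
#'   vector of association keys), `count`, and `trace` (tibble step,
#'   mask_id, gain, cumulative).
#' @export
greedy_cover_fixed_m <- function(instance, m, alpha0 = NULL) {
  stopifnot(inherits(instance, "coverage_instance"))
  n_masks <- length(instance$masks)
  if (m < 1 || m > n_masks) {
    stop("strategy size m must be between 1 and ", n_masks, call. = FALSE)
  }
  if (!is.null(alpha0)) instance$alpha0 <- alpha0
  sets <- instance_sets(instance, m)
  ids <- names(sets)
  covered <- character()
  picked <- character()
  trace <- vector("list", m)
  for (step in seq_len(m)) {
    gains <- vapply(ids, function(id) {
      if (id %in% picked) -1L else length(setdiff(sets[[id]], covered))
    }, 0L)
    best <- ids[which.max(gains)] # ids sorted; which.max takes first tie
    gain <- max(gains)
    if (gain <= 0) {
      # no mask adds coverage: fill with unused masks in id order
      remaining <- setdiff(ids, picked)
      fill <- remaining[seq_len(m - step + 1L)]
      for (f in seq_along(fill)) {
        trace[[step + f - 1L]] <- tibble::tibble(
          step = step + f - 1L, mask_id = fill[f], gain = 0L,
          cumulative = length(covered)
        )
      }
      picked <- c(picked, fill)
      break
    }
    covered <- union(covered, sets[[best]])
    picked <- c(picked, best)
    trace[[step]] <- tibble::tibble(
      step = step, mask_id = best, gain = gain, cumulative = length(covered)
    )
  }
  list(
    strategy = new_strategy(picked, paste0("greedy_m", m), instance$alpha0),
    covered = sort(covered), count = length(covered),
    trace = purrr::list_rbind(trace)
  )
}

#' Search strategy sizes and return the overall highest-yield strategy
#'
#' Runs [greedy_cover_fixed_m()] for every size m in `1:m_max` and returns
#' the strategy with the largest covered-association count. Ties go to the
#' smallest m (fewer tests).
#'
#' @param instance A [coverage_instance()].
#' @param m_max Largest size to consider (default: all candidate masks).
#' @return List with `best` (the winning greedy result), `m` (its size), and
#'   `by_m` (tibble m, count summarizing the cross-size comparison).
#' @export
optimal_strategy_search <- function(instance, m_max = length(instance$masks)) {
  stopifnot(inherits(instance, "coverage_instance"))
  if (length(instance$masks) == 0) {
    stop("empty coverage instance", call. = FALSE)
  }
  m_max <- min(m_max, length(instance$masks))
  runs <- lapply(seq_len(m_max), function(m) greedy_cover_fixed_m(instance, m))
  counts <- vapply(runs, `[[`, 0L, "count")
  best_m <- which.max(counts) # first maximum = smallest m
  list(
    best = runs[[best_m]], m = best_m,
    by_m = tibble::tibble(m = seq_len(m_max), count = counts)
  )
}

#' Truncate a greedy trace to a smaller strategy
#'
#' Keeps the first `size` picks of a greedy trace and recounts coverage at
#' the re-corrected threshold `alpha0 / size`.
#'
#' @param instance The [coverage_instance()] the trace came from.
#' @param greedy_result A [greedy_cover_fixed_m()] result.
#' @param size Number of leading picks to keep (`<= m`).
#' @return List with `strategy`, `covered`, `count` as in
#'   [greedy_cover_fixed_m()].
#' @export
truncate_strategy <- function(instance, greedy_result, size) {
  picks <- greedy_result$trace$mask_id
  stopifnot(size >= 1, size <= length(picks))
  keep <- picks[seq_len(size)]
  sets <- instance_sets(instance, size)
  covered <- sort(unique(unlist(sets[keep], use.names = FALSE)))
  list(
    strategy = new_strategy(keep, paste0("greedy_trunc_m", size), instance$alpha0),
    covered = covered, count = length(covered)
  )
}

#' Leave-one-trait-out validation of the greedy optimizer
#'
#' For each trait, the optimizer is run on all other traits; the resulting
#' strategy is scored on the held-out trait and compared with the held-out
#' trait's own optimal count. The per-trait coverage fraction is reported
#' (NaN when the trait-specific optimum is 0).
#'
#' @param results Burden-test results covering at least two traits.
#' @param freq_class `"total"`, `"low-frequency"` or `"rare"`.
#' @param alpha0 Mask-level threshold.
#' @param m_max Largest strategy size searched.
#' @param aaf_bins The three bins, widest first.
#' @return Tibble trait, m (size of the cross-trait strategy),
#'   `loto_count`, `max_count`, `fraction`.
#' @export
leave_one_trait_out <- function(results, freq_class = c("total", "low-frequency", "rare"),
                                alpha0 = 2.5e-6, m_max = NULL,
                                aaf_bins = c(0.5, 0.01, 0.001)) {
  freq_class <- match.arg(freq_class)
  traits <- sort(unique(results$trait))
  if (length(traits) < 2) {
    stop("leave-one-trait-out needs at least two traits", call. = FALSE)
  }
  masks <- sort(unique(results$mask_id))
  m_max <- m_max %||% length(masks)
  purrr::map(traits, function(tr) {
    inst_rest <- coverage_instance(
      dplyr::filter(results, .data$trait != tr), freq_class, alpha0,
      masks = masks, aaf_bins = aaf_bins
    )
    opt_rest <- optimal_strategy_search(inst_rest, m_max)
    inst_tr <- coverage_instance(
      dplyr::filter(results, .data$trait == tr), freq_class, alpha0,
      masks = masks, aaf_bins = aaf_bins
    )
    sets_tr <- instance_sets(inst_tr, opt_rest$best$strategy$m)
    held <- length(unique(unlist(
      sets_tr[opt_rest$best$strategy$mask_ids],
      use.names = FALSE
    )))
    opt_tr <- optimal_strategy_search(inst_tr, m_max)
    tibble::tibble(
      trait = tr, m = opt_rest$m, loto_count = held,
      max_count = opt_tr$best$count,
      fraction = ifelse(opt_tr$best$count == 0, NaN, held / opt_tr$best$count)
    )
  }) |> purrr::list_rbind()
}
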