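# build a coverage instance directly from per-mask association sets with
# chosen p-values
inst_from_sets <- function(sets, p = 1e-12, alpha0 = 2.5e-6) {
  maskcover:::new_coverage_instance(
    lapply(sets, function(k) tibble::tibble(key = k, p = p)),
    alpha0 = alpha0
  )
}

exhaustive_cover <- function(instance, m) {
  sets <- maskcover:::instance_sets(instance, m)
  ids <- names(sets)
  best <- 0L
  for (combo in utils::combn(length(ids), m, simplify = FALSE)) {
    cnt <- length(unique(unlist(sets[combo], use.names = FALSE)))
    best <- max(best, cnt)
  }
  best
}

random_instance <- function(seed) {
  set.seed(seed)
  n_masks <- sample(4:12, 1)
  n_assoc <- sample(10:60, 1)
  keys <- sprintf("a%02d", seq_len(n_assoc))
  alpha0 <- 2.5e-6
  sets <- lapply(seq_len(n_masks), function(i) {
    k <- sample(keys, sample(0:n_assoc, 1))
    # p-values straddle the m-dependent thresholds
    tibble::tibble(key = k, p = alpha0 / 4 * 10^runif(length(k), -2, 1.2))
  })
  names(sets) <- sprintf("m%02d", seq_len(n_masks))
  maskcover:::new_coverage_instance(sets, alpha0 = alpha0)
}

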