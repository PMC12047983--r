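# End-to-end orchestration: simulate/ingest -> masks -> scan -> strategies ->
# cluster -> optimize -> report, with TSV outputs and a config-hash manifest.

config_hash <- function(config) digest::digest(unclass(config), algo = "md5")

write_stage <- function(tbl, dir, name, hash) {
  path <- file.path(dir, paste0(name, ".tsv"))
  readr::write_tsv(tbl, path)
  path
}

#' Run the full masking-strategy pipeline on a cohort
#'
#' Stages, in order: evaluate the mask catalog (after normalization and
#' deduplication), attach composite scores and append the combined
#' pLoF/composite-damaging masks, scan every mask x gene x bin x trait with
#' burden tests, calibrate (drop empty and inflated masks), count per-mask
#' significant associations for each frequency class, cluster masks and pick
#' representative strategies, and run the greedy covering optimizer. All
#' tabular outputs are written as TSVs into `dir`, together with a
#' `manifest.json` recording the configuration and its hash; a rerun with an
#' identical configuration and inputs is byte-identical.
#'
#' @param cohort A [simulate_cohort()]-shaped list (`variants`, `genotypes`,
#'   `phenotypes`, `covariates`, `catalog`).
#' @param dir Output directory (created if needed).
#' @param config A [pipeline_config()].
#' @param composite Add composite scores and combo masks (default `TRUE`;
#'   needs `*_rankscore` columns).
#' @param freq_classes Frequency classes to optimize (default all three).
#' @return A `mask_pipeline` list: `scan` (the `mask_scan`), `catalog` (the
#'   deduplicated, extended catalog), `clustering`, `mask_counts`,
#'   `representatives`, `optimal` (per frequency class), `dir`, `config`.
#' @export
run_pipeline <- function(cohort, dir, config = pipeline_config(),
                         composite = TRUE,
                         freq_classes = c("total", "low-frequency", "rare")) {
  stopifnot(all(c("variants", "genotypes", "phenotypes", "catalog") %in% names(cohort)))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  variants <- cohort$variants

  catalog <- dedupe_catalog(cohort$catalog) |>
    dplyr::select("mask_id", "expression", "source")
  if (composite) {
    cs <- add_composite_scores(variants,
      threshold = config$composite_threshold, seed = config$seed
    )
    variants <- cs$variants
    catalog <- dplyr::bind_rows(catalog, build_composite_masks()) |>
      dplyr::arrange(.data$mask_id)
  }
  catalog <- categorize_catalog(catalog)
  write_stage(catalog, dir, "catalog", hash)

  membership <- evaluate_catalog(catalog, variants)
  scan <- run_mask_scan(
    catalog, variants, cohort$genotypes, cohort$phenotypes,
    covariates = cohort$covariates, config = config, membership = membership
  )
  write_stage(scan$results, dir, "burden_results", hash)
  write_stage(scan$calibration$mask_summary, dir, "calibration", hash)

  kept <- setdiff(catalog$mask_id, scan$dropped_masks)
  membership_kept <- membership[kept, , drop = FALSE]
  counts <- lapply(stats::setNames(freq_classes, freq_classes), function(fc) {
    mask_significant_counts(scan$results, fc, config$alpha0, config$aaf_bins,
      masks = kept
    )
  })
  counts_tbl <- purrr::imap(counts, ~ dplyr::mutate(.x, freq_class = .y)) |>
    purrr::list_rbind()
  write_stage(counts_tbl, dir, "mask_counts", hash)

  clustering <- NULL
  representatives <- list()
  if (nrow(membership_kept) >= 2) {
    clustering <- cluster_and_subcluster(membership_kept, variants$maf, config)
    write_stage(clustering$assignments, dir, "clusters", hash)
    representatives <- lapply(counts, function(ct) {
      list(
        cluster = select_representatives(clustering, ct, "cluster",
          alpha0 = config$alpha0
        ),
        subcluster = select_representatives(clustering, ct, "subcluster",
          alpha0 = config$alpha0
        )
      )
    })
  }

  optimal <- lapply(stats::setNames(freq_classes, freq_classes), function(fc) {
    inst <- coverage_instance(scan$results, fc, config$alpha0,
      masks = kept, aaf_bins = config$aaf_bins
    )
    optimal_strategy_search(inst)
  })
  opt_tbl <- purrr::imap(optimal, function(o, fc) {
    tibble::tibble(
      freq_class = fc, m = o$m, count = o$best$count,
      mask_ids = paste(o$best$strategy$mask_ids, collapse = ",")
    )
  }) |> purrr::list_rbind()
  write_stage(opt_tbl, dir, "optimal_strategies", hash)
  trace_tbl <- purrr::imap(optimal, ~ dplyr::mutate(.x$best$trace, freq_class = .y)) |>
    purrr::list_rbind()
  write_stage(trace_tbl, dir, "greedy_traces", hash)

  manifest <- list(
    config = unclass(config), config_hash = hash,
    n_masks = nrow(catalog), n_masks_kept = length(kept),
    n_variants = nrow(variants),
    n_traits = length(setdiff(names(cohort$phenotypes), "sample_id")),
    dropped_masks = scan$dropped_masks
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )

  structure(
    list(
      scan = scan, catalog = catalog, clustering = clustering,
      mask_counts = counts, representatives = representatives,
      optimal = optimal, dir = dir, config = config
    ),
    class = "mask_pipeline"
  )
}

#' @export
print.mask_pipeline <- function(x, ...) {
  cat("<mask_pipeline> outputs in ", x$dir, "\n", sep = "")
  for (fc in names(x$optimal)) {
    o <- x$optimal[[fc]]
    cat(
      "  ", fc, ": optimal m = ", o$m, ", ", o$best$count,
      " significant associations\n",
      sep = ""
    )
  }
  invisible(x)
}

# -- group-file export (REGENIE dialect) --------------------------------------

#' Export burden-engine group files
#'
#' Writes the three tab-separated, header-less files external burden engines
#' consume: a set-list file (gene, chrom, first position, comma-joined
#' variant ids), an annotation file (variant, gene, label; one row per mask
#' membership, label = mask id), and a mask-definition file (mask id,
#' comma-joined labels). [read_group_files()] parses them back into a
#' membership matrix.
#'
#' @param variants Variant annotation tibble.
#' @param membership Masks x variants logical matrix from
#'   [evaluate_catalog()].
#' @param dir Output directory.
#' @return Invisibly, the three file paths.
#' @export
export_group_files <- function(variants, membership, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  setlist <- variants |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      chrom = dplyr::first(.data$chrom), pos = min(.data$pos),
      ids = paste(.data$variant_id, collapse = ","), .groups = "drop"
    ) |>
    dplyr::arrange(.data$gene)
  p1 <- file.path(dir, "setlist.tsv")
  readr::write_tsv(setlist, p1, col_names = FALSE)

  idx <- which(membership, arr.ind = TRUE)
  ann <- tibble::tibble(
    variant_id = colnames(membership)[idx[, "col"]],
    gene = variants$gene[match(colnames(membership)[idx[, "col"]], variants$variant_id)],
    label = rownames(membership)[idx[, "row"]]
  ) |>
    dplyr::arrange(.data$variant_id, .data$label)
  p2 <- file.path(dir, "annotations.tsv")
  readr::write_tsv(ann, p2, col_names = FALSE)

  maskdef <- tibble::tibble(
    mask_id = rownames(membership), labels = rownames(membership)
  )
  p3 <- file.path(dir, "masks.tsv")
  readr::write_tsv(maskdef, p3, col_names = FALSE)
  invisible(c(setlist = p1, annotations = p2, masks = p3))
}

#' @rdname export_group_files
#' @return `read_group_files()` returns the reconstructed logical membership
#'   matrix (masks x variants).
#' @export
read_group_files <- function(dir) {
  setlist <- readr::read_tsv(file.path(dir, "setlist.tsv"),
    col_names = c("gene", "chrom", "pos", "ids"), col_types = "ccic"
  )
  ann <- readr::read_tsv(file.path(dir, "annotations.tsv"),
    col_names = c("variant_id", "gene", "label"), col_types = "ccc"
  )
  maskdef <- readr::read_tsv(file.path(dir, "masks.tsv"),
    col_names = c("mask_id", "labels"), col_types = "cc"
  )
  variant_ids <- unlist(strsplit(setlist$ids, ","), use.names = FALSE)
  mem <- matrix(FALSE,
    nrow = nrow(maskdef), ncol = length(variant_ids),
    dimnames = list(maskdef$mask_id, variant_ids)
  )
  for (i in seq_len(nrow(maskdef))) {
    labels <- strsplit(maskdef$labels[i], ",")[[1]]
    vids <- ann$variant_id[ann$label %in% labels]
    mem[i, vids] <- TRUE
  }
  mem
}
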