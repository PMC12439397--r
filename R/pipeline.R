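#' Run the full cell-type-resolved comparison pipeline
#'
#' Chains the stages: QC filtering, small-sample exclusion, log
#' normalization, optional variable-gene selection, optional per-patient
#' centering (integration stand-in), imputation masking against the raw
#' counts, pseudobulk aggregation, per-cell-type moderated-t differential
#' expression, pairwise correlation homogeneity analysis with the mixed
#' model, union-signature clustering with two-group separation, and
#' missing-tolerant PCA of the aggregated data.
#'
#' @param dataset A `cell_dataset` (e.g. from [simulate_dataset()] or
#'   [read_cell_matrix()]).
#' @param config A [run_config()].
#' @param focal_cell_type Cell type used for sample exclusion and the
#'   focal-type PCA (default from `config$qc`).
#' @param integrated Optional externally integrated expression matrix used
#'   in place of the built-in centering stand-in.
#' @return A list with elements `dataset` (post-QC), `excluded`, `masked`,
#'   `pseudobulk`, `de`, `correlations`, `correlation_tests`, `lmm`,
#'   `signature`, `dend`, `separation`, `pca_focal`, `pca_bulk`, and
#'   `config`.
#' @export
run_pipeline <- function(dataset, config = run_config(),
                         focal_cell_type = config$qc$focal_cell_type,
                         integrated = NULL) {
  stopifnot(inherits(dataset, "cell_dataset"))
  ds <- qc_filter_cells(dataset, config$qc)
  excl <- exclude_small_samples(ds, config$qc)
  ds <- excl$dataset
  ds <- lognormalize(ds)
  if (!is.null(config$n_hvg) && config$n_hvg < nrow(ds$counts)) {
    hvg <- select_variable_genes(ds$normalized, config$n_hvg)
    ds$counts <- ds$counts[hvg, , drop = FALSE]
    ds$normalized <- ds$normalized[hvg, , drop = FALSE]
    ds$features <- ds$features[match(hvg, ds$features$gene_id), , drop = FALSE]
  }
  expr <- if (!is.null(integrated)) {
    integrated[rownames(ds$counts), colnames(ds$counts), drop = FALSE]
  } else if (config$center_batches) {
    center_by_batch(ds$normalized, ds$cells)
  } else {
    ds$normalized
  }
  masked <- mask_imputed(expr, ds$counts,
                         provenance = if (config$center_batches ||
                                          !is.null(integrated))
                           "integrated-masked" else "normalized")
  pb <- pseudobulk(masked, ds$cells, min_cells = config$min_cells)
  design <- design_spec(pb$groups,
                        min_patients = config$min_patients_per_group,
                        fdr_cutoffs = config$fdr_cutoffs)
  de <- run_de(pb, design)
  recs <- purrr::map_dfr(names(pb$values),
                         function(ct) pseudobulk_pair_correlations(pb, ct))
  cor_tests <- compare_correlation_groups(recs)
  lmm <- fit_lmm_contrasts(recs)
  tested_cts <- unique(de$table$cell_type)
  sig <- signature_matrix(pb, de, tested_cts, k = config$n_top_signature)
  dend <- hcluster(sig)
  sep <- two_group_separation(dend, pb$groups)
  pca_focal <- NULL
  if (focal_cell_type %in% names(pb$values)) {
    vf <- t(pb$values[[focal_cell_type]])
    vf <- vf[, colSums(!is.na(vf)) > 0, drop = FALSE]
    pca_focal <- nipals_pca(vf, n_components = min(10, nrow(vf) - 1))
  }
  bulk <- simulated_bulk(pb)
  pca_bulk <- nipals_pca(t(bulk$bulk), n_components = min(10, ncol(bulk$bulk) - 1))
  list(dataset = ds, excluded = excl$excluded, masked = masked,
       pseudobulk = pb, de = de,
       correlations = recs, correlation_tests = cor_tests, lmm = lmm,
       signature = sig, dend = dend, separation = sep,
       pca_focal = pca_focal, pca_bulk = pca_bulk,
       config = config)
}
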