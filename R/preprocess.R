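#' Quality-control parameters for cell filtering
#'
#' Defaults follow common single-nucleus practice: keep cells with
#' 500--10,000 detected genes, 1,000--60,000 total counts, and < 10%
#' mitochondrial reads; gene/count bounds are inclusive, the mitochondrial
#' criterion is strict.
#'
#' @param min_genes,max_genes Inclusive bounds on detected genes per cell.
#' @param min_counts,max_counts Inclusive bounds on total counts per cell.
#' @param max_mito_frac Strict upper bound on the mitochondrial count
#'   fraction.
#' @param min_cells_focal_type Minimum number of focal-type cells a patient
#'   must contribute to be retained by [exclude_small_samples()].
#' @param focal_cell_type Label of the focal cell type (typically the tumor
#'   type).
#' @return A `qc_params` list.
#' @export
qc_params <- function(min_genes = 500, max_genes = 10000,
                      min_counts = 1000, max_counts = 60000,
                      max_mito_frac = 0.10,
                      min_cells_focal_type = 100,
                      focal_cell_type = "tumor") {
  stopifnot(min_genes <= max_genes, min_counts <= max_counts,
            max_mito_frac >= 0, max_mito_frac <= 1,
            min_cells_focal_type >= 0)
  structure(list(min_genes = min_genes, max_genes = max_genes,
                 min_counts = min_counts, max_counts = max_counts,
                 max_mito_frac = max_mito_frac,
                 min_cells_focal_type = min_cells_focal_type,
                 focal_cell_type = focal_cell_type),
            class = "qc_params")
}

#' Filter cells on detected genes, total counts and mitochondrial fraction
#'
#' Keeps cells whose detected-gene count and total counts fall inside the
#' inclusive `[min, max]` ranges and whose mitochondrial count fraction is
#' strictly below `max_mito_frac`.  Cell order is preserved and QC
#' statistics (`n_genes`, `n_counts`, `mito_frac`) are appended to the cell
#' annotation.  The operation is idempotent.
#'
#' @param dataset A `cell_dataset` (raw counts).
#' @param params A [qc_params()] object.
#' @return The filtered `cell_dataset`.
#' @export
qc_filter_cells <- function(dataset, params = qc_params()) {
  stopifnot(inherits(dataset, "cell_dataset"))
  counts <- dataset$counts
  if (params$max_mito_frac < 1 && !any(dataset$features$mito)) {
    stop("no mitochondrial genes flagged in `features$mito`; ",
         "cannot evaluate the mitochondrial QC criterion")
  }
  n_genes <- Matrix::colSums(counts > 0)
  n_counts <- Matrix::colSums(counts)
  mito_counts <- Matrix::colSums(counts[dataset$features$mito, , drop = FALSE])
  mito_frac <- ifelse(n_counts > 0, mito_counts / n_counts, 0)
  keep <- n_genes >= params$min_genes & n_genes <= params$max_genes &
    n_counts >= params$min_counts & n_counts <= params$max_counts &
    mito_frac < params$max_mito_frac
  out <- dataset
  out$counts <- counts[, keep, drop = FALSE]
  out$cells <- dplyr::mutate(dataset$cells[keep, , drop = FALSE],
                             n_genes = unname(n_genes[keep]),
                             n_counts = unname(n_counts[keep]),
                             mito_frac = unname(mito_frac[keep]))
  out
}

#' Exclude patients with too few cells of the focal type
#'
#' Removes all cells of patients whose number of focal-type cells (after QC)
#' is below `min_cells_focal_type`; the boundary count itself is kept.
#'
#' @param dataset A `cell_dataset`.
#' @param params A [qc_params()] object naming the focal cell type and the
#'   threshold.
#' @return List with `dataset` (filtered) and `excluded` (tibble: patient,
#'   n_focal_cells).
#' @export
exclude_small_samples <- function(dataset, params = qc_params()) {
  stopifnot(inherits(dataset, "cell_dataset"))
  cells <- dataset$cells
  if (!params$focal_cell_type %in% cells$cell_type &&
      params$min_cells_focal_type > 0) {
    stop("focal cell type '", params$focal_cell_type,
         "' absent from the annotation")
  }
  focal_n <- table(factor(cells$patient[cells$cell_type == params$focal_cell_type],
                          levels = unique(cells$patient)))
  excluded <- names(focal_n)[focal_n < params$min_cells_focal_type]
  keep <- !cells$patient %in% excluded
  if (!any(keep)) warning("all patients excluded by the focal-cell threshold")
  out <- dataset
  out$counts <- dataset$counts[, keep, drop = FALSE]
  out$cells <- cells[keep, , drop = FALSE]
  list(dataset = out,
       excluded = tibble::tibble(patient = excluded,
                                 n_focal_cells = as.integer(focal_n[excluded])))
}

#' Log-normalize counts
#'
#' The standard "LogNormalize" transform: `value(g, c) = ln(1 + count(g, c)
#' * scale / total(c))`.  Zeros map to zeros, so the sparse structure is
#' preserved.
#'
#' @param x A `cell_dataset` or a sparse/dense count matrix (genes x cells).
#' @param scale Scale factor (default 1e4).
#' @return If `x` is a `cell_dataset`, the same object with a `normalized`
#'   sparse matrix added; otherwise the normalized matrix.
#' @export
lognormalize <- function(x, scale = 1e4) {
  if (inherits(x, "cell_dataset")) {
    x$normalized <- lognormalize(x$counts, scale)
    return(x)
  }
  m <- methods::as(Matrix::Matrix(x, sparse = TRUE), "CsparseMatrix")
  totals <- Matrix::colSums(m)
  if (any(totals == 0)) {
    bad <- colnames(m)[totals == 0]
    if (is.null(bad)) bad <- which(totals == 0)
    stop("cell(s) with zero total counts: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  j <- rep(seq_len(ncol(m)), diff(m@p))
  m@x <- log1p(m@x * scale / totals[j])
  m
}

#' Select highly variable genes by binned standardized dispersion
#'
#' A deterministic surrogate for integration-feature selection: per gene,
#' the dispersion `var/mean` of normalized values is z-scored within 20
#' equal-occupancy bins of the gene mean, and the top `n_hvg` genes by this
#' standardized dispersion are returned.  Ties break by gene id.
#'
#' @param m Normalized genes x cells matrix (sparse or dense) with rownames.
#' @param n_hvg Number of genes to keep.
#' @param n_bins Number of equal-occupancy mean bins.
#' @return Character vector of gene ids, ranked.
#' @export
select_variable_genes <- function(m, n_hvg, n_bins = 20) {
  if (inherits(m, "cell_dataset")) {
    m <- if (!is.null(m$normalized)) m$normalized else m$counts
  }
  ids <- rownames(m)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(m)))
  if (n_hvg >= nrow(m)) {
    if (n_hvg > nrow(m)) {
      warning("`n_hvg` exceeds the number of genes; returning all genes")
    }
    disp <- hvg_standardized_dispersion(m, n_bins)
    return(ids[order(-disp, ids)])
  }
  disp <- hvg_standardized_dispersion(m, n_bins)
  ids[order(-disp, ids)][seq_len(n_hvg)]
}

hvg_standardized_dispersion <- function(m, n_bins = 20) {
  mu <- Matrix::rowMeans(m)
  ex2 <- Matrix::rowMeans(m^2)
  n <- ncol(m)
  v <- (ex2 - mu^2) * n / max(n - 1, 1)
  disp <- ifelse(mu > 0, v / mu, 0)
  # shrink the bin count so each bin holds at least 5 genes (z-scoring
  # degenerates in near-singleton bins)
  n_bins_eff <- max(1, min(n_bins, floor(length(mu) / 5)))
  bins <- ggplot2::cut_number(rank(mu, ties.method = "first"), n = n_bins_eff)
  z <- rep(0, length(disp))
  for (b in levels(bins)) {
    idx <- bins == b
    s <- stats::sd(disp[idx])
    z[idx] <- if (is.na(s) || s == 0) 0 else (disp[idx] - mean(disp[idx])) / s
  }
  z
}

#' Center expression per gene within each patient (integration stand-in)
#'
#' Subtracts, per gene and patient, the mean over that patient's nonzero
#' entries from those entries; zeros pass through untouched.  This is a
#' deliberately simple batch-alignment stand-in: a pipeline run on matrices
#' integrated by an external method can supply that matrix instead.
#'
#' @param m Normalized sparse genes x cells matrix (or `cell_dataset` with a
#'   `normalized` slot).
#' @param ann Cell annotation tibble with `barcode` and `patient` (taken
#'   from the dataset when `m` is a `cell_dataset`).
#' @return A `dgCMatrix` with the same stored-entry pattern; stored values
#'   are the centered ones (explicit zeros possible).
#' @export
center_by_batch <- function(m, ann = NULL) {
  if (inherits(m, "cell_dataset")) {
    ann <- m$cells
    m <- if (!is.null(m$normalized)) m$normalized else
      stop("run lognormalize() first")
  }
  stopifnot(inherits(m, "sparseMatrix"), !is.null(ann))
  m <- methods::as(m, "CsparseMatrix")
  pat <- factor(ann$patient)
  ind <- Matrix::sparseMatrix(i = seq_len(ncol(m)), j = as.integer(pat),
                              x = 1, dims = c(ncol(m), nlevels(pat)))
  sums <- as.matrix(m %*% ind)
  nnz <- as.matrix((m != 0) %*% ind)
  means <- ifelse(nnz > 0, sums / nnz, 0)
  j <- rep(seq_len(ncol(m)), diff(m@p))
  m@x <- m@x - means[cbind(m@i + 1L, as.integer(pat)[j])]
  m
}

#' Mask entries that were zero in the raw data
#'
#' Declares every position with a zero raw count missing, so that values an
#' integration method imputed at unmeasured positions cannot influence
#' downstream statistics.  Positions with positive raw counts keep the
#' expression value unchanged; the missing fraction of the result equals
#' the raw zero fraction exactly.
#'
#' @param expr Expression matrix (normalized and/or batch-centered), same
#'   genes x cells index sets as `raw`; sparse or dense.
#' @param raw Raw count matrix (sparse), or a `cell_dataset`.
#' @param provenance Provenance flag stored on the result.
#' @return A `masked_matrix`.
#' @export
mask_imputed <- function(expr, raw, provenance = "integrated-masked") {
  if (inherits(raw, "cell_dataset")) raw <- raw$counts
  if (!identical(dim(expr), dim(raw))) {
    stop("`expr` and `raw` dimensions differ: ",
         paste(dim(expr), collapse = "x"), " vs ",
         paste(dim(raw), collapse = "x"))
  }
  if (!is.null(rownames(expr)) && !is.null(rownames(raw)) &&
      !identical(rownames(expr), rownames(raw))) {
    stop("gene index sets of `expr` and `raw` differ")
  }
  if (!is.null(colnames(expr)) && !is.null(colnames(raw)) &&
      !identical(colnames(expr), colnames(raw))) {
    stop("cell index sets of `expr` and `raw` differ")
  }
  raw <- Matrix::drop0(methods::as(Matrix::Matrix(raw, sparse = TRUE),
                                   "CsparseMatrix"))
  if (inherits(expr, "sparseMatrix")) {
    expr <- methods::as(expr, "CsparseMatrix")
    if (identical(expr@i, raw@i) && identical(expr@p, raw@p)) {
      # common fast path: expr carries values exactly at raw-positive
      # positions (lognormalize / center_by_batch preserve the pattern)
      vals <- expr@x
      out <- methods::new("dgCMatrix", i = raw@i, p = raw@p, x = vals,
                          Dim = raw@Dim, Dimnames = raw@Dimnames)
      return(new_masked_matrix(out, provenance))
    }
    expr <- as.matrix(expr)
  }
  j <- rep(seq_len(ncol(raw)), diff(raw@p))
  vals <- expr[cbind(raw@i + 1L, j)]
  out <- methods::new("dgCMatrix", i = raw@i, p = raw@p, x = as.numeric(vals),
                      Dim = raw@Dim, Dimnames = raw@Dimnames)
  new_masked_matrix(out, provenance)
}
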