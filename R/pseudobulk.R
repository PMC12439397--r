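#' Aggregate masked single-cell expression into patient x cell-type profiles
#'
#' For each cell type, computes the mean over *observed* (non-missing)
#' entries of each gene across the cells of every patient.  An aggregated
#' entry is kept only when at least `min_cells` observed cells support it;
#' otherwise it is missing.  The number of supporting cells is recorded for
#' every entry.
#'
#' @param m A `masked_matrix` (from [mask_imputed()]) or a sparse normalized
#'   matrix (zeros then count as missing).
#' @param ann Cell annotation tibble with `barcode`, `patient`, `group`,
#'   `cell_type` in the column order of `m`.
#' @param min_cells Minimum number of observed supporting cells per entry.
#' @return A `pseudobulk` object: per cell type a genes x patients matrix
#'   with `NA` for missing entries, a parallel supporting-cell-count matrix,
#'   and the patient-to-group map.
#' @export
pseudobulk <- function(m, ann, min_cells = 10) {
  if (inherits(m, "sparseMatrix")) {
    m <- new_masked_matrix(Matrix::drop0(methods::as(m, "CsparseMatrix")),
                           provenance = "normalized")
  }
  stopifnot(inherits(m, "masked_matrix"), nrow(ann) == ncol(m$values))
  v <- m$values
  obs <- mm_observed(m)
  patients <- unique(ann$patient)
  groups <- stats::setNames(ann$group[match(patients, ann$patient)], patients)
  cts <- unique(ann$cell_type)
  values <- counts <- list()
  for (ct in cts) {
    idx <- which(ann$cell_type == ct)
    if (!length(idx)) next
    pat <- factor(ann$patient[idx], levels = patients)
    ind <- Matrix::sparseMatrix(i = seq_along(idx), j = as.integer(pat), x = 1,
                                dims = c(length(idx), length(patients)))
    sums <- as.matrix(v[, idx, drop = FALSE] %*% ind)
    nobs <- as.matrix(obs[, idx, drop = FALSE] %*% ind)
    val <- sums / nobs
    val[nobs < min_cells] <- NA_real_
    dimnames(val) <- dimnames(nobs) <- list(rownames(v), patients)
    values[[ct]] <- val
    counts[[ct]] <- nobs
  }
  empty <- setdiff(cts, names(values))
  if (length(empty)) {
    warning("cell type(s) with no cells dropped: ",
            paste(empty, collapse = ", "))
  }
  structure(list(values = values, n_cells = counts, groups = groups,
                 min_cells = min_cells),
            class = "pseudobulk")
}

#' @export
print.pseudobulk <- function(x, ...) {
  cat("<pseudobulk> ", length(x$values), " cell types x ",
      length(x$groups), " patients x ", nrow(x$values[[1]]), " genes; ",
      "min_cells = ", x$min_cells, "\n", sep = "")
  for (ct in names(x$values)) {
    cat("  ", ct, ": ",
        format(100 * mean(!is.na(x$values[[ct]])), digits = 3),
        "% entries present\n", sep = "")
  }
  invisible(x)
}

#' Tidy a pseudobulk tensor into a long tibble
#'
#' @param x A `pseudobulk` object.
#' @param ... Unused.
#' @return Tibble with cell_type, gene, patient, group, value (NA when
#'   missing), n_cells.
#' @export
tidy.pseudobulk <- function(x, ...) {
  purrr::map_dfr(names(x$values), function(ct) {
    v <- x$values[[ct]]
    tibble::tibble(
      cell_type = ct,
      gene = rep(rownames(v), ncol(v)),
      patient = rep(colnames(v), each = nrow(v)),
      group = rep(unname(x$groups[colnames(v)]), each = nrow(v)),
      value = as.vector(v),
      n_cells = as.vector(x$n_cells[[ct]])
    )
  })
}

#' Simulated bulk expression and per-gene group log2 fold changes
#'
#' Emulates bulk tissue profiles by summing each patient's per-cell-type
#' mean expression over cell types (missing entries contribute 0, as a
#' patient lacking a cell type contributes no signal to its bulk), then
#' compares the group means per gene on the log2 scale with a small
#' pseudocount `eps` guarding against division by zero.
#'
#' @param pb A `pseudobulk` object.
#' @param eps Pseudocount added to both group means.
#' @return List with `bulk` (genes x patients matrix) and `log2fc` (tibble:
#'   gene, mean_A, mean_B, log2fc; group A relative to group B).
#' @export
simulated_bulk <- function(pb, eps = 1e-9) {
  stopifnot(inherits(pb, "pseudobulk"), length(pb$values) > 0)
  bulk <- Reduce(`+`, lapply(pb$values, function(v) {
    v[is.na(v)] <- 0
    v
  }))
  grp <- pb$groups[colnames(bulk)]
  gl <- sort(unique(grp))
  mean_A <- rowMeans(bulk[, grp == gl[1], drop = FALSE])
  mean_B <- rowMeans(bulk[, grp == gl[2], drop = FALSE])
  list(bulk = bulk,
       log2fc = tibble::tibble(gene = rownames(bulk),
                               mean_A = unname(mean_A),
                               mean_B = unname(mean_B),
                               log2fc = unname(log2((mean_A + eps) /
                                                      (mean_B + eps)))))
}

#' Dotplot summary of selected genes across cell types and groups
#'
#' For every requested (gene, cell type, group) combination: the mean of the
#' aggregated expression over the group's patients with an observed entry,
#' and the fraction of the group's patients expressing the gene (observed
#' entry present).  Genes absent from the tensor are reported in a
#' `skipped` attribute instead of failing.
#'
#' @param pb A `pseudobulk` object.
#' @param genes Character vector of genes.
#' @param cell_types Cell types to include (default: all in the tensor).
#' @return Tibble with gene, cell_type, group, mean_expr (NA when no patient
#'   expresses the gene), frac_patients; attribute `skipped` lists unknown
#'   genes.
#' @export
dotplot_summary <- function(pb, genes, cell_types = names(pb$values)) {
  stopifnot(inherits(pb, "pseudobulk"))
  cell_types <- intersect(cell_types, names(pb$values))
  known <- rownames(pb$values[[1]])
  skipped <- setdiff(genes, known)
  genes <- intersect(genes, known)
  grp <- pb$groups
  out <- purrr::map_dfr(cell_types, function(ct) {
    v <- pb$values[[ct]][genes, , drop = FALSE]
    purrr::map_dfr(sort(unique(grp)), function(g) {
      cols <- names(grp)[grp == g]
      sub <- v[, cols, drop = FALSE]
      n_expr <- rowSums(!is.na(sub))
      tibble::tibble(
        gene = genes, cell_type = ct, group = g,
        mean_expr = unname(ifelse(n_expr > 0, rowMeans(sub, na.rm = TRUE),
                                  NA_real_)),
        frac_patients = unname(n_expr) / length(cols)
      )
    })
  })
  attr(out, "skipped") <- skipped
  out
}
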