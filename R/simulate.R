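#' Simulate a hierarchical two-group single-nucleus dataset
#'
#' Draws a sparse gene-by-cell count matrix with known ground truth.  Per
#' cell, counts are negative binomial with log-mean
#' `baseline(gene, cell type) + patient intercept + gene-wise patient jitter
#' + log2_effect * log(2) * [group == A] + log(library factor)`, then thinned
#' entry-wise by a Bernoulli dropout step calibrated in a single step so the
#' realized global zero fraction approaches `dropout_target`.
#'
#' @param config A [sim_config()] object.
#' @return A `cell_dataset`: list with `counts` (sparse dgCMatrix, genes x
#'   cells), `features` (tibble: gene_id, symbol, mito), `cells` (tibble:
#'   barcode, patient, group, cell_type), and `truth` (planted effects,
#'   null cell types, homogeneity SDs).  Deterministic given `config$seed`.
#' @export
simulate_dataset <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n_genes <- config$n_genes
  gene_ids <- sim_gene_ids(n_genes)
  ct_names <- names(config$cell_types)
  patients <- c(sprintf("A%02d", seq_len(config$n_patients_A)),
                sprintf("B%02d", seq_len(config$n_patients_B)))
  groups <- stats::setNames(rep(c("A", "B"),
                                c(config$n_patients_A, config$n_patients_B)),
                            patients)
  sd_pat <- ifelse(groups == "A",
                   config$patient_effect_sd_A, config$patient_effect_sd_B)

  theta <- rep_len(config$nb_dispersion, n_genes)
  base <- config$baseline_log_mean
  if (is.null(base)) {
    gene_base <- stats::rnorm(n_genes, config$baseline_mu, config$baseline_sd)
    base <- gene_base +
      matrix(stats::rnorm(n_genes * length(ct_names), 0, config$celltype_sd),
             n_genes, length(ct_names))
  }
  colnames(base) <- ct_names

  # patient-level effects: one shared intercept per (patient, cell type),
  # plus per-gene jitter at the same (patient, cell type) granularity --
  # the jitter is what decorrelates patient profiles within a cell type
  intercept <- matrix(stats::rnorm(length(patients) * length(ct_names)),
                      length(patients), length(ct_names)) * sd_pat
  dimnames(intercept) <- list(patients, ct_names)
  jitter_sd <- config$patient_jitter_frac * sd_pat
  # gene-level heterogeneity of between-patient variance (lognormal, mean 1)
  sdl <- config$patient_jitter_gene_sdlog %||% 0
  tau <- if (sdl > 0) {
    exp(stats::rnorm(n_genes, -sdl^2 / 2, sdl))
  } else {
    rep(1, n_genes)
  }
  jitter <- lapply(ct_names, function(ct) {
    matrix(stats::rnorm(n_genes * length(patients)), n_genes,
           length(patients), dimnames = list(gene_ids, patients)) *
      rep(jitter_sd, each = n_genes) * tau
  })
  names(jitter) <- ct_names

  mito <- rep(FALSE, n_genes)
  n_mito <- round(config$mito_gene_fraction * n_genes)
  if (n_mito > 0) mito[sample.int(n_genes, n_mito)] <- TRUE

  eff <- config$group_effect_table
  delta <- matrix(0, n_genes, length(ct_names), dimnames = list(gene_ids, ct_names))
  if (nrow(eff)) {
    delta[cbind(match(eff$gene, gene_ids), match(eff$cell_type, ct_names))] <-
      eff$log2_effect * log(2)
  }

  blocks <- vector("list", length(ct_names))
  cell_meta <- vector("list", length(ct_names))
  for (k in seq_along(ct_names)) {
    ct <- ct_names[k]
    n_cells_pat <- stats::rpois(length(patients), config$cell_types[[k]])
    pat_of_cell <- rep(seq_along(patients), n_cells_pat)
    n_cells <- length(pat_of_cell)
    if (n_cells == 0L) {
      blocks[[k]] <- matrix(0L, n_genes, 0L)
      cell_meta[[k]] <- tibble::tibble(patient = character(),
                                       group = character(),
                                       cell_type = character())
      next
    }
    lib <- exp(stats::rnorm(n_cells, config$library_size_log_mean,
                            config$library_size_log_sd))
    logmu <- base[, k] + jitter[[ct]][, pat_of_cell, drop = FALSE]
    logmu <- logmu + rep(intercept[pat_of_cell, k] + log(lib), each = n_genes)
    is_A <- groups[pat_of_cell] == "A"
    if (any(delta[, k] != 0) && any(is_A)) {
      logmu[, is_A] <- logmu[, is_A] + delta[, k]
    }
    cnt <- stats::rnbinom(n_genes * n_cells,
                          size = rep(theta, n_cells), mu = exp(logmu))
    blocks[[k]] <- matrix(cnt, n_genes, n_cells)
    cell_meta[[k]] <- tibble::tibble(patient = patients[pat_of_cell],
                                     group = unname(groups[pat_of_cell]),
                                     cell_type = ct)
  }
  counts <- do.call(cbind, blocks)
  cells <- dplyr::bind_rows(cell_meta)
  cells$barcode <- sprintf("c%05d", seq_len(nrow(cells)))
  cells <- cells[, c("barcode", "patient", "group", "cell_type")]

  # entry-wise Bernoulli dropout with a gene-specific retention propensity
  # tied to baseline expression (well-expressed genes drop out less, as in
  # real single-nucleus data); a scalar alpha is calibrated by fixed-point
  # iteration so the realized global zero fraction meets dropout_target
  z0_gene <- rowMeans(counts == 0L)
  if (mean(z0_gene) < config$dropout_target) {
    retain <- stats::plogis(0.5 + (rowMeans(base) - mean(rowMeans(base))))
    target_keep <- 1 - config$dropout_target
    alpha <- target_keep / mean((1 - z0_gene) * retain)
    for (it in 1:5) {
      keep_prob <- pmin(1, alpha * retain)
      realized <- mean((1 - z0_gene) * keep_prob)
      if (abs(realized - target_keep) < 1e-6) break
      alpha <- alpha * target_keep / realized
    }
    keep_prob <- pmin(1, alpha * retain)
    pos <- which(counts > 0L)
    g_of_pos <- (pos - 1L) %% n_genes + 1L
    drop <- stats::runif(length(pos)) >= keep_prob[g_of_pos]
    counts[pos[drop]] <- 0L
  }

  counts <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
  dimnames(counts) <- list(gene_ids, cells$barcode)

  truth <- list(
    effects = eff,
    null_cell_types = setdiff(ct_names, unique(eff$cell_type)),
    homogeneity = c(sd_A = config$patient_effect_sd_A,
                    sd_B = config$patient_effect_sd_B)
  )
  structure(list(
    counts = counts,
    features = tibble::tibble(gene_id = gene_ids, symbol = gene_ids, mito = mito),
    cells = cells,
    truth = truth,
    config = config
  ), class = "cell_dataset")
}

#' @export
print.cell_dataset <- function(x, ...) {
  cat("<cell_dataset> ", nrow(x$counts), " genes x ", ncol(x$counts), " cells; ",
      length(unique(x$cells$patient)), " patients; ",
      length(unique(x$cells$cell_type)), " cell types\n", sep = "")
  cat("  zero fraction:",
      format(sparsity_summary(x$counts)$global, digits = 3), "\n")
  invisible(x)
}

#' Zero / missing fraction summaries
#'
#' For a count matrix the summary counts zeros; for a [mask_imputed()] result
#' it counts missing (masked) entries.
#'
#' @param m A `cell_dataset`, a (sparse) matrix, or a `masked_matrix`.
#' @return List with `global` (overall fraction) and `per_cell`
#'   (tibble: barcode, fraction).
#' @export
sparsity_summary <- function(m) {
  if (inherits(m, "cell_dataset")) m <- m$counts
  if (inherits(m, "masked_matrix")) {
    obs <- mm_observed(m)
    n_missing_col <- nrow(obs) - Matrix::colSums(obs)
    nm <- colnames(obs)
    n_row <- nrow(obs)
  } else {
    if (length(m) == 0L) stop("matrix is empty")
    if (inherits(m, "sparseMatrix")) {
      n_missing_col <- nrow(m) -
        Matrix::colSums(methods::as(m, "CsparseMatrix") != 0)
    } else {
      n_missing_col <- colSums(m == 0)
    }
    nm <- colnames(m)
    n_row <- nrow(m)
  }
  if (length(n_missing_col) == 0L) stop("matrix is empty")
  tib <- tibble::tibble(
    barcode = if (is.null(nm)) as.character(seq_along(n_missing_col)) else nm,
    fraction = as.numeric(n_missing_col) / n_row
  )
  list(global = sum(n_missing_col) / (as.numeric(n_row) * length(n_missing_col)),
       per_cell = tib)
}
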