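# Shared fixtures and independent oracles used across test files.

# tiny deterministic count dataset built by hand (no simulator involved)
make_tiny_dataset <- function(n_genes = 6, n_cells = 8,
                              patients = rep(c("A01", "B01"), each = 4),
                              groups = rep(c("A", "B"), each = 4),
                              cell_type = "tumor",
                              counts = NULL, mito = NULL) {
  if (is.null(counts)) {
    set.seed(42)
    counts <- matrix(rpois(n_genes * n_cells, 3), n_genes, n_cells)
  }
  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  barcodes <- sprintf("c%05d", seq_len(n_cells))
  cm <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
  dimnames(cm) <- list(gene_ids, barcodes)
  if (is.null(mito)) mito <- c(TRUE, rep(FALSE, n_genes - 1))
  structure(list(
    counts = cm,
    features = tibble::tibble(gene_id = gene_ids, symbol = gene_ids,
                              mito = mito),
    cells = tibble::tibble(barcode = barcodes, patient = patients,
                           group = groups,
                           cell_type = rep_len(cell_type, n_cells)),
    truth = NULL
  ), class = "cell_dataset")
}

# masked matrix from a dense matrix with NA = missing
masked_from_dense <- function(m) {
  obs <- which(!is.na(m), arr.ind = TRUE)
  v <- Matrix::sparseMatrix(i = obs[, 1], j = obs[, 2], x = m[obs],
                            dims = dim(m), dimnames = dimnames(m))
  celltypewise:::new_masked_matrix(methods::as(v, "CsparseMatrix"))
}

# brute-force pseudobulk oracle: nested loops over (cell type, gene, patient)
oracle_pseudobulk <- function(dense_na, ann, min_cells) {
  cts <- unique(ann$cell_type)
  patients <- unique(ann$patient)
  out <- list()
  for (ct in cts) {
    val <- matrix(NA_real_, nrow(dense_na), length(patients),
                  dimnames = list(rownames(dense_na), patients))
    for (g in seq_len(nrow(dense_na))) {
      for (p in patients) {
        cols <- which(ann$cell_type == ct & ann$patient == p)
        v <- dense_na[g, cols]
        v <- v[!is.na(v)]
        if (length(v) >= min_cells) val[g, p] <- mean(v)
      }
    }
    out[[ct]] <- val
  }
  out
}

# brute-force BH: q_i = min over j with p_(j) >= p_(i) of p_(j) * n / j, capped
oracle_bh <- function(p) {
  n <- length(p)
  ord <- order(p)
  q <- numeric(n)
  for (i in seq_len(n)) {
    rank_i <- which(ord == i)
    cand <- vapply(seq(rank_i, n), function(j) p[ord[j]] * n / j, numeric(1))
    q[i] <- min(1, min(cand))
  }
  q
}

# brute-force ordered enrichment: evaluate every prefix length
oracle_ordered_min_p <- function(ranked, set, background) {
  N <- length(unique(background))
  set <- intersect(unique(set), background)
  K <- length(set)
  if (K == 0) return(list(min_p = 1, L_star = length(ranked)))
  p_all <- vapply(seq_along(ranked), function(L) {
    k <- sum(ranked[seq_len(L)] %in% set)
    stats::phyper(k - 1, K, N - K, L, lower.tail = FALSE)
  }, numeric(1))
  list(min_p = min(p_all), L_star = which.min(p_all))
}

# per-gene two-group regression t oracle via lm()
oracle_regression_t <- function(y, group) {
  use <- !is.na(y)
  fit <- stats::lm(y[use] ~ group[use])
  unname(summary(fit)$coefficients[2, "t value"])
}

# shared cached template pipeline runs for the multi-seed recovery tests;
# each entry keeps only light summaries
.template_run_cache <- new.env(parent = emptyenv())
template_run_summaries <- function(seeds = 1:20) {
  key <- paste(seeds, collapse = ",")
  if (!is.null(.template_run_cache[[key]])) return(.template_run_cache[[key]])
  out <- lapply(seeds, function(s) {
    ds <- simulate_dataset(sim_template(seed = s))
    res <- suppressWarnings(run_pipeline(ds, template_run_config(seed = s)))
    tab <- res$de$table
    tumor <- tab[tab$cell_type == "tumor", ]
    eff_cts <- unique(ds$truth$effects$cell_type)
    sig_eff <- vapply(eff_cts, function(ct) {
      sum(tab$fdr < 0.05 & tab$cell_type == ct)
    }, numeric(1))
    corr_means <- tapply(res$correlations$r, res$correlations$pair_class, mean)
    con <- res$lmm$contrasts
    aabb <- con$estimate[con$contrast == "A-A - B-B"]
    tumor_sig <- signature_matrix(res$pseudobulk, res$de, "tumor",
                                  k = res$config$n_top_signature)
    sep_tumor <- two_group_separation(hcluster(tumor_sig),
                                      res$pseudobulk$groups)
    list(
      seed = s,
      zero_fraction = sparsity_summary(ds)$global,
      tumor_sig_frac = mean(tumor$fdr < 0.05),
      max_eff_discoveries = if (length(sig_eff)) max(sig_eff) else 0,
      mean_r_AA = unname(corr_means["A-A"]),
      mean_r_BB = unname(corr_means["B-B"]),
      lmm_contrast_AA_BB = aabb,
      union_perfect = res$separation$perfect,
      tumor_only_perfect = sep_tumor$perfect,
      elapsed = NA_real_
    )
  })
  .template_run_cache[[key]] <- out
  out
}

# planted-effect study for FDR / power assessment: 10% of genes per
# designated cell type at |log2FC| = 1, analysed without the centering
# stand-in so the DE calibration is measured on its own
fdr_power_run <- function(seed) {
  base_cfg <- sim_template(seed = seed)
  n_genes <- base_cfg$n_genes
  ids <- sprintf("g%04d", seq_len(n_genes))
  eff_types <- c("stromal", "Tcell", "myeloid")
  n_de <- round(0.10 * n_genes)
  base <- base_cfg$baseline_log_mean
  eff <- purrr::map_dfr(seq_along(eff_types), function(k) {
    ct <- eff_types[k]
    expressed <- order(base[, ct], decreasing = TRUE)[seq_len(round(0.2 * n_genes))]
    idx <- expressed[((seq_len(n_de) - 1L) * 3L + (k - 1L)) %%
                       length(expressed) + 1L]
    tibble::tibble(gene = ids[unique(idx)][seq_len(n_de)],
                   cell_type = ct,
                   log2_effect = rep_len(c(-1, 1), n_de))
  })
  cfg <- sim_config(
    n_patients_A = 6, n_patients_B = 6,
    cell_types = base_cfg$cell_types, n_genes = n_genes,
    baseline_log_mean = base,
    patient_effect_sd_A = 0.15, patient_effect_sd_B = 0.35,
    group_effect_table = eff, dropout_target = 0.88, seed = seed)
  ds <- simulate_dataset(cfg)
  rc <- template_run_config(seed = seed)
  rc$center_batches <- FALSE
  res <- suppressWarnings(run_pipeline(ds, rc))
  tab <- res$de$table[res$de$table$cell_type %in% eff_types, ]
  truth_key <- paste(eff$cell_type, eff$gene)
  tested_key <- paste(tab$cell_type, tab$gene)
  is_planted <- tested_key %in% truth_key
  disc <- tab$fdr < 0.05
  list(
    fdp = if (any(disc)) sum(disc & !is_planted) / sum(disc) else 0,
    sensitivity = if (any(is_planted)) {
      sum(disc & is_planted) / sum(is_planted)
    } else NA_real_,
    n_disc = sum(disc), n_eligible_planted = sum(is_planted)
  )
}
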