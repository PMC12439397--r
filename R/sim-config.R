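#' Configuration for the hierarchical single-nucleus count simulator
#'
#' Describes a two-group study (group A vs group B patients) with several
#' cell types per patient.  Counts are drawn per cell from a negative
#' binomial whose log-mean combines a gene-by-cell-type baseline,
#' patient-level random effects (a profile-wide intercept plus gene-specific
#' jitter), planted group effects restricted to selected cell types, and a
#' per-cell library-size factor.  An entry-wise dropout step then thins the
#' counts towards a target zero fraction, emulating the extreme sparsity of
#' single-nucleus data.
#'
#' @param n_patients_A,n_patients_B Number of patients per group (>= 1).
#' @param cell_types Named numeric vector: cell-type label -> expected number
#'   of cells per patient (Poisson mean).
#' @param n_genes Number of genes.
#' @param baseline_log_mean Optional `n_genes` x `length(cell_types)` matrix
#'   of per-gene, per-cell-type log means (natural log of the negative
#'   binomial mean per cell before library scaling).  If `NULL`, baselines
#'   are drawn at simulation time as gene effects `N(baseline_mu,
#'   baseline_sd)` plus cell-type-specific deviations `N(0, celltype_sd)`.
#' @param baseline_mu,baseline_sd,celltype_sd Parameters of the drawn
#'   baseline when `baseline_log_mean` is `NULL`.
#' @param nb_dispersion Negative binomial size parameter theta (variance
#'   `mu + mu^2/theta`); scalar or per-gene vector.
#' @param patient_effect_sd_A,patient_effect_sd_B Standard deviation of the
#'   per-patient, per-cell-type log-scale random intercept in each group.
#'   Setting `patient_effect_sd_A < patient_effect_sd_B` makes group A
#'   patients more alike than group B patients.
#' @param patient_jitter_frac Fraction of the group's patient-effect SD used
#'   for per-gene jitter at (patient, cell type) granularity.  The shared
#'   intercept alone would shift whole profiles without decorrelating them;
#'   the jitter is what drives between-patient correlation apart.
#' @param patient_jitter_gene_sdlog Log-SD of a per-gene lognormal
#'   multiplier (mean 1) on the jitter SD.  Real datasets show strongly
#'   heterogeneous between-patient variance across genes (equivalently a
#'   finite prior df in an empirical-Bayes variance fit); 0 gives the
#'   unrealistic homogeneous-variance limit.
#' @param group_effect_table Tibble/data.frame with columns `gene`,
#'   `cell_type`, `log2_effect`: planted effects, applied to group A
#'   (positive `log2_effect` means higher in group A).
#' @param dropout_target Target global zero fraction in `[0, 1]`; counts are
#'   thinned entry-wise towards it (default 0.88, the sparsity level typical
#'   of single-nucleus data).
#' @param mito_gene_fraction Fraction of genes flagged as mitochondrial.
#' @param library_size_log_mean,library_size_log_sd Log-normal parameters of
#'   the per-cell library-size factor.
#' @param seed Integer seed; a fixed seed gives byte-identical output.
#'
#' @return A `sim_config` object (a validated list).
#' @seealso [simulate_dataset()], [sim_template()]
#' @export
sim_config <- function(n_patients_A,
                       n_patients_B,
                       cell_types,
                       n_genes,
                       baseline_log_mean = NULL,
                       baseline_mu = 0.5,
                       baseline_sd = 1,
                       celltype_sd = 0.5,
                       nb_dispersion = 2,
                       patient_effect_sd_A = 0.15,
                       patient_effect_sd_B = 0.15,
                       patient_jitter_frac = 0.5,
                       patient_jitter_gene_sdlog = 0.6,
                       group_effect_table = NULL,
                       dropout_target = 0.88,
                       mito_gene_fraction = 0.03,
                       library_size_log_mean = 0,
                       library_size_log_sd = 0.3,
                       seed = 1L) {
  if (is.null(names(cell_types)) || anyDuplicated(names(cell_types))) {
    stop("`cell_types` must be a named vector with unique labels")
  }
  if (is.null(group_effect_table)) {
    group_effect_table <- tibble::tibble(gene = character(),
                                         cell_type = character(),
                                         log2_effect = numeric())
  }
  group_effect_table <- tibble::as_tibble(group_effect_table)
  cfg <- structure(list(
    n_patients_A = as.integer(n_patients_A),
    n_patients_B = as.integer(n_patients_B),
    cell_types = cell_types,
    n_genes = as.integer(n_genes),
    baseline_log_mean = baseline_log_mean,
    baseline_mu = baseline_mu,
    baseline_sd = baseline_sd,
    celltype_sd = celltype_sd,
    nb_dispersion = nb_dispersion,
    patient_effect_sd_A = patient_effect_sd_A,
    patient_effect_sd_B = patient_effect_sd_B,
    patient_jitter_frac = patient_jitter_frac,
    patient_jitter_gene_sdlog = patient_jitter_gene_sdlog,
    group_effect_table = group_effect_table,
    dropout_target = dropout_target,
    mito_gene_fraction = mito_gene_fraction,
    library_size_log_mean = library_size_log_mean,
    library_size_log_sd = library_size_log_sd,
    seed = as.integer(seed)
  ), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_patients_A < 1L || cfg$n_patients_B < 1L) {
    stop("each group needs at least one patient")
  }
  if (cfg$n_genes < 1L) stop("`n_genes` must be >= 1")
  if (cfg$dropout_target < 0 || cfg$dropout_target > 1) {
    stop("`dropout_target` must lie in [0, 1]")
  }
  if (cfg$mito_gene_fraction < 0 || cfg$mito_gene_fraction > 1) {
    stop("`mito_gene_fraction` must lie in [0, 1]")
  }
  if (any(cfg$nb_dispersion <= 0)) stop("`nb_dispersion` must be positive")
  if (cfg$patient_effect_sd_A < 0 || cfg$patient_effect_sd_B < 0) {
    stop("patient effect SDs must be nonnegative")
  }
  eff <- cfg$group_effect_table
  if (nrow(eff)) {
    if (!all(c("gene", "cell_type", "log2_effect") %in% names(eff))) {
      stop("`group_effect_table` needs columns gene, cell_type, log2_effect")
    }
    bad_ct <- setdiff(unique(eff$cell_type), names(cfg$cell_types))
    if (length(bad_ct)) {
      stop("group_effect_table references unknown cell type(s): ",
           paste(bad_ct, collapse = ", "))
    }
    ids <- sim_gene_ids(cfg$n_genes)
    bad_g <- setdiff(unique(eff$gene), ids)
    if (length(bad_g)) {
      stop("group_effect_table references unknown gene(s): ",
           paste(utils::head(bad_g, 5), collapse = ", "))
    }
  }
  if (!is.null(cfg$baseline_log_mean)) {
    if (!is.matrix(cfg$baseline_log_mean) ||
        nrow(cfg$baseline_log_mean) != cfg$n_genes ||
        ncol(cfg$baseline_log_mean) != length(cfg$cell_types)) {
      stop("`baseline_log_mean` must be an n_genes x n_cell_types matrix")
    }
  }
  invisible(cfg)
}

sim_gene_ids <- function(n) sprintf("g%04d", seq_len(n))

#' Default scaled-down two-group study template
#'
#' A desk-scale analogue of a 15-vs-10 patient two-group metastasis study:
#' 6 vs 6 patients, five cell types including a "tumor" type, about 300
#' cells per patient, 2,000 genes, and an 0.88 dropout target.  Group
#' effects are planted only in microenvironment cell types ("stromal",
#' "Tcell", "myeloid"), never in the tumor type, and predominantly lower
#' expression in group A; group A patients carry a smaller patient-effect SD
#' than group B patients (higher within-A homogeneity).
#'
#' The template draws its gene-by-cell-type baseline matrix itself (from a
#' local RNG keyed to `seed`) and places planted effects on well-expressed
#' genes (top 20% baseline in the target cell type): a planted effect on a
#' gene too sparse to clear the supporting-cell rule could never be tested,
#' in the same way that the discoveries of a real study are by construction
#' among its testable genes.
#'
#' @param n_de_per_type Number of planted genes per effect-bearing cell type.
#' @param effect_log2 Absolute planted effect size in log2 units.
#' @param frac_negative Fraction of planted effects that lower expression in
#'   group A.
#' @param seed Integer seed stored in the config.
#'
#' @return A [sim_config()] object whose truth has zero effects in the
#'   "tumor" type and `patient_effect_sd_A < patient_effect_sd_B`.
#' @export
sim_template <- function(n_de_per_type = 60, effect_log2 = 1,
                         frac_negative = 0.75, seed = 1L) {
  n_genes <- 2000L
  cell_types <- c(tumor = 120, stromal = 50, Tcell = 50,
                  myeloid = 40, endothelial = 40)
  effect_types <- c("stromal", "Tcell", "myeloid")
  ids <- sim_gene_ids(n_genes)
  base <- with_local_rng(seed, {
    gene_base <- stats::rnorm(n_genes, 0.5, 1)
    gene_base + matrix(stats::rnorm(n_genes * length(cell_types), 0, 0.5),
                       n_genes, length(cell_types))
  })
  colnames(base) <- names(cell_types)
  eff <- purrr::map_dfr(seq_along(effect_types), function(k) {
    ct <- effect_types[k]
    expressed <- order(base[, ct], decreasing = TRUE)[seq_len(round(0.2 * n_genes))]
    # deterministic stride over the expressed genes, offset per cell type
    idx <- expressed[((seq_len(n_de_per_type) - 1L) * 7L + (k - 1L) * 3L) %%
                       length(expressed) + 1L]
    n_neg <- round(frac_negative * n_de_per_type)
    sgn <- rep(c(-1, 1), c(n_neg, n_de_per_type - n_neg))
    tibble::tibble(gene = ids[idx], cell_type = ct,
                   log2_effect = sgn * effect_log2)
  })
  sim_config(
    n_patients_A = 6L, n_patients_B = 6L,
    cell_types = cell_types,
    n_genes = n_genes,
    baseline_log_mean = base,
    patient_effect_sd_A = 0.15,
    patient_effect_sd_B = 0.35,
    group_effect_table = eff,
    dropout_target = 0.88,
    seed = seed
  )
}

# evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's stream afterwards
with_local_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  force(expr)
}

#' Run configuration matched to the simulation template scale
#'
#' The QC defaults of [qc_params()] describe full-transcriptome data
#' (tens of thousands of genes, thousands of counts per cell); the
#' 2,000-gene template needs proportionally scaled bounds.  This config
#' keeps every structural rule (inclusive bounds, strict mitochondrial
#' criterion, >= 10 supporting cells, >= 4 patients per group, FDR cutoffs
#' 0.05/0.1/0.2, top-50 signatures, 100 cell pairs) and only rescales the
#' per-cell QC ranges and the focal-cell threshold.
#'
#' `center_batches` defaults to `FALSE` here: the simulator emulates data
#' that are already on a common scale (it has no technical batch
#' structure), and applying the per-patient centering stand-in to
#' batch-free data couples cell types through the patient-wide gene mean
#' -- an artifact a real integration method does not share.  Enable it
#' (or supply an externally integrated matrix) for real multi-batch data.
#'
#' @param seed Integer seed.
#' @param center_batches Apply the centering stand-in (default `FALSE`).
#' @return A [run_config()] object.
#' @export
template_run_config <- function(seed = 1L, center_batches = FALSE) {
  run_config(
    qc = qc_params(min_genes = 100, max_genes = 2000,
                   min_counts = 200, max_counts = 1e5,
                   max_mito_frac = 0.10,
                   min_cells_focal_type = 50,
                   focal_cell_type = "tumor"),
    min_cells = 10,
    min_patients_per_group = 4,
    fdr_cutoffs = c(0.05, 0.1, 0.2),
    n_top_signature = 50,
    n_cell_pairs = 100,
    n_hvg = NULL,
    center_batches = center_batches,
    seed = seed
  )
}
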