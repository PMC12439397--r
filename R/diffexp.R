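#' Specify the two-group design for differential expression
#'
#' @param group Named character vector mapping patient -> group label (two
#'   levels).  The reported log2 fold change is the first group level
#'   (alphabetically, or `levels(factor)` order) minus the second, i.e.
#'   positive values mean higher expression in group A when the labels are
#'   "A" and "B".
#' @param covariates Optional data frame of patient-level covariates
#'   (rownames = patients, or a `patient` column); entered additively into
#'   the per-gene linear model.
#' @param min_patients Minimum number of patients with an observed
#'   aggregated value required in *each* group for a gene to be tested
#'   (default 4; use 3 for small-cohort variants).
#' @param fdr_cutoffs FDR cutoffs at which significant genes are counted.
#' @return A `design_spec` list.
#' @export
design_spec <- function(group, covariates = NULL, min_patients = 4,
                        fdr_cutoffs = c(0.05, 0.1, 0.2)) {
  if (is.null(names(group))) stop("`group` must be named by patient")
  group <- stats::setNames(factor(group), names(group))
  if (nlevels(group) != 2) stop("`group` must have exactly two levels")
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if ("patient" %in% names(covariates)) {
      rownames(covariates) <- covariates$patient
      covariates$patient <- NULL
    }
    missing_cov <- setdiff(names(group), rownames(covariates))
    if (length(missing_cov)) {
      stop("covariates missing for patient(s): ",
           paste(missing_cov, collapse = ", "))
    }
    if (anyNA(covariates[names(group), , drop = FALSE])) {
      stop("covariates must be complete for all patients")
    }
  }
  stopifnot(min_patients >= 1, all(fdr_cutoffs > 0 & fdr_cutoffs < 1))
  structure(list(group = group, covariates = covariates,
                 min_patients = as.integer(min_patients),
                 fdr_cutoffs = fdr_cutoffs),
            class = "design_spec")
}

#' Genes eligible for testing in a cell type
#'
#' A gene is tested only if its aggregated value is observed in at least
#' `min_patients` patients of each group.
#'
#' @param pb A [pseudobulk()] object.
#' @param ct Cell type label.
#' @param design A [design_spec()].
#' @return Character vector of eligible gene ids.
#' @export
eligible_genes <- function(pb, ct, design) {
  v <- pb_matrix(pb, ct)
  grp <- design$group[colnames(v)]
  nA <- rowSums(!is.na(v[, !is.na(grp) & grp == levels(grp)[1], drop = FALSE]))
  nB <- rowSums(!is.na(v[, !is.na(grp) & grp == levels(grp)[2], drop = FALSE]))
  rownames(v)[nA >= design$min_patients & nB >= design$min_patients]
}

pb_matrix <- function(pb, ct) {
  stopifnot(inherits(pb, "pseudobulk"))
  if (!ct %in% names(pb$values)) {
    stop("cell type '", ct, "' not present in the pseudobulk tensor")
  }
  pb$values[[ct]]
}

#' Per-gene ordinary least squares on aggregated profiles
#'
#' Fits, per eligible gene, expression ~ group (+ covariates) over the
#' patients with an observed entry for that gene (per-gene row deletion).
#' Without covariates the closed two-group form is used.
#'
#' @inheritParams eligible_genes
#' @param genes Genes to fit (default: [eligible_genes()]).
#' @return Tibble: gene, n_A, n_B, mean_A, mean_B, coef (group contrast on
#'   the modelling scale), v_g (design-based unscaled coefficient variance),
#'   s2 (residual variance), df (residual degrees of freedom).  Genes with
#'   `df <= 0` are dropped with a message.
#' @export
fit_linear_models <- function(pb, ct, design, genes = NULL) {
  v <- pb_matrix(pb, ct)
  if (is.null(genes)) genes <- eligible_genes(pb, ct, design)
  v <- v[genes, , drop = FALSE]
  grp <- design$group[colnames(v)]
  iA <- !is.na(grp) & grp == levels(grp)[1]
  iB <- !is.na(grp) & grp == levels(grp)[2]
  if (is.null(design$covariates)) {
    res <- fit_two_group_closed(v, iA, iB)
  } else {
    res <- fit_with_covariates(v, grp, design$covariates[colnames(v), ,
                                                         drop = FALSE])
  }
  res <- res[res$df > 0, , drop = FALSE]
  dropped <- setdiff(genes, res$gene)
  if (length(dropped)) {
    message(length(dropped), " gene(s) dropped: no residual degrees of freedom")
  }
  tibble::as_tibble(res)
}

fit_two_group_closed <- function(v, iA, iB) {
  obs <- !is.na(v)
  v0 <- v; v0[!obs] <- 0
  nA <- rowSums(obs[, iA, drop = FALSE]); nB <- rowSums(obs[, iB, drop = FALSE])
  sA <- rowSums(v0[, iA, drop = FALSE]);  sB <- rowSums(v0[, iB, drop = FALSE])
  qA <- rowSums(v0[, iA, drop = FALSE]^2); qB <- rowSums(v0[, iB, drop = FALSE]^2)
  mA <- sA / nA; mB <- sB / nB
  rss <- (qA - nA * mA^2) + (qB - nB * mB^2)
  rss <- pmax(rss, 0)
  df <- nA + nB - 2
  tibble::tibble(gene = rownames(v), n_A = unname(nA), n_B = unname(nB),
                 mean_A = unname(mA), mean_B = unname(mB),
                 coef = unname(mA - mB), v_g = unname(1 / nA + 1 / nB),
                 s2 = unname(ifelse(df > 0, rss / df, NA_real_)),
                 df = unname(df))
}

fit_with_covariates <- function(v, grp, cov) {
  gA <- as.numeric(grp == levels(grp)[1])
  X <- stats::model.matrix(~ ., data = cbind(gA = gA, cov))
  ci <- which(colnames(X) == "gA")
  out <- lapply(seq_len(nrow(v)), function(g) {
    use <- which(!is.na(v[g, ]))
    y <- v[g, use]
    Xg <- X[use, , drop = FALSE]
    fit <- stats::lm.fit(Xg, y)
    rank <- fit$rank
    df <- length(use) - rank
    if (df <= 0 || is.na(fit$coefficients[ci])) {
      return(NULL)
    }
    XtXi <- chol2inv(chol(crossprod(Xg)))
    iA <- grp[use] == levels(grp)[1]
    list(gene = rownames(v)[g],
         n_A = sum(iA), n_B = sum(!iA & !is.na(grp[use])),
         mean_A = mean(y[iA]), mean_B = mean(y[!iA]),
         coef = unname(fit$coefficients[ci]), v_g = XtXi[ci, ci],
         s2 = sum(fit$residuals^2) / df, df = df)
  })
  dplyr::bind_rows(out[!vapply(out, is.null, logical(1))])
}

#' Empirical-Bayes moderation of per-gene variances
#'
#' Fits the scaled inverse chi-square prior `sigma_g^2 ~ s0^2 * d0 /
#' chisq(d0)` to the observed residual variances by matching the first two
#' moments of `log(s_g^2)` against digamma/trigamma identities of the
#' scaled-F sampling distribution, then returns the posterior (shrunken)
#' variances `s2_post = (d0 * s0^2 + df * s2) / (d0 + df)`.
#'
#' @param s2 Per-gene residual variances.
#' @param df Per-gene residual degrees of freedom.
#' @param d0_override Optional forced prior degrees of freedom: `0` disables
#'   moderation (ordinary t), `Inf` forces complete shrinkage to `s0^2`.
#' @return List with `d0`, `s0_sq`, `s2_post` (vector), and `moderated`
#'   (logical: FALSE when the fallback for < 2 usable variances fired).
#' @export
ebayes_moderate <- function(s2, df, d0_override = NULL) {
  ok <- is.finite(s2) & s2 > 0 & df > 0
  if (sum(ok) < 2) {
    warning("fewer than 2 finite positive variances; no moderation applied")
    return(list(d0 = 0, s0_sq = NA_real_, s2_post = s2, moderated = FALSE))
  }
  z <- log(s2[ok])
  e <- z - digamma(df[ok] / 2) + log(df[ok] / 2)
  emean <- mean(e)
  evar <- stats::var(e)
  slack <- evar - mean(trigamma(df[ok] / 2))
  if (is.finite(slack) && slack > 0) {
    d0 <- 2 * trigamma_inverse(slack)
    s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_sq <- exp(emean)
  }
  if (d0 > 1e6) d0 <- Inf
  if (!is.null(d0_override)) d0 <- d0_override
  s2_post <- if (is.infinite(d0)) {
    rep(s0_sq, length(s2))
  } else if (d0 == 0) {
    s2
  } else {
    (d0 * s0_sq + df * s2) / (d0 + df)
  }
  list(d0 = d0, s0_sq = s0_sq, s2_post = s2_post, moderated = TRUE)
}

# Newton solve of trigamma(x) = y; monotone decreasing, convex in 1/x
trigamma_inverse <- function(y, tol = 1e-8, max_iter = 100) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in seq_len(max_iter)) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, 2)
    x <- x + dif
    if (abs(dif / x) < tol) break
  }
  x
}

#' Benjamini-Hochberg adjusted p-values
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Step-up adjusted q-values, capped at 1.
#' @export
bh_fdr <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Cell-type-wise moderated-t differential expression
#'
#' Runs, for every cell type in the tensor: the per-group eligibility rule,
#' per-gene OLS on the aggregated log-normalized values, empirical-Bayes
#' variance moderation, the moderated t-statistic with `d0 + df` degrees of
#' freedom, and BH FDR within the cell type.  The log2 fold change is the
#' group contrast divided by `log(2)` (models are fit on natural-log
#' values); positive values mean higher in the first group level.
#'
#' @param pb A [pseudobulk()] object.
#' @param design A [design_spec()].
#' @param cell_types Cell types to test (default all).
#' @param d0_override Passed to [ebayes_moderate()] (testing aid).
#' @return A `de_result`: `table` (tibble over cell types x genes), `priors`
#'   (d0 and s0^2 per cell type), `summary` (significant counts per cell
#'   type x cutoff x direction), plus the design.
#' @export
run_de <- function(pb, design, cell_types = names(pb$values),
                   d0_override = NULL) {
  tabs <- list(); priors <- list()
  for (ct in cell_types) {
    fit <- fit_linear_models(pb, ct, design)
    if (!nrow(fit)) next
    eb <- ebayes_moderate(fit$s2, fit$df, d0_override = d0_override)
    df_total <- if (is.infinite(eb$d0)) Inf else eb$d0 + fit$df
    tstat <- fit$coef / sqrt(eb$s2_post * fit$v_g)
    p <- 2 * stats::pt(-abs(tstat), df = df_total)
    tabs[[ct]] <- dplyr::mutate(fit,
                                cell_type = ct,
                                log2fc = .data$coef / log(2),
                                s2_post = eb$s2_post,
                                t = tstat, p_value = p,
                                fdr = bh_fdr(p),
                                .before = 1)
    priors[[ct]] <- tibble::tibble(cell_type = ct, d0 = eb$d0,
                                   s0_sq = eb$s0_sq,
                                   n_tested = nrow(fit))
  }
  if (!length(tabs)) stop("no cell type had any eligible gene")
  table <- dplyr::relocate(dplyr::bind_rows(tabs), "cell_type", "gene")
  summary <- de_summary_table(table, design$fdr_cutoffs)
  structure(list(table = table, priors = dplyr::bind_rows(priors),
                 summary = summary, design = design),
            class = "de_result")
}

de_summary_table <- function(table, cutoffs) {
  purrr::map_dfr(cutoffs, function(ct_off) {
    table |>
      dplyr::group_by(.data$cell_type) |>
      dplyr::summarise(
        cutoff = ct_off,
        n_tested = dplyr::n(),
        n_sig = sum(.data$fdr < ct_off),
        n_up = sum(.data$fdr < ct_off & .data$log2fc > 0),
        n_down = sum(.data$fdr < ct_off & .data$log2fc < 0),
        .groups = "drop")
  })
}

#' @export
print.de_result <- function(x, ...) {
  cat("<de_result> ", length(unique(x$table$cell_type)), " cell types, ",
      nrow(x$table), " (cell type, gene) tests\n", sep = "")
  print(x$summary, n = Inf)
  invisible(x)
}

#' @export
tidy.de_result <- function(x, ...) x$table

#' @export
glance.de_result <- function(x, ...) {
  tibble::tibble(
    n_cell_types = length(unique(x$table$cell_type)),
    n_tests = nrow(x$table),
    n_sig_min_cutoff = sum(x$table$fdr < min(x$design$fdr_cutoffs)),
    min_cutoff = min(x$design$fdr_cutoffs)
  )
}

#' Top signature genes of a cell type
#'
#' The `k` tested genes with the smallest unadjusted p-value; ties break by
#' larger `|t|`, then by gene id.
#'
#' @param de A `de_result`.
#' @param ct Cell type.
#' @param k Number of genes (default 50).
#' @return Character vector of gene ids, ranked.
#' @export
top_signature_genes <- function(de, ct, k = 50) {
  tab <- de$table[de$table$cell_type == ct, ]
  if (!nrow(tab)) stop("cell type '", ct, "' was not tested")
  ord <- order(tab$p_value, -abs(tab$t), tab$gene)
  if (k > nrow(tab)) {
    warning("only ", nrow(tab), " tested genes in '", ct, "'; returning all")
    k <- nrow(tab)
  }
  tab$gene[ord][seq_len(k)]
}
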