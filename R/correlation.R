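#' Pairwise Pearson correlations between patients' aggregated profiles
#'
#' For one cell type, computes the Pearson correlation between every
#' unordered pair of patients over the genes observed in both (pairwise
#' complete); pairs sharing fewer than `min_shared_genes` genes are dropped
#' with a warning.  Each record carries the pair class: within group A
#' (`A-A`), within group B (`B-B`), or between groups (`A-B`).
#'
#' @param pb A [pseudobulk()] object.
#' @param ct Cell type label.
#' @param min_shared_genes Minimum number of jointly observed genes.
#' @return Tibble: cell_type, patient_i, patient_j, pair_class, r, n_genes.
#' @export
pseudobulk_pair_correlations <- function(pb, ct, min_shared_genes = 10) {
  v <- pb_matrix(pb, ct)
  patients <- colnames(v)[colSums(!is.na(v)) > 0]
  if (length(patients) < 2) {
    warning("fewer than 2 patients with entries for '", ct, "'")
    return(empty_correlation_records())
  }
  grp <- pb$groups[patients]
  pairs <- utils::combn(patients, 2)
  recs <- purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    pi <- pairs[1, k]; pj <- pairs[2, k]
    shared <- !is.na(v[, pi]) & !is.na(v[, pj])
    n <- sum(shared)
    if (n < min_shared_genes) {
      return(tibble::tibble(patient_i = pi, patient_j = pj,
                            pair_class = pair_class(grp[pi], grp[pj]),
                            r = NA_real_, n_genes = n))
    }
    tibble::tibble(patient_i = pi, patient_j = pj,
                   pair_class = pair_class(grp[pi], grp[pj]),
                   r = stats::cor(v[shared, pi], v[shared, pj]),
                   n_genes = n)
  })
  dropped <- sum(is.na(recs$r))
  if (dropped) {
    warning(dropped, " pair(s) dropped: fewer than ", min_shared_genes,
            " shared genes")
    recs <- recs[!is.na(recs$r), , drop = FALSE]
  }
  dplyr::mutate(recs, cell_type = ct, .before = 1)
}

pair_class <- function(gi, gj) {
  g <- sort(c(gi, gj))
  paste(g[1], g[2], sep = "-")
}

empty_contrast_table <- function() {
  tibble::tibble(contrast = character(), estimate = numeric(),
                 se = numeric(), z = numeric(), p_value = numeric(),
                 fdr = numeric())
}

empty_correlation_records <- function() {
  tibble::tibble(cell_type = character(), patient_i = character(),
                 patient_j = character(), pair_class = character(),
                 r = numeric(), n_genes = integer())
}

#' Compare correlation distributions between pair classes
#'
#' Welch two-sample t-tests between the correlation distributions of every
#' pair of pair classes (A-A vs B-B, A-A vs A-B, B-B vs A-B), per cell
#' type, with BH FDR across all tests performed in the call.  Significance
#' stars: `*` for FDR < 0.05, `**` for FDR < 0.001.
#'
#' @param records Correlation records
#'   (from [pseudobulk_pair_correlations()] or
#'   [sample_cellpair_correlations()]; several cell types may be
#'   concatenated).
#' @return Tibble: cell_type, class_1, class_2, n_1, n_2, mean_1, mean_2,
#'   t, p_value, fdr, stars, skipped (TRUE when a class had < 2 records or
#'   zero variance in both classes).
#' @export
compare_correlation_groups <- function(records) {
  out <- records |>
    dplyr::group_by(.data$cell_type) |>
    dplyr::group_modify(function(d, key) {
      classes <- sort(unique(d$pair_class))
      if (length(classes) < 2) return(tibble::tibble())
      cmb <- utils::combn(classes, 2)
      purrr::map_dfr(seq_len(ncol(cmb)), function(k) {
        r1 <- d$r[d$pair_class == cmb[1, k]]
        r2 <- d$r[d$pair_class == cmb[2, k]]
        base <- tibble::tibble(class_1 = cmb[1, k], class_2 = cmb[2, k],
                               n_1 = length(r1), n_2 = length(r2),
                               mean_1 = mean(r1), mean_2 = mean(r2))
        if (length(r1) < 2 || length(r2) < 2 ||
            (stats::sd(r1) == 0 && stats::sd(r2) == 0)) {
          return(dplyr::mutate(base, t = NA_real_, p_value = NA_real_,
                               skipped = TRUE))
        }
        tt <- stats::t.test(r1, r2, var.equal = FALSE)
        dplyr::mutate(base, t = unname(tt$statistic),
                      p_value = tt$p.value, skipped = FALSE)
      })
    }) |>
    dplyr::ungroup()
  if (!nrow(out)) return(out)
  out$fdr <- NA_real_
  out$fdr[!out$skipped] <- bh_fdr(out$p_value[!out$skipped])
  out$stars <- dplyr::case_when(
    is.na(out$fdr) ~ "",
    out$fdr < 0.001 ~ "**",
    out$fdr < 0.05 ~ "*",
    TRUE ~ ""
  )
  out
}

#' Cell-level correlation via randomly sampled cross-sample cell pairs
#'
#' For every unordered pair of samples (patients), draws `n_pairs` pairs of
#' cells -- one from each sample, uniformly with replacement -- computes the
#' Pearson correlation of each cell pair over the genes observed in both
#' cells, and records the mean.  Draws with fewer than `min_shared_genes`
#' jointly observed genes are redrawn (bounded retries); when a sample pair
#' has fewer total combinations than `n_pairs`, all combinations are used
#' once (exhaustive mode).
#'
#' @param m A `masked_matrix` (or sparse normalized matrix, zeros treated
#'   as missing).
#' @param ann Cell annotation (barcode, patient, group, cell_type) aligned
#'   with the columns of `m`.
#' @param ct Cell type to analyse.
#' @param n_pairs Number of cell pairs per sample pair (default 100).
#' @param seed Integer seed.
#' @param min_shared_genes Minimum jointly observed genes per draw.
#' @param max_retry_factor Bound on redraws, as a multiple of `n_pairs`.
#' @return Tibble like [pseudobulk_pair_correlations()] with `n_genes`
#'   replaced by `n_pairs_used`.
#' @export
sample_cellpair_correlations <- function(m, ann, ct, n_pairs = 100,
                                         seed = 1L, min_shared_genes = 10,
                                         max_retry_factor = 10) {
  if (inherits(m, "sparseMatrix")) {
    m <- new_masked_matrix(Matrix::drop0(methods::as(m, "CsparseMatrix")),
                           provenance = "normalized")
  }
  stopifnot(inherits(m, "masked_matrix"))
  set.seed(seed)
  dm <- mm_dense(m)
  idx <- which(ann$cell_type == ct)
  pat <- ann$patient[idx]
  patients <- unique(pat)
  if (length(patients) < 2) {
    warning("fewer than 2 samples with cells of type '", ct, "'")
    return(empty_correlation_records())
  }
  grp <- stats::setNames(ann$group[match(patients, ann$patient)], patients)
  pairs <- utils::combn(patients, 2)
  recs <- purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    ci <- idx[pat == pairs[1, k]]
    cj <- idx[pat == pairs[2, k]]
    total <- as.numeric(length(ci)) * length(cj)
    rs <- c()
    if (total <= n_pairs) {
      for (a in ci) for (b in cj) {
        rs <- c(rs, cellpair_r(dm[, a], dm[, b], min_shared_genes))
      }
    } else {
      draws <- 0L
      while (length(rs) < n_pairs && draws < max_retry_factor * n_pairs) {
        draws <- draws + 1L
        r1 <- cellpair_r(dm[, sample(ci, 1)], dm[, sample(cj, 1)],
                         min_shared_genes)
        if (!is.na(r1)) rs <- c(rs, r1)
      }
    }
    rs <- rs[!is.na(rs)]
    if (!length(rs)) {
      return(tibble::tibble(patient_i = pairs[1, k], patient_j = pairs[2, k],
                            pair_class = pair_class(grp[pairs[1, k]],
                                                    grp[pairs[2, k]]),
                            r = NA_real_, n_pairs_used = 0L))
    }
    tibble::tibble(patient_i = pairs[1, k], patient_j = pairs[2, k],
                   pair_class = pair_class(grp[pairs[1, k]], grp[pairs[2, k]]),
                   r = mean(rs), n_pairs_used = length(rs))
  })
  skipped <- sum(is.na(recs$r))
  if (skipped) {
    warning(skipped, " sample pair(s) skipped: no cell pair with >= ",
            min_shared_genes, " shared genes")
    recs <- recs[!is.na(recs$r), , drop = FALSE]
  }
  dplyr::mutate(recs, cell_type = ct, .before = 1)
}

cellpair_r <- function(x, y, min_shared_genes) {
  shared <- !is.na(x) & !is.na(y)
  if (sum(shared) < min_shared_genes) return(NA_real_)
  if (stats::sd(x[shared]) == 0 || stats::sd(y[shared]) == 0) return(NA_real_)
  stats::cor(x[shared], y[shared])
}

#' Random-intercept mixed model over correlation records
#'
#' Fits `r ~ pair_class + (1 | patient_pair)` by REML, profiling the
#' likelihood over the variance ratio `lambda = sigma_u^2 / sigma_e^2` in
#' one dimension, then reports estimated marginal means per pair class and
#' all pairwise class contrasts with normal-approximation p-values and BH
#' FDR.  The random-effect level is the unordered patient pair, shared
#' across cell types when records from several cell types are fit jointly.
#'
#' @param records Correlation records (possibly several cell types).
#' @param force_sigma_u_zero If `TRUE`, constrains `sigma_u^2 = 0` (the fit
#'   then reduces to OLS).
#' @return An `lmm_fit` object: class means (`emmeans`), `contrasts`
#'   (estimate, se, z, p_value, fdr), variance components `sigma_u_sq` and
#'   `sigma_e_sq`, the REML log-likelihood, and a `boundary` flag.
#' @export
fit_lmm_contrasts <- function(records, force_sigma_u_zero = FALSE) {
  d <- records[!is.na(records$r), , drop = FALSE]
  if (nrow(d) < 2) stop("need at least 2 correlation records")
  d$pair_id <- paste(pmin(d$patient_i, d$patient_j),
                     pmax(d$patient_i, d$patient_j), sep = "|")
  cls <- factor(d$pair_class)
  X <- if (nlevels(cls) == 1) {
    matrix(1, nrow(d), 1)
  } else {
    stats::model.matrix(~ 0 + cls)
  }
  colnames(X) <- levels(cls)
  Z <- stats::model.matrix(~ 0 + factor(d$pair_id))
  y <- d$r
  n <- length(y); p <- qr(X)$rank
  if (p >= n) stop("more fixed-effect levels than observations")

  reml <- function(log_lambda) {
    lam <- exp(log_lambda)
    V <- diag(n) + lam * tcrossprod(Z)
    ch <- chol(V)
    Vi_X <- backsolve(ch, forwardsolve(t(ch), X))
    Vi_y <- backsolve(ch, forwardsolve(t(ch), y))
    XtViX <- crossprod(X, Vi_X)
    beta <- solve(XtViX, crossprod(X, Vi_y))
    r <- y - X %*% beta
    Vi_r <- backsolve(ch, forwardsolve(t(ch), r))
    rss <- drop(crossprod(r, Vi_r))
    sigma_e <- rss / (n - p)
    ll <- -0.5 * ((n - p) * log(sigma_e) + 2 * sum(log(diag(ch))) +
                    determinant(XtViX, logarithm = TRUE)$modulus + (n - p))
    list(ll = as.numeric(ll), beta = drop(beta), sigma_e = sigma_e,
         XtViX = XtViX, lambda = lam)
  }

  ols <- stats::lm.fit(X, y)
  if (sum(ols$residuals^2) < 1e-24) {
    # degenerate: a perfect fixed-effect fit leaves no variance to split
    means <- tibble::tibble(pair_class = levels(cls),
                            emmean = unname(ols$coefficients), se = 0)
    contrasts <- empty_contrast_table()
    if (nlevels(cls) >= 2) {
      cmb <- utils::combn(levels(cls), 2)
      contrasts <- purrr::map_dfr(seq_len(ncol(cmb)), function(k) {
        est <- ols$coefficients[cmb[1, k]] - ols$coefficients[cmb[2, k]]
        tibble::tibble(contrast = paste(cmb[1, k], "-", cmb[2, k]),
                       estimate = unname(est), se = 0, z = NA_real_,
                       p_value = NA_real_, fdr = NA_real_)
      })
    }
    return(structure(list(emmeans = means, contrasts = contrasts,
                          sigma_u_sq = 0, sigma_e_sq = 0,
                          reml_loglik = Inf, boundary = TRUE,
                          n_obs = n, n_pairs = ncol(Z)),
                     class = "lmm_fit"))
  }

  if (force_sigma_u_zero) {
    best <- reml(-Inf)
    best$lambda <- 0
  } else {
    opt <- stats::optimize(function(l) -reml(l)$ll, interval = c(-12, 12),
                           tol = 1e-10)
    at_zero <- reml(-Inf)
    if (at_zero$ll >= -opt$objective) {
      best <- at_zero
      best$lambda <- 0
    } else {
      best <- reml(opt$minimum)
    }
  }
  sigma_u <- best$lambda * best$sigma_e
  vcov_beta <- best$sigma_e * solve(best$XtViX)
  means <- tibble::tibble(pair_class = levels(cls),
                          emmean = best$beta,
                          se = sqrt(diag(vcov_beta)))
  contrasts <- empty_contrast_table()
  if (nlevels(cls) >= 2) {
    cmb <- utils::combn(levels(cls), 2)
    contrasts <- purrr::map_dfr(seq_len(ncol(cmb)), function(k) {
      i <- match(cmb[1, k], levels(cls)); j <- match(cmb[2, k], levels(cls))
      est <- best$beta[i] - best$beta[j]
      se <- sqrt(vcov_beta[i, i] + vcov_beta[j, j] - 2 * vcov_beta[i, j])
      tibble::tibble(contrast = paste(cmb[1, k], "-", cmb[2, k]),
                     estimate = est, se = se, z = est / se,
                     p_value = 2 * stats::pnorm(-abs(est / se)))
    })
    contrasts$fdr <- bh_fdr(contrasts$p_value)
  }
  structure(list(emmeans = means, contrasts = contrasts,
                 sigma_u_sq = sigma_u, sigma_e_sq = best$sigma_e,
                 reml_loglik = best$ll,
                 boundary = best$lambda == 0,
                 n_obs = n, n_pairs = ncol(Z)),
            class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("<lmm_fit> r ~ pair_class + (1 | patient_pair); ", x$n_obs,
      " records, ", x$n_pairs, " patient pairs\n", sep = "")
  cat("  sigma_u^2 = ", format(x$sigma_u_sq, digits = 4),
      if (x$boundary) " (boundary)", ", sigma_e^2 = ",
      format(x$sigma_e_sq, digits = 4), "\n", sep = "")
  print(x$contrasts)
  invisible(x)
}

#' @export
tidy.lmm_fit <- function(x, ...) x$contrasts

#' @export
glance.lmm_fit <- function(x, ...) {
  tibble::tibble(sigma_u_sq = x$sigma_u_sq, sigma_e_sq = x$sigma_e_sq,
                 reml_loglik = x$reml_loglik, boundary = x$boundary,
                 n_obs = x$n_obs, n_pairs = x$n_pairs)
}
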