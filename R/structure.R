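#' Patients x signature-genes matrix for clustering
#'
#' Collects, for each requested cell type, its top-`k` lowest-p genes from
#' the differential expression result and looks their aggregated values up
#' in the tensor.  Columns are (cell type, gene) pairs labelled
#' `"celltype:gene"`; missing tensor entries stay missing.  Passing several
#' cell types gives the union signature.
#'
#' @param pb A [pseudobulk()] object.
#' @param de A [run_de()] result.
#' @param cell_types Cell types to include.
#' @param k Signature size per cell type (default 50).
#' @return Numeric matrix, patients x signature columns, with `NA` for
#'   missing entries.
#' @export
signature_matrix <- function(pb, de, cell_types, k = 50) {
  cols <- list()
  for (ct in cell_types) {
    genes <- top_signature_genes(de, ct, k)
    v <- pb_matrix(pb, ct)[genes, , drop = FALSE]
    block <- t(v)
    colnames(block) <- paste(ct, genes, sep = ":")
    cols[[ct]] <- block
  }
  out <- do.call(cbind, cols)
  if (is.null(out) || ncol(out) == 0) stop("empty signature")
  out
}

#' Pairwise-complete scaled Euclidean distances
#'
#' `d(i, j) = sqrt((D / |S_ij|) * sum_{g in S_ij} (x_ig - x_jg)^2)` where
#' `S_ij` are the columns observed in both rows and `D` the total number of
#' columns; on complete data this is the ordinary Euclidean distance.
#'
#' @param x Numeric matrix (rows = objects), `NA` for missing.
#' @return A dense symmetric matrix of distances.
#' @export
pairwise_complete_dist <- function(x) {
  w <- !is.na(x)
  x0 <- x
  x0[!w] <- 0
  sq <- x0^2
  a <- sq %*% t(w)
  cc <- x0 %*% t(x0)
  s <- w %*% t(w)
  d2 <- a + t(a) - 2 * cc
  if (any(s[upper.tri(s)] == 0)) {
    bad <- which(s == 0 & upper.tri(s), arr.ind = TRUE)[1, ]
    stop("rows ", rownames(x)[bad[1]] %||% bad[1], " and ",
         rownames(x)[bad[2]] %||% bad[2], " share no observed column")
  }
  d <- sqrt(pmax(ncol(x) * d2 / pmax(s, 1), 0))
  diag(d) <- 0
  dimnames(d) <- list(rownames(x), rownames(x))
  d
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Complete-linkage hierarchical clustering tolerating missing values
#'
#' Agglomerative clustering on [pairwise_complete_dist()] distances with
#' complete linkage and deterministic tie-breaking (the merge with the
#' smallest pair of cluster indices wins).  The result is a standard
#' `hclust` object, so [stats::cutree()] and plotting work directly.
#'
#' @param x Numeric matrix (rows = objects to cluster), `NA` allowed.
#' @param dist_matrix Optional precomputed distance matrix (overrides `x`).
#' @return An object of class `hclust`.
#' @export
hcluster <- function(x, dist_matrix = NULL) {
  d <- if (is.null(dist_matrix)) pairwise_complete_dist(x) else as.matrix(dist_matrix)
  n <- nrow(d)
  if (n < 2) stop("need at least 2 rows to cluster")
  labels <- rownames(d) %||% as.character(seq_len(n))
  active <- seq_len(n)
  code <- -seq_len(n)            # hclust encoding: negatives are singletons
  dm <- d
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    best <- c(NA, NA); best_d <- Inf
    for (ii in seq_along(active)[-length(active)]) {
      for (jj in seq((ii + 1), length(active))) {
        dij <- dm[active[ii], active[jj]]
        if (dij < best_d) {
          best_d <- dij; best <- c(ii, jj)
        }
      }
    }
    i <- best[1]; j <- best[2]
    a <- active[i]; b <- active[j]
    merge[step, ] <- sort(c(code[a], code[b]))
    height[step] <- best_d
    # complete linkage: distance of the merged cluster is the max
    dm[a, ] <- pmax(dm[a, ], dm[b, ])
    dm[, a] <- dm[a, ]
    dm[a, a] <- 0
    code[a] <- step
    active <- active[-j]
  }
  out <- list(merge = merge, height = height,
              order = hclust_order(merge),
              labels = labels, method = "complete",
              dist.method = "euclidean-pairwise-complete",
              call = match.call())
  class(out) <- "hclust"
  out
}

hclust_order <- function(merge) {
  n <- nrow(merge) + 1
  expand <- function(k) {
    if (k < 0) return(-k)
    c(expand(merge[k, 1]), expand(merge[k, 2]))
  }
  expand(n - 1)
}

# leaf index sets of every internal node, as sorted integer vectors
node_members <- function(merge) {
  lapply(seq_len(nrow(merge)), function(k) {
    stack <- c(merge[k, 1], merge[k, 2])
    leaves <- integer()
    while (length(stack)) {
      v <- stack[1]; stack <- stack[-1]
      if (v < 0) leaves <- c(leaves, -v)
      else stack <- c(stack, merge[v, 1], merge[v, 2])
    }
    sort(leaves)
  })
}

#' Assess two-group separation of a dendrogram
#'
#' Cuts the tree at the root into two clusters and compares the partition
#' with the known group labels: `perfect` when they coincide, plus the
#' adjusted Rand index of the 2-cut partition against the groups.
#'
#' @param dend An `hclust` object (e.g. from [hcluster()]).
#' @param groups Named vector of group labels (names = leaf labels), or a
#'   vector in leaf order.
#' @return List with `perfect` (logical) and `ari` (numeric).
#' @export
two_group_separation <- function(dend, groups) {
  cl <- stats::cutree(dend, k = 2)
  if (!is.null(names(groups))) {
    if (!all(dend$labels %in% names(groups))) {
      stop("every leaf needs a group label")
    }
    groups <- groups[dend$labels]
  }
  tab <- table(cl, groups)
  perfect <- nrow(tab) == 2 && ncol(tab) == 2 &&
    (all(diag(tab) == 0) || all(tab[cbind(1:2, 2:1)] == 0))
  list(perfect = perfect,
       ari = mclust::adjustedRandIndex(cl, as.character(groups)))
}

#' Multiscale bootstrap stability of dendrogram nodes
#'
#' For each scale `r`, resamples `round(r * D)` of the `D` columns with
#' replacement, reclusters, and records per original internal node the
#' fraction of replicates containing exactly that leaf-membership set
#' (`BP_r`).  The approximately-unbiased value per node comes from the
#' two-parameter multiscale model `qnorm(1 - BP_r) = v * sqrt(r) +
#' c / sqrt(r)` (signed distance `v`, boundary curvature `c`), fit by
#' weighted least squares with weights `B * dnorm(z)^2 / (BP (1 - BP))`
#' over the informative scales (those with `0 < BP_r < 1`), giving
#' `AU = 100 * (1 - pnorm(v - c))`.  `BP` is reported at `r = 1`.
#' When fewer than two scales are informative (e.g. a node contained in
#' every replicate at every scale) the extrapolation is undefined; the node
#' is flagged and its `AU` falls back to the plain bootstrap support.
#'
#' @param x The matrix that was clustered (rows = leaves).
#' @param dend The [hcluster()] result on `x`.
#' @param n_boot Bootstrap replicates per scale (default 1000; < 100 warns).
#' @param scales Resampling scale factors (default 0.5 to 1.4 by 0.1).
#' @param seed Integer seed.
#' @return Tibble: node (merge row), members (label string), bp, au,
#'   flagged (degenerate probit fit).
#' @export
bootstrap_stability <- function(x, dend, n_boot = 1000,
                                scales = seq(0.5, 1.4, by = 0.1),
                                seed = 1L) {
  if (n_boot < 100) warning("n_boot < 100 gives unstable AU estimates")
  set.seed(seed)
  D <- ncol(x)
  members <- node_members(dend$merge)
  keys <- vapply(members, paste, character(1), collapse = ",")
  counts <- matrix(0L, length(keys), length(scales),
                   dimnames = list(keys, NULL))
  for (si in seq_along(scales)) {
    d2 <- max(1L, round(scales[si] * D))
    for (b in seq_len(n_boot)) {
      cols <- sample.int(D, d2, replace = TRUE)
      xb <- x[, cols, drop = FALSE]
      db <- tryCatch(pairwise_complete_dist(xb), error = function(e) NULL)
      if (is.null(db)) next
      hb <- hcluster(xb, dist_matrix = db)
      kb <- vapply(node_members(hb$merge), paste, character(1), collapse = ",")
      hit <- keys %in% kb
      counts[hit, si] <- counts[hit, si] + 1L
    }
  }
  bp_mat <- counts / n_boot
  r1 <- which.min(abs(scales - 1))
  out <- purrr::map_dfr(seq_along(keys), function(k) {
    bp_raw <- bp_mat[k, ]
    # scales saturated at 0 or 1 carry no information about the curve;
    # with fewer than two informative scales the extrapolation is
    # undefined and the plain bootstrap support is reported, flagged
    use <- bp_raw > 0 & bp_raw < 1
    au <- NA_real_
    flagged <- TRUE
    if (sum(use) >= 2) {
      bp_r <- pmin(pmax(bp_raw[use], 1 / (n_boot + 1)), n_boot / (n_boot + 1))
      z <- stats::qnorm(1 - bp_r)
      wt <- n_boot * stats::dnorm(z)^2 / (bp_r * (1 - bp_r))
      Xf <- cbind(sqrt(scales[use]), 1 / sqrt(scales[use]))
      fit <- tryCatch(stats::lm.wfit(Xf, z, wt), error = function(e) NULL)
      flagged <- is.null(fit) || fit$rank < 2 ||
        any(!is.finite(fit$coefficients))
      if (!flagged) {
        # z = v*sqrt(r) + c/sqrt(r); AU = 1 - Phi(v - c)
        au <- 100 * (1 - stats::pnorm(fit$coefficients[1] -
                                        fit$coefficients[2]))
      }
    }
    if (is.na(au)) au <- 100 * bp_raw[r1]
    tibble::tibble(
      node = k,
      members = paste(dend$labels[members[[k]]], collapse = ","),
      bp = 100 * bp_mat[k, r1],
      au = au,
      flagged = flagged)
  })
  out
}

#' PCA with missing values by NIPALS iteration
#'
#' Sequential principal components computed by nonlinear iterative partial
#' least squares: columns are mean-centered over their observed values, and
#' every score/loading update sums only over observed cells, so missing
#' entries are skipped rather than imputed.  Components are deflated on the
#' observed entries; each loading's first nonzero element is forced
#' positive for a deterministic sign.
#'
#' @param x Samples x variables matrix, `NA` for missing; every column
#'   needs at least one observed value.
#' @param n_components Number of components (default 10, capped at
#'   `min(dim(x))` with a warning).
#' @param tol Relative score-change convergence tolerance.
#' @param max_iter Maximum NIPALS iterations per component; components that
#'   fail to converge are flagged and iteration stops gracefully.
#' @return A `nipals_pca` object: `scores` (samples x components),
#'   `loadings` (variables x components), `r2` (observed-variance fraction
#'   captured, cumulative), `converged`, `iterations`.
#' @export
nipals_pca <- function(x, n_components = 10, tol = 1e-8, max_iter = 500) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least 2 samples")
  w <- !is.na(x)
  if (any(colSums(w) == 0)) {
    stop("column(s) without any observed value: ",
         paste(utils::head(which(colSums(w) == 0), 5), collapse = ", "))
  }
  if (n_components > min(nrow(x), ncol(x))) {
    warning("`n_components` capped at min(dim(x)) = ", min(dim(x)))
    n_components <- min(nrow(x), ncol(x))
  }
  mu <- colSums(ifelse(w, x, 0)) / colSums(w)
  E <- sweep(x, 2, mu)
  E0 <- ifelse(w, E, 0)
  total_ss <- sum(E0^2)
  scores <- matrix(NA_real_, nrow(x), n_components,
                   dimnames = list(rownames(x), paste0("PC", seq_len(n_components))))
  loadings <- matrix(NA_real_, ncol(x), n_components,
                     dimnames = list(colnames(x), paste0("PC", seq_len(n_components))))
  r2 <- numeric(n_components)
  converged <- logical(n_components)
  iters <- integer(n_components)
  for (h in seq_len(n_components)) {
    col_var <- colSums(E0^2)
    tvec <- E0[, which.max(col_var)]
    if (all(tvec == 0)) break
    it <- 0L
    repeat {
      it <- it + 1L
      den_p <- crossprod(w, tvec^2)
      p <- as.vector(crossprod(E0, tvec)) / ifelse(den_p > 0, den_p, 1)
      p_norm <- sqrt(sum(p^2))
      if (p_norm == 0) break
      p <- p / p_norm
      den_t <- w %*% p^2
      t_new <- as.vector(E0 %*% p) / ifelse(den_t > 0, den_t, 1)
      delta <- sqrt(sum((t_new - tvec)^2)) / max(sqrt(sum(t_new^2)), 1e-300)
      tvec <- t_new
      if (delta < tol || it >= max_iter) break
    }
    converged[h] <- it < max_iter
    iters[h] <- it
    # deterministic sign: first nonzero loading positive
    nz <- which(abs(p) > 1e-12)
    if (length(nz) && p[nz[1]] < 0) {
      p <- -p; tvec <- -tvec
    }
    scores[, h] <- tvec
    loadings[, h] <- p
    E0 <- E0 - ifelse(w, outer(tvec, p), 0)
    r2[h] <- 1 - sum(E0^2) / total_ss
    if (!converged[h]) {
      warning("component ", h, " did not converge in ", max_iter,
              " iterations; stopping")
      scores <- scores[, seq_len(h), drop = FALSE]
      loadings <- loadings[, seq_len(h), drop = FALSE]
      r2 <- r2[seq_len(h)]
      converged <- converged[seq_len(h)]
      iters <- iters[seq_len(h)]
      break
    }
  }
  structure(list(scores = scores, loadings = loadings, r2 = r2,
                 center = mu, converged = converged, iterations = iters),
            class = "nipals_pca")
}

#' @export
print.nipals_pca <- function(x, ...) {
  cat("<nipals_pca> ", ncol(x$scores), " components; cumulative observed R^2: ",
      paste(format(x$r2, digits = 3), collapse = " "), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.nipals_pca <- function(x, ...) {
  tibble::as_tibble(x$scores, rownames = "sample") |>
    tidyr::pivot_longer(-"sample", names_to = "component", values_to = "score")
}

#' @export
glance.nipals_pca <- function(x, ...) {
  tibble::tibble(n_components = ncol(x$scores),
                 r2_cumulative = x$r2[length(x$r2)],
                 all_converged = all(x$converged))
}
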