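#' Ordered-query minimum hypergeometric enrichment of one gene set
#'
#' Tests a gene set against every prefix of a ranked gene list: for prefix
#' length `L` with `k_L` set members among the first `L` genes, the
#' upper-tail hypergeometric probability of observing at least `k_L`
#' members in `L` draws from a background of size `N` containing `K` set
#' members.  The minimum over prefixes is returned.  Only prefix lengths
#' where a set member enters the prefix (plus the full length) need to be
#' evaluated: at fixed overlap the tail probability only decreases when a
#' member enters, so all minima lie on this reduced grid.
#'
#' @param ranked Character vector of genes, best first; must be a subset of
#'   `background` with no duplicates.
#' @param set Character vector of gene ids (intersected with the background
#'   before testing).
#' @param background Character vector: the tested universe.
#' @return List with `min_p`, `L_star` (prefix length of the minimum),
#'   `overlap` (set members in that prefix), and `set_size` (after
#'   background intersection).
#' @export
ordered_min_p <- function(ranked, set, background) {
  if (anyDuplicated(ranked)) stop("`ranked` contains duplicate genes")
  if (!all(ranked %in% background)) {
    stop("`ranked` must be a subset of `background`")
  }
  N <- length(unique(background))
  set <- intersect(unique(set), background)
  K <- length(set)
  n <- length(ranked)
  if (K == 0) {
    return(list(min_p = 1, L_star = n, overlap = 0L, set_size = 0L))
  }
  member <- ranked %in% set
  k_cum <- cumsum(member)
  grid <- unique(c(which(member), n))
  p_grid <- stats::phyper(k_cum[grid] - 1, K, N - K, grid, lower.tail = FALSE)
  best <- which.min(p_grid)
  list(min_p = p_grid[best], L_star = grid[best],
       overlap = as.integer(k_cum[grid[best]]), set_size = as.integer(K))
}

#' Ranked-list enrichment of a collection with permutation calibration
#'
#' Computes [ordered_min_p()] for every set, then calibrates the minimum
#' p-values family-wise: the ranking is permuted `n_perm` times, all sets'
#' minimum p-values are recomputed, and a set's adjusted p is the fraction
#' of permutations in which the smallest minimum p across all sets is at or
#' below the observed one (max-T style), using the `(r + 1) / (n_perm + 1)`
#' estimator.  Sets smaller than `min_set_size` or larger than half the
#' background are skipped.
#'
#' @param ranked Character vector of genes, best first.
#' @param sets A named list of character vectors (e.g. from [read_gmt()]).
#' @param background Character vector: the tested universe (must be given
#'   explicitly; there is no silent default).
#' @param n_perm Number of ranking permutations (default 1000; < 100 warns).
#' @param seed Integer seed.
#' @param min_set_size Minimum post-intersection set size (default 3).
#' @return Tibble: set, set_size, overlap, L_star, min_p, adj_p, skipped.
#' @export
calibrate_and_adjust <- function(ranked, sets, background, n_perm = 1000,
                                 seed = 1L, min_set_size = 3) {
  if (missing(background) || is.null(background)) {
    stop("`background` must be supplied explicitly")
  }
  if (!length(sets)) stop("need at least one gene set")
  if (is.null(names(sets)) || anyDuplicated(names(sets))) {
    stop("`sets` must be uniquely named")
  }
  if (n_perm < 100) warning("n_perm < 100 gives coarse adjusted p-values")
  set.seed(seed)
  trimmed <- lapply(sets, function(s) intersect(unique(s), background))
  sizes <- lengths(trimmed)
  usable <- sizes >= min_set_size & sizes <= length(unique(background)) / 2
  obs <- purrr::map(trimmed[usable], ~ ordered_min_p(ranked, .x, background))
  obs_min_p <- vapply(obs, `[[`, numeric(1), "min_p")
  perm_family_min <- numeric(n_perm)
  if (!any(usable)) n_perm <- 0L
  for (b in seq_len(n_perm)) {
    rperm <- sample(ranked)
    pvals <- vapply(trimmed[usable], function(s) {
      ordered_min_p(rperm, s, background)$min_p
    }, numeric(1))
    perm_family_min[b] <- min(pvals)
  }
  adj <- vapply(obs_min_p, function(p0) {
    (sum(perm_family_min <= p0) + 1) / (n_perm + 1)
  }, numeric(1))
  out <- tibble::tibble(
    set = names(sets),
    set_size = as.integer(sizes),
    overlap = NA_integer_, L_star = NA_integer_,
    min_p = NA_real_, adj_p = NA_real_,
    skipped = !usable
  )
  idx <- match(names(obs), out$set)
  out$overlap[idx] <- vapply(obs, `[[`, integer(1), "overlap")
  out$L_star[idx] <- vapply(obs, function(o) as.integer(o$L_star), integer(1))
  out$min_p[idx] <- obs_min_p
  out$adj_p[idx] <- adj
  dplyr::arrange(out, .data$skipped, .data$adj_p, .data$min_p)
}

#' Build a ranked gene list from a differential expression result
#'
#' Genes of one cell type ordered by unadjusted p-value (ties by `|t|`
#' descending, then gene id), ignoring the direction of change.
#'
#' @param de A [run_de()] result.
#' @param ct Cell type.
#' @return Character vector of gene ids, best first.
#' @export
ranked_gene_list <- function(de, ct) {
  tab <- de$table[de$table$cell_type == ct, ]
  if (!nrow(tab)) stop("cell type '", ct, "' was not tested")
  tab$gene[order(tab$p_value, -abs(tab$t), tab$gene)]
}
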