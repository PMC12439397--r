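make_pb_cor <- function(v, groups) {
  structure(list(values = list(tumor = v),
                 n_cells = list(tumor = v * 0 + 10),
                 groups = groups, min_cells = 10),
            class = "pseudobulk")
}

test_that("pairwise profile correlations follow the Pearson definition", {
  v <- cbind(P1 = c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12),
             P2 = c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12),
             P3 = c(12, 11, 10, 9, 8, 7, 6, 5, 4, 3, 2, 1))
  rownames(v) <- sprintf("g%02d", 1:12)
  groups <- c(P1 = "A", P2 = "A", P3 = "B")
  recs <- pseudobulk_pair_correlations(make_pb_cor(v, groups), "tumor")
  expect_equal(nrow(recs), choose(3, 2))
  r12 <- recs$r[recs$patient_i == "P1" & recs$patient_j == "P2"]
  r13 <- recs$r[recs$patient_i == "P1" & recs$patient_j == "P3"]
  expect_equal(r12, 1)
  expect_equal(r13, -1)
  expect_equal(recs$pair_class[recs$patient_i == "P1" &
                                 recs$patient_j == "P2"], "A-A")
  expect_equal(recs$pair_class[recs$patient_i == "P1" &
                                 recs$patient_j == "P3"], "A-B")
})

test_that("pairwise-complete handling drops under-supported pairs", {
  set.seed(50)
  v <- matrix(rnorm(60), 20, 3,
              dimnames = list(sprintf("g%02d", 1:20), c("P1", "P2", "P3")))
  v[1:15, "P3"] <- NA   # P3 shares only 5 genes
  groups <- c(P1 = "A", P2 = "A", P3 = "B")
  expect_warning(
    recs <- pseudobulk_pair_correlations(make_pb_cor(v, groups), "tumor",
                                         min_shared_genes = 10),
    "dropped")
  expect_equal(nrow(recs), 1)
  expect_equal(recs$n_genes, 20)
  # the retained correlation uses exactly the jointly observed genes
  expect_equal(recs$r, cor(v[, "P1"], v[, "P2"]))
})

test_that("class comparisons use Welch tests with family-wide FDR and stars", {
  set.seed(51)
  recs <- tibble::tibble(
    cell_type = "tumor",
    patient_i = "x", patient_j = "y",
    pair_class = rep(c("A-A", "B-B", "A-B"), each = 20),
    r = c(rnorm(20, 0.9, 0.01), rnorm(20, 0.5, 0.01), rnorm(20, 0.7, 0.01)),
    n_genes = 100L)
  out <- compare_correlation_groups(recs)
  aabb <- out[out$class_1 == "A-A" & out$class_2 == "B-B", ]
  expect_lt(aabb$fdr, 0.001)
  expect_equal(aabb$stars, "**")
  ref <- t.test(recs$r[recs$pair_class == "A-A"],
                recs$r[recs$pair_class == "B-B"], var.equal = FALSE)
  expect_equal(aabb$p_value, ref$p.value)
  # identical distributions: no star
  recs2 <- recs
  recs2$r <- rep(c(0.5, 0.6, 0.7, 0.55, 0.65), 12)
  out2 <- compare_correlation_groups(recs2)
  expect_true(all(out2$stars == ""))
  # singleton class is skipped, not fatal
  recs3 <- recs[c(1, 21:40, 41:60), ]
  out3 <- compare_correlation_groups(recs3)
  expect_true(any(out3$skipped))
  expect_true(all(is.na(out3$p_value[out3$skipped])))
})

test_that("cell-pair sampling is deterministic and matches exhaustive enumeration", {
  set.seed(52)
  m <- matrix(rnorm(30 * 8, 2), 30, 8)
  m[sample(length(m), 40)] <- NA
  dimnames(m) <- list(sprintf("g%02d", 1:30), sprintf("c%d", 1:8))
  ann <- tibble::tibble(barcode = colnames(m),
                        patient = rep(c("P1", "P2"), each = 4),
                        group = rep(c("A", "B"), each = 4),
                        cell_type = "tumor")
  mm <- masked_from_dense(m)
  # exhaustive mode: 16 possible cross-sample pairs <= n_pairs
  recs <- sample_cellpair_correlations(mm, ann, "tumor", n_pairs = 100,
                                       seed = 1)
  rs <- c()
  for (a in 1:4) {
    for (b in 5:8) {
      sh <- !is.na(m[, a]) & !is.na(m[, b])
      if (sum(sh) >= 10) rs <- c(rs, cor(m[sh, a], m[sh, b]))
    }
  }
  expect_equal(recs$r, mean(rs))
  expect_equal(recs$n_pairs_used, length(rs))
  # determinism under a fixed seed in sampling mode
  ann2 <- ann; ann2$patient <- rep(c("P1", "P2"), 4)
  r1 <- sample_cellpair_correlations(mm, ann2, "tumor", n_pairs = 5, seed = 9)
  r2 <- sample_cellpair_correlations(mm, ann2, "tumor", n_pairs = 5, seed = 9)
  expect_identical(r1, r2)
  # two samples holding copies of one identical cell correlate at 1
  m_id <- cbind(c1 = c(1, 5, 2, 7, 3, 8, 1, 4, 6, 2, 9, 3),
                c2 = c(1, 5, 2, 7, 3, 8, 1, 4, 6, 2, 9, 3))
  ann_id <- tibble::tibble(barcode = c("c1", "c2"),
                           patient = c("P1", "P2"),
                           group = c("A", "B"), cell_type = "tumor")
  rid <- sample_cellpair_correlations(masked_from_dense(m_id), ann_id,
                                      "tumor", n_pairs = 3, seed = 1)
  expect_equal(rid$r, 1)
})

test_that("REML variance components match the balanced one-way closed form", {
  set.seed(53)
  n_pairs <- 12; k <- 4
  u <- rnorm(n_pairs, 0, 0.3)
  recs <- purrr::map_dfr(seq_len(n_pairs), function(i) {
    tibble::tibble(cell_type = paste0("ct", 1:k),
                   patient_i = sprintf("P%02d", i),
                   patient_j = sprintf("Q%02d", i),
                   pair_class = "A-A",
                   r = 0.5 + u[i] + rnorm(k, 0, 0.2),
                   n_genes = 50L)
  })
  fit <- fit_lmm_contrasts(recs)
  # balanced one-way ANOVA estimator of the between-group variance
  y <- matrix(recs$r, nrow = k)   # k obs per pair, pairs in columns
  msb <- k * var(colMeans(y))
  msw <- mean(apply(y, 2, var))
  expect_equal(fit$sigma_u_sq, (msb - msw) / k, tolerance = 1e-6)
  expect_equal(fit$sigma_e_sq, msw, tolerance = 1e-4)
  # observation order must not matter
  fit_perm <- fit_lmm_contrasts(recs[sample(nrow(recs)), ])
  expect_equal(fit_perm$sigma_u_sq, fit$sigma_u_sq, tolerance = 1e-6)
})

test_that("constrained sigma_u = 0 reproduces ordinary least squares", {
  set.seed(54)
  recs <- tibble::tibble(
    cell_type = "tumor",
    patient_i = rep(sprintf("P%d", 1:10), 3),
    patient_j = rep(sprintf("Q%d", 1:10), 3),
    pair_class = rep(c("A-A", "B-B", "A-B"), each = 10),
    r = rnorm(30, rep(c(0.8, 0.6, 0.7), each = 10), 0.05),
    n_genes = 50L)
  fit <- fit_lmm_contrasts(recs, force_sigma_u_zero = TRUE)
  ols <- lm(r ~ 0 + pair_class, data = recs)
  expect_equal(fit$emmeans$emmean, unname(coef(ols)), tolerance = 1e-8)
  est <- fit$contrasts$estimate[fit$contrasts$contrast == "A-A - B-B"]
  expect_equal(est, unname(coef(ols)["pair_classA-A"] -
                             coef(ols)["pair_classB-B"]), tolerance = 1e-8)
  expect_equal(fit$sigma_u_sq, 0)
})

test_that("REML fit agrees with the established mixed-model reference", {
  skip_if_not_installed("lme4")
  set.seed(55)
  n_pairs <- 15
  u <- rnorm(n_pairs, 0, 0.25)
  cls <- rep(c("A-A", "B-B", "A-B"), each = 5)
  recs <- purrr::map_dfr(seq_len(n_pairs), function(i) {
    tibble::tibble(cell_type = paste0("ct", 1:3),
                   patient_i = sprintf("P%02d", i),
                   patient_j = sprintf("Q%02d", i),
                   pair_class = cls[i],
                   r = 0.6 + 0.1 * (cls[i] == "A-A") + u[i] + rnorm(3, 0, 0.1),
                   n_genes = 50L)
  })
  fit <- fit_lmm_contrasts(recs)
  recs$pair_id <- paste(recs$patient_i, recs$patient_j)
  ref <- lme4::lmer(r ~ 0 + pair_class + (1 | pair_id), data = recs,
                    REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(ref))
  expect_equal(fit$sigma_u_sq, vc$vcov[1], tolerance = 1e-4)
  expect_equal(fit$sigma_e_sq, vc$vcov[2], tolerance = 1e-4)
  expect_equal(fit$emmeans$emmean, unname(lme4::fixef(ref)), tolerance = 1e-5)
})

test_that("degenerate all-identical records give zero variances and contrasts", {
  recs <- tibble::tibble(cell_type = "tumor",
                         patient_i = rep(sprintf("P%d", 1:6), 2),
                         patient_j = rep(sprintf("Q%d", 1:6), 2),
                         pair_class = rep(c("A-A", "B-B"), 6),
                         r = 0.7, n_genes = 50L)
  fit <- fit_lmm_contrasts(recs)
  expect_equal(fit$sigma_u_sq, 0)
  expect_equal(fit$sigma_e_sq, 0)
  expect_equal(fit$contrasts$estimate, 0)
})
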