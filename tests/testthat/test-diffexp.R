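make_pb <- function(values_list, groups, min_cells = 10) {
  structure(list(values = values_list,
                 n_cells = lapply(values_list, function(v) v * 0 + min_cells),
                 groups = groups, min_cells = min_cells),
            class = "pseudobulk")
}

test_that("per-group eligibility thresholds act per gene", {
  set.seed(40)
  v <- matrix(rnorm(3 * 13), 3, 13,
              dimnames = list(c("g1", "g2", "g3"),
                              c(paste0("A", 1:3), paste0("B", 1:10))))
  v["g2", "A3"] <- NA # g2: 2 A patients only
  groups <- c(rep("A", 3), rep("B", 10))
  names(groups) <- colnames(v)
  pb <- make_pb(list(tumor = v), groups)
  des4 <- design_spec(groups, min_patients = 4)
  des3 <- design_spec(groups, min_patients = 3)
  # g1 has 3 A-patients: excluded at 4, included at 3
  expect_false("g1" %in% eligible_genes(pb, "tumor", des4))
  expect_true("g1" %in% eligible_genes(pb, "tumor", des3))
  expect_false("g2" %in% eligible_genes(pb, "tumor", des3))
  # fully observed tensor: everything eligible
  v_full <- matrix(rnorm(3 * 13), 3, 13, dimnames = dimnames(v))
  expect_setequal(eligible_genes(make_pb(list(tumor = v_full), groups),
                                 "tumor", des3),
                  rownames(v))
})

test_that("two-group fits match lm() and respect covariate orthogonality", {
  set.seed(41)
  patients <- c(paste0("A", 1:4), paste0("B", 1:4))
  groups <- stats::setNames(rep(c("A", "B"), each = 4), patients)
  v <- matrix(rnorm(20 * 8, mean = 2), 20, 8,
              dimnames = list(sprintf("g%02d", 1:20), patients))
  v[3, 2] <- NA
  pb <- make_pb(list(tumor = v), groups)
  des <- design_spec(groups, min_patients = 3)
  fit <- fit_linear_models(pb, "tumor", des)
  for (g in c("g01", "g03", "g15")) {
    y <- v[g, ]
    use <- !is.na(y)
    ref <- stats::lm(y[use] ~ I(groups[use] == "A"))
    expect_equal(fit$coef[fit$gene == g], unname(coef(ref)[2]),
                 tolerance = 1e-12)
    expect_equal(fit$s2[fit$gene == g],
                 sum(resid(ref)^2) / ref$df.residual, tolerance = 1e-12)
    expect_equal(fit$df[fit$gene == g], ref$df.residual)
  }
  # equal group means -> coefficient 0
  v0 <- v
  v0[1, ] <- rep(c(1, 2, 3, 4), 2)
  fit0 <- fit_linear_models(make_pb(list(tumor = v0), groups), "tumor", des)
  expect_equal(fit0$coef[fit0$gene == "g01"], 0)
  # balanced binary covariate orthogonal to group leaves the contrast as is
  cov <- data.frame(treated = rep(c(0, 1), 4), row.names = patients)
  des_cov <- design_spec(groups, covariates = cov, min_patients = 3)
  v_c <- matrix(rnorm(10 * 8, mean = 2), 10, 8,
                dimnames = list(sprintf("h%02d", 1:10), patients))
  fit_plain <- fit_linear_models(make_pb(list(tumor = v_c), groups), "tumor", des)
  fit_cov <- fit_linear_models(make_pb(list(tumor = v_c), groups), "tumor", des_cov)
  expect_equal(fit_cov$coef, fit_plain$coef, tolerance = 1e-10)
})

test_that("moderated t reduces to the ordinary regression t at d0 = 0", {
  set.seed(42)
  patients <- c(paste0("A", 1:5), paste0("B", 1:5))
  groups <- stats::setNames(rep(c("A", "B"), each = 5), patients)
  v <- matrix(rnorm(50 * 10, mean = 1), 50, 10,
              dimnames = list(sprintf("g%02d", 1:50), patients))
  v[sample(length(v), 40)] <- NA
  pb <- make_pb(list(tumor = v), groups)
  de <- run_de(pb, design_spec(groups, min_patients = 3), d0_override = 0)
  for (g in de$table$gene) {
    t_oracle <- oracle_regression_t(v[g, ], factor(groups, c("B", "A")))
    expect_equal(de$table$t[de$table$gene == g], t_oracle, tolerance = 1e-10)
  }
})

test_that("d0 = Inf override shrinks every posterior variance to s0^2", {
  set.seed(43)
  s2 <- rchisq(100, 5) / 5
  eb <- ebayes_moderate(s2, rep(8, 100), d0_override = Inf)
  expect_true(all(eb$s2_post == eb$s0_sq))
  eb0 <- ebayes_moderate(s2, rep(8, 100), d0_override = 0)
  expect_identical(eb0$s2_post, s2)
})

test_that("hyperparameter recovery on variances drawn from the prior model", {
  set.seed(44)
  n <- 5000; d0 <- 4; s0 <- 0.25; dg <- 10
  sigma2 <- d0 * s0 / rchisq(n, d0)            # scaled inverse chi-square
  s2 <- sigma2 * rchisq(n, dg) / dg            # sampling layer
  eb <- ebayes_moderate(s2, rep(dg, n))
  expect_equal(eb$d0, d0, tolerance = 0.25)
  expect_equal(eb$s0_sq, s0, tolerance = 0.10)
})

test_that("moderation agrees with the established empirical-Bayes reference", {
  skip_if_not_installed("limma")
  set.seed(45)
  n <- 800; dg <- 8
  sigma2 <- 6 * 0.3 / rchisq(n, 6)
  s2 <- sigma2 * rchisq(n, dg) / dg
  eb <- ebayes_moderate(s2, rep(dg, n))
  sq <- limma::squeezeVar(s2, df = dg)
  expect_equal(eb$d0, sq$df.prior, tolerance = 0.02)
  expect_equal(eb$s0_sq, sq$var.prior, tolerance = 0.02)
  expect_equal(eb$s2_post, sq$var.post, tolerance = 0.02)
})

test_that("BH agrees with the brute-force step-up definition", {
  expect_equal(bh_fdr(0.02), 0.02)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(46)
  for (i in 1:50) {
    p <- runif(sample(3:30, 1))
    expect_equal(bh_fdr(p), oracle_bh(p))
  }
})

test_that("run_de reports per-cutoff counts and enforces eligibility", {
  set.seed(47)
  patients <- c(paste0("A", 1:6), paste0("B", 1:6))
  groups <- stats::setNames(rep(c("A", "B"), each = 6), patients)
  v <- matrix(rnorm(200 * 12), 200, 12,
              dimnames = list(sprintf("g%03d", 1:200), patients))
  v[1:50, 1:6] <- v[1:50, 1:6] + 2      # strong effects in 50 genes
  pb <- make_pb(list(tumor = v), groups)
  de <- run_de(pb, design_spec(groups))
  expect_true(all(de$table$fdr >= de$table$p_value))
  expect_setequal(unique(de$summary$cutoff), c(0.05, 0.1, 0.2))
  sig <- de$table$gene[de$table$fdr < 0.05]
  expect_gt(length(intersect(sig, sprintf("g%03d", 1:50))), 30)
  expect_true(all(de$table$log2fc[de$table$gene %in% sig] > 0))
  # dropping patients below the threshold removes genes from the tested set
  v2 <- v
  v2[51:200, c("B4", "B5", "B6")] <- NA
  de2 <- run_de(make_pb(list(tumor = v2), groups), design_spec(groups))
  expect_setequal(de2$table$gene, sprintf("g%03d", 1:50))
})

test_that("signature selection ranks by p with the documented tie-break", {
  tab <- tibble::tibble(
    cell_type = "tumor",
    gene = c("g1", "g2", "g3", "g4"),
    t = c(2.0, -3.0, 2.5, 1.0),
    p_value = c(0.01, 0.01, 0.005, 0.5),
    fdr = c(0.02, 0.02, 0.01, 0.5))
  de <- structure(list(table = tab), class = "de_result")
  expect_equal(top_signature_genes(de, "tumor", 1), "g3")
  # p tie between g1 and g2 -> larger |t| first
  expect_equal(top_signature_genes(de, "tumor", 3), c("g3", "g2", "g1"))
  expect_warning(all4 <- top_signature_genes(de, "tumor", 10), "returning all")
  expect_equal(all4, c("g3", "g2", "g1", "g4"))
  expect_error(top_signature_genes(de, "stromal", 1), "not tested")
})
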