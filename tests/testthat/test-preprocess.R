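test_that("QC bounds are inclusive for genes/counts and strict for mito", {
  # 4 genes; craft cells with known detected-gene counts and totals
  counts <- cbind(
    c(5, 5, 5, 0),    # 3 genes, 15 counts
    c(2, 2, 2, 2),    # 4 genes, 8 counts
    c(0, 9, 0, 0),    # 1 gene, 9 counts
    c(0, 4, 4, 0)     # 2 genes, 8 counts, no mito
  )
  ds <- make_tiny_dataset(n_genes = 4, n_cells = 4,
                          patients = rep("A01", 4), groups = rep("A", 4),
                          counts = counts,
                          mito = c(TRUE, FALSE, FALSE, FALSE))
  p <- qc_params(min_genes = 2, max_genes = 3, min_counts = 8,
                 max_counts = 15, max_mito_frac = 0.30,
                 min_cells_focal_type = 0)
  kept <- qc_filter_cells(ds, p)
  # cell 1: 3 genes (inclusive upper), 15 counts (inclusive), mito 5/15 > 0.3 -> out
  # cell 2: 4 genes -> out; cell 3: 1 gene -> out
  # cell 4: 2 genes, 8 counts, mito 0 -> kept
  expect_equal(kept$cells$barcode, "c00004")
  expect_equal(kept$cells$n_genes, 2)
  # boundary: mito exactly at the bound is excluded (strict <)
  p2 <- qc_params(min_genes = 1, max_genes = 4, min_counts = 1,
                  max_counts = 100, max_mito_frac = 5 / 15,
                  min_cells_focal_type = 0)
  kept2 <- qc_filter_cells(ds, p2)
  expect_false("c00001" %in% kept2$cells$barcode)
})

test_that("QC filtering keeps everything when all cells pass, and is idempotent", {
  ds <- make_tiny_dataset()
  p <- qc_params(min_genes = 0, max_genes = 100, min_counts = 0,
                 max_counts = 1e5, max_mito_frac = 1)
  once <- qc_filter_cells(ds, p)
  expect_equal(ncol(once$counts), ncol(ds$counts))
  twice <- qc_filter_cells(once, p)
  expect_equal(as.matrix(twice$counts), as.matrix(once$counts))
  expect_equal(twice$cells$barcode, once$cells$barcode)
})

test_that("QC refuses to run the mito criterion without mito flags", {
  ds <- make_tiny_dataset(mito = rep(FALSE, 6))
  expect_error(qc_filter_cells(ds, qc_params(max_mito_frac = 0.1)),
               "mitochondrial")
  expect_silent(qc_filter_cells(ds, qc_params(min_genes = 0, max_genes = 100,
                                              min_counts = 0, max_counts = 1e5,
                                              max_mito_frac = 1)))
})

test_that("patients with too few focal cells are excluded at the threshold", {
  n <- 82 + 100 + 120
  patients <- rep(c("P1", "P2", "P3"), c(82, 100, 120))
  ds <- make_tiny_dataset(n_genes = 5, n_cells = n, patients = patients,
                          groups = rep("A", n), cell_type = "tumor")
  p <- qc_params(min_cells_focal_type = 100, focal_cell_type = "tumor")
  res <- exclude_small_samples(ds, p)
  expect_equal(res$excluded$patient, "P1")
  expect_equal(res$excluded$n_focal_cells, 82L)
  expect_setequal(unique(res$dataset$cells$patient), c("P2", "P3"))
  # boundary: exactly 100 focal cells is kept
  expect_true("P2" %in% res$dataset$cells$patient)
  res0 <- exclude_small_samples(ds, qc_params(min_cells_focal_type = 0))
  expect_equal(nrow(res0$excluded), 0)
  expect_equal(ncol(res0$dataset$counts), n)
})

test_that("lognormalize matches its closed form and preserves zeros", {
  counts <- matrix(0, 3, 2)
  counts[1, 1] <- 10; counts[2, 1] <- 9990
  counts[3, 2] <- 50
  m <- lognormalize(Matrix::Matrix(counts, sparse = TRUE), scale = 1e4)
  expect_equal(m[1, 1], log(11))            # 10 * 1e4 / 1e4 = 10 -> ln(11)
  expect_equal(m[3, 2], log(1 + 1e4))
  expect_equal(m[2, 2], 0)
  # doubling the scale strictly increases every nonzero value
  m2 <- lognormalize(Matrix::Matrix(counts, sparse = TRUE), scale = 2e4)
  nz <- which(as.matrix(m) > 0)
  expect_true(all(as.matrix(m2)[nz] > as.matrix(m)[nz]))
  # per-cell monotonicity in counts
  set.seed(1)
  cnt <- matrix(rpois(200, 5), 20, 10)
  ln <- as.matrix(lognormalize(Matrix::Matrix(cnt, sparse = TRUE)))
  for (j in 1:10) {
    ord <- order(cnt[, j])
    expect_true(all(diff(ln[ord, j]) >= 0))
  }
  bad <- Matrix::Matrix(cbind(c(1, 0), c(0, 0)), sparse = TRUE)
  colnames(bad) <- c("ok", "empty")
  expect_error(lognormalize(bad), "empty")
})

test_that("variable-gene selection ranks by binned standardized dispersion", {
  set.seed(3)
  n_genes <- 60
  m <- matrix(rpois(n_genes * 30, 4), n_genes, 30,
              dimnames = list(sprintf("g%02d", 1:n_genes), NULL))
  m[5, ] <- 4                      # constant gene
  m[6, ] <- rpois(30, 4) * c(1, 9) # wildly variable gene
  norm <- as.matrix(lognormalize(Matrix::Matrix(m, sparse = TRUE)))
  expect_setequal(select_variable_genes(norm, n_genes), rownames(m))
  expect_equal(select_variable_genes(rbind(constant = 1,
                                           variable = norm[6, ]), 1),
               "variable")
  # independent brute-force recomputation of the ranking statistic
  got <- select_variable_genes(norm, 10)
  mu <- rowMeans(norm)
  v <- apply(norm, 1, var)
  disp <- ifelse(mu > 0, v / mu, 0)
  bins <- ggplot2::cut_number(rank(mu, ties.method = "first"),
                              n = max(1, min(20, floor(n_genes / 5))))
  z <- rep(0, n_genes)
  for (b in levels(bins)) {
    i <- bins == b
    s <- sd(disp[i])
    z[i] <- if (is.na(s) || s == 0) 0 else (disp[i] - mean(disp[i])) / s
  }
  want <- rownames(m)[order(-z, rownames(m))][1:10]
  expect_equal(got, want)
  expect_warning(select_variable_genes(norm, n_genes + 5), "all genes")
})

test_that("center_by_batch zeroes per-patient nonzero gene means", {
  set.seed(8)
  cnt <- matrix(rpois(40 * 20, 2), 40, 20)
  ann <- tibble::tibble(barcode = sprintf("c%02d", 1:20),
                        patient = rep(c("P1", "P2"), each = 10))
  norm <- lognormalize(Matrix::Matrix(cnt, sparse = TRUE))
  cen <- center_by_batch(norm, ann)
  dn <- as.matrix(cen)
  for (p in c("P1", "P2")) {
    cols <- which(ann$patient == p)
    for (g in 1:40) {
      nz <- cols[cnt[g, cols] > 0]
      if (length(nz)) expect_lt(abs(mean(dn[g, nz])), 1e-10)
    }
  }
  # zeros pass through
  expect_true(all(dn[cnt == 0] == 0))
  # two patients with identical profiles get identical centered output
  cnt2 <- cbind(cnt[, 1:10], cnt[, 1:10])
  cen2 <- as.matrix(center_by_batch(lognormalize(Matrix::Matrix(cnt2, sparse = TRUE)),
                                    ann))
  expect_equal(cen2[, 1:10], cen2[, 11:20])
})

test_that("mask_imputed masks exactly the raw zeros", {
  set.seed(11)
  raw <- matrix(rpois(50 * 50, 0.7), 50, 50)
  expr <- matrix(rnorm(50 * 50), 50, 50)  # dense stand-in for integrated data
  mm <- mask_imputed(expr, Matrix::Matrix(raw, sparse = TRUE))
  dn <- mm_dense(mm)
  for (i in 1:50) {
    for (j in 1:50) {
      if (raw[i, j] == 0) {
        expect_true(is.na(dn[i, j]))
      } else {
        expect_identical(dn[i, j], expr[i, j])
      }
    }
  }
  expect_equal(sparsity_summary(mm)$global, mean(raw == 0))
  # all-positive raw -> nothing missing
  mm2 <- mask_imputed(expr, Matrix::Matrix(raw + 1, sparse = TRUE))
  expect_equal(sum(is.na(mm_dense(mm2))), 0)
  expect_error(mask_imputed(expr[1:10, ], Matrix::Matrix(raw, sparse = TRUE)),
               "dimensions differ")
})

test_that("mask_imputed sparse fast path agrees with the dense path", {
  set.seed(12)
  raw <- Matrix::rsparsematrix(30, 20, density = 0.2)
  raw@x <- abs(round(raw@x * 10)) + 1
  raw <- Matrix::drop0(raw)
  norm <- lognormalize(raw)
  fast <- mask_imputed(norm, raw)
  slow <- mask_imputed(as.matrix(norm), raw)
  expect_equal(mm_dense(fast), mm_dense(slow))
  expect_equal(fast$provenance, "integrated-masked")
})
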