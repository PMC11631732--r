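test_that("QC removes exactly the cells violating each boundary rule", {
  res <- qc_filter(qc_toy())
  expect_setequal(colnames(res$sce), c("cell2", "cell4", "cell6"))
  expect_equal(res$report$removed_low_genes, 1)
  expect_equal(res$report$removed_low_umi, 1)
  expect_equal(res$report$removed_high_mito, 1)
  expect_equal(res$report$removed_total, 3)
  expect_false(res$report$empty)
})

test_that("QC is idempotent and warns (not errors) when nothing survives", {
  once <- qc_filter(qc_toy())
  twice <- qc_filter(once$sce)
  expect_equal(twice$report$removed_total, 0)
  expect_identical(colnames(twice$sce), colnames(once$sce))
  expect_warning(res <- qc_filter(qc_toy(), qc_thresholds(min_umi = 1e9)),
                 "every cell")
  expect_true(res$report$empty)
  expect_equal(ncol(res$sce), 0)
})

test_that("normalization rescales cells to the target total then log-transforms", {
  m <- matrix(c(1, 1, 0,
                3, 1, 0), nrow = 3,
              dimnames = list(c("ga", "gb", "gz"), c("c1", "c2")))
  sce <- normalize_log(toy_sce(m))
  ln <- SummarizedExperiment::assay(sce, "lognorm")
  expect_equal(as.numeric(expm1(ln[, "c1"])), c(5e5, 5e5, 0))
  expect_equal(as.numeric(expm1(ln[, "c2"])), c(7.5e5, 2.5e5, 0))
  # per-cell pre-log totals equal the scale factor
  expect_equal(unname(Matrix::colSums(expm1(ln))), c(1e6, 1e6))
  # zero pattern preserved exactly
  expect_identical(as.matrix(ln == 0), m == 0)
  bad <- toy_sce(matrix(c(1, 0), 1, 2, dimnames = list("g", c("ok", "empty"))))
  expect_error(normalize_log(bad), "empty")
})

test_that("HVG selection favors variable genes and is deterministic", {
  set.seed(51)
  n_cells <- 400
  counts <- matrix(rpois(20 * n_cells, 5), nrow = 20,
                   dimnames = list(sprintf("g%02d", 1:20), NULL))
  counts["g01", ] <- rpois(n_cells, c(rep(1, n_cells / 2), rep(40, n_cells / 2)))
  counts["g02", ] <- 5  # constant raw counts
  sce <- normalize_log(toy_sce(counts))
  # k = n returns everything; the differential gene leads
  all_genes <- select_hvg(sce, k = 20)
  expect_setequal(all_genes, rownames(counts))
  expect_equal(select_hvg(sce, k = 3)[1], "g01")
  expect_error(select_hvg(sce, k = 21), "exceeds")
  # constant library sizes + constant counts = zero dispersion: such a gene
  # must rank behind every non-constant gene
  even <- rbind(h01 = rep(7, 100), rmultinom(100, 93, prob = rep(1, 9)))
  rownames(even) <- sprintf("h%02d", 1:10)
  sce2 <- normalize_log(toy_sce(even))
  expect_equal(select_hvg(sce2, k = 10)[10], "h01")
})

test_that("a planted differential gene outranks i.i.d. noise genes", {
  set.seed(52)
  n_cells <- 2000
  counts <- matrix(rpois(50 * n_cells, 4), nrow = 50,
                   dimnames = list(sprintf("g%02d", 1:50), NULL))
  counts["g25", ] <- rpois(n_cells, rep(c(0.5, 30), each = n_cells / 2))
  sce <- normalize_log(toy_sce(counts))
  expect_equal(select_hvg(sce, k = 1), "g25")
})

test_that("PCA ordering, rank handling and reconstruction behave", {
  set.seed(53)
  x <- matrix(rnorm(30 * 80), nrow = 30)
  rownames(x) <- sprintf("g%02d", 1:30)
  p <- pca_embed(x, n_components = 10)
  expect_true(all(diff(p$explained_variance) <= 1e-10))
  # exact rank 2: later components carry ~no variance
  basis <- matrix(rnorm(30 * 2), 30, 2)
  low <- basis %*% matrix(rnorm(2 * 60), 2, 60)
  rownames(low) <- rownames(x)[1:30]
  expect_warning(p2 <- pca_embed(low, n_components = 10), "rank")
  expect_lt(sum(p2$explained_variance[3:10]) / sum(p2$explained_variance), 1e-8)
  # full decomposition reconstructs the input
  pf <- pca_embed(x, n_components = 30)
  rec <- tcrossprod(pf$scores, pf$loadings) + rep(pf$center, each = 80)
  expect_equal(unname(rec), unname(t(x)), tolerance = 1e-8)
  expect_error(pca_embed(x, n_components = 100), "rank")
})

test_that("ridge batch regression removes offsets at lambda 0 and vanishes at large lambda", {
  set.seed(54)
  x <- matrix(rnorm(200 * 5), 200, 5)
  batch <- rep(c("a", "b"), each = 100)
  shifted <- x + outer(as.numeric(batch == "b") * 2, rep(1, 5))
  fixed <- regress_batch(shifted, batch, ridge_lambda = 0)
  for (j in 1:5) {
    expect_lt(abs(mean(fixed[batch == "a", j]) - mean(fixed[batch == "b", j])), 1e-10)
  }
  # global feature means unchanged (mean-zero correction)
  expect_equal(colMeans(fixed), colMeans(shifted), tolerance = 1e-12)
  # infinite-penalty limit: no correction
  frozen <- regress_batch(shifted, batch, ridge_lambda = 1e9)
  expect_equal(frozen, shifted, tolerance = 1e-5)
  # identical batches at lambda 0: correction is the (tiny) mean imbalance only
  same <- regress_batch(x, batch, ridge_lambda = 0)
  expect_lt(max(abs(same - x)), 0.5)
  expect_warning(regress_batch(x, rep("a", 200)), "single batch")
})

test_that("marker annotation assigns by mean marker expression with fixed tie order", {
  sets <- list(T = c("CD3D", "CD3E"), epithelial = c("EPCAM", "KRT8"))
  sce2 <- normalize_log(toy_sce(matrix(c(5, 5, 0, 0,
                                         0, 0, 5, 5,
                                         0, 0, 0, 1), 4, 3,
                                       dimnames = list(c("CD3D", "CD3E", "EPCAM", "KRT8"),
                                                       c("tcell", "epi", "weak")))))
  ann <- annotate_by_markers(sce2, sets)
  expect_equal(ann$label, c("T", "epithelial", "epithelial"))
  expect_true(all(ann$margin[1:2] > 0))
  expect_error(annotate_by_markers(sce2, list(T = character(0))), "empty")
  expect_error(annotate_by_markers(sce2, list(T = "NOPE")), "absent")
})

test_that("cells with no marker signal are unassigned; simulated labels are recovered", {
  sets <- list(T = "CD3D", B = "MS4A1")
  m <- matrix(c(0, 0, 4, 0, 3, 2), 3, 2,
              dimnames = list(c("CD3D", "MS4A1", "OTHER"), NULL))
  ann <- annotate_by_markers(normalize_log(toy_sce(m)), sets)
  expect_equal(ann$label[1], "unassigned")
  # simulation with 4-fold marker enrichment: >= 95% accuracy
  types <- c(malignant = 0, epithelial = 0, fibroblast = 0, endothelial = 0,
             T = 0.5, NK = 0, myeloid = 0, B = 0.5)
  pi <- matrix(0.2, 20, 8, dimnames = list(NULL, names(types)))
  lam <- matrix(2, 20, 8, dimnames = dimnames(pi))
  pi[1:3, "T"] <- 0.9; lam[1:3, "T"] <- 8    # T markers
  pi[4:6, "B"] <- 0.9; lam[4:6, "B"] <- 8    # B markers
  cfg <- sc_sim_config(n_genes = 20, n_patients = 4, cells_per_patient = 250,
                       cell_type_proportions = types, pi = pi, lambda = lam,
                       mito_gene_fraction = 0, batch_effect_scale = 0, seed = 55)
  sce <- normalize_log(simulate_sc_cohort(cfg))
  genes <- rownames(sce)
  ann <- annotate_by_markers(sce, list(T = genes[1:3], B = genes[4:6]))
  expect_gt(mean(ann$label == sce$cell_type), 0.95)
})
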