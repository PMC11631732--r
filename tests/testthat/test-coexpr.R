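test_that("co-expression fraction counts dual-positive cells on raw counts", {
  m <- matrix(c(1, 0, 2, 3,
                1, 1, 0, 4,
                0, 0, 0, 0), nrow = 3, byrow = TRUE,
              dimnames = list(c("A", "B", "Z"), NULL))
  sce <- toy_sce(m)
  expect_equal(coexpression_fraction(sce, "A", "B")$fraction, 0.5)
  expect_equal(coexpression_fraction(sce, "A", "Z")$fraction, 0)
  # empty cell set: flagged record, not an error
  rec <- coexpression_fraction(sce, "A", "B", cells = integer(0))
  expect_equal(rec$n_cells, 0)
  expect_true(is.na(rec$fraction))
  expect_error(coexpression_fraction(sce, "A", "missing"), "not present")
})

test_that("co-expression is symmetric and bounded by the marginal ECFs", {
  set.seed(71)
  for (i in 1:25) {
    m <- matrix(rpois(2 * 50, 0.8), nrow = 2, dimnames = list(c("A", "B"), NULL))
    sce <- toy_sce(m)
    ab <- coexpression_fraction(sce, "A", "B")$fraction
    ba <- coexpression_fraction(sce, "B", "A")$fraction
    expect_identical(ab, ba)
    expect_lte(ab, min(expressing_cell_fraction(sce, "A")$ecf,
                       expressing_cell_fraction(sce, "B")$ecf))
  }
})

test_that("independent expression gives a product-of-marginals co-expression fraction", {
  set.seed(72)
  n <- 10000
  m <- rbind(A = rbinom(n, 1, 0.4) * (1 + rpois(n, 2)),
             B = rbinom(n, 1, 0.5) * (1 + rpois(n, 2)))
  frac <- coexpression_fraction(m, "A", "B")$fraction
  se <- sqrt(0.2 * 0.8 / n)
  expect_lt(abs(frac - 0.2), 3 * se)
})

test_that("patient threshold summary uses a strict inequality", {
  recs <- fraction_records(malignant = c(0, 0, 0), stromal = c(0, 0, 0))
  s0 <- patient_threshold_summary(recs, threshold = 0.10)
  expect_true(all(s0$patient_fraction == 0))
  # threshold 0: any nonzero fraction counts, zeros do not
  recs2 <- fraction_records(malignant = c(0.02, 0), stromal = c(0, 0))
  s1 <- patient_threshold_summary(recs2, threshold = 0)
  expect_equal(s1$patient_fraction[s1$group == "malignant"], 0.5)
  # a fraction exactly at the threshold does not count
  recs3 <- fraction_records(malignant = c(0.10, 0.11), stromal = c(0, 0))
  s2 <- patient_threshold_summary(recs3, threshold = 0.10)
  expect_equal(s2$patient_fraction[s2$group == "malignant"], 0.5)
})

test_that("patient summary matches the Beta tail probability on simulated fractions", {
  set.seed(73)
  fr <- rbeta(2000, 2, 5)
  recs <- fraction_records(malignant = fr, stromal = rep(0, 2))
  s <- patient_threshold_summary(recs, threshold = 0.10)
  p_true <- pbeta(0.10, 2, 5, lower.tail = FALSE)
  se <- sqrt(p_true * (1 - p_true) / 2000)
  expect_lt(abs(s$patient_fraction[s$group == "malignant"] - p_true), 3 * se)
})

test_that("malignant-vs-stromal comparison degenerates and separates correctly", {
  # identical values on both sides: p ~ 1
  same <- fraction_records(malignant = rep(0.2, 5), stromal = rep(0.2, 5))
  expect_gte(compare_malignant_vs_stromal(same)$p_value, 0.99)
  # complete separation at n = 10 per side: exact rank-sum p below 1e-3
  set.seed(74)
  sep <- fraction_records(malignant = runif(10, 0.5, 0.9),
                          stromal = runif(10, 0.01, 0.1))
  res <- compare_malignant_vs_stromal(sep)
  expect_lt(res$p_value, 1e-3)
  expect_gt(res$median_malignant, res$median_stromal)
  expect_error(compare_malignant_vs_stromal(
    fraction_records(malignant = 0.5, stromal = 0.1)), "at least two")
})

test_that("records below the cell-count floor are excluded from tests", {
  recs <- fraction_records(malignant = c(0.5, 0.6, 0.7), stromal = c(0.1, 0.1, 0.9))
  recs$n_cells[recs$group != "malignant" & recs$fraction == 0.9] <- 5
  recs$valid <- recs$n_cells >= 10
  res <- compare_malignant_vs_stromal(recs)
  expect_equal(res$n_stromal, 2)
})

test_that("partner screen reduces to single-gene ECF for self-partner and ranks specificity", {
  types <- c(malignant = 0.5, epithelial = 0, fibroblast = 0.5, endothelial = 0,
             T = 0, NK = 0, myeloid = 0, B = 0)
  pi <- matrix(0.05, 40, 8, dimnames = list(NULL, names(types)))
  lam <- matrix(3, 40, 8, dimnames = dimnames(pi))
  pi[1, ] <- 0.6                                    # anchor: everywhere
  pi[2, "malignant"] <- 0.6                         # partner1: tumor-specific
  pi[3, ] <- 0.6                                    # partner2: everywhere
  cfg <- sc_sim_config(n_genes = 40, n_patients = 5, cells_per_patient = 200,
                       cell_type_proportions = types, pi = pi, lambda = lam,
                       mito_gene_fraction = 0, seed = 75)
  sce <- simulate_sc_cohort(cfg)
  g <- rownames(sce)
  ps <- partner_screen(sce, anchor = g[1], partners = c(g[1], g[2], g[3]))
  # A & A = A: self-partner fraction equals the anchor ECF per patient group
  rec_self <- ps$records[ps$records$partner == g[1] & ps$records$group == "malignant", ]
  for (i in seq_len(nrow(rec_self))) {
    sel <- sce$patient == rec_self$patient[i] & sce$cell_type == "malignant"
    expect_equal(rec_self$fraction[i],
                 expressing_cell_fraction(sce, g[1], cells = sel)$ecf)
  }
  # tumor-specific partner beats the ubiquitous one on the specificity view
  summ <- ps$summary
  expect_lt(summ$rank_specificity[summ$partner == g[2]],
            summ$rank_specificity[summ$partner == g[3]])
  # a partner that is never expressed yields all-zero fractions
  pi[4, ] <- 0
  cfg2 <- sc_sim_config(n_genes = 40, n_patients = 2, cells_per_patient = 50,
                        cell_type_proportions = types, pi = pi, lambda = lam,
                        mito_gene_fraction = 0, seed = 76)
  sce2 <- simulate_sc_cohort(cfg2)
  ps2 <- partner_screen(sce2, anchor = rownames(sce2)[1],
                        partners = rownames(sce2)[4])
  expect_true(all(ps2$records$fraction[!is.na(ps2$records$fraction)] == 0))
  expect_warning(partner_screen(sce2, rownames(sce2)[1],
                                partners = c(rownames(sce2)[2], "NOPE")),
                 "skipped")
})
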