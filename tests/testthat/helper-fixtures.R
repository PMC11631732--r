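# Fixture builders shared across test files. Everything is generated in code;
# no data files.

# A SingleCellExperiment from a dense genes-by-cells count matrix.
toy_sce <- function(counts, patient = NULL, cell_type = NULL, batch = NULL) {
  n <- ncol(counts)
  if (is.null(colnames(counts))) colnames(counts) <- sprintf("c%03d", seq_len(n))
  if (is.null(rownames(counts))) rownames(counts) <- sprintf("g%03d", seq_len(nrow(counts)))
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                       "CsparseMatrix")),
    colData = S4Vectors::DataFrame(
      patient = patient %||% rep("P1", n),
      cell_type = cell_type %||% rep("malignant", n),
      batch = batch %||% rep("D1", n),
      row.names = colnames(counts))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A 6-cell toy matrix exercising each QC rule at its boundary:
#   cell1: 2 detected genes (below 3)          -> removed
#   cell2: 3 detected genes, 200 UMI, low mito -> retained
#   cell3: 199 total UMI                       -> removed
#   cell4: 200 total UMI                       -> retained
#   cell5: 21% mitochondrial                   -> removed
#   cell6: 20% mitochondrial (boundary)        -> retained
qc_toy <- function() {
  m <- matrix(0, nrow = 4, ncol = 6,
              dimnames = list(c("MT-G1", "G1", "G2", "G3"), paste0("cell", 1:6)))
  m[c("G1", "G2"), "cell1"] <- c(400, 100)
  m[c("G1", "G2", "G3"), "cell2"] <- c(100, 60, 40)
  m[c("G1", "G2", "G3"), "cell3"] <- c(99, 60, 40)
  m[c("G1", "G2", "G3"), "cell4"] <- c(100, 60, 40)
  m[c("MT-G1", "G1", "G2"), "cell5"] <- c(42, 98, 60)
  m[c("MT-G1", "G1", "G2"), "cell6"] <- c(40, 100, 60)
  toy_sce(m)
}

# Mann-Whitney pair-counting AUC oracle: ties count one half.
pair_count_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(cmp)
}

# Hand-rolled two-group log-rank oracle: O-E/V from hypergeometric terms.
logrank_oracle <- function(time_a, event_a, time_b, event_b) {
  time <- c(time_a, time_b)
  event <- c(event_a, event_b)
  grp <- rep(c(1, 2), c(length(time_a), length(time_b)))
  o_minus_e <- 0; v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & grp == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & grp == 1)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}

# Co-expression records table built directly from per-patient fractions.
fraction_records <- function(malignant, stromal, stromal_group = "fibroblast") {
  rbind(
    data.frame(patient = sprintf("P%02d", seq_along(malignant)),
               group = "malignant", anchor = "A", partner = "B",
               n_cells = 100, n_dual = round(100 * malignant),
               fraction = malignant, valid = TRUE),
    data.frame(patient = sprintf("P%02d", seq_along(stromal)),
               group = stromal_group, anchor = "A", partner = "B",
               n_cells = 100, n_dual = round(100 * stromal),
               fraction = stromal, valid = TRUE)
  )
}
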