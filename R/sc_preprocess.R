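# Single-cell preprocessing: QC filtering, counts-per-million log
# normalization, highly variable genes, PCA, ridge batch regression, and a
# marker-score cell annotator.

#' QC thresholds for cell filtering
#'
#' Cells are removed when they have fewer than `min_genes_detected` detected
#' genes, fewer than `min_umi` total UMI counts, or a mitochondrial UMI
#' fraction greater than `max_mito_fraction`.
#'
#' @param min_genes_detected minimum detected genes per cell (default 3).
#' @param min_umi minimum total UMI per cell (default 200).
#' @param max_mito_fraction maximal mitochondrial fraction (default 0.20,
#'   exclusive: exactly 20% is retained).
#' @export
qc_thresholds <- function(min_genes_detected = 3, min_umi = 200,
                          max_mito_fraction = 0.20) {
  stopifnot(min_genes_detected >= 0, min_umi >= 0,
            max_mito_fraction >= 0, max_mito_fraction <= 1)
  structure(list(min_genes_detected = min_genes_detected, min_umi = min_umi,
                 max_mito_fraction = max_mito_fraction),
            class = "qc_thresholds")
}

sce_counts <- function(sce) SummarizedExperiment::assay(sce, "counts")

#' Filter low-quality cells
#'
#' Applies the three QC rules and reports how many cells each rule removes
#' (cells can fail several rules; the `removed_total` entry counts each cell
#' once). Mitochondrial genes are recognized by a case-insensitive symbol
#' prefix, "MT-" by default.
#'
#' @param sce a `SingleCellExperiment` with a `counts` assay.
#' @param thresholds a [qc_thresholds()] object.
#' @param mito_pattern regex anchored at the symbol start that marks
#'   mitochondrial genes.
#' @return list with the filtered `sce` and a `report` list
#'   (`n_input`, `removed_low_genes`, `removed_low_umi`, `removed_high_mito`,
#'   `removed_total`, `n_retained`, `empty`).
#' @export
qc_filter <- function(sce, thresholds = qc_thresholds(), mito_pattern = "^MT-") {
  counts <- sce_counts(sce)
  detected <- Matrix::colSums(counts > 0)
  total <- Matrix::colSums(counts)
  mito <- grepl(mito_pattern, rownames(counts), ignore.case = TRUE)
  mito_umi <- if (any(mito)) Matrix::colSums(counts[mito, , drop = FALSE]) else 0
  mito_frac <- ifelse(total > 0, mito_umi / total, 0)

  fail_genes <- detected < thresholds$min_genes_detected
  fail_umi <- total < thresholds$min_umi
  fail_mito <- mito_frac > thresholds$max_mito_fraction
  keep <- !(fail_genes | fail_umi | fail_mito)

  report <- list(
    n_input = ncol(counts),
    removed_low_genes = sum(fail_genes),
    removed_low_umi = sum(fail_umi),
    removed_high_mito = sum(fail_mito),
    removed_total = sum(!keep),
    n_retained = sum(keep),
    empty = !any(keep)
  )
  if (report$empty) {
    warning("QC filtering removed every cell", call. = FALSE)
  }
  out <- sce[, keep]
  SummarizedExperiment::colData(out)$n_genes_detected <- detected[keep]
  SummarizedExperiment::colData(out)$total_umi <- total[keep]
  SummarizedExperiment::colData(out)$mito_fraction <- mito_frac[keep]
  list(sce = out, report = report)
}

#' Counts-per-million log normalization
#'
#' Scales each cell's counts to a fixed library size (1e6 by default) and
#' applies `log1p` (natural log). Zero counts stay exactly zero.
#'
#' @param sce a `SingleCellExperiment` with a `counts` assay; cells with zero
#'   total counts must already be filtered out.
#' @param scale target per-cell total before the log.
#' @return the `sce` with a dense-free `lognorm` assay added and the scale
#'   factor recorded in `metadata(sce)$normalization`.
#' @export
normalize_log <- function(sce, scale = 1e6) {
  counts <- sce_counts(sce)
  total <- Matrix::colSums(counts)
  if (any(total == 0)) {
    bad <- colnames(counts)[total == 0][1]
    stop(sprintf("cell '%s' has zero total counts; run qc_filter first", bad),
         call. = FALSE)
  }
  lognorm <- counts
  lognorm@x <- log1p(lognorm@x / rep.int(total, diff(lognorm@p)) * scale)
  SummarizedExperiment::assay(sce, "lognorm") <- lognorm
  S4Vectors::metadata(sce)$normalization <- list(scale = scale, log_base = exp(1))
  sce
}

#' Select highly variable genes by binned normalized dispersion
#'
#' Dispersion is variance/mean of the pre-log normalized values (counts per
#' `scale`); genes are placed into 20 equal-frequency mean bins and their
#' dispersions z-scored within each bin, which removes the mean-dispersion
#' trend. The top `k` genes by normalized dispersion are returned,
#' deterministic ties broken by gene symbol.
#'
#' @param sce a `SingleCellExperiment` with a `lognorm` assay
#'   ([normalize_log()]).
#' @param k number of genes to select (default 2000, capped at the number of
#'   genes available).
#' @param n_bins number of mean bins for the z-scoring.
#' @return character vector of `k` gene symbols, most variable first.
#' @export
select_hvg <- function(sce, k = 2000, n_bins = 20) {
  lognorm <- SummarizedExperiment::assay(sce, "lognorm")
  if (k > nrow(lognorm)) {
    stop(sprintf("k = %d exceeds the %d genes available", k, nrow(lognorm)),
         call. = FALSE)
  }
  x <- expm1(lognorm)  # back to the pre-log normalized scale
  mu <- Matrix::rowMeans(x)
  ex2 <- Matrix::rowMeans(x^2)
  v <- (ex2 - mu^2) * ncol(x) / max(ncol(x) - 1, 1)
  disp <- ifelse(mu > 0, v / mu, 0)

  bins <- cut(rank(mu, ties.method = "first"),
              breaks = n_bins, labels = FALSE, include.lowest = TRUE)
  norm_disp <- disp
  for (b in unique(bins)) {
    i <- bins == b
    s <- stats::sd(disp[i])
    norm_disp[i] <- if (is.na(s) || s == 0) 0 else (disp[i] - mean(disp[i])) / s
  }
  norm_disp[v <= 0] <- -Inf  # zero-variance genes are never "highly variable"
  ord <- order(-norm_disp, rownames(lognorm))
  rownames(lognorm)[ord][seq_len(k)]
}

#' PCA embedding of cells
#'
#' Centers each gene across cells and decomposes; components come out ordered
#' by non-increasing explained variance. If the data have lower rank than
#' `n_components`, the available components are returned with a warning.
#'
#' @param sce_or_matrix a `SingleCellExperiment` (its `lognorm` assay is
#'   used, optionally restricted to `genes`) or a features-by-cells matrix.
#' @param n_components number of components to keep (default 30).
#' @param genes optional gene subset (e.g. the HVG set).
#' @return list with `scores` (cells x components), `loadings`,
#'   `explained_variance` and `center`.
#' @export
pca_embed <- function(sce_or_matrix, n_components = 30, genes = NULL) {
  x <- if (methods::is(sce_or_matrix, "SingleCellExperiment")) {
    SummarizedExperiment::assay(sce_or_matrix, "lognorm")
  } else sce_or_matrix
  if (!is.null(genes)) x <- x[genes, , drop = FALSE]
  x <- as.matrix(x)
  if (n_components > min(dim(x))) {
    stop("n_components exceeds the matrix rank bound", call. = FALSE)
  }
  p <- stats::prcomp(t(x), center = TRUE, scale. = FALSE, rank. = n_components)
  ev <- p$sdev^2
  avail <- sum(ev > max(ev) * 1e-12)
  if (avail < n_components) {
    warning(sprintf("input rank %d < %d requested components", avail, n_components),
            call. = FALSE)
  }
  keep <- seq_len(min(n_components, ncol(p$x)))
  list(scores = p$x[, keep, drop = FALSE],
       loadings = p$rotation[, keep, drop = FALSE],
       explained_variance = ev[keep], center = p$center)
}

#' Ridge regression batch correction
#'
#' For each feature, regresses the (mean-centered) values on one-hot batch
#' indicators with an L2 penalty `ridge_lambda` and subtracts the centered
#' fitted batch effect. With `ridge_lambda = 0` the per-batch feature means
#' become equal; as the penalty grows the correction shrinks to zero. The
#' correction is mean-zero across cells, so global feature means are
#' unchanged.
#'
#' @param x cells-by-features matrix (e.g. a PCA embedding) or
#'   features-by-cells matrix with `features_in_rows = TRUE`.
#' @param batch batch id per cell (at least two distinct values; with a
#'   single batch the input is returned unchanged, with a warning).
#' @param ridge_lambda non-negative ridge penalty (default 1).
#' @param features_in_rows set when `x` is features x cells.
#' @return corrected matrix with the shape of `x`.
#' @export
regress_batch <- function(x, batch, ridge_lambda = 1.0, features_in_rows = FALSE) {
  if (features_in_rows) {
    return(t(regress_batch(t(as.matrix(x)), batch, ridge_lambda)))
  }
  x <- as.matrix(x)
  stopifnot(length(batch) == nrow(x), ridge_lambda >= 0)
  batch <- factor(batch)
  if (nlevels(batch) < 2) {
    warning("single batch: returning the input unchanged", call. = FALSE)
    return(x)
  }
  centered <- sweep(x, 2, colMeans(x))
  n_b <- as.vector(table(batch))
  # per-batch column sums of the centered data: B x features
  sums <- rowsum(centered, batch)
  beta <- sums / (n_b + ridge_lambda)      # ridge solution, Z'Z diagonal
  fitted <- beta[as.integer(batch), , drop = FALSE]
  correction <- sweep(fitted, 2, colMeans(fitted))
  dimnames(correction) <- dimnames(x)
  x - correction
}

#' Annotate cells by marker-set mean expression
#'
#' Each cell is assigned the cell type whose marker set has the highest mean
#' log-normalized expression in that cell; cells where every marker score is
#' zero are labeled "unassigned". Ties are broken by the order of
#' `marker_sets`.
#'
#' @param sce a `SingleCellExperiment` with a `lognorm` assay.
#' @param marker_sets named list mapping cell type to a character vector of
#'   marker genes (all present in the matrix; empty sets are an error).
#' @return data.frame with `cell`, `label`, `score` (winning mean) and
#'   `margin` (gap to the runner-up).
#' @export
annotate_by_markers <- function(sce, marker_sets) {
  lognorm <- SummarizedExperiment::assay(sce, "lognorm")
  stopifnot(is.list(marker_sets), length(marker_sets) >= 1,
            !is.null(names(marker_sets)))
  if (any(lengths(marker_sets) == 0)) {
    stop("empty marker set supplied", call. = FALSE)
  }
  missing <- setdiff(unlist(marker_sets), rownames(lognorm))
  if (length(missing) > 0) {
    stop("marker genes absent from matrix: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  scores <- vapply(marker_sets, function(gs) {
    Matrix::colMeans(lognorm[gs, , drop = FALSE])
  }, numeric(ncol(lognorm)))
  scores <- matrix(scores, ncol = length(marker_sets),
                   dimnames = list(colnames(lognorm), names(marker_sets)))
  best <- apply(scores, 1, which.max)       # first maximum = declared order
  top <- scores[cbind(seq_len(nrow(scores)), best)]
  second <- apply(scores, 1, function(s) if (length(s) > 1) max(s[-which.max(s)]) else 0)
  label <- ifelse(top <= 0, "unassigned", colnames(scores)[best])
  data.frame(cell = rownames(scores), label = label, score = top,
             margin = top - second, row.names = NULL, stringsAsFactors = FALSE)
}
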