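# Tumor-associated antigen screening: expressing-cell fraction, random-forest
# ranking of genes separating malignant from normal cells, and intersection
# with a surfaceome list.

#' Expressing cell fraction (ECF)
#'
#' The fraction of cells in a group whose *raw* count for a gene exceeds
#' zero. Defined on raw counts, so it is invariant to normalization.
#'
#' @param sce a `SingleCellExperiment` with a `counts` assay, or a
#'   genes-by-cells count matrix.
#' @param gene gene symbol (row name).
#' @param cells logical/integer/character selector of the cell group; `NULL`
#'   uses all cells.
#' @param group optional group label recorded in the result.
#' @return list with `gene`, `group`, `n_cells`, `n_expressing`, `ecf`.
#' @export
expressing_cell_fraction <- function(sce, gene, cells = NULL, group = "all") {
  counts <- if (methods::is(sce, "SingleCellExperiment")) sce_counts(sce) else sce
  if (!gene %in% rownames(counts)) {
    stop(sprintf("gene '%s' not present", gene), call. = FALSE)
  }
  v <- counts[gene, , drop = TRUE]
  if (!is.null(cells)) v <- v[cells]
  n <- length(v)
  if (n == 0) stop("cell group is empty", call. = FALSE)
  n_expr <- sum(v > 0)
  list(gene = gene, group = group, n_cells = n,
       n_expressing = n_expr, ecf = n_expr / n)
}

stratified_split <- function(labels, split) {
  stopifnot(length(split) == 3, abs(sum(split) - 1) < 1e-8)
  part <- integer(length(labels))
  for (lv in levels(labels)) {
    idx <- sample(which(labels == lv))
    n <- length(idx)
    n_train <- round(split[1] * n)
    n_test <- round(split[2] * n)
    part[idx[seq_len(n_train)]] <- 1L
    part[idx[n_train + seq_len(n_test)]] <- 2L
    if (n_train + n_test < n) part[idx[(n_train + n_test + 1):n]] <- 3L
  }
  part
}

ranger_scores <- function(fit, x, positive) {
  pr <- stats::predict(fit, data = x, predict.all = TRUE, num.threads = 1)
  cls <- fit$forest$levels
  rowMeans(pr$predictions == match(positive, cls))
}

#' Rank genes separating tumor from normal cells with a random forest
#'
#' Cells are split into stratified training/testing/validation subsets
#' (default 6:2:2). A 1000-tree random forest is fit on the training split;
#' when a grid of `mtry` values is supplied, `cv_folds`-fold cross-validation
#' on the training split picks the value with the best mean AUC before the
#' final fit. Per-gene importance is the permutation importance (mean
#' decrease in out-of-bag accuracy); negative importances are kept and ranked
#' as-is. AUC on the held-out testing split is the model-selection metric and
#' the validation-split AUC is reported alongside.
#'
#' @param sce a `SingleCellExperiment` (its `lognorm` assay is used) or a
#'   features-by-cells matrix.
#' @param labels two-level factor/character per cell (e.g. tumor/normal).
#' @param n_trees number of trees (default 1000).
#' @param split train/test/validation proportions, summing to 1.
#' @param cv_folds folds for `mtry` selection (used when `mtry` has
#'   length > 1).
#' @param mtry candidate values for the number of variables per split;
#'   `NULL` uses the ranger default (floor of sqrt(p)).
#' @param genes optional feature restriction (e.g. a surfaceome list).
#' @param seed integer seed; the split and the forest are deterministic
#'   given it.
#' @return data.frame of class `ranked_gene_table`, sorted by importance
#'   descending, with columns `gene`, `importance`, `rank`, `is_surface`
#'   (`NA` until [intersect_surfaceome()]); attributes `test_auc`,
#'   `validation_auc`, `mtry`, `seed`.
#' @export
rank_features <- function(sce, labels, n_trees = 1000, split = c(0.6, 0.2, 0.2),
                          cv_folds = 10, mtry = NULL, genes = NULL, seed = 1L) {
  x <- if (methods::is(sce, "SingleCellExperiment")) {
    SummarizedExperiment::assay(sce, "lognorm")
  } else sce
  if (!is.null(genes)) x <- x[intersect(genes, rownames(x)), , drop = FALSE]
  x <- t(as.matrix(x))  # cells x genes
  labels <- factor(labels)
  if (nlevels(labels) != 2) {
    stop("labels must contain exactly two classes", call. = FALSE)
  }
  positive <- levels(labels)[2]
  set.seed(derive_seed(seed, "rf-split"))
  part <- stratified_split(labels, split)

  x_train <- x[part == 1L, , drop = FALSE]; y_train <- labels[part == 1L]
  x_test <- x[part == 2L, , drop = FALSE]; y_test <- labels[part == 2L]
  x_val <- x[part == 3L, , drop = FALSE]; y_val <- labels[part == 3L]

  if (length(mtry) > 1) {
    folds <- sample(rep_len(seq_len(cv_folds), nrow(x_train)))
    cv_auc <- vapply(mtry, function(m) {
      mean(vapply(seq_len(cv_folds), function(f) {
        fit <- ranger::ranger(x = x_train[folds != f, , drop = FALSE],
                              y = y_train[folds != f],
                              num.trees = n_trees, mtry = m,
                              num.threads = 1,
                              seed = derive_seed(seed, paste0("cv", f, "m", m)))
        sc <- ranger_scores(fit, x_train[folds == f, , drop = FALSE], positive)
        roc_curve(sc, y_train[folds == f] == positive)$auc
      }, numeric(1)))
    }, numeric(1))
    mtry <- mtry[which.max(cv_auc)]
  }

  fit <- ranger::ranger(x = x_train, y = y_train, num.trees = n_trees,
                        mtry = mtry, importance = "permutation",
                        num.threads = 1, seed = derive_seed(seed, "rf-final"))
  test_auc <- roc_curve(ranger_scores(fit, x_test, positive),
                        y_test == positive)$auc
  val_auc <- roc_curve(ranger_scores(fit, x_val, positive),
                       y_val == positive)$auc

  imp <- fit$variable.importance
  ord <- order(-imp, names(imp))
  out <- data.frame(gene = names(imp)[ord], importance = unname(imp)[ord],
                    rank = seq_along(imp), is_surface = NA,
                    stringsAsFactors = FALSE)
  class(out) <- c("ranked_gene_table", "data.frame")
  attr(out, "test_auc") <- test_auc
  attr(out, "validation_auc") <- val_auc
  attr(out, "mtry") <- fit$mtry
  attr(out, "seed") <- seed
  out
}

#' @export
print.ranked_gene_table <- function(x, ...) {
  cat(sprintf("Ranked gene table: %d genes; test AUC %.3f, validation AUC %.3f\n",
              nrow(x), attr(x, "test_auc"), attr(x, "validation_auc")))
  print.data.frame(utils::head(x, 10), ...)
  if (nrow(x) > 10) cat(sprintf("... and %d more genes\n", nrow(x) - 10))
  invisible(x)
}

#' Read a surfaceome gene list
#'
#' Plain text, one gene symbol per line; blank lines and `#` comments are
#' skipped.
#'
#' @param path file path.
#' @return character vector of symbols.
#' @export
read_surfaceome <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Intersect a gene ranking with the surfaceome
#'
#' Marks surfaceome membership on the ranking, then returns the `top_k`
#' highest-importance genes among surfaceome members (rank-then-filter; to
#' pre-restrict the classifier to the surfaceome instead, pass the list as
#' `genes` to [rank_features()]).
#'
#' @param ranking a `ranked_gene_table` from [rank_features()].
#' @param surface_list character vector of surfaceome gene symbols
#'   (non-empty).
#' @param top_k number of candidates to return (default 100).
#' @return character vector of candidate genes (possibly shorter than
#'   `top_k`, with a warning); the annotated ranking is attached as
#'   attribute `"ranking"`.
#' @export
intersect_surfaceome <- function(ranking, surface_list, top_k = 100) {
  if (length(surface_list) == 0) {
    stop("surface_list is empty", call. = FALSE)
  }
  ranking$is_surface <- ranking$gene %in% surface_list
  hits <- ranking$gene[ranking$is_surface]
  if (length(hits) == 0) {
    warning("no ranked gene is on the surfaceome list", call. = FALSE)
  } else if (length(hits) < top_k) {
    warning(sprintf("only %d surfaceome genes available (top_k = %d)",
                    length(hits), top_k), call. = FALSE)
  }
  out <- utils::head(hits, top_k)
  attr(out, "ranking") <- ranking
  out
}
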