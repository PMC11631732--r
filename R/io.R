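# Plain-text readers/writers for the pipeline's interchange formats:
# MatrixMarket counts with TSV sidecars, and CSV tables.

#' Write a single-cell cohort as MTX + TSV sidecars
#'
#' @param sce a `SingleCellExperiment` with a `counts` assay.
#' @param dir output directory (created if needed); writes `matrix.mtx`,
#'   `genes.tsv` and `cells.tsv`.
#' @return `dir`, invisibly.
#' @export
write_sc_inputs <- function(sce, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(sce_counts(sce), file.path(dir, "matrix.mtx"))
  genes <- as.data.frame(SummarizedExperiment::rowData(sce))
  genes <- cbind(symbol = rownames(sce), genes[setdiff(names(genes), "symbol")])
  utils::write.table(genes, file.path(dir, "genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cells <- as.data.frame(SummarizedExperiment::colData(sce))
  cells <- cbind(cell = colnames(sce), cells)
  utils::write.table(cells, file.path(dir, "cells.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a single-cell cohort written by [write_sc_inputs()]
#'
#' @param dir directory containing `matrix.mtx`, `genes.tsv`, `cells.tsv`.
#' @return a `SingleCellExperiment` with the `counts` assay and metadata
#'   columns restored.
#' @export
read_sc_inputs <- function(dir) {
  counts <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")),
                        "CsparseMatrix")
  genes <- utils::read.delim(file.path(dir, "genes.tsv"), stringsAsFactors = FALSE)
  cells <- utils::read.delim(file.path(dir, "cells.tsv"), stringsAsFactors = FALSE)
  stopifnot(nrow(genes) == nrow(counts), nrow(cells) == ncol(counts))
  rownames(counts) <- genes$symbol
  colnames(counts) <- cells$cell
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(cells[setdiff(names(cells), "cell")],
                                   row.names = cells$cell),
    rowData = S4Vectors::DataFrame(genes[setdiff(names(genes), "symbol")],
                                   row.names = genes$symbol)
  )
}

#' Read an IHC staining table
#'
#' CSV with columns `sample_id`, `marker`, `pct_1plus`, `pct_2plus`,
#' `pct_3plus` (or already `pct_weak`/`pct_moderate`/`pct_strong`).
#'
#' @param path CSV path.
#' @return validated IHC record table ([ihc_record()]).
#' @export
read_ihc_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  ren <- c(pct_1plus = "pct_weak", pct_2plus = "pct_moderate",
           pct_3plus = "pct_strong")
  for (old in names(ren)) {
    if (old %in% names(df)) names(df)[names(df) == old] <- ren[[old]]
  }
  ihc_record(df$sample_id, df$marker, df$pct_weak, df$pct_moderate, df$pct_strong)
}
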