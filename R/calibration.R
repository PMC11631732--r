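# Cross-modality calibration: TPM conversion, ROC/AUC against IHC-derived
# labels, Youden threshold selection, and cohort coverage estimation.

#' Convert raw counts to TPM
#'
#' Transcripts per million: per-gene counts are divided by effective gene
#' length to give a rate, and rates are rescaled to sum to 1e6 per sample.
#'
#' @param counts non-negative count vector or genes-by-samples matrix.
#' @param lengths positive effective lengths, one per gene.
#' @return TPM values with the shape of `counts`; each sample sums to 1e6.
#' @export
tpm_from_counts <- function(counts, lengths) {
  assert_positive(lengths, "effective lengths")
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (is.matrix(counts)) {
    rate <- counts / lengths
    tot <- colSums(rate)
    if (any(tot == 0)) stop("sample with all-zero counts", call. = FALSE)
    sweep(rate, 2, tot, "/") * 1e6
  } else {
    rate <- counts / lengths
    tot <- sum(rate)
    if (tot == 0) stop("sample with all-zero counts", call. = FALSE)
    rate / tot * 1e6
  }
}

#' log2(TPM + 1) transform
#' @param tpm non-negative TPM values.
#' @return `log2(tpm + 1)`.
#' @export
log2p1 <- function(tpm) {
  if (any(tpm < 0)) stop("TPM values must be non-negative", call. = FALSE)
  log2(tpm + 1)
}

#' ROC curve and AUC for a continuous score against binary labels
#'
#' Sweeps classification thresholds over the unique score values (a sample is
#' called positive when its score is >= the threshold) and records the
#' true-positive and false-positive rates at each. The AUC is computed by the
#' trapezoid rule and equals the Mann-Whitney concordance probability, with
#' tied (positive, negative) score pairs counted one half.
#'
#' @param scores numeric score per sample (here log2(TPM+1)).
#' @param labels binary truth per sample (logical, or 0/1); here IHC
#'   positivity, typically H-score > 0.
#' @return object of class `taa_roc`: list with `points` (data.frame of
#'   threshold, fpr, tpr from (1,1) up to (0,0)), `auc`, `n_pos`, `n_neg`.
#' @examples
#' roc <- roc_curve(c(0.9, 0.6, 0.4, 0.2), c(1, 0, 1, 0))
#' roc$auc  # 0.75: 3 of 4 (positive, negative) pairs concordant
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    stop("both classes must be present to build a ROC curve", call. = FALSE)
  }
  s <- sort(unique(scores))
  # thresholds: below the minimum (everything positive), then each unique score
  thr <- c(-Inf, s)
  tpr <- vapply(thr, function(t) sum(scores[labels] >= t) / n_pos, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores[!labels] >= t) / n_neg, numeric(1))
  # append the all-negative endpoint (0,0)
  pts <- data.frame(threshold = c(thr, Inf), fpr = c(fpr, 0), tpr = c(tpr, 0))
  # trapezoid rule over the curve ordered by increasing fpr
  o <- order(pts$fpr, pts$tpr)
  fx <- pts$fpr[o]; fy <- pts$tpr[o]
  auc <- sum(diff(fx) * (utils::head(fy, -1) + utils::tail(fy, -1)) / 2)
  structure(
    list(points = pts, auc = auc, n_pos = n_pos, n_neg = n_neg,
         scores = scores, labels = labels),
    class = "taa_roc"
  )
}

#' @export
print.taa_roc <- function(x, ...) {
  cat(sprintf("ROC curve: AUC = %.4f (%d positive / %d negative labels)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' Youden's optimal threshold from a ROC curve
#'
#' Maximizes Youden's J = TPR - FPR over thresholds. The reported cut-off is
#' the midpoint between the two adjacent unique scores straddling the optimal
#' operating point; ties in J are broken towards the smallest cut-off
#' (maximal sensitivity).
#'
#' @param roc object from [roc_curve()].
#' @return list with `theta` (the cut-off, in score units), `j` (Youden's J),
#'   `sensitivity` and `specificity` at the cut-off.
#' @export
youden_threshold <- function(roc) {
  stopifnot(inherits(roc, "taa_roc"))
  s <- sort(unique(roc$scores))
  # candidate cut-offs: midpoints between adjacent unique scores, plus the
  # unique scores themselves as degenerate ends
  if (length(s) == 1) {
    return(list(theta = s, j = 0, sensitivity = 1, specificity = 0))
  }
  mid <- (utils::head(s, -1) + utils::tail(s, -1)) / 2
  cand <- sort(unique(c(s[1], mid, s[length(s)])))
  tpr <- vapply(cand, function(t) mean(roc$scores[roc$labels] >= t), numeric(1))
  fpr <- vapply(cand, function(t) mean(roc$scores[!roc$labels] >= t), numeric(1))
  j <- tpr - fpr
  best <- which(j == max(j))[1]  # candidates sorted ascending: smallest theta wins
  list(theta = cand[best], j = j[best],
       sensitivity = tpr[best], specificity = 1 - fpr[best])
}

#' Calibrate an RNA cut-off for a marker from paired IHC/RNA samples
#'
#' Convenience wrapper: builds the ROC of log2(TPM+1) scores against IHC
#' positivity labels (H-score > `label_cutoff`) and selects the Youden
#' threshold.
#'
#' @param panel data.frame with columns `log2_tpm1` and either `h_score` or
#'   the three staining percentage columns accepted by [h_score()].
#' @param marker marker name recorded in the result.
#' @param label_cutoff H-score above which a sample counts as IHC positive
#'   (default 0, i.e. any staining).
#' @return list with `marker`, `roc`, `auc`, `theta`, `j`, `n_pos`, `n_neg`.
#' @export
calibrate_marker <- function(panel, marker = "marker", label_cutoff = 0) {
  if (is.null(panel$h_score)) panel <- h_score(panel)
  labels <- panel$h_score > label_cutoff
  roc <- roc_curve(panel$log2_tpm1, labels)
  yt <- youden_threshold(roc)
  list(marker = marker, roc = roc, auc = roc$auc, theta = yt$theta, j = yt$j,
       sensitivity = yt$sensitivity, specificity = yt$specificity,
       n_pos = roc$n_pos, n_neg = roc$n_neg)
}

#' Apply calibrated cut-offs to a cohort expression table
#'
#' A sample is positive for a marker when its log2(TPM+1) expression is
#' greater than or equal to the marker's cut-off (closed boundary), and
#' dual-positive when positive for every marker supplied. Percentages use the
#' half-up one-decimal rounding of [cohort_positivity_rate()].
#'
#' @param expr data.frame or matrix of cohort expression, samples in rows,
#'   markers in named columns, log2(TPM+1) scale.
#' @param cutoffs named numeric vector of cut-offs, names matching columns of
#'   `expr`.
#' @return list with per-marker summaries (`markers`), the dual-positivity
#'   summary (`dual`), the per-sample dual flags (`dual_flags`) and the
#'   cut-offs used.
#' @export
apply_cutoffs <- function(expr, cutoffs) {
  expr <- as.data.frame(expr)
  missing <- setdiff(names(cutoffs), colnames(expr))
  if (length(missing) > 0) {
    stop("markers absent from expression table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  calls <- lapply(names(cutoffs), function(m) expr[[m]] >= cutoffs[[m]])
  names(calls) <- names(cutoffs)
  markers <- lapply(calls, cohort_positivity_rate)
  dual_flags <- Reduce(`&`, calls)
  list(markers = markers, dual = cohort_positivity_rate(dual_flags),
       dual_flags = dual_flags, cutoffs = cutoffs)
}

#' Published reference cut-offs and AUCs
#'
#' The log2(TPM+1) cut-offs (EGFR 2.23, MUC1 1.5) and LUAD PDX AUCs (EGFR
#' 0.97, MUC1 0.6) reported for the original patient-derived xenograft
#' calibration. Shipped as documented constants for comparison; re-deriving
#' them requires the original paired PDX RNA/IHC data.
#'
#' @format named list with `cutoffs` and `aucs`, each a named numeric vector.
#' @export
taa_reference_cutoffs <- list(
  cutoffs = c(EGFR = 2.23, MUC1 = 1.5),
  aucs = c(EGFR = 0.97, MUC1 = 0.6)
)
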