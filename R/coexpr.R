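# Anchor/partner co-expression at single-cell resolution: per-patient,
# per-cell-group dual-positive fractions, patient-level threshold summaries,
# and the malignant-vs-stromal rank-sum comparison.

#' Co-expression fraction for one cell set
#'
#' Fraction of cells in which both the anchor and the partner gene have raw
#' count > 0. Like the ECF, this is defined on raw counts and is symmetric in
#' the two genes.
#'
#' @param sce a `SingleCellExperiment` with a `counts` assay, or a
#'   genes-by-cells count matrix.
#' @param anchor,partner gene symbols.
#' @param cells selector of the cell set (`NULL` = all cells).
#' @param group,patient labels recorded in the record.
#' @return one-row data.frame: `patient`, `group`, `anchor`, `partner`,
#'   `n_cells`, `n_dual`, `fraction` (NA when `n_cells` is 0).
#' @export
coexpression_fraction <- function(sce, anchor, partner, cells = NULL,
                                  group = "all", patient = "all") {
  counts <- if (methods::is(sce, "SingleCellExperiment")) sce_counts(sce) else sce
  for (g in c(anchor, partner)) {
    if (!g %in% rownames(counts)) {
      stop(sprintf("gene '%s' not present", g), call. = FALSE)
    }
  }
  a <- counts[anchor, , drop = TRUE]
  b <- counts[partner, , drop = TRUE]
  if (!is.null(cells)) { a <- a[cells]; b <- b[cells] }
  n <- length(a)
  n_dual <- sum(a > 0 & b > 0)
  data.frame(patient = patient, group = group, anchor = anchor,
             partner = partner, n_cells = n, n_dual = n_dual,
             fraction = if (n > 0) n_dual / n else NA_real_,
             stringsAsFactors = FALSE)
}

#' All per-patient, per-cell-group co-expression records
#'
#' Computes [coexpression_fraction()] for every (patient, cell group)
#' combination present in the cohort. Groups with fewer than `min_cells`
#' cells are flagged (`valid = FALSE`) and excluded from downstream
#' summaries and tests, since their fraction estimates are unstable.
#'
#' @param sce a `SingleCellExperiment` whose `colData` has `patient` and
#'   `cell_type` columns.
#' @param anchor,partner gene symbols.
#' @param min_cells minimal group size for a record to count (default 10).
#' @return data.frame of records with a `valid` column.
#' @export
coexpression_records <- function(sce, anchor, partner, min_cells = 10) {
  cd <- SummarizedExperiment::colData(sce)
  combos <- unique(data.frame(patient = cd$patient, group = cd$cell_type,
                              stringsAsFactors = FALSE))
  recs <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    sel <- cd$patient == combos$patient[i] & cd$cell_type == combos$group[i]
    coexpression_fraction(sce, anchor, partner, cells = sel,
                          group = combos$group[i], patient = combos$patient[i])
  }))
  recs$valid <- recs$n_cells >= min_cells
  recs[order(recs$group, recs$patient), , drop = FALSE]
}

#' Fraction of patients above a co-expression threshold, per cell group
#'
#' For each cell group, the proportion of patients whose co-expression
#' fraction strictly exceeds `threshold` (default 10%).
#'
#' @param records output of [coexpression_records()]; invalid records are
#'   dropped.
#' @param threshold co-expression fraction cut (strict inequality).
#' @return data.frame with `group`, `n_patients`, `n_above`,
#'   `patient_fraction`.
#' @export
patient_threshold_summary <- function(records, threshold = 0.10) {
  keep <- !is.na(records$fraction)
  if (!is.null(records$valid)) keep <- keep & records$valid
  records <- records[keep, , drop = FALSE]
  out <- do.call(rbind, lapply(split(records, records$group), function(d) {
    data.frame(group = d$group[1], n_patients = nrow(d),
               n_above = sum(d$fraction > threshold),
               patient_fraction = mean(d$fraction > threshold),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Compare malignant vs stromal co-expression fractions
#'
#' Two-sided Wilcoxon rank-sum test of the per-patient malignant
#' co-expression fractions against the pooled per-(patient, stromal group)
#' fractions. The exact distribution is used for small untied samples
#' (both sides <= `exact_max`); otherwise the normal approximation with tie
#' and continuity correction applies.
#'
#' @param records output of [coexpression_records()].
#' @param malignant_group name of the malignant cell group.
#' @param exact_max maximal per-side size for the exact test (default 12).
#' @return list with `statistic` (rank-sum W), `p_value`, per-side `n` and
#'   medians.
#' @export
compare_malignant_vs_stromal <- function(records, malignant_group = "malignant",
                                         exact_max = 12) {
  records <- records[(records$valid %||% TRUE) & !is.na(records$fraction), ,
                     drop = FALSE]
  mal <- records$fraction[records$group == malignant_group]
  str <- records$fraction[records$group != malignant_group]
  if (length(mal) < 2 || length(str) < 2) {
    stop("need at least two observations on each side", call. = FALSE)
  }
  if (diff(range(c(mal, str))) == 0) {
    # every observation tied: no evidence either way
    return(list(statistic = length(mal) * length(str) / 2, p_value = 1,
                n_malignant = length(mal), n_stromal = length(str),
                median_malignant = stats::median(mal),
                median_stromal = stats::median(str)))
  }
  ties <- anyDuplicated(c(mal, str)) > 0
  exact <- !ties && max(length(mal), length(str)) <= exact_max
  wt <- stats::wilcox.test(mal, str, alternative = "two.sided", exact = exact,
                           correct = TRUE)
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       n_malignant = length(mal), n_stromal = length(str),
       median_malignant = stats::median(mal), median_stromal = stats::median(str))
}

#' Screen candidate partner genes against an anchor
#'
#' Computes co-expression records for each partner, the per-group patient
#' threshold summaries, and two partner rankings: by median malignant
#' fraction (potency view) and by maximal stromal fraction (specificity
#' view, smaller is better).
#'
#' @param sce a `SingleCellExperiment` with `patient` and `cell_type`
#'   metadata.
#' @param anchor anchor gene symbol.
#' @param partners candidate partner symbols; partners absent from the
#'   matrix are skipped with a warning.
#' @param threshold patient-level co-expression threshold (default 0.10).
#' @param min_cells minimal group size per record.
#' @param malignant_group name of the malignant cell group.
#' @return list with `records` (all partners stacked), `summary` (one row
#'   per partner: median malignant fraction, max stromal fraction, patient
#'   fraction above threshold in malignant cells, rank on each view).
#' @export
partner_screen <- function(sce, anchor, partners = c("MUC1", "MET", "ERBB3", "TACSTD2"),
                           threshold = 0.10, min_cells = 10,
                           malignant_group = "malignant") {
  present <- partners[partners %in% rownames(sce)]
  absent <- setdiff(partners, present)
  if (length(absent) > 0) {
    warning("partners absent from matrix, skipped: ",
            paste(absent, collapse = ", "), call. = FALSE)
  }
  if (length(present) == 0) stop("no partner gene present", call. = FALSE)
  recs <- do.call(rbind, lapply(present, function(p) {
    coexpression_records(sce, anchor, p, min_cells = min_cells)
  }))
  summ <- do.call(rbind, lapply(present, function(p) {
    d <- recs[recs$partner == p & recs$valid & !is.na(recs$fraction), , drop = FALSE]
    mal <- d$fraction[d$group == malignant_group]
    str <- d$fraction[d$group != malignant_group]
    data.frame(partner = p,
               median_malignant = stats::median(mal),
               max_stromal = if (length(str)) max(str) else NA_real_,
               patients_above = mean(mal > threshold),
               stringsAsFactors = FALSE)
  }))
  summ$rank_potency <- rank(-summ$median_malignant, ties.method = "min")
  summ$rank_specificity <- rank(summ$max_stromal, ties.method = "min")
  rownames(summ) <- NULL
  list(records = recs, summary = summ)
}
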