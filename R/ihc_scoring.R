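# Immunohistochemistry quantification: H-scores, expression tiers,
# sample-level co-positivity and cohort positivity rates.

#' Construct a table of IHC staining records
#'
#' An IHC record holds, for one sample and one marker, the percentage of
#' tumor cells showing weak (1+), moderate (2+) and strong (3+) membranous
#' staining. Percentages are on the 0-100 scale and may not sum past 100
#' (the remainder is unstained).
#'
#' @param sample_id character vector of sample identifiers.
#' @param marker character vector of marker (gene/protein) names.
#' @param pct_weak,pct_moderate,pct_strong percentages of cells at intensity
#'   1+, 2+ and 3+ respectively, each in \[0, 100\].
#' @return a `data.frame` with one row per (sample, marker).
#' @export
ihc_record <- function(sample_id, marker, pct_weak, pct_moderate, pct_strong) {
  df <- data.frame(
    sample_id = as.character(sample_id),
    marker = as.character(marker),
    pct_weak = as.numeric(pct_weak),
    pct_moderate = as.numeric(pct_moderate),
    pct_strong = as.numeric(pct_strong),
    stringsAsFactors = FALSE
  )
  validate_ihc(df)
  df
}

validate_ihc <- function(df) {
  pcts <- df[, c("pct_weak", "pct_moderate", "pct_strong")]
  if (any(!is.finite(as.matrix(pcts))) || any(pcts < 0) || any(pcts > 100)) {
    stop("staining percentages must lie in [0, 100]", call. = FALSE)
  }
  tot <- rowSums(pcts)
  if (any(tot > 100 + 1e-8)) {
    bad <- df$sample_id[tot > 100 + 1e-8][1]
    stop(sprintf("staining percentages sum to more than 100%% for sample '%s'", bad),
         call. = FALSE)
  }
  invisible(df)
}

#' Compute H-scores and expression tiers from IHC records
#'
#' The H-score weights the percentage of cells at each staining intensity by
#' the intensity value: `1*pct_weak + 2*pct_moderate + 3*pct_strong`, giving a
#' value in \[0, 300\]. Tiers are nested: a sample is *positive* if its
#' H-score exceeds 0, *medium* at H-score >= 100 and *high* at H-score >= 200
#' (both cut-offs inclusive); a zero H-score is *negative*.
#'
#' @param records IHC record table as produced by [ihc_record()].
#' @param medium_cutoff,high_cutoff H-score cut-offs for the medium and high
#'   tiers (defaults 100 and 200, inclusive).
#' @return the input table with `h_score` and `tier` columns added; `tier` is
#'   a factor with levels negative < positive < medium < high.
#' @examples
#' h_score(ihc_record("s1", "EGFR", 10, 20, 30))  # H-score 140, tier medium
#' @export
h_score <- function(records, medium_cutoff = 100, high_cutoff = 200) {
  validate_ihc(records)
  value <- records$pct_weak + 2 * records$pct_moderate + 3 * records$pct_strong
  tier <- ifelse(value >= high_cutoff, "high",
          ifelse(value >= medium_cutoff, "medium",
          ifelse(value > 0, "positive", "negative")))
  records$h_score <- value
  records$tier <- factor(tier, levels = c("negative", "positive", "medium", "high"),
                         ordered = TRUE)
  records
}

#' Sample-level dual-marker co-positivity
#'
#' A sample is called co-positive when at least `min_pct` percent of its tumor
#' cells stain positive for *both* markers, regardless of staining intensity
#' (total stained percentage `pct_weak + pct_moderate + pct_strong`).
#'
#' @param rec_a,rec_b single-row IHC records for the two markers, same sample.
#' @param min_pct minimum total stained percentage required for each marker
#'   (default 1, i.e. at least 1% of cells).
#' @return logical flag.
#' @export
sample_co_positive <- function(rec_a, rec_b, min_pct = 1.0) {
  stopifnot(nrow(rec_a) == 1, nrow(rec_b) == 1)
  if (!identical(rec_a$sample_id, rec_b$sample_id)) {
    stop("records belong to different samples: ",
         rec_a$sample_id, " vs ", rec_b$sample_id, call. = FALSE)
  }
  tot_a <- rec_a$pct_weak + rec_a$pct_moderate + rec_a$pct_strong
  tot_b <- rec_b$pct_weak + rec_b$pct_moderate + rec_b$pct_strong
  tot_a >= min_pct && tot_b >= min_pct
}

#' Cohort positivity rate
#'
#' Summarizes a vector of per-sample positivity calls into a count and a
#' percentage, rounded half-up to one decimal (63 of 64 positives prints as
#' 98.4).
#'
#' @param calls logical vector of per-sample calls.
#' @return list with `n_pos`, `n_total` and `percentage`.
#' @export
cohort_positivity_rate <- function(calls) {
  if (length(calls) == 0) stop("no samples supplied", call. = FALSE)
  stopifnot(is.logical(calls))
  n_pos <- sum(calls)
  n_total <- length(calls)
  list(n_pos = n_pos, n_total = n_total,
       percentage = round_half_up(100 * n_pos / n_total, 1))
}

tier_threshold_met <- function(h, tier) {
  switch(tier,
    positive = h > 0,
    medium = h >= 100,
    high = h >= 200,
    stop(sprintf("unknown tier '%s'", tier), call. = FALSE)
  )
}

#' Dual-marker tier co-occurrence
#'
#' Flags samples in which both markers reach an expression tier: positive
#' (H-score > 0), medium (H-score >= 100) or high (H-score >= 200).
#'
#' @param scored_a,scored_b H-scored tables ([h_score()]) for the two markers,
#'   with matching `sample_id` order; or single rows for one sample.
#' @param tier one of "positive", "medium", "high".
#' @return logical vector of per-sample co-occurrence flags, plus the cohort
#'   summary from [cohort_positivity_rate()] as attribute `"summary"`.
#' @export
tier_co_occurrence <- function(scored_a, scored_b, tier = c("medium", "positive", "high")) {
  tier <- match.arg(tier)
  if (!identical(scored_a$sample_id, scored_b$sample_id)) {
    stop("sample ids of the two markers do not align", call. = FALSE)
  }
  flags <- tier_threshold_met(scored_a$h_score, tier) &
           tier_threshold_met(scored_b$h_score, tier)
  attr(flags, "summary") <- cohort_positivity_rate(flags)
  flags
}
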