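# Synthetic-data generators with known ground truth for every input modality
# the pipeline consumes: multi-batch single-cell UMI counts, paired IHC/RNA
# panels, and survival cohorts with configurable dual-positivity and hazard.

TAA_CELL_TYPES <- c("malignant", "epithelial", "fibroblast", "endothelial",
                    "T", "NK", "myeloid", "B")

#' Configuration for the single-cell cohort simulator
#'
#' Counts are drawn from a zero-inflated negative binomial: gene g in a cell
#' of type t is expressed with probability `pi[g, t]` and, if expressed,
#' draws a zero-truncated NB count with untruncated mean `lambda[g, t]`
#' scaled by a multiplicative per-(batch, gene) log-normal effect. The
#' truncation makes `pi` exactly the expressing-cell probability that the
#' ECF statistic estimates. The first `ceiling(mito_gene_fraction * n_genes)` genes
#' carry the "MT-" symbol prefix so that QC has a mitochondrial annotation.
#'
#' @param n_genes,n_patients,n_datasets,cells_per_patient cohort dimensions;
#'   patients are assigned to datasets (batches) round-robin.
#' @param cell_type_proportions named probability vector over the eight cell
#'   types (malignant, epithelial, fibroblast, endothelial, T, NK, myeloid,
#'   B); must sum to 1.
#' @param pi,lambda optional genes-by-types matrices of expression
#'   probabilities and NB means; when `NULL` they are drawn reproducibly from
#'   the seed (see [default_sc_truth()]).
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2);
#'   default 0.5, typical of UMI data.
#' @param mito_gene_fraction fraction of genes flagged as mitochondrial.
#' @param batch_effect_scale sdlog of the log-normal per-(batch, gene)
#'   multiplier; 0 disables batch effects.
#' @param seed integer RNG seed.
#' @return validated config list of class `sc_sim_config`.
#' @export
sc_sim_config <- function(n_genes = 500, n_patients = 5, n_datasets = 2,
                          cells_per_patient = 200,
                          cell_type_proportions = c(
                            malignant = 0.30, epithelial = 0.15,
                            fibroblast = 0.10, endothelial = 0.05,
                            T = 0.15, NK = 0.05, myeloid = 0.15, B = 0.05),
                          pi = NULL, lambda = NULL,
                          dispersion = 0.5, mito_gene_fraction = 0.05,
                          batch_effect_scale = 0.15, seed = 1L) {
  stopifnot(n_genes >= 1, n_patients >= 1, n_datasets >= 1, cells_per_patient >= 1)
  if (is.null(names(cell_type_proportions)) ||
      !all(names(cell_type_proportions) %in% TAA_CELL_TYPES)) {
    stop("cell_type_proportions must be named with the known cell types",
         call. = FALSE)
  }
  assert_prob(cell_type_proportions, "cell type proportions")
  if (abs(sum(cell_type_proportions) - 1) > 1e-8) {
    stop("cell type proportions must sum to 1", call. = FALSE)
  }
  if (!is.null(pi)) assert_prob(pi, "expression probabilities pi")
  if (!is.null(lambda) && any(lambda <= 0)) {
    stop("expression means lambda must be > 0", call. = FALSE)
  }
  if (dispersion < 0) stop("dispersion must be >= 0", call. = FALSE)
  assert_prob(mito_gene_fraction, "mito_gene_fraction")
  structure(list(
    n_genes = as.integer(n_genes), n_patients = as.integer(n_patients),
    n_datasets = as.integer(n_datasets),
    cells_per_patient = as.integer(cells_per_patient),
    cell_type_proportions = cell_type_proportions,
    pi = pi, lambda = lambda, dispersion = dispersion,
    mito_gene_fraction = mito_gene_fraction,
    batch_effect_scale = batch_effect_scale, seed = as.integer(seed)
  ), class = "sc_sim_config")
}

sc_gene_names <- function(config) {
  n_mito <- ceiling(config$mito_gene_fraction * config$n_genes)
  c(if (n_mito > 0) sprintf("MT-G%04d", seq_len(n_mito)),
    sprintf("G%04d", seq_len(config$n_genes - n_mito)))
}

#' Default ground-truth expression parameters for the single-cell simulator
#'
#' Draws, reproducibly from the config seed, a baseline per-gene expression
#' probability shared across cell types (uniform on 0.02-0.45) and a per-gene
#' NB mean (gamma distributed, shifted off zero). Callers can edit the
#' returned matrices — e.g. plant malignant-specific genes — and pass them
#' back through [sc_sim_config()].
#'
#' @param config an [sc_sim_config()].
#' @return list with `pi` and `lambda`, genes-by-types matrices with gene
#'   symbols as row names.
#' @export
default_sc_truth <- function(config) {
  genes <- sc_gene_names(config)
  withr_seed <- derive_seed(config$seed, "sc-truth")
  set.seed(withr_seed)
  # calibrated so a few-hundred-gene panel yields several hundred UMI per
  # cell, the scale at which the standard QC thresholds operate
  base_pi <- stats::runif(config$n_genes, 0.05, 0.50)
  base_lambda <- stats::rgamma(config$n_genes, shape = 3, scale = 1.5) + 1
  types <- names(config$cell_type_proportions)
  pi <- matrix(base_pi, config$n_genes, length(types),
               dimnames = list(genes, types))
  lambda <- matrix(base_lambda, config$n_genes, length(types),
                   dimnames = list(genes, types))
  list(pi = pi, lambda = lambda)
}

#' Simulate a multi-batch tumor/normal single-cell cohort
#'
#' @param config an [sc_sim_config()].
#' @return a [SingleCellExperiment::SingleCellExperiment] with a sparse
#'   `counts` assay; `colData` columns `patient`, `batch`, `cell_type`,
#'   `malignant`, `n_genes_detected`, `total_umi`, `mito_fraction`; `rowData`
#'   column `is_mito`; and the true `pi`/`lambda` matrices plus the config in
#'   `metadata(sce)$truth` / `$config`.
#' @export
simulate_sc_cohort <- function(config) {
  stopifnot(inherits(config, "sc_sim_config"))
  truth <- if (is.null(config$pi) || is.null(config$lambda)) {
    d <- default_sc_truth(config)
    list(pi = config$pi %||% d$pi, lambda = config$lambda %||% d$lambda)
  } else {
    list(pi = config$pi, lambda = config$lambda)
  }
  genes <- rownames(truth$pi) %||% sc_gene_names(config)
  stopifnot(nrow(truth$pi) == config$n_genes,
            identical(dim(truth$pi), dim(truth$lambda)))
  types <- names(config$cell_type_proportions)

  set.seed(derive_seed(config$seed, "sc-cells"))
  patients <- sprintf("P%02d", seq_len(config$n_patients))
  patient_batch <- sprintf("D%d", ((seq_len(config$n_patients) - 1) %% config$n_datasets) + 1)
  names(patient_batch) <- patients
  cell_patient <- rep(patients, each = config$cells_per_patient)
  n_cells <- length(cell_patient)
  cell_batch <- patient_batch[cell_patient]
  cell_type <- sample(types, n_cells, replace = TRUE,
                      prob = config$cell_type_proportions)

  batches <- sort(unique(cell_batch))
  batch_mult <- matrix(
    exp(stats::rnorm(config$n_genes * length(batches), 0, config$batch_effect_scale)),
    config$n_genes, length(batches), dimnames = list(genes, batches))

  size <- if (config$dispersion > 0) 1 / config$dispersion else Inf
  counts <- matrix(0L, config$n_genes, n_cells, dimnames = list(genes, NULL))
  for (b in batches) {
    for (t in types) {
      idx <- which(cell_batch == b & cell_type == t)
      k <- length(idx)
      if (k == 0) next
      mu <- truth$lambda[, t] * batch_mult[, b]
      on <- matrix(stats::rbinom(config$n_genes * k, 1L, rep(truth$pi[, t], k)),
                   config$n_genes, k)
      # zero-truncated draw for the expressed component, so that
      # P(count > 0) is exactly pi (pi is the expressing-cell probability)
      mu_rep <- rep(mu, k)
      p0 <- if (is.finite(size)) (size / (size + mu_rep))^size else exp(-mu_rep)
      u <- p0 + stats::runif(config$n_genes * k) * (1 - p0)
      draw <- if (is.finite(size)) {
        stats::qnbinom(u, mu = mu_rep, size = size)
      } else {
        stats::qpois(u, mu_rep)
      }
      counts[, idx] <- on * matrix(draw, config$n_genes, k)
    }
  }
  colnames(counts) <- sprintf("%s_C%04d", cell_patient, seq_len(n_cells))

  total_umi <- colSums(counts)
  mito <- startsWith(toupper(genes), "MT-")
  mito_umi <- if (any(mito)) colSums(counts[mito, , drop = FALSE]) else rep(0, n_cells)
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = methods::as(counts, "CsparseMatrix")),
    colData = S4Vectors::DataFrame(
      patient = cell_patient, batch = unname(cell_batch),
      cell_type = cell_type, malignant = cell_type == "malignant",
      n_genes_detected = colSums(counts > 0), total_umi = total_umi,
      mito_fraction = ifelse(total_umi > 0, mito_umi / total_umi, 0),
      row.names = colnames(counts)),
    rowData = S4Vectors::DataFrame(symbol = genes, is_mito = mito,
                                   row.names = genes)
  )
  S4Vectors::metadata(sce)$truth <- truth
  S4Vectors::metadata(sce)$config <- config
  sce
}

#' Configuration for the paired IHC/RNA panel simulator
#'
#' Emulates patient-derived xenograft panels in which each sample has both an
#' IHC staining record and an RNA log2(TPM+1) score for one marker. A latent
#' positive/negative state is drawn at `prevalence`; RNA scores for positives
#' are centered `separation/2` standard deviations above the true threshold
#' `true_threshold` and negatives the same distance below, so `separation`
#' controls the achievable AUC. IHC percentages make the H-score positive iff
#' the latent state is positive, except that with probability up to
#' `h_score_noise` (peaking for samples whose RNA score sits near the
#' threshold) the IHC call is flipped, which degrades the AUC.
#'
#' @param n_samples number of paired samples.
#' @param true_threshold latent RNA threshold theta*, log2(TPM+1) units.
#' @param separation distance between class means in units of `rna_sd`
#'   (non-negative).
#' @param prevalence probability of the latent positive state, in (0, 1).
#' @param h_score_noise maximal probability of flipping an IHC call.
#' @param rna_sd within-class standard deviation of the RNA score.
#' @param seed integer RNG seed.
#' @export
paired_sim_config <- function(n_samples = 60, true_threshold = 1.5,
                              separation = 3, prevalence = 0.5,
                              h_score_noise = 0, rna_sd = 0.5, seed = 1L) {
  stopifnot(n_samples >= 2, separation >= 0, rna_sd > 0)
  if (prevalence <= 0 || prevalence >= 1) {
    stop("prevalence must lie strictly inside (0, 1)", call. = FALSE)
  }
  assert_prob(h_score_noise, "h_score_noise")
  structure(list(n_samples = as.integer(n_samples),
                 true_threshold = true_threshold, separation = separation,
                 prevalence = prevalence, h_score_noise = h_score_noise,
                 rna_sd = rna_sd, seed = as.integer(seed)),
            class = "paired_sim_config")
}

#' Simulate a paired IHC/RNA calibration panel
#'
#' @param config a [paired_sim_config()].
#' @return data.frame with columns `sample_id`, `pct_weak`, `pct_moderate`,
#'   `pct_strong`, `h_score`, `log2_tpm1` and the latent `true_state`.
#' @export
simulate_paired_panel <- function(config) {
  stopifnot(inherits(config, "paired_sim_config"))
  set.seed(derive_seed(config$seed, "paired-panel"))
  n <- config$n_samples
  state <- stats::rbinom(n, 1L, config$prevalence) == 1L
  shift <- config$separation * config$rna_sd / 2
  mu <- ifelse(state, config$true_threshold + shift, config$true_threshold - shift)
  score <- pmax(stats::rnorm(n, mu, config$rna_sd), 0)

  ihc_state <- state
  if (config$h_score_noise > 0) {
    # flips concentrate on samples whose RNA score sits near the threshold
    closeness <- exp(-((score - config$true_threshold) / config$rna_sd)^2 / 2)
    flip <- stats::runif(n) < config$h_score_noise * closeness
    ihc_state <- xor(ihc_state, flip)
  }

  total <- ifelse(ihc_state, stats::runif(n, 20, 100), 0)
  w <- matrix(stats::rgamma(3 * n, shape = 1), n, 3)
  w <- w / rowSums(w)
  rec <- ihc_record(sample_id = sprintf("S%03d", seq_len(n)),
                    marker = "marker",
                    pct_weak = total * w[, 1],
                    pct_moderate = total * w[, 2],
                    pct_strong = total * w[, 3])
  rec <- h_score(rec)
  rec$log2_tpm1 <- score
  rec$true_state <- state
  rec
}

#' Configuration for the survival-cohort simulator
#'
#' Emulates a TCGA-style cohort: per-gene latent positivity states drawn
#' independently at configured fractions, well-separated log2(TPM+1)
#' expression for positive vs negative states, tumor stages drawn from a
#' categorical distribution, and exponential survival whose hazard is
#' multiplied by `hazard_ratio` for samples positive for both genes.
#' Censored samples (a `censoring_rate` fraction) have their time drawn
#' uniformly before the latent event time.
#'
#' @param n_samples cohort size.
#' @param positivity named vector of per-gene true positivity fractions; the
#'   defaults mirror reported TCGA-LUAD rates for EGFR (0.975) and MUC1 (1).
#' @param mean_pos,sd_pos,mean_neg,sd_neg normal expression parameters for
#'   the positive and negative states, log2(TPM+1) scale.
#' @param stage_probs named probabilities over stages I-IV.
#' @param baseline_hazard events per day for non-dual-positive samples.
#' @param hazard_ratio multiplicative hazard for dual-positive samples (> 0).
#' @param censoring_rate expected fraction of censored samples, in \[0, 1\].
#' @param seed integer RNG seed.
#' @export
cohort_sim_config <- function(n_samples = 500,
                              positivity = c(EGFR = 0.975, MUC1 = 1.0),
                              mean_pos = 4, sd_pos = 0.6,
                              mean_neg = 0.5, sd_neg = 0.3,
                              stage_probs = c(I = 0.30, II = 0.25, III = 0.30, IV = 0.15),
                              baseline_hazard = 1 / 1000,
                              hazard_ratio = 2,
                              censoring_rate = 0.3, seed = 1L) {
  stopifnot(n_samples >= 1, length(positivity) >= 1, !is.null(names(positivity)))
  assert_prob(positivity, "positivity fractions")
  assert_prob(censoring_rate, "censoring_rate")
  assert_positive(hazard_ratio, "hazard_ratio")
  assert_positive(baseline_hazard, "baseline_hazard")
  stopifnot(identical(sort(names(stage_probs)), sort(c("I", "II", "III", "IV"))),
            abs(sum(stage_probs) - 1) < 1e-8)
  structure(list(n_samples = as.integer(n_samples), positivity = positivity,
                 mean_pos = mean_pos, sd_pos = sd_pos,
                 mean_neg = mean_neg, sd_neg = sd_neg,
                 stage_probs = stage_probs, baseline_hazard = baseline_hazard,
                 hazard_ratio = hazard_ratio, censoring_rate = censoring_rate,
                 seed = as.integer(seed)),
            class = "cohort_sim_config")
}

#' Simulate an expression + clinical cohort
#'
#' @param config a [cohort_sim_config()].
#' @return list with `expression` (data.frame: sample_id plus one log2(TPM+1)
#'   column per gene), `clinical` (sample_id, time, event, stage) and `truth`
#'   (the latent per-gene positivity states and the dual-positive flag).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_sim_config"))
  set.seed(derive_seed(config$seed, "cohort"))
  n <- config$n_samples
  genes <- names(config$positivity)
  states <- sapply(genes, function(g) stats::rbinom(n, 1L, config$positivity[[g]]) == 1L)
  states <- matrix(states, nrow = n, dimnames = list(NULL, genes))
  expr <- apply(states, 2, function(s) {
    pmax(ifelse(s, stats::rnorm(n, config$mean_pos, config$sd_pos),
                stats::rnorm(n, config$mean_neg, config$sd_neg)), 0)
  })
  dual <- rowSums(states) == length(genes)
  hazard <- config$baseline_hazard * ifelse(dual, config$hazard_ratio, 1)
  event_time <- stats::rexp(n, rate = hazard)
  censored <- stats::rbinom(n, 1L, config$censoring_rate) == 1L
  time <- ifelse(censored, stats::runif(n, 0, event_time), event_time)
  time <- pmax(time, 1e-6)
  stage <- sample(names(config$stage_probs), n, replace = TRUE,
                  prob = config$stage_probs)
  sample_id <- sprintf("T%04d", seq_len(n))
  list(
    expression = data.frame(sample_id = sample_id, expr,
                            check.names = FALSE, stringsAsFactors = FALSE),
    clinical = data.frame(sample_id = sample_id, time = time,
                          event = as.integer(!censored), stage = stage,
                          stringsAsFactors = FALSE),
    truth = data.frame(sample_id = sample_id, states, dual_positive = dual,
                       check.names = FALSE, stringsAsFactors = FALSE)
  )
}
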