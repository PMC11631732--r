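# End-to-end runner: simulate -> preprocess -> screen -> coexpr -> ihc ->
# calibrate -> coverage -> survive, with every intermediate written to disk
# and a machine-readable report.

#' Pipeline configuration
#'
#' One nested list drives the whole run. Numeric defaults follow the
#' conventions used throughout the package: QC at 3 genes / 200 UMI / 20%
#' mito, 2000 HVG (capped at the gene count), 30 principal components,
#' 1000-tree forest with a 6:2:2 split, top-100 surfaceome candidates,
#' raw-count co-expression with a 10% patient threshold, H-score tiers at
#' 100/200, the 1% dual co-positivity rule, and stage III/IV survival with a
#' median split. The demo problem sizes are deliberately small so a full run
#' takes well under five minutes on one CPU.
#'
#' @param seed global integer seed; every stochastic stage derives its own
#'   stream from it.
#' @param anchor anchor gene (default "EGFR").
#' @param partners candidate partner genes.
#' @param sc,qc,screen,coexpr,paired,cohort,survival per-stage parameter
#'   lists; any entry supplied here overrides the default.
#' @return nested configuration list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, anchor = "EGFR",
                            partners = c("MUC1", "MET", "ERBB3", "TACSTD2"),
                            sc = list(), qc = list(), screen = list(),
                            coexpr = list(), paired = list(), cohort = list(),
                            survival = list()) {
  merge_block <- function(defaults, user) {
    defaults[names(user)] <- user
    defaults
  }
  cfg <- list(
    seed = as.integer(seed), anchor = anchor, partners = partners,
    sc = merge_block(list(n_genes = 300, n_patients = 6, n_datasets = 2,
                          cells_per_patient = 150, dispersion = 0.5,
                          mito_gene_fraction = 0.05, batch_effect_scale = 0.15),
                     sc),
    qc = merge_block(list(min_genes_detected = 3, min_umi = 200,
                          max_mito_fraction = 0.20), qc),
    screen = merge_block(list(n_trees = 1000, split = c(0.6, 0.2, 0.2),
                              cv_folds = 10, top_k = 100, hvg_k = 2000,
                              n_components = 30, ridge_lambda = 1.0), screen),
    coexpr = merge_block(list(threshold = 0.10, min_cells = 10), coexpr),
    paired = merge_block(list(n_samples = 200, separation = 3,
                              prevalence = 0.5, h_score_noise = 0,
                              true_thresholds = c(EGFR = 2.23, MUC1 = 1.5)),
                         paired),
    cohort = merge_block(list(n_samples = 500,
                              positivity = c(EGFR = 0.975, MUC1 = 1.0),
                              hazard_ratio = 2, censoring_rate = 0.3), cohort),
    survival = merge_block(list(rule = "median", stage_filter = c("III", "IV"),
                                contrast = "high_vs_rest"), survival)
  )
  structure(cfg, class = "pipeline_config")
}

# Ground truth for the demo cohort: anchor and partners are planted with
# malignant-enriched expression; MUC1 is the tumor-specific partner while
# MET/ERBB3/TACSTD2 leak into stromal populations to different degrees.
planted_sc_truth <- function(sc_config, anchor, partners) {
  truth <- default_sc_truth(sc_config)
  genes <- rownames(truth$pi)
  planted <- c(anchor, partners)
  slots <- genes[!startsWith(genes, "MT-")][seq_along(planted)]
  rownames(truth$pi)[match(slots, genes)] <- planted
  rownames(truth$lambda) <- rownames(truth$pi)
  stromal <- setdiff(colnames(truth$pi), c("malignant", "epithelial"))
  set_gene <- function(g, mal, epi, str) {
    truth$pi[g, ] <<- str
    truth$pi[g, "malignant"] <<- mal
    truth$pi[g, "epithelial"] <<- epi
    truth$lambda[g, ] <<- 3
  }
  set_gene(anchor, 0.80, 0.40, 0.15)
  if (length(partners) >= 1) set_gene(partners[1], 0.70, 0.30, 0.04)  # specific
  for (p in partners[-1]) set_gene(p, 0.55, 0.35, 0.30)               # leaky
  truth
}

stage_msg <- function(log, fmt, ...) {
  line <- sprintf(paste0("[%s] ", fmt), format(Sys.time(), "%H:%M:%S"), ...)
  c(log, line)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full dual-TAA pipeline on simulated inputs
#'
#' Executes, in order: single-cell simulation, QC, normalization, HVG
#' selection, PCA, ridge batch correction, random-forest screening with
#' surfaceome intersection, anchor/partner co-expression analysis, paired
#' IHC/RNA panel simulation with H-scoring and ROC/Youden calibration,
#' cohort simulation with coverage estimation, and stage III/IV survival
#' stratification. Every intermediate table is written under `outdir` and a
#' JSON report summarizes the headline numbers. Rerunning with the same
#' config and seed reproduces the report bit for bit.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory.
#' @return the report (named list), invisibly also written to
#'   `outdir/report.json`; the report digest is in `$report_md5` of the
#'   returned attributes and in `outdir/report.md5`.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = tempfile("dualtaa_")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log <- character()

  # config + hash: every output of the run is tied to this hash
  config_path <- file.path(outdir, "config.json")
  jsonlite::write_json(unclass(config), config_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  config_hash <- unname(tools::md5sum(config_path))
  log <- stage_msg(log, "config hash %s", config_hash)

  # -- simulate single-cell cohort ------------------------------------------
  sc <- run_stage("simulate", {
    sc_cfg <- do.call(sc_sim_config, c(config$sc, list(seed = derive_seed(config$seed, "sc"))))
    truth <- planted_sc_truth(sc_cfg, config$anchor, config$partners)
    sc_cfg <- do.call(sc_sim_config, c(config$sc,
                                       list(pi = truth$pi, lambda = truth$lambda,
                                            seed = derive_seed(config$seed, "sc"))))
    simulate_sc_cohort(sc_cfg)
  })
  write_sc_inputs(sc, file.path(outdir, "sc_raw"))
  log <- stage_msg(log, "simulated %d genes x %d cells", nrow(sc), ncol(sc))

  # -- preprocess ------------------------------------------------------------
  qc <- run_stage("qc", do.call(qc_thresholds, config$qc))
  qcres <- run_stage("qc", qc_filter(sc, qc))
  utils::write.csv(as.data.frame(qcres$report[1:6]),
                   file.path(outdir, "qc_report.csv"), row.names = FALSE)
  sce <- run_stage("normalize", normalize_log(qcres$sce))
  hvg <- run_stage("hvg", select_hvg(sce, k = min(config$screen$hvg_k, nrow(sce))))
  emb <- run_stage("pca", pca_embed(sce, genes = hvg,
                                    n_components = min(config$screen$n_components,
                                                       length(hvg), ncol(sce))))
  corrected <- run_stage("batch-correct",
                         regress_batch(emb$scores, sce$batch,
                                       ridge_lambda = config$screen$ridge_lambda))
  utils::write.csv(data.frame(cell = rownames(corrected), corrected),
                   file.path(outdir, "embedding.csv"), row.names = FALSE)
  log <- stage_msg(log, "QC retained %d/%d cells; %d HVG; %d PCs",
                   qcres$report$n_retained, qcres$report$n_input,
                   length(hvg), ncol(corrected))

  # -- screen ----------------------------------------------------------------
  surfaceome <- run_stage("screen", {
    genes <- rownames(sce)
    non_mito <- genes[!startsWith(genes, "MT-")]
    sort(unique(c(config$anchor, config$partners,
                  non_mito[seq(1, length(non_mito), by = 3)])))
  })
  writeLines(surfaceome, file.path(outdir, "surfaceome.txt"))
  ranking <- run_stage("screen", {
    rank_features(sce, ifelse(sce$malignant, "tumor", "normal"),
                  n_trees = config$screen$n_trees, split = config$screen$split,
                  cv_folds = config$screen$cv_folds,
                  seed = derive_seed(config$seed, "screen"))
  })
  candidates <- run_stage("screen",
                          intersect_surfaceome(ranking, surfaceome,
                                               top_k = config$screen$top_k))
  utils::write.csv(attr(candidates, "ranking"), file.path(outdir, "ranking.csv"),
                   row.names = FALSE)
  log <- stage_msg(log, "screen: test AUC %.3f; %d surfaceome candidates",
                   attr(ranking, "test_auc"), length(candidates))

  # -- co-expression ---------------------------------------------------------
  coex <- run_stage("coexpr", partner_screen(
    sce, config$anchor, partners = config$partners,
    threshold = config$coexpr$threshold, min_cells = config$coexpr$min_cells))
  utils::write.csv(coex$records, file.path(outdir, "coexpression_records.csv"),
                   row.names = FALSE)
  utils::write.csv(coex$summary, file.path(outdir, "coexpression_summary.csv"),
                   row.names = FALSE)
  anchor_partner <- coex$records[coex$records$partner == config$partners[1], ]
  mvs <- run_stage("coexpr", compare_malignant_vs_stromal(anchor_partner))
  log <- stage_msg(log, "coexpr %s/%s: malignant median %.3f, stromal median %.3f, p %.3g",
                   config$anchor, config$partners[1], mvs$median_malignant,
                   mvs$median_stromal, mvs$p_value)

  # -- paired IHC/RNA calibration -------------------------------------------
  markers <- names(config$paired$true_thresholds)
  calibrations <- run_stage("calibrate", lapply(markers, function(m) {
    pc <- paired_sim_config(
      n_samples = config$paired$n_samples,
      true_threshold = config$paired$true_thresholds[[m]],
      separation = config$paired$separation,
      prevalence = config$paired$prevalence,
      h_score_noise = config$paired$h_score_noise,
      seed = derive_seed(config$seed, paste0("paired-", m)))
    panel <- simulate_paired_panel(pc)
    panel$marker <- m
    utils::write.csv(panel, file.path(outdir, sprintf("paired_panel_%s.csv", m)),
                     row.names = FALSE)
    calibrate_marker(panel, marker = m)
  }))
  names(calibrations) <- markers
  thetas <- vapply(calibrations, `[[`, numeric(1), "theta")
  jsonlite::write_json(
    lapply(calibrations, function(cl) cl[c("marker", "auc", "theta", "j",
                                           "n_pos", "n_neg")]),
    file.path(outdir, "calibration.json"), auto_unbox = TRUE, digits = NA)
  log <- stage_msg(log, "calibration: %s",
                   paste(sprintf("%s theta %.3f (AUC %.3f)", markers, thetas,
                                 vapply(calibrations, `[[`, numeric(1), "auc")),
                         collapse = "; "))

  # -- cohort coverage -------------------------------------------------------
  cohort <- run_stage("coverage", simulate_cohort(do.call(
    cohort_sim_config, c(config$cohort, list(seed = derive_seed(config$seed, "cohort"))))))
  expr <- cohort$expression[, markers, drop = FALSE]
  coverage <- run_stage("coverage", apply_cutoffs(expr, thetas))
  utils::write.csv(cohort$expression, file.path(outdir, "cohort_expression.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$clinical, file.path(outdir, "cohort_clinical.csv"),
                   row.names = FALSE)
  log <- stage_msg(log, "coverage: dual %.1f%% (%d/%d)",
                   coverage$dual$percentage, coverage$dual$n_pos,
                   coverage$dual$n_total)

  # -- survival --------------------------------------------------------------
  surv_records <- cbind(cohort$clinical, cohort$expression[markers])
  grouped <- run_stage("survive", group_by_dual_expression(
    surv_records, markers[1], markers[2], rule = config$survival$rule,
    cutoffs = thetas, stage_filter = config$survival$stage_filter))
  contrast <- run_stage("survive",
                        dual_survival_contrast(grouped, config$survival$contrast))
  utils::write.csv(contrast$km_dual_high, file.path(outdir, "km_dual_high.csv"),
                   row.names = FALSE)
  utils::write.csv(contrast$km_comparison, file.path(outdir, "km_comparison.csv"),
                   row.names = FALSE)
  log <- stage_msg(log, "survival (%s): log-rank p %.4f, HR %.2f",
                   config$survival$contrast, contrast$logrank$p_value,
                   contrast$cox$hr)

  report <- list(
    config_hash = config_hash,
    seed = config$seed,
    sc = list(n_genes = nrow(sc), n_cells = ncol(sc),
              n_retained = qcres$report$n_retained),
    screen = list(test_auc = attr(ranking, "test_auc"),
                  validation_auc = attr(ranking, "validation_auc"),
                  candidates = as.character(candidates)),
    coexpr = list(partner_summary = coex$summary,
                  malignant_vs_stromal_p = mvs$p_value,
                  median_malignant = mvs$median_malignant,
                  median_stromal = mvs$median_stromal),
    calibration = lapply(calibrations, function(cl)
      cl[c("marker", "auc", "theta", "j")]),
    coverage = list(per_marker = coverage$markers, dual = coverage$dual),
    survival = list(contrast = config$survival$contrast,
                    logrank_chisq = contrast$logrank$chisq,
                    logrank_p = contrast$logrank$p_value,
                    hazard_ratio = contrast$cox$hr,
                    hr_ci = c(contrast$cox$ci_lower, contrast$cox$ci_upper))
  )
  report_path <- file.path(outdir, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  digest <- unname(tools::md5sum(report_path))
  writeLines(digest, file.path(outdir, "report.md5"))
  writeLines(log, file.path(outdir, "pipeline.log"))
  attr(report, "report_md5") <- digest
  attr(report, "outdir") <- outdir
  invisible(report)
}
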