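# Survival stratification of dual-expression groups: Kaplan-Meier curves,
# log-rank comparison, and univariate Cox models (via the survival package).

#' Label cohort samples by dual-gene expression group
#'
#' After restricting to the requested tumor stages, each gene is dichotomized
#' into high/low — either at its median within the stage-filtered cohort
#' (default) or at a supplied calibrated cut-off — and samples are labeled
#' `dual-high` (high for both genes), `dual-low` (low for both) or `mixed`.
#'
#' @param records data.frame with columns `time`, `event`, `stage` and one
#'   log2(TPM+1) expression column per gene.
#' @param gene_a,gene_b column names of the two genes.
#' @param rule "median" (per-gene median split, ties going low: high means
#'   strictly above the median) or "cutoff" (high means >= the calibrated
#'   cut-off in `cutoffs`).
#' @param cutoffs named numeric vector of cut-offs (required for
#'   `rule = "cutoff"`).
#' @param stage_filter stages retained (default III/IV, the advanced-stage
#'   patients relevant for systemic therapy); `NULL` keeps all.
#' @return the filtered records with a `group` factor column
#'   (dual-high / mixed / dual-low) and per-gene logical `high_<gene>` columns.
#' @export
group_by_dual_expression <- function(records, gene_a, gene_b,
                                     rule = c("median", "cutoff"),
                                     cutoffs = NULL,
                                     stage_filter = c("III", "IV")) {
  rule <- match.arg(rule)
  stopifnot(all(c(gene_a, gene_b, "time", "event") %in% colnames(records)))
  if (!is.null(stage_filter)) {
    records <- records[records$stage %in% stage_filter, , drop = FALSE]
  }
  if (nrow(records) == 0) {
    stop("no samples left after stage filtering", call. = FALSE)
  }
  high <- function(g) {
    if (rule == "median") {
      records[[g]] > stats::median(records[[g]])
    } else {
      if (is.null(cutoffs) || is.na(cutoffs[g])) {
        stop(sprintf("no cut-off supplied for gene '%s'", g), call. = FALSE)
      }
      records[[g]] >= cutoffs[[g]]
    }
  }
  ha <- high(gene_a); hb <- high(gene_b)
  grp <- ifelse(ha & hb, "dual-high", ifelse(!ha & !hb, "dual-low", "mixed"))
  records$group <- factor(grp, levels = c("dual-high", "mixed", "dual-low"))
  records[[paste0("high_", gene_a)]] <- ha
  records[[paste0("high_", gene_b)]] <- hb
  records
}

#' Kaplan-Meier product-limit estimate
#'
#' @param times positive follow-up times.
#' @param events event indicators (1 = event, 0 = censored).
#' @return data.frame of the survival step function: `time`, `n_risk`,
#'   `n_event`, `n_censor`, `surv`, with the fitted `survfit` object attached
#'   as attribute `"fit"`. S(0) = 1 and the curve drops only at event times.
#' @export
km_estimate <- function(times, events) {
  if (length(times) < 1) stop("need at least one subject", call. = FALSE)
  if (any(times <= 0)) stop("follow-up times must be positive", call. = FALSE)
  stopifnot(all(events %in% c(0, 1)))
  fit <- survival::survfit(survival::Surv(times, events) ~ 1, conf.type = "none")
  out <- data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
                    n_censor = fit$n.censor, surv = fit$surv)
  attr(out, "fit") <- fit
  out
}

#' Two-group log-rank test
#'
#' Standard observed-minus-expected log-rank chi-square with one degree of
#' freedom, two-sided p-value.
#'
#' @param time_a,event_a follow-up and event indicators for group A.
#' @param time_b,event_b follow-up and event indicators for group B.
#' @return list with `chisq`, `p_value`, `n` (per group) and `obs`/`exp`
#'   event counts per group.
#' @export
logrank_test <- function(time_a, event_a, time_b, event_b) {
  if (length(time_a) == 0 || length(time_b) == 0) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  if (sum(event_a) + sum(event_b) == 0) {
    stop("log-rank test needs at least one event", call. = FALSE)
  }
  time <- c(time_a, time_b)
  event <- c(event_a, event_b)
  grp <- factor(rep(c("A", "B"), c(length(time_a), length(time_b))))
  sd <- survival::survdiff(survival::Surv(time, event) ~ grp)
  p <- stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)
  list(chisq = unname(sd$chisq), p_value = p,
       n = as.vector(sd$n), obs = as.vector(sd$obs), exp = as.vector(sd$exp))
}

#' Univariate Cox proportional-hazards model
#'
#' Partial-likelihood fit with Breslow tie handling; the hazard ratio and its
#' Wald 95% confidence interval come from the observed information. A
#' non-converged or infinite fit (monotone likelihood) is flagged rather than
#' silently returned.
#'
#' @param time,event follow-up times and event indicators.
#' @param covariate numeric or two-level covariate (non-constant).
#' @return list with `hr`, `ci_lower`, `ci_upper`, `log_hr`, `se`, `p_value`,
#'   `score_chisq` (the score test, which equals the log-rank statistic for a
#'   binary covariate) and `converged`.
#' @export
cox_univariate <- function(time, event, covariate) {
  if (length(unique(covariate)) < 2) {
    stop("covariate is constant", call. = FALSE)
  }
  x <- if (is.numeric(covariate)) covariate else as.numeric(factor(covariate)) - 1
  fit <- survival::coxph(survival::Surv(time, event) ~ x, ties = "breslow")
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(diag(fit$var)))
  converged <- is.finite(beta) && se < 1e3
  if (!converged) {
    warning("Cox fit did not converge to a finite hazard ratio", call. = FALSE)
  }
  z <- stats::qnorm(0.975)
  list(hr = exp(beta), ci_lower = exp(beta - z * se), ci_upper = exp(beta + z * se),
       log_hr = beta, se = se,
       p_value = 2 * stats::pnorm(-abs(beta / se)),
       score_chisq = unname(fit$score),
       converged = converged)
}

#' Survival contrast between dual-expression groups
#'
#' Runs the log-rank test for one of the two contrasts used in practice:
#' dual-high vs all other patients, or dual-high vs dual-low only.
#'
#' @param grouped output of [group_by_dual_expression()].
#' @param contrast "high_vs_rest" or "high_vs_low".
#' @return the [logrank_test()] result plus the Kaplan-Meier tables per arm
#'   and the univariate Cox hazard ratio of dual-high membership.
#' @export
dual_survival_contrast <- function(grouped, contrast = c("high_vs_rest", "high_vs_low")) {
  contrast <- match.arg(contrast)
  a <- grouped[grouped$group == "dual-high", , drop = FALSE]
  b <- if (contrast == "high_vs_rest") {
    grouped[grouped$group != "dual-high", , drop = FALSE]
  } else {
    grouped[grouped$group == "dual-low", , drop = FALSE]
  }
  lr <- logrank_test(a$time, a$event, b$time, b$event)
  both <- rbind(a, b)
  cox <- cox_univariate(both$time, both$event,
                        as.numeric(both$group == "dual-high"))
  list(contrast = contrast, logrank = lr, cox = cox,
       km_dual_high = km_estimate(a$time, a$event),
       km_comparison = km_estimate(b$time, b$event))
}
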