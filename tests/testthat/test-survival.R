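test_that("Kaplan-Meier estimate matches hand product-limit computations", {
  # four subjects, distinct event times, no censoring: uniform decrements
  km <- km_estimate(c(2, 5, 7, 9), c(1, 1, 1, 1))
  expect_equal(km$surv, c(0.75, 0.5, 0.25, 0))
  # censoring thins the risk set: times 1,2,3,4 with events at 1 and 3
  km2 <- km_estimate(1:4, c(1, 0, 1, 0))
  ev <- km2[km2$n_event > 0, ]
  expect_equal(ev$surv, c(3 / 4, 3 / 4 * 1 / 2))
  # all censored: flat at 1
  km3 <- km_estimate(c(3, 6, 8), c(0, 0, 0))
  expect_true(all(km3$surv == 1))
  expect_error(km_estimate(c(0, 1), c(1, 1)), "positive")
})

test_that("KM equals the empirical survival function without censoring", {
  set.seed(41)
  times <- rexp(80, 1 / 50)
  km <- km_estimate(times, rep(1, 80))
  emp <- vapply(km$time, function(t) mean(times > t), numeric(1))
  expect_equal(km$surv, emp, tolerance = 1e-12)
})

test_that("log-rank statistic matches the hand O-E/V oracle and degenerates correctly", {
  # identical groups: chi-square 0, p 1
  lr0 <- logrank_test(c(1, 2, 3), c(1, 1, 0), c(1, 2, 3), c(1, 1, 0))
  expect_equal(lr0$chisq, 0, tolerance = 1e-12)
  expect_equal(lr0$p_value, 1)
  # fully separated groups: agree with explicit hypergeometric summation
  ta <- c(1, 2); tb <- c(10, 11)
  lr <- logrank_test(ta, c(1, 1), tb, c(1, 1))
  expect_equal(lr$chisq, logrank_oracle(ta, c(1, 1), tb, c(1, 1)),
               tolerance = 1e-9)
  # random instances with censoring
  set.seed(42)
  for (i in 1:10) {
    t1 <- rexp(15, 1); e1 <- rbinom(15, 1, 0.7)
    t2 <- rexp(20, 1.5); e2 <- rbinom(20, 1, 0.7)
    if (sum(e1) + sum(e2) == 0) e1[1] <- 1
    expect_equal(logrank_test(t1, e1, t2, e2)$chisq,
                 logrank_oracle(t1, e1, t2, e2), tolerance = 1e-8)
  }
  expect_error(logrank_test(c(1, 2), c(0, 0), c(3), c(0)), "at least one event")
})

test_that("log-rank is symmetric in group order and invariant to time rescaling", {
  set.seed(43)
  t1 <- rexp(25); e1 <- rbinom(25, 1, 0.8)
  t2 <- rexp(25, 2); e2 <- rbinom(25, 1, 0.8)
  a <- logrank_test(t1, e1, t2, e2)
  b <- logrank_test(t2, e2, t1, e1)
  expect_equal(a$chisq, b$chisq)
  expect_equal(a$p_value, b$p_value)
  scaled <- logrank_test(t1 * 365, e1, t2 * 365, e2)
  expect_equal(a$chisq, scaled$chisq, tolerance = 1e-10)
})

test_that("Cox model recovers a planted hazard ratio and flags degenerate input", {
  set.seed(44)
  n <- 2000
  x <- rbinom(n, 1, 0.5)
  times <- rexp(n, rate = 0.01 * 2^x)
  fit <- cox_univariate(times, rep(1, n), x)
  expect_true(fit$converged)
  expect_gt(fit$hr, 1.8)
  expect_lt(fit$hr, 2.2)
  expect_true(fit$ci_lower < fit$hr && fit$hr < fit$ci_upper)
  # two identical groups: HR ~ 1
  null <- cox_univariate(rep(rexp(500, 0.01), 2), rep(1, 1000),
                         rep(c(0, 1), each = 500))
  expect_lt(abs(null$log_hr), 0.02)
  expect_error(cox_univariate(rexp(10), rep(1, 10), rep(1, 10)), "constant")
})

test_that("Cox score test equals the log-rank statistic for binary covariates", {
  set.seed(45)
  for (i in 1:5) {
    n <- 120
    x <- rbinom(n, 1, 0.5)
    times <- round(rexp(n, 0.02 * 1.5^x), 2) + 0.01
    events <- rbinom(n, 1, 0.8)
    if (sum(events) == 0) events[1] <- 1
    # distinct times: Breslow vs exact tie handling coincide
    times <- times + seq_len(n) * 1e-6
    lr <- logrank_test(times[x == 0], events[x == 0], times[x == 1], events[x == 1])
    cx <- cox_univariate(times, events, x)
    expect_equal(cx$score_chisq, lr$chisq, tolerance = 1e-6)
  }
})

test_that("dual-expression grouping honors the rule and the stage filter", {
  rec <- data.frame(
    sample_id = sprintf("s%d", 1:6),
    time = c(10, 20, 30, 40, 50, 60), event = c(1, 1, 0, 1, 0, 1),
    stage = c("III", "IV", "III", "II", "IV", "III"),
    EGFR = c(5, 5, 1, 9, 1, 2), MUC1 = c(6, 4, 1, 9, 4, 1))
  g <- group_by_dual_expression(rec, "EGFR", "MUC1", rule = "median")
  expect_false("s4" %in% g$sample_id)  # stage II excluded
  expect_equal(nrow(g), 5)
  # medians within the filtered cohort: EGFR 2, MUC1 4; high = strictly above
  expect_equal(as.character(g$group[g$sample_id == "s1"]), "dual-high")
  expect_equal(as.character(g$group[g$sample_id == "s3"]), "dual-low")
  # calibrated cut-off at/below the minimum makes everyone dual-high
  g2 <- group_by_dual_expression(rec, "EGFR", "MUC1", rule = "cutoff",
                                 cutoffs = c(EGFR = 1, MUC1 = 1),
                                 stage_filter = NULL)
  expect_true(all(g2$group == "dual-high"))
  expect_error(group_by_dual_expression(rec, "EGFR", "MUC1",
                                        stage_filter = "X"), "no samples")
})

test_that("dual-survival contrast separates a strongly stratified cohort", {
  set.seed(46)
  co <- simulate_cohort(cohort_sim_config(
    n_samples = 800, positivity = c(EGFR = 0.5, MUC1 = 1.0),
    hazard_ratio = 3, censoring_rate = 0.2, seed = 47))
  rec <- cbind(co$clinical, co$expression[c("EGFR", "MUC1")])
  g <- group_by_dual_expression(rec, "EGFR", "MUC1", rule = "cutoff",
                                cutoffs = c(EGFR = 2, MUC1 = 2),
                                stage_filter = NULL)
  res <- dual_survival_contrast(g, "high_vs_rest")
  expect_lt(res$logrank$p_value, 1e-6)
  expect_gt(res$cox$hr, 2)
})
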