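test_that("AICc matches hand arithmetic and its limits", {
  expect_equal(aicc(-10, 3, 20), 27.5)
  # k = 0: correction term vanishes, AICc = -2 logLik
  expect_equal(aicc(-10, 0, 20), 20)
  # n -> infinity recovers AIC
  aic <- -2 * (-10) + 2 * 3
  expect_equal(aicc(-10, 3, 1e9), aic, tolerance = 1e-6)
  # AICc strictly exceeds AIC for k >= 1 and the gap shrinks with n
  expect_gt(aicc(-10, 3, 20), aic)
  expect_lt(aicc(-10, 3, 200) - aic, aicc(-10, 3, 20) - aic)
  expect_error(aicc(-10, 3, 4), "undefined")
})

test_that("Holm adjustment matches hand computation and is order-invariant", {
  expect_equal(holm_bonferroni(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holm_bonferroni(0.2), 0.2)
  expect_equal(holm_bonferroni(rep(1, 5)), rep(1, 5))
  expect_error(holm_bonferroni(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(holm_bonferroni(c(0.5, NA)), "\\[0, 1\\]")
  set.seed(8)
  p <- runif(12)
  adj <- holm_bonferroni(p)
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  # permutation invariance: adjusted values travel with their inputs
  perm <- sample(12)
  expect_equal(holm_bonferroni(p[perm]), adj[perm])
  # monotone in the raw-p order
  expect_true(all(diff(adj[order(p)]) >= 0))
})

test_that("the likelihood-ratio test matches the chi-square tail", {
  d <- toy_long_table(n_fish = 8, resid_sd = 0.3, seed = 2)
  tab <- build_long_table(d)
  full <- fit_lmm(tab, "(1 | fish)", reml = FALSE)
  lrt0 <- likelihood_ratio_test(full, full)
  expect_equal(lrt0$statistic, 0)
  expect_equal(lrt0$p, 1)
  # hand value: 2*dlogLik = 6 on 1 df -> p = 0.01431
  expect_equal(pchisq(6, 1, lower.tail = FALSE), 0.014306, tolerance = 1e-4)
  # interaction test has the right df on the 4-condition design
  red <- lme4::lmer(log_ratio ~ period + condition + (1 | fish),
                    data = tab, REML = FALSE)
  lrt <- likelihood_ratio_test(full, red)
  expect_equal(lrt$df, 6)
  expect_gte(lrt$p, 0)
  # REML fits are refitted to ML automatically
  full_reml <- fit_lmm(tab, "(1 | fish)", reml = TRUE)
  lrt2 <- likelihood_ratio_test(full_reml, red)
  expect_equal(lrt2$statistic, lrt$statistic, tolerance = 1e-6)
  expect_error(likelihood_ratio_test(red, full), "nested")
})

test_that("AICc selection finds the generating random structure", {
  cands <- c("(1 | fish)", "(1 + period | fish)")
  # strong per-fish period slopes: the slope model should win most runs
  wins <- 0
  for (r in 1:60) {
    d <- toy_long_table(n_fish = 8, period_slope_sd = 0.6, resid_sd = 0.15,
                        seed = 100 + r)
    tab <- build_long_table(d)
    sel <- select_random_structure(tab, cands)
    if (sel$random == "(1 + period | fish)") wins <- wins + 1
  }
  expect_gte(wins / 60, 0.8)
  # intercept-only data: the simpler structure wins most runs
  wins0 <- 0
  for (r in 1:40) {
    d <- toy_long_table(n_fish = 8, period_slope_sd = 0, resid_sd = 0.3,
                        seed = 300 + r)
    tab <- build_long_table(d)
    sel <- select_random_structure(tab, cands)
    if (sel$random == "(1 | fish)") wins0 <- wins0 + 1
  }
  expect_gt(wins0 / 40, 0.5)
  # single candidate returned unconditionally
  d <- toy_long_table(seed = 7)
  sel1 <- select_random_structure(build_long_table(d), "(1 | fish)")
  expect_equal(sel1$random, "(1 | fish)")
})

test_that("the mixed model recovers known fixed effects", {
  # all log ratios equal c: intercept c, everything else ~ 0
  d <- toy_long_table(n_fish = 6, fish_sd = 0, resid_sd = 0, seed = 1)
  d$log_ratio <- 0.42
  fit <- fit_lmm(build_long_table(d), "(1 | fish)")
  expect_equal(fit$coefficients["(Intercept)", "estimate"], 0.42,
               tolerance = 1e-8)
  others <- setdiff(rownames(fit$coefficients), "(Intercept)")
  expect_true(all(abs(fit$coefficients[others, "estimate"]) < 1e-8))
  # one row per fixed-effect term of the 3x4 treatment-coded design
  expect_equal(nrow(fit$coefficients), 12)
  # known Period-2 x Condition interaction of 0.7 is recovered within 0.15
  ests <- vapply(1:12, function(r) {
    d <- toy_long_table(n_fish = 8, resid_sd = 0.2, fish_sd = 0.1,
                        cond_p2_effects = c("Absent-vs-Absent" = 0, A = 0.7,
                                            B = 0, C = 0), seed = 500 + r)
    fit <- fit_lmm(build_long_table(d), "(1 | fish)")
    # with Period 2 and Absent-vs-Absent as references the A-vs-control
    # stimulus-period effect is the conditionA main term
    fit$coefficients["conditionA", "estimate"]
  }, numeric(1))
  expect_lt(abs(mean(ests) - 0.7), 0.15)
  expect_true(all(abs(ests - 0.7) < 0.3))
})

test_that("marginal means equal raw cell means on balanced saturated data", {
  d <- toy_long_table(n_fish = 8, resid_sd = 0.25, fish_sd = 0.05,
                      cond_p2_effects = c("Absent-vs-Absent" = 0, A = 0.5,
                                          B = 0.2, C = 0), seed = 9)
  tab <- build_long_table(d)
  fit <- fit_lmm(tab, "(1 | fish)")
  em <- estimated_marginal_means(fit, "condition")
  raw <- aggregate(log_ratio ~ condition + period, tab, mean)
  m <- merge(em, raw, by = c("condition", "period"))
  expect_equal(m$emmean, m$log_ratio, tolerance = 1e-6)
  # all-equal data: all emmeans equal, symmetric intervals
  d0 <- d; d0$log_ratio <- 0.3
  em0 <- estimated_marginal_means(fit_lmm(build_long_table(d0), "(1 | fish)"),
                                  "period")
  expect_equal(em0$emmean, rep(0.3, nrow(em0)), tolerance = 1e-6)
  expect_equal(em0$upper - em0$emmean, em0$emmean - em0$lower,
               tolerance = 1e-8)
})

test_that("the full chain runs, is deterministic, and nulls stay null", {
  d <- toy_long_table(n_fish = 8, resid_sd = 0.25, fish_sd = 0.1,
                      cond_p2_effects = c("Absent-vs-Absent" = 0, A = 0.8,
                                          B = 0.4, C = 0.1), seed = 77)
  an <- run_paper_analysis(d, candidates = c("(1 | fish)",
                                             "(1 + period | fish)"))
  expect_s3_class(an, "preference_analysis")
  expect_true(an$lrt$interaction$p < 0.001)
  expect_equal(sort(unique(as.character(an$emmeans_by_condition$condition))),
               sort(c("Absent-vs-Absent", "A", "B", "C")))
  expect_true(all(an$posthoc$between_conditions$p_holm >=
                    an$posthoc$between_conditions$p_raw - 1e-12))
  an2 <- run_paper_analysis(d, candidates = c("(1 | fish)",
                                              "(1 + period | fish)"))
  expect_equal(an$fit$coefficients, an2$fit$coefficients)
  expect_equal(an$posthoc, an2$posthoc)
  # report writer emits the tidy CSV set
  out <- withr::local_tempdir()
  write_analysis_report(an, out)
  expect_true(all(file.exists(file.path(out,
    c("fixed_effects.csv", "model_selection.csv",
      "likelihood_ratio_tests.csv", "emmeans_by_condition.csv",
      "posthoc_between_conditions.csv")))))
  # null data: adjusted p-values rarely cross 0.05
  hits <- vapply(1:10, function(r) {
    dn <- toy_long_table(n_fish = 8, resid_sd = 0.3, seed = 900 + r)
    ann <- run_paper_analysis(dn, candidates = "(1 | fish)")
    any(ann$posthoc$between_conditions$p_holm < 0.05)
  }, logical(1))
  expect_lte(sum(hits), 1)
})
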