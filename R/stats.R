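#' Second-order Akaike Information Criterion
#'
#' `AICc = -2 logLik + 2k + 2k(k+1)/(n-k-1)`: AIC plus the small-sample
#' correction, which vanishes as n grows and is undefined for `n <= k + 1`.
#'
#' @param loglik maximized log-likelihood.
#' @param k number of estimated parameters.
#' @param n number of observations.
#' @return the AICc value.
#' @examples
#' aicc(-10, 3, 20)   # 27.5
#' @export
aicc <- function(loglik, k, n) {
  if (n <= k + 1) stop("AICc undefined for n <= k + 1")
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' @rdname aicc
#' @param fit a fitted model with `logLik()` support.
#' @export
aicc_fit <- function(fit) {
  ll <- logLik(fit)
  aicc(as.numeric(ll), attr(ll, "df"), stats::nobs(fit))
}

#' Long table of log ratios for mixed-effects analysis
#'
#' Reshapes a [preference_table()] into the modelling table: one row per
#' fish x condition x period (periods 1-3), with treatment contrasts
#' anchored at Period 2 and the Absent-vs-Absent condition so that the
#' intercept is the blank-monitor stimulus-period baseline.
#'
#' @param records a `preference_table` or compatible data frame with `fish`,
#'   `condition`, `period`, `log_ratio`.
#' @return data frame with factors `fish`, `condition` (reference
#'   Absent-vs-Absent), `period` (reference "2") and numeric `log_ratio`.
#' @export
build_long_table <- function(records) {
  d <- as.data.frame(records)
  d <- d[d$period %in% 1:3, c("fish", "condition", "period", "log_ratio")]
  if (anyNA(d$log_ratio)) stop("log_ratio contains missing values")
  d$fish <- factor(d$fish)
  conds <- unique(as.character(d$condition))
  ref <- if ("Absent-vs-Absent" %in% conds) "Absent-vs-Absent" else conds[1]
  d$condition <- stats::relevel(factor(d$condition), ref = ref)
  d$period <- factor(d$period, levels = c("2", "1", "3"))
  rownames(d) <- NULL
  d
}

#' Candidate random-effects structures
#'
#' The comparison set: by-fish random intercept, plus up to two simultaneous
#' random slopes (Period, Condition).
#'
#' @return character vector of random-effects formula terms.
#' @export
candidate_random_structures <- function() {
  c("(1 | fish)",
    "(1 + period | fish)",
    "(1 + condition | fish)",
    "(1 + period + condition | fish)")
}

.lmm_formula <- function(random) {
  as.formula(paste("log_ratio ~ period * condition +", random))
}

.fit_quietly <- function(formula, data, reml) {
  fit <- try(suppressWarnings(suppressMessages(
    lmerTest::lmer(formula, data = data, REML = reml,
                   control = lme4::lmerControl(check.conv.singular =
                     lme4::.makeCC(action = "ignore", tol = 1e-4))))),
    silent = TRUE)
  if (inherits(fit, "try-error")) NULL else fit
}

#' Select the random-effects structure by AICc
#'
#' Fits every candidate by maximum likelihood and keeps the structure with
#' the smallest AICc; ties go to the structure with fewer parameters.
#'
#' @param table a long table from [build_long_table()].
#' @param candidates random-effects terms, default
#'   [candidate_random_structures()].
#' @return list with `random` (the selected term), `table` (candidate, k, n,
#'   logLik, AICc) and `fit` (the selected ML fit).
#' @export
select_random_structure <- function(table,
                                    candidates = candidate_random_structures()) {
  fits <- lapply(candidates, function(r)
    .fit_quietly(.lmm_formula(r), table, reml = FALSE))
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) stop("no candidate random structure could be fitted")
  stats_tab <- do.call(rbind, lapply(which(ok), function(i) {
    ll <- logLik(fits[[i]])
    data.frame(random = candidates[i], k = attr(ll, "df"),
               n = stats::nobs(fits[[i]]), logLik = as.numeric(ll),
               AICc = aicc(as.numeric(ll), attr(ll, "df"),
                           stats::nobs(fits[[i]])))
  }))
  rownames(stats_tab) <- NULL
  best <- stats_tab[order(stats_tab$AICc, stats_tab$k), ][1, "random"]
  list(random = best, table = stats_tab,
       fit = fits[[match(best, candidates)]])
}

#' Fit the preference mixed model
#'
#' Linear mixed-effects regression of the log ratios on Period x Condition
#' (treatment contrasts at Period 2 / Absent-vs-Absent) with the given
#' random-effects structure. REML for the reported fit, ML for model
#' comparison. Coefficient degrees of freedom use the Satterthwaite
#' approximation.
#'
#' @param table from [build_long_table()].
#' @param random random-effects term, e.g. `"(1 | fish)"`.
#' @param reml logical.
#' @return list of class `pref_lmm` with the `fit` and its `coefficients`
#'   table (estimate, SE, df, t, p per fixed-effect term).
#' @export
fit_lmm <- function(table, random = "(1 | fish)", reml = TRUE) {
  fit <- .fit_quietly(.lmm_formula(random), table, reml = reml)
  if (is.null(fit)) stop("mixed model failed to fit")
  ct <- as.data.frame(summary(fit)$coefficients)
  names(ct) <- c("estimate", "se", "df", "t", "p")
  structure(list(fit = fit, random = random, reml = reml,
                 coefficients = ct, n = stats::nobs(fit)),
            class = "pref_lmm")
}

#' @export
print.pref_lmm <- function(x, ...) {
  cat(sprintf("<pref_lmm> log_ratio ~ period * condition + %s (%s, n = %d)\n",
              x$random, if (x$reml) "REML" else "ML", x$n))
  print(round(x$coefficients, 3))
  invisible(x)
}

#' Likelihood-ratio test between nested mixed models
#'
#' `2 (logLik_full - logLik_reduced)` against a chi-square with the parameter
#' difference as degrees of freedom. Both models must be ML fits on the same
#' data; REML fits are refitted by ML.
#'
#' @param full,reduced fitted models (lmer fits or `pref_lmm` objects).
#' @return list with `statistic`, `df`, `p`.
#' @export
likelihood_ratio_test <- function(full, reduced) {
  get_fit <- function(m) if (inherits(m, "pref_lmm")) m$fit else m
  f <- get_fit(full); r <- get_fit(reduced)
  if (lme4::isREML(f)) f <- lme4::refitML(f)
  if (lme4::isREML(r)) r <- lme4::refitML(r)
  if (stats::nobs(f) != stats::nobs(r)) {
    stop("models were fitted to different data")
  }
  llf <- logLik(f); llr <- logLik(r)
  df <- attr(llf, "df") - attr(llr, "df")
  if (df < 0) stop("'reduced' must be nested in 'full' (fewer parameters)")
  stat <- max(0, 2 * (as.numeric(llf) - as.numeric(llr)))
  p <- if (df == 0) 1 else pchisq(stat, df, lower.tail = FALSE)
  list(statistic = stat, df = df, p = p)
}

#' Estimated marginal means of the preference model
#'
#' Model-based cell means averaged over the other factor's levels with equal
#' weights, with Satterthwaite degrees of freedom and 95% confidence
#' intervals.
#'
#' @param fit a `pref_lmm` or lmer fit.
#' @param by `"condition"` (within each period) or `"period"` (within each
#'   condition).
#' @return data frame with the cell, `emmean`, `se`, `df`, `lower`, `upper`.
#' @export
estimated_marginal_means <- function(fit, by = c("condition", "period")) {
  by <- match.arg(by)
  f <- if (inherits(fit, "pref_lmm")) fit$fit else fit
  spec <- if (by == "condition") ~ condition | period else ~ period | condition
  em <- emmeans::emmeans(f, spec, lmer.df = "satterthwaite")
  out <- as.data.frame(em)
  names(out)[names(out) == "SE"] <- "se"
  names(out)[names(out) == "lower.CL"] <- "lower"
  names(out)[names(out) == "upper.CL"] <- "upper"
  out
}

#' Holm-Bonferroni adjustment
#'
#' Step-down familywise adjustment: with the p-values sorted ascending, the
#' i-th is multiplied by (m - i + 1), running maxima are enforced, capped at
#' 1, and the result is returned in the input order.
#'
#' @param p numeric p-values in \[0, 1\].
#' @return adjusted p-values, aligned with the input.
#' @examples
#' holm_bonferroni(c(0.01, 0.04, 0.03))   # 0.03 0.06 0.06
#' @export
holm_bonferroni <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(p, method = "holm")
}

#' Post hoc comparisons with Holm adjustment
#'
#' The two comparison families of the analysis chain: (1) between conditions
#' within each period and (2) between periods within each condition. Raw
#' p-values come from pairwise contrasts of the estimated marginal means;
#' the Holm adjustment is applied within each family.
#'
#' @param fit a `pref_lmm` or lmer fit.
#' @return list with data frames `between_conditions` and `between_periods`,
#'   each with `contrast`, the conditioning cell, `estimate`, `se`, `df`,
#'   `t`, `p_raw`, `p_holm`.
#' @export
posthoc_comparisons <- function(fit) {
  f <- if (inherits(fit, "pref_lmm")) fit$fit else fit
  fam <- function(spec) {
    em <- emmeans::emmeans(f, spec, lmer.df = "satterthwaite")
    pr <- as.data.frame(emmeans::contrast(em, method = "pairwise",
                                          adjust = "none"))
    names(pr)[names(pr) == "SE"] <- "se"
    names(pr)[names(pr) == "t.ratio"] <- "t"
    names(pr)[names(pr) == "p.value"] <- "p_raw"
    pr$p_holm <- holm_bonferroni(pr$p_raw)
    pr
  }
  list(between_conditions = fam(~ condition | period),
       between_periods = fam(~ period | condition))
}

#' The full inferential chain on a preference table
#'
#' Runs the complete analysis: AICc selection of the random-effects
#' structure (ML fits), the final REML fit with Satterthwaite degrees of
#' freedom, likelihood-ratio tests of the fixed effects (interaction, then
#' each main effect), estimated marginal means by condition and by period,
#' and both Holm-adjusted post hoc families.
#'
#' @param records a `preference_table` or a ready long table.
#' @param candidates candidate random structures; the default full set can be
#'   restricted for small designs.
#' @return a `preference_analysis` list: `selection`, `fit` (`pref_lmm`),
#'   `lrt` (interaction/condition/period), `emmeans_by_condition`,
#'   `emmeans_by_period`, `posthoc`.
#' @export
run_paper_analysis <- function(records,
                               candidates = candidate_random_structures()) {
  tab <- if (all(c("fish", "condition", "period", "log_ratio") %in%
                 names(records)) && is.factor(records$period)) {
    records
  } else {
    build_long_table(records)
  }
  sel <- select_random_structure(tab, candidates)
  fit <- fit_lmm(tab, random = sel$random, reml = TRUE)

  ml <- function(fx) .fit_quietly(
    as.formula(paste("log_ratio ~", fx, "+", sel$random)), tab, reml = FALSE)
  full <- ml("period * condition")
  add <- ml("period + condition")
  no_cond <- ml("period")
  no_per <- ml("condition")
  lrt <- list(interaction = likelihood_ratio_test(full, add),
              condition = likelihood_ratio_test(add, no_per),
              period = likelihood_ratio_test(add, no_cond))

  structure(list(selection = sel[c("random", "table")], fit = fit,
                 lrt = lrt,
                 emmeans_by_condition = estimated_marginal_means(fit, "condition"),
                 emmeans_by_period = estimated_marginal_means(fit, "period"),
                 posthoc = posthoc_comparisons(fit),
                 table = tab),
            class = "preference_analysis")
}

#' @export
print.preference_analysis <- function(x, ...) {
  cat("<preference_analysis>\n")
  cat("  random structure (AICc):", x$selection$random, "\n")
  cat(sprintf("  LRT interaction: chi2(%d) = %.2f, p = %.4g\n",
              x$lrt$interaction$df, x$lrt$interaction$statistic,
              x$lrt$interaction$p))
  cat("  fixed effects (REML, Satterthwaite df):\n")
  print(round(x$fit$coefficients, 3))
  invisible(x)
}

#' Write the analysis report as tidy CSVs
#'
#' @param analysis a `preference_analysis`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_analysis_report <- function(analysis, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  co <- analysis$fit$coefficients
  co <- cbind(term = rownames(co), co)
  write.csv(co, file.path(dir, "fixed_effects.csv"), row.names = FALSE)
  write.csv(analysis$selection$table, file.path(dir, "model_selection.csv"),
            row.names = FALSE)
  lr <- do.call(rbind, lapply(names(analysis$lrt), function(n)
    data.frame(effect = n, statistic = analysis$lrt[[n]]$statistic,
               df = analysis$lrt[[n]]$df, p = analysis$lrt[[n]]$p)))
  write.csv(lr, file.path(dir, "likelihood_ratio_tests.csv"),
            row.names = FALSE)
  write.csv(analysis$emmeans_by_condition,
            file.path(dir, "emmeans_by_condition.csv"), row.names = FALSE)
  write.csv(analysis$emmeans_by_period,
            file.path(dir, "emmeans_by_period.csv"), row.names = FALSE)
  write.csv(analysis$posthoc$between_conditions,
            file.path(dir, "posthoc_between_conditions.csv"),
            row.names = FALSE)
  write.csv(analysis$posthoc$between_periods,
            file.path(dir, "posthoc_between_periods.csv"), row.names = FALSE)
  invisible(dir)
}
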