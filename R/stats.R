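group_comparison <- function(effect, se, df, statistic, p, method,
                             conf_level = 0.95) {
  tcrit <- stats::qt(1 - (1 - conf_level) / 2, df)
  tibble::tibble(
    effect = effect, se = se,
    ci_lo = effect - tcrit * se, ci_hi = effect + tcrit * se,
    statistic = statistic, df = df, p_value = p, method = method
  )
}

#' Pooled two-sample t-test from printed summary statistics
#'
#' Student's pooled-variance unpaired t-test computed from per-group
#' (n, mean, sd) triples, so published group comparisons can be reproduced
#' from a summary table alone. Identical formulas to [t_test_pooled()]:
#' `sp^2 = ((n1-1) s1^2 + (n2-1) s2^2) / (n1+n2-2)`,
#' `t = (m1 - m2) / (sp sqrt(1/n1 + 1/n2))`, two-sided p on `n1+n2-2` df,
#' CI as `effect +/- t_crit * se`.
#'
#' @param g1,g2 Lists (or one-row data frames) with `n`, `mean`, `sd`;
#'   see [ref_summary()] for the packaged reference values.
#' @param conf_level Confidence level for the CI (default 0.95).
#' @return One-row tibble: `effect` (mean1 - mean2), `se`, `ci_lo`,
#'   `ci_hi`, `statistic`, `df`, `p_value`, `method`.
#' @export
#' @examples
#' t_test_from_summary(ref_summary("brainpad", "PWS"),
#'                     ref_summary("brainpad", "Control"))
t_test_from_summary <- function(g1, g2, conf_level = 0.95) {
  n1 <- g1$n; n2 <- g2$n
  if (is.null(n1) || is.null(n2) || n1 < 2 || n2 < 2) {
    stop("both groups need n >= 2", call. = FALSE)
  }
  if (g1$sd < 0 || g2$sd < 0) stop("sd must be >= 0", call. = FALSE)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * g1$sd^2 + (n2 - 1) * g2$sd^2) / df
  if (sp2 <= 0) {
    stop("zero pooled variance: both groups are constant", call. = FALSE)
  }
  effect <- g1$mean - g2$mean
  se <- sqrt(sp2) * sqrt(1 / n1 + 1 / n2)
  t <- effect / se
  p <- 2 * stats::pt(-abs(t), df)
  group_comparison(effect, se, df, t, p, "pooled t (from summary)", conf_level)
}

#' Pooled two-sample t-test from raw samples
#'
#' Student's (equal-variance) unpaired t-test; effect is
#' `mean(x1) - mean(x2)`. Equivalent to summarising each sample and calling
#' [t_test_from_summary()] — that equivalence is a tested invariant.
#'
#' @param x1,x2 Numeric samples, each of length >= 2.
#' @param conf_level Confidence level for the CI.
#' @return One-row tibble as in [t_test_from_summary()].
#' @export
t_test_pooled <- function(x1, x2, conf_level = 0.95) {
  stopifnot(length(x1) >= 2, length(x2) >= 2)
  out <- t_test_from_summary(
    list(n = length(x1), mean = mean(x1), sd = stats::sd(x1)),
    list(n = length(x2), mean = mean(x2), sd = stats::sd(x2)),
    conf_level = conf_level
  )
  out$method <- "pooled t"
  out
}

#' Mann-Whitney U test
#'
#' Rank-sum test via [stats::wilcox.test()]: exact enumeration for small
#' tie-free samples (both n < 20), otherwise the normal approximation with
#' tie correction. `U` is the number of (x1, x2) pairs with x1 > x2 (+ 1/2
#' per tie).
#'
#' @param x1,x2 Numeric samples.
#' @param exact Force exact/approximate; default chooses as above.
#' @return One-row tibble: `U`, `p_value`, `method`.
#' @export
mann_whitney_u <- function(x1, x2, exact = NULL) {
  if (is.null(exact)) {
    exact <- length(x1) < 20 && length(x2) < 20 &&
      !any(duplicated(c(x1, x2)))
  }
  wt <- suppressWarnings(stats::wilcox.test(x1, x2, exact = exact,
                                            correct = FALSE))
  tibble::tibble(U = unname(wt$statistic), p_value = wt$p.value,
                 method = wt$method)
}

#' Pearson chi-squared test for a 2x2 table
#'
#' Without continuity correction by default (the convention that matches
#' printed sex-distribution comparisons in the reference design); Yates
#' correction available via `correct = TRUE`.
#'
#' @param counts 2x2 matrix of nonnegative integer counts (or a length-4
#'   vector filled by row: a, b, c, d).
#' @param correct Apply Yates continuity correction.
#' @return One-row tibble: `chi2`, `df`, `p_value`.
#' @export
chi_squared_2x2 <- function(counts, correct = FALSE) {
  tab <- if (is.matrix(counts)) counts else matrix(counts, 2, 2, byrow = TRUE)
  stopifnot(identical(dim(tab), c(2L, 2L)), all(tab >= 0))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("zero margin in 2x2 table", call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  tibble::tibble(chi2 = unname(ct$statistic), df = unname(ct$parameter),
                 p_value = ct$p.value)
}

#' Pearson correlation with t-based p-value
#'
#' Sample Pearson r with two-sided p from
#' `t = r sqrt((n-2) / (1-r^2))` on n-2 df.
#'
#' @param x,y Numeric vectors, length >= 3.
#' @return One-row tibble: `r`, `n`, `statistic`, `df`, `p_value`.
#' @export
pearson_r <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance input to Pearson correlation", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), n = n,
                 statistic = unname(ct$statistic),
                 df = unname(ct$parameter), p_value = ct$p.value)
}

check_full_rank <- function(X) {
  qr_ <- qr(X)
  if (qr_$rank < ncol(X)) {
    bad <- colnames(X)[qr_$pivot[(qr_$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear terms: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Covariate-adjusted group effect on brain-PAD
#'
#' Ordinary least squares of the response (typically brain-PAD, years) on
#' an intercept, a group indicator, and the named covariates on their raw
#' scale. The group coefficient is the adjusted group effect, reported with
#' SE, 95% CI, t and two-sided p; covariate coefficients and the adjusted
#' R^2 come along. No multiple-testing correction is applied (a deliberate
#' fidelity choice to the reference analysis).
#'
#' @param data Data frame with the response, group and covariate columns.
#' @param response Name of the response column.
#' @param group Name of the group column (2 levels; the *first* level
#'   alphabetically is the reference, so the effect is level2 - level1 —
#'   pass a factor to control the direction).
#' @param covariates Character vector of covariate column names (may be
#'   empty for the unadjusted comparison).
#' @param conf_level CI level.
#' @return A `regression_fit`: list with `terms` tibble (term, estimate,
#'   se, ci_lo, ci_hi, statistic, p_value), `group_term`, `adjusted_r2`,
#'   `n`, `formula`.
#' @export
adjusted_group_effect <- function(data, response, group,
                                  covariates = character(), conf_level = 0.95) {
  stopifnot(is.data.frame(data))
  miss <- setdiff(c(response, group, covariates), names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  fml <- stats::reformulate(c(group, covariates), response = response)
  mf <- stats::model.frame(fml, data = data)
  X <- stats::model.matrix(fml, mf)
  check_full_rank(X)
  fit <- stats::lm(fml, data = data)
  cf <- summary(fit)$coefficients
  tcrit <- stats::qt(1 - (1 - conf_level) / 2, fit$df.residual)
  terms_tbl <- tibble::tibble(
    term = rownames(cf),
    estimate = unname(cf[, 1]), se = unname(cf[, 2]),
    ci_lo = unname(cf[, 1] - tcrit * cf[, 2]),
    ci_hi = unname(cf[, 1] + tcrit * cf[, 2]),
    statistic = unname(cf[, 3]), p_value = unname(cf[, 4])
  )
  gterm <- grep(paste0("^", group), terms_tbl$term, value = TRUE)[1]
  structure(
    list(terms = terms_tbl, group_term = gterm,
         adjusted_r2 = summary(fit)$adj.r.squared,
         n = nrow(mf), df_residual = fit$df.residual,
         formula = deparse(fml), lm = fit),
    class = "regression_fit"
  )
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("<regression_fit> %s (n = %d, adj R^2 = %.3f)\n",
              x$formula, x$n, x$adjusted_r2))
  print(x$terms)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.regression_fit <- function(x, ...) x$terms

#' @exportS3Method generics::glance
glance.regression_fit <- function(x, ...) {
  tibble::tibble(adjusted_r2 = x$adjusted_r2, n = x$n,
                 df_residual = x$df_residual)
}

#' Adjusted group effect as a one-row comparison
#'
#' Pulls the group coefficient out of [adjusted_group_effect()] in the
#' same shape as the t-test comparisons.
#'
#' @inheritParams adjusted_group_effect
#' @return One-row tibble: effect, se, ci_lo, ci_hi, statistic, df,
#'   p_value, method.
#' @export
group_effect_row <- function(data, response, group,
                             covariates = character(), conf_level = 0.95) {
  fit <- adjusted_group_effect(data, response, group, covariates, conf_level)
  row <- fit$terms[fit$terms$term == fit$group_term, ]
  tibble::tibble(
    effect = row$estimate, se = row$se, ci_lo = row$ci_lo, ci_hi = row$ci_hi,
    statistic = row$statistic, df = fit$df_residual, p_value = row$p_value,
    method = paste0("OLS adjusted (",
                    if (length(covariates)) paste(covariates, collapse = "+")
                    else "unadjusted", ")")
  )
}

#' Group-by-covariate interaction test
#'
#' OLS of the response on group, covariate and their product; returns the
#' interaction term's two-sided p (do the two groups share a slope?).
#'
#' @inheritParams adjusted_group_effect
#' @param covariate Single covariate column name.
#' @return One-row tibble: `term`, `estimate`, `se`, `statistic`, `df`,
#'   `p_value`.
#' @export
interaction_test <- function(data, response, group, covariate) {
  stopifnot(length(covariate) == 1L)
  if (stats::sd(data[[covariate]]) == 0) {
    stop("covariate '", covariate, "' is constant; interaction design is ",
         "rank deficient", call. = FALSE)
  }
  fml <- stats::as.formula(paste(response, "~", group, "*", covariate))
  X <- stats::model.matrix(fml, stats::model.frame(fml, data))
  check_full_rank(X)
  fit <- stats::lm(fml, data = data)
  cf <- summary(fit)$coefficients
  irow <- grep(":", rownames(cf))
  tibble::tibble(
    term = rownames(cf)[irow],
    estimate = cf[irow, 1], se = cf[irow, 2], statistic = cf[irow, 3],
    df = fit$df.residual, p_value = cf[irow, 4]
  )
}

#' BMI-matched subcohort filter
#'
#' Restricts a two-group cohort to the BMI overlap region: patients are
#' kept when their BMI does not exceed the control maximum, controls when
#' theirs is not below the patient minimum. Boundary subjects (BMI exactly
#' equal to the other group's extreme) are retained — the reference
#' analysis prints strict inequalities yet keeps its boundary subjects, so
#' `<=`/`>=` is the documented convention here.
#'
#' @param cohort Data frame with group and BMI columns.
#' @param group Group column name.
#' @param bmi BMI column name.
#' @param patient_label Level of `group` identifying patients; all other
#'   rows are treated as controls.
#' @return The filtered cohort (same columns); warns if a group empties.
#' @export
bmi_match_filter <- function(cohort, group = "group", bmi = "bmi",
                             patient_label = "PWS") {
  stopifnot(all(c(group, bmi) %in% names(cohort)))
  is_pat <- cohort[[group]] == patient_label
  if (!any(is_pat) || all(is_pat)) {
    stop("need both a '", patient_label, "' group and a comparison group",
         call. = FALSE)
  }
  max_ctrl <- max(cohort[[bmi]][!is_pat])
  min_pat <- min(cohort[[bmi]][is_pat])
  keep <- (is_pat & cohort[[bmi]] <= max_ctrl) |
    (!is_pat & cohort[[bmi]] >= min_pat)
  out <- cohort[keep, , drop = FALSE]
  if (!any(out[[group]] == patient_label) ||
      all(out[[group]] == patient_label)) {
    warning("BMI matching emptied a group (disjoint BMI ranges)",
            call. = FALSE)
  }
  out
}

#' Compare a single subject's brain-PAD against a normative cohort
#'
#' z-score of the subject's brain-PAD against the normative mean/SD, plus
#' the mid-rank empirical percentile within the normative scores.
#'
#' @param subject_pad Subject brain-PAD (years), or a [gpr_predict()] row.
#' @param norms Numeric vector of normative brain-PAD values (n >= 2).
#' @return One-row tibble: `brain_pad`, `norm_mean`, `norm_sd`, `z`,
#'   `percentile`.
#' @export
single_subject_vs_norm <- function(subject_pad, norms) {
  if (is.data.frame(subject_pad)) subject_pad <- subject_pad$brain_pad
  stopifnot(length(subject_pad) == 1L, length(norms) >= 2)
  s <- stats::sd(norms)
  if (s == 0) stop("normative scores have zero SD", call. = FALSE)
  pct <- 100 * (sum(norms < subject_pad) + 0.5 * sum(norms == subject_pad)) /
    length(norms)
  tibble::tibble(
    brain_pad = subject_pad, norm_mean = mean(norms), norm_sd = s,
    z = (subject_pad - mean(norms)) / s, percentile = pct
  )
}
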