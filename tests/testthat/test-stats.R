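test_that("pooled t matches the textbook formula and stats::t.test", {
  set.seed(51)
  x1 <- rnorm(14, 5, 2); x2 <- rnorm(22, 3, 2.5)
  out <- t_test_pooled(x1, x2)
  # brute-force formula
  sp <- sqrt(((14 - 1) * var(x1) + (22 - 1) * var(x2)) / (14 + 22 - 2))
  t_brute <- (mean(x1) - mean(x2)) / (sp * sqrt(1 / 14 + 1 / 22))
  expect_equal(out$statistic, t_brute, tolerance = 1e-12)
  # independent route through stats::t.test
  tt <- t.test(x1, x2, var.equal = TRUE)
  expect_equal(out$statistic, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(out$p_value, tt$p.value, tolerance = 1e-10)
  expect_equal(c(out$ci_lo, out$ci_hi), as.numeric(tt$conf.int),
               tolerance = 1e-10)
})

test_that("summary-based and raw t-tests agree to near machine precision", {
  for (seed in 52:55) {
    set.seed(seed)
    x1 <- rnorm(sample(5:40, 1), runif(1, -5, 5), runif(1, 0.5, 4))
    x2 <- rnorm(sample(5:40, 1), runif(1, -5, 5), runif(1, 0.5, 4))
    raw <- t_test_pooled(x1, x2)
    smry <- t_test_from_summary(
      list(n = length(x1), mean = mean(x1), sd = sd(x1)),
      list(n = length(x2), mean = mean(x2), sd = sd(x2))
    )
    expect_equal(raw$effect, smry$effect, tolerance = 1e-10)
    expect_equal(raw$statistic, smry$statistic, tolerance = 1e-10)
    expect_equal(raw$p_value, smry$p_value, tolerance = 1e-10)
  }
})

test_that("t-test degenerate and symmetric cases behave", {
  x <- c(1, 2, 3, 4)
  out <- t_test_pooled(x, x)
  expect_equal(out$statistic, 0)
  expect_equal(out$p_value, 1)
  expect_error(t_test_pooled(c(2, 2, 2), c(2, 2)), "pooled variance")
  expect_error(t_test_from_summary(list(n = 1, mean = 0, sd = 1),
                                   list(n = 5, mean = 0, sd = 1)), "n >= 2")

  # swapping groups negates effect and t, preserves p
  set.seed(56)
  a <- rnorm(10); b <- rnorm(12, 1)
  ab <- t_test_pooled(a, b); ba <- t_test_pooled(b, a)
  expect_equal(ab$effect, -ba$effect, tolerance = 1e-12)
  expect_equal(ab$statistic, -ba$statistic, tolerance = 1e-12)
  expect_equal(ab$p_value, ba$p_value, tolerance = 1e-12)
})

test_that("published group comparisons are reproduced from summaries", {
  # brain-PAD: PWS (20, +8.74, 9.14) vs controls (40, +1.50, 7.42)
  bp <- t_test_from_summary(list(n = 20, mean = 8.74, sd = 9.14),
                            list(n = 40, mean = 1.50, sd = 7.42))
  expect_equal(bp$effect, 7.24, tolerance = 1e-12)
  expect_equal(bp$se, 2.20, tolerance = 0.005)
  expect_equal(bp$statistic, 3.29, tolerance = 0.005)
  expect_equal(bp$ci_lo, 2.83, tolerance = 0.02)
  expect_equal(bp$ci_hi, 11.63, tolerance = 0.02)
  expect_lt(bp$p_value, 0.005)

  # IQ: (20, 63.1, 11.9) vs (40, 112.9, 11.2)
  iq <- t_test_from_summary(list(n = 20, mean = 63.1, sd = 11.9),
                            list(n = 40, mean = 112.9, sd = 11.2))
  expect_equal(abs(iq$effect), 49.8, tolerance = 1e-12)
  expect_equal(iq$se, 3.1, tolerance = 0.05)
  expect_equal(abs(iq$statistic), 15.9, tolerance = 0.05)

  # BMI: (20, 30.1, 7.2) vs (40, 24.1, 3.8); printed t = -4.26 carries
  # rounding of the printed moments
  bmi <- t_test_from_summary(list(n = 20, mean = 30.1, sd = 7.2),
                             list(n = 40, mean = 24.1, sd = 3.8))
  expect_equal(bmi$effect, 6.0, tolerance = 1e-12)
  expect_equal(bmi$se, 1.4, tolerance = 0.05)
  expect_equal(abs(bmi$statistic), 4.26, tolerance = 0.05)
})

test_that("samples rescaled to the printed moments give the printed t", {
  set.seed(57)
  x1 <- match_moments(rnorm(20), 8.74, 9.14)
  x2 <- match_moments(rnorm(40), 1.50, 7.42)
  out <- t_test_pooled(x1, x2)
  expect_equal(round(out$statistic, 2), 3.29)
  expect_equal(out$effect, 7.24, tolerance = 1e-10)
})

test_that("Mann-Whitney U matches brute-force pair counting", {
  # exhaustive pair wins: x1 = {1,3}, x2 = {2,4}
  x1 <- c(1, 3); x2 <- c(2, 4)
  wins <- sum(outer(x1, x2, ">")) + 0.5 * sum(outer(x1, x2, "=="))
  out <- mann_whitney_u(x1, x2)
  expect_equal(out$U, wins)  # = 1

  # random case against the enumeration oracle
  set.seed(58)
  a <- sample(1:100, 8); b <- sample(101:200, 6) - 100.5
  expect_equal(mann_whitney_u(a, b)$U,
               sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "==")))

  # complete separation maximises U
  expect_equal(mann_whitney_u(c(10, 11, 12), c(1, 2))$U, 6)

  # identical samples: exact p = 1
  expect_equal(mann_whitney_u(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
})

test_that("chi-squared on 2x2 tables matches the O-E formula", {
  # perfectly proportional table
  out <- chi_squared_2x2(matrix(c(10, 20, 5, 10), 2, 2))
  expect_equal(out$chi2, 0, tolerance = 1e-12)
  expect_equal(out$p_value, 1, tolerance = 1e-12)

  # published sex table: 14/6 males/females vs 26/14 -> p ~ 0.70
  sex <- chi_squared_2x2(matrix(c(14, 6, 26, 14), 2, 2, byrow = TRUE))
  expect_equal(sex$p_value, 0.70, tolerance = 0.005)

  # brute force sum (O-E)^2/E, no correction
  tab <- matrix(c(7, 13, 11, 5), 2, 2)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(chi_squared_2x2(tab)$chi2, sum((tab - E)^2 / E),
               tolerance = 1e-12)

  expect_error(chi_squared_2x2(matrix(c(0, 0, 3, 4), 2, 2, byrow = TRUE)),
               "margin")
})

test_that("Pearson correlation matches the covariance formula", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_r(x, 2 * x + 1)$r, 1, tolerance = 1e-12)
  expect_equal(pearson_r(x, -x)$r, -1, tolerance = 1e-12)
  set.seed(59)
  a <- rnorm(30); b <- rnorm(30)
  brute <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(pearson_r(a, b)$r, brute, tolerance = 1e-12)
  expect_error(pearson_r(rep(1, 5), rnorm(5)), "zero variance")
})

test_that("OLS group effects match the normal equations", {
  set.seed(60)
  n <- 50
  dat <- data.frame(
    grp = factor(rep(c("A", "B"), each = n / 2)),
    c1 = rnorm(n), c2 = rnorm(n)
  )
  dat$y <- 2 + 3 * (dat$grp == "B") + 1.5 * dat$c1 - 0.7 * dat$c2 + rnorm(n)
  fit <- adjusted_group_effect(dat, "y", "grp", c("c1", "c2"))
  X <- cbind(1, dat$grp == "B", dat$c1, dat$c2)
  beta <- solve(t(X) %*% X, t(X) %*% dat$y)
  expect_equal(unname(fit$terms$estimate), as.numeric(beta),
               tolerance = 1e-10)
})

test_that("orthogonal covariates leave the group effect untouched", {
  set.seed(61)
  n <- 40
  grp <- rep(c(0, 1), each = n / 2)
  # covariate orthogonal to both group and response by construction
  cov_raw <- rnorm(n)
  cov_orth <- residuals(lm(cov_raw ~ grp))
  y <- 1 + 2 * grp + rnorm(n)
  y_orth <- residuals(lm(y ~ cov_orth)) + fitted(lm(y ~ 1))
  dat <- data.frame(y = y_orth, grp = factor(grp), cv = cov_orth)
  fit <- adjusted_group_effect(dat, "y", "grp", "cv")
  unadj <- mean(y_orth[grp == 1]) - mean(y_orth[grp == 0])
  g <- fit$terms$estimate[fit$terms$term == fit$group_term]
  expect_equal(g, unadj, tolerance = 1e-10)
})

test_that("a confounded design still recovers the generative group effect", {
  set.seed(62)
  n <- 200
  grp <- rep(c(0, 1), each = n / 2)
  confounder <- 5 * grp + rnorm(n)       # covariate differs by group
  y <- 1 + 4 * grp + 2 * confounder + rnorm(n)
  dat <- data.frame(y = y, grp = factor(grp), cf = confounder)
  fit <- adjusted_group_effect(dat, "y", "grp", "cf")
  row <- fit$terms[fit$terms$term == fit$group_term, ]
  expect_true(row$ci_lo <= 4 && 4 <= row$ci_hi)
  # the unadjusted effect is badly biased (4 + 2*5 = 14)
  unadj <- t_test_pooled(y[grp == 1], y[grp == 0])
  expect_gt(unadj$effect, 10)
})

test_that("rank-deficient designs are rejected with the offending term", {
  dat <- data.frame(y = rnorm(10), grp = factor(rep(c("A", "B"), 5)),
                    flat = rep(1, 10))
  expect_error(adjusted_group_effect(dat, "y", "grp", "flat"),
               "rank deficient")
  expect_error(interaction_test(dat, "y", "grp", "flat"), "constant")
})

test_that("interaction tests detect differing slopes and not shared ones", {
  set.seed(63)
  n <- 120
  grp <- rep(c(0, 1), each = n / 2)
  x <- rnorm(n)
  # shared slope: interaction p should not be extreme
  y_shared <- 1 + 2 * grp + 1.5 * x + rnorm(n)
  d1 <- data.frame(y = y_shared, grp = factor(grp), x = x)
  p_shared <- interaction_test(d1, "y", "grp", "x")$p_value
  expect_gt(p_shared, 0.001)

  # strongly differing slopes
  y_diff <- 1 + 2 * grp + (1.5 + 3 * grp) * x + rnorm(n)
  d2 <- data.frame(y = y_diff, grp = factor(grp), x = x)
  expect_lt(interaction_test(d2, "y", "grp", "x")$p_value, 0.001)
})

test_that("BMI matching keeps the overlap region, boundaries included", {
  coh <- data.frame(
    group = c(rep("PWS", 3), rep("Control", 3)),
    bmi = c(22, 30, 48, 19, 24, 34)
  )
  out <- bmi_match_filter(coh)
  expect_setequal(out$bmi[out$group == "PWS"], c(22, 30))      # 48 removed
  expect_setequal(out$bmi[out$group == "Control"], c(24, 34))  # 19 removed

  # boundary subjects exactly at the other group's extreme are retained
  coh2 <- data.frame(group = c("PWS", "PWS", "Control", "Control"),
                     bmi = c(21.5, 34.2, 21.5, 34.2))
  expect_equal(nrow(bmi_match_filter(coh2)), 4)

  # fully overlapping ranges: unchanged
  coh3 <- data.frame(group = rep(c("PWS", "Control"), each = 3),
                     bmi = c(20, 25, 30, 20, 26, 30))
  expect_equal(nrow(bmi_match_filter(coh3)), 6)

  # disjoint ranges: both groups emptied with a warning
  coh4 <- data.frame(group = rep(c("PWS", "Control"), each = 2),
                     bmi = c(40, 45, 20, 22))
  expect_warning(out4 <- bmi_match_filter(coh4), "emptied")
  expect_equal(nrow(out4), 0)
})

test_that("single-subject normative comparison computes z and percentile", {
  # published chain: +12.87 vs norms 0.84 +/- 6.48
  set.seed(64)
  norms <- match_moments(rnorm(95), 0.84, 6.48)
  out <- single_subject_vs_norm(12.87, norms)
  expect_equal(out$z, (12.87 - 0.84) / 6.48, tolerance = 1e-10)
  expect_equal(out$z, 1.86, tolerance = 0.005)

  # subject at the norm mean: z = 0, percentile ~ 50
  sym <- c(-2, -1, 0, 1, 2)
  mid <- single_subject_vs_norm(0, sym)
  expect_equal(mid$z, 0)
  expect_equal(mid$percentile, 50)

  # brute-force z on random instances
  for (seed in 65:67) {
    set.seed(seed)
    nr <- rnorm(20); sb <- rnorm(1)
    expect_equal(single_subject_vs_norm(sb, nr)$z,
                 (sb - mean(nr)) / sd(nr), tolerance = 1e-12)
  }
  expect_error(single_subject_vs_norm(1, c(2, 2, 2)), "zero SD")
})

test_that("group-effect CIs cover zero at the nominal rate under the null", {
  cov <- evaluate_ci_coverage(n_sims = 500, base_seed = 19)
  rate <- attr(cov, "summary")$coverage
  bounds <- qbinom(c(0.025, 0.975), 500, 0.95) / 500
  expect_gte(rate, bounds[1])
  expect_lte(rate, bounds[2])
})
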