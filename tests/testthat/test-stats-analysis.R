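test_that("small-sample Mann-Whitney enumerates the exact distribution", {
  r <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 0.1)   # 2/20 arrangements as extreme
  # symmetric orientation
  r2 <- mann_whitney(c(4, 5, 6), c(1, 2, 3))
  expect_equal(r2$statistic, 9)
  expect_equal(r2$p_value, 0.1)
  # identical samples: p = 1
  expect_gte(mann_whitney(c(1, 2, 3), c(1, 2, 3))$p_value, 0.999)
  expect_error(mann_whitney(numeric(0), 1:3), "nonempty")
})

test_that("exact Mann-Whitney matches wilcox.test and its normal limit", {
  set.seed(13)
  for (i in 1:50) {   # no ties: wilcox.test's exact p is the oracle
    a <- rnorm(5); b <- rnorm(6)
    expect_equal(mann_whitney(a, b)$p_value,
                 wilcox.test(a, b)$p.value, tolerance = 1e-12)
  }
  # the normal approximation tracks the exact p up to the discreteness of
  # the n = 6 + 6 null distribution (worst-case jump ~ 2 P(U = u))
  worst <- 0
  for (i in 1:200) {
    a <- sample(1:8, 6, replace = TRUE)   # ties likely
    b <- sample(1:8, 6, replace = TRUE)
    p_exact <- mann_whitney(a, b)$p_value
    p_norm <- suppressWarnings(
      wilcox.test(a, b, exact = FALSE, correct = FALSE)$p.value)
    worst <- max(worst, abs(p_exact - p_norm))
  }
  expect_lt(worst, 0.2)
})

test_that("Mann-Whitney has near-complete power under a 2-sd shift", {
  set.seed(17)
  rejections <- mean(replicate(1000, {
    mann_whitney(rnorm(50), rnorm(50, 2))$p_value < 0.05
  }))
  expect_gt(rejections, 0.99)
})

test_that("Kruskal-Wallis follows the rank formula and the null chi-square", {
  same <- kruskal_wallis(list(c(1, 5, 9), c(1, 5, 9), c(1, 5, 9)))
  expect_lt(same$statistic, 1e-9)
  # separated groups {1,2},{3,4},{5,6}: H = 12/(6*7) * sum(R_j^2/n_j) - 3*7
  r <- kruskal_wallis(list(c(1, 2), c(3, 4), c(5, 6)))
  h_manual <- 12 / (6 * 7) * (3^2 / 2 + 7^2 / 2 + 11^2 / 2) - 3 * 7
  expect_equal(r$statistic, h_manual, tolerance = 1e-9)
  expect_equal(r$statistic, 4.5714286, tolerance = 1e-6)
  expect_equal(r$df, 2)
  expect_error(kruskal_wallis(list(1:3)), "at least 2")
})

test_that("Kruskal-Wallis holds its type-I error on null Gaussian groups", {
  set.seed(19)
  rate <- mean(replicate(2000, {
    kruskal_wallis(lapply(1:6, function(i) rnorm(20)))$p_value < 0.05
  }))
  expect_gte(rate, 0.04)
  expect_lte(rate, 0.06)
})

test_that("two-group Kruskal-Wallis orders p like Mann-Whitney", {
  set.seed(23)
  ps <- t(replicate(30, {
    a <- rnorm(15); b <- rnorm(15, runif(1, 0, 1.5))
    c(mw = mann_whitney(a, b)$p_value,
      kw = kruskal_wallis(list(a, b))$p_value)
  }))
  expect_equal(order(ps[, "mw"]), order(ps[, "kw"]))
})

test_that("chi-square matches the demographic worked example", {
  # sex by group: 8/7 controls, 42/41 diabetic
  r <- chi_square(matrix(c(8, 42, 7, 41), 2))
  expect_equal(round(r$statistic, 2), 0.04)
  expect_equal(r$df, 1)
  expect_equal(round(r$p_value, 3), 0.846)
  # proportional table: no association
  expect_lt(chi_square(matrix(c(10, 20, 30, 60), 2))$statistic, 1e-9)
  # maximally associated 2x2
  expect_equal(chi_square(matrix(c(10, 0, 0, 10), 2))$statistic, 20)
  expect_error(chi_square(matrix(c(0, 0, 3, 5), 2)), "marginal")
})

test_that("Welch's t from summaries matches the cohort age comparison", {
  r <- welch_t(57.5, 13.0, 15, 60.5, 12.9, 83)
  expect_equal(round(r$statistic, 2), -0.82, tolerance = 0.011)
  expect_equal(round(r$df, 2), 19.32, tolerance = 0.011)
  expect_equal(r$p_value, 0.4203, tolerance = 1e-3)
  # oracle: t.test on samples engineered to have these exact summaries
  set.seed(29)
  mk <- function(n, m, s) { x <- rnorm(n); m + s * (x - mean(x)) / sd(x) }
  a <- mk(15, 57.5, 13.0); b <- mk(83, 60.5, 12.9)
  tt <- t.test(a, b)
  expect_equal(r$statistic, unname(tt$statistic), tolerance = 1e-9)
  expect_equal(r$df, unname(tt$parameter), tolerance = 1e-9)
  expect_equal(r$p_value, tt$p.value, tolerance = 1e-9)
})

test_that("Welch's t is zero at equal means and scales inversely with sd", {
  expect_equal(welch_t(5, 1, 10, 5, 2, 12)$statistic, 0)
  expect_equal(welch_t(5, 1, 10, 5, 2, 12)$p_value, 1)
  t1 <- welch_t(0, 1, 20, 1, 1, 20)$statistic
  t2 <- welch_t(0, 2, 20, 1, 2, 20)$statistic
  expect_equal(t2, t1 / 2, tolerance = 1e-12)
  expect_error(welch_t(0, 1, 1, 1, 1, 20), "n >= 2")
})

test_that("Spearman handles monotone, tied and constant inputs", {
  expect_equal(spearman(1:10, (1:10)^3)$statistic, 1)
  expect_equal(spearman(1:10, -(1:10))$statistic, -1)
  r <- spearman(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5))
  expect_equal(r$statistic, 0.8)   # 1 - 6*4/(5*24)
  const <- spearman(c(1, 1, 1, 1), c(1, 2, 3, 4))
  expect_true(const$undefined)
  expect_true(is.na(const$statistic))
  # oracle: cor.test with the asymptotic t approximation
  set.seed(31)
  x <- rnorm(40); y <- x + rnorm(40)
  s <- spearman(x, y)
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  expect_equal(s$statistic, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(s$p_value, ct$p.value, tolerance = 1e-6)
})

test_that("strength labels follow the absolute-rho cut-points", {
  expect_identical(strength_label(0.44), "moderate")
  expect_identical(strength_label(0.27), "weak")
  expect_identical(strength_label(-0.85), "high")
  # boundary values go to the upper category
  expect_identical(strength_label(0.3), "moderate")
  expect_identical(strength_label(0.7), "high")
  expect_identical(strength_label(c(0, 1, -1)), c("weak", "high", "high"))
  expect_error(strength_label(1.2), "exceed")
})

test_that("correlation matrices have the configured shape and fields", {
  set.seed(37)
  oct <- as.data.frame(matrix(rnorm(200 * 5), 200,
                              dimnames = list(NULL, paste0("rnfl_",
                                c("whole", "S", "N", "I", "T")))))
  octa <- as.data.frame(matrix(rnorm(200 * 6), 200,
                               dimnames = list(NULL, paste0("octa_m", 1:6))))
  cm <- correlation_matrix(oct, octa)
  expect_equal(nrow(cm), 30)
  expect_equal(attr(cm, "family_size"), 30)
  expect_true(all(cm$p_adj >= cm$p - 1e-15))
  expect_lte(sum(cm$significant), sum(cm$p < 0.05))
  # cells with <3 complete pairs are flagged missing
  oct$rnfl_whole[3:200] <- NA
  cm2 <- correlation_matrix(oct, octa)
  expect_true(all(cm2$missing[cm2$oct_var == "rnfl_whole"]))
})

test_that("a known latent coupling is recovered from the synthetic cohort", {
  rhos <- vapply(1:10, function(s) {
    coh <- generate_cohort(cohort_config(n_per_grade = c(DR0 = 500),
                                         seed = s))
    spearman(coh$rnfl_I, coh$octa_flux_I)$statistic
  }, numeric(1))
  expect_lt(abs(mean(rhos) - implied_spearman(0.4)), 0.1)
})

test_that("permuting one table wipes out Bonferroni-corrected significance", {
  coh <- generate_cohort(cohort_config(n_per_grade = c(DR0 = 200), seed = 41))
  oct <- coh[paste0("rnfl_", c("whole", "S", "N", "I", "T"))]
  octa <- coh[paste0("octa_flux_", c("whole", "S", "N", "I", "T"))]
  expect_gt(sum(correlation_matrix(oct, octa)$significant), 0)
  set.seed(43)
  frac_sig <- mean(replicate(50, {
    cm <- correlation_matrix(oct[sample(nrow(oct)), , drop = FALSE], octa)
    mean(cm$significant)
  }))
  expect_lte(frac_sig, 0.05)
})

test_that("family-wise error stays at alpha under an independent null", {
  set.seed(47)
  fwe <- mean(replicate(1000, {
    oct <- as.data.frame(matrix(rnorm(40 * 4), 40))
    octa <- as.data.frame(matrix(rnorm(40 * 5), 40))
    any(correlation_matrix(oct, octa)$significant)
  }))
  # binomial tolerance around alpha = 0.05 (Bonferroni is conservative)
  expect_lte(fwe, 0.05 + 2 * sqrt(0.05 * 0.95 / 1000))
})
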