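test_that("adjusted test without covariates reduces to the pooled-variance t-test", {
  vals <- c(3.1, 2.4, 5.0, 4.2, 3.3, 2.8, 6.1, 5.5, 4.9, 6.3, 5.8, 7.0)
  grp <- rep(c("a", "b"), each = 6)
  res <- adjusted_group_test(vals, grp)
  tt <- t.test(vals[grp == "b"], vals[grp == "a"], var.equal = TRUE)
  expect_equal(res$t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(res$p, tt$p.value, tolerance = 1e-12)
  expect_equal(res$df, 10)
})

test_that("adjusted test equals brute-force normal-equation OLS", {
  set.seed(30)
  grp <- factor(rep(c("a", "b"), each = 5))
  age <- rnorm(10, 30, 5)
  vals <- rnorm(10) + 0.5 * (grp == "b") + 0.1 * age
  res <- adjusted_group_test(vals, grp, data.frame(age = age))
  x <- cbind(1, as.numeric(grp == "b"), age)
  oracle <- bruteforce_ols_t(x, vals, col = 2L)
  expect_equal(res$t, oracle$t, tolerance = 1e-10)
  expect_equal(res$df, oracle$df)
})

test_that("adjusted test guards rank deficiency, missingness and group levels", {
  set.seed(31)
  grp <- rep(c("a", "b"), each = 10)
  vals <- rnorm(20)
  age <- rnorm(20)
  expect_error(adjusted_group_test(vals, grp, data.frame(a1 = age, a2 = 2 * age)),
               "collinear")
  expect_error(adjusted_group_test(vals, rep("a", 20)), "two levels")
  # listwise deletion reduces n
  vals[1] <- NA
  res <- adjusted_group_test(vals, grp, data.frame(age = age))
  expect_identical(res$n, 19L)
})

test_that("partial correlation reduces and matches the residualization oracle", {
  set.seed(32)
  x <- rnorm(20); y <- 0.6 * x + rnorm(20)
  plain <- partial_pearson(x, y)
  expect_equal(plain$r, cor(x, y), tolerance = 1e-12)
  expect_equal(plain$p, cor.test(x, y)$p.value, tolerance = 1e-10)

  # removing the shared covariate recovers a perfect residual correlation
  z <- rnorm(20)
  expect_equal(partial_pearson(x + 2 * z, x + 2 * z + 0 * y,
                               data.frame(z = z))$r, 1, tolerance = 1e-12)

  # 15-point toy with 2 covariates vs explicit two-stage residualization
  x2 <- rnorm(15); y2 <- rnorm(15)
  c1 <- rnorm(15); c2 <- rnorm(15)
  res <- partial_pearson(x2, y2, data.frame(c1 = c1, c2 = c2))
  d <- cbind(1, c1, c2)
  rx <- x2 - d %*% solve(t(d) %*% d, t(d) %*% x2)
  ry <- y2 - d %*% solve(t(d) %*% d, t(d) %*% y2)
  expect_equal(res$r, cor(rx, ry)[1, 1], tolerance = 1e-10)
  expect_identical(res$df, 15L - 2L - 2L)
})

test_that("partial correlation is invariant to affine covariate transforms", {
  set.seed(33)
  x <- rnorm(30); y <- rnorm(30); z <- rnorm(30)
  a <- partial_pearson(x, y, data.frame(z = z))
  b <- partial_pearson(x, y, data.frame(z = 10 * z - 3))
  expect_equal(a$r, b$r, tolerance = 1e-12)
  expect_equal(a$p, b$p, tolerance = 1e-12)
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(fdr_bh(rep(0.03, 7)), rep(0.03, 7))
  expect_equal(fdr_bh(seq(0.01, 0.07, by = 0.01)), rep(0.07, 7))
  expect_error(fdr_bh(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(34)
  for (rep in 1:200) {
    p <- runif(sample(c(7, 49), 1))
    expect_equal(fdr_bh(p), bruteforce_bh(p), tolerance = 1e-15)
  }
  # q >= p and order preservation; agrees with the stock BH implementation
  p <- runif(49)
  q <- fdr_bh(p)
  expect_equal(q, p.adjust(p, method = "BH"), tolerance = 1e-12)
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= -1e-15))
})

test_that("chi-square and Mann-Whitney demographics tests match hand values", {
  res <- chisq_2x2(matrix(c(93, 80, 122, 141), 2))
  expect_equal(res$chi2, 2.267, tolerance = 5e-4)
  expect_equal(chisq_2x2(matrix(c(10, 20, 10, 20), 2))$chi2, 0)
  expect_equal(chisq_2x2(matrix(c(10, 0, 0, 10), 2))$chi2, 20)
  expect_error(chisq_2x2(matrix(c(0, 0, 5, 5), 2)), "marginal")

  mw <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(mw$z, 0)
  expect_equal(mw$p, 1)
  expect_equal(mann_whitney(c(1, 2, 3), c(4, 5, 6))$U, 0)
  set.seed(35)
  x <- sample(1:5, 8, replace = TRUE)
  y <- sample(1:5, 8, replace = TRUE)
  expect_equal(mann_whitney(x, y)$U, bruteforce_u(x, y))
  # two-sided p agrees with the tie-aware normal approximation in base R
  expect_equal(mann_whitney(x, y)$p,
               suppressWarnings(wilcox.test(x, y, correct = FALSE,
                                            exact = FALSE)$p.value),
               tolerance = 1e-10)
})

test_that("group contrast table controls FDR within the declared families", {
  set.seed(36)
  truth <- synthetic_truth(k = 3, atlas = synthetic_atlas(24), seed = 2)
  cohort <- simulate_cohort(truth, 10, 10, t_len = 100, seed = 3)
  dyn <- dynamics_table(lapply(seq_along(cohort$states), function(i)
    dynamic_profile(cohort$states[[i]], 3L,
                    subject_id = cohort$manifest$subject_id[i])))
  tab <- group_contrast_table(dyn, cohort$manifest)
  expect_s3_class(tab, "stat_table")
  for (f in unique(tab$family)) {
    idx <- tab$family == f & !is.na(tab$p)
    expect_equal(tab$q[idx], fdr_bh(tab$p[idx]))
  }
  # per-CAP families have K members; path families K x K
  expect_identical(sum(tab$family == "dwell"), 3L)
  expect_identical(sum(tab$family == "path_transition"), 9L)
  expect_true(all(tab$q >= tab$p - 1e-15, na.rm = TRUE))
})

test_that("symptom correlations recover a planted HAMD linkage", {
  set.seed(37)
  truth <- synthetic_truth(k = 3, atlas = synthetic_atlas(24),
                           hamd_slope = 1.5, hamd_sigma = 3, seed = 5)
  cohort <- simulate_cohort(truth, 5, 200, t_len = 240, seed = 6)
  dyn <- dynamics_table(lapply(seq_along(cohort$states), function(i)
    dynamic_profile(cohort$states[[i]], 3L,
                    subject_id = cohort$manifest$subject_id[i])))
  ct <- symptom_correlation_table(dyn, cohort$manifest, group = "patient")
  row <- ct[ct$metric == "dwell" & ct$cap_from == truth$effect_cap, ]
  expect_gt(row$r, 0)
  # expected correlation from the generating linear model
  pat <- cohort$manifest$group == "patient"
  d_true <- vapply(cohort$states[pat], function(s)
    dwell_and_occurrence(s, 3L)$dwell_time[truth$effect_cap + 1L], numeric(1))
  r_true <- 1.5 * sd(d_true) / sqrt(1.5^2 * var(d_true) + 3^2)
  expect_lt(abs(row$r - r_true), 0.15)
})
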