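test_that("pearson correlation matches hand-computed values", {
  res <- pearson_corr(c(1, 2, 3), c(6, 4, 5))
  expect_equal(res$r, -0.5, tolerance = 1e-12)
  expect_equal(res$df, 1)

  exact <- pearson_corr(1:10, 2 * (1:10) + 1)
  expect_equal(exact$r, 1, tolerance = 1e-12)

  set.seed(1)
  x <- rnorm(20); y <- rnorm(20)
  expect_equal(pearson_corr(x, -y)$r, -pearson_corr(x, y)$r)
  # p agrees with cor.test
  ct <- cor.test(x, y)
  res2 <- pearson_corr(x, y)
  expect_equal(res2$p, ct$p.value)

  expect_error(pearson_corr(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(pearson_corr(1:2, 1:2), "at least 3")
})

test_that("partial correlation equals the residual and recursive oracles", {
  set.seed(2)
  n <- 40
  z <- rnorm(n)
  x <- 0.5 * z + rnorm(n)
  y <- -0.3 * z + rnorm(n)
  res <- partial_corr(x, y, z)
  # recursive formula oracle
  rxy <- cor(x, y); rxz <- cor(x, z); ryz <- cor(y, z)
  want <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  expect_equal(res$r, want, tolerance = 1e-10)
  expect_equal(res$df, n - 3)

  # orthogonal covariate changes nothing (on pre-residualized data)
  xo <- lm(x ~ z)$residuals
  yo <- lm(y ~ z)$residuals
  expect_equal(partial_corr(xo, yo, z)$r, pearson_corr(xo, yo)$r,
               tolerance = 1e-10)

  # several covariates vs explicit double residualization
  z2 <- cbind(z, rnorm(n))
  rx <- lm(x ~ z2)$residuals
  ry <- lm(y ~ z2)$residuals
  expect_equal(partial_corr(x, y, z2)$r, cor(rx, ry), tolerance = 1e-10)

  expect_error(partial_corr(x, z, z), "zero residual variance")
  expect_error(partial_corr(x, y, cbind(z, 2 * z)), "collinear")
})

test_that("rm_ancova reproduces the mixed-design df structure", {
  set.seed(3)
  n <- 30; k <- 4
  Y <- matrix(rnorm(n * k), n)
  age <- runif(n, 9, 18.5)
  res <- rm_ancova(Y, age)
  eff <- res$effects
  expect_equal(eff$df1[eff$effect == "covariate"], 1)
  expect_equal(eff$df2[eff$effect == "covariate"], n - 2)
  # GG-corrected within dfs keep the ratio df2/df1 = n - 2
  w <- eff[eff$effect == "within", ]
  expect_equal(w$df2 / w$df1, n - 2)
  expect_equal(res$df_uncorrected[["within"]], k - 1)
  expect_equal(res$df_uncorrected[["error"]], (k - 1) * (n - 2))
  expect_gte(res$epsilon, 1 / (k - 1))
  expect_lte(res$epsilon, 1)

  expect_error(rm_ancova(Y[1:4, ], age[1:4]), "at least 5")
  Yna <- Y; Yna[2, 3] <- NA
  expect_error(rm_ancova(Yna, age), "missing")
})

test_that("rm_ancova agrees with the car multivariate-lm oracle", {
  skip_if_not_installed("car")
  set.seed(4)
  for (i in 1:5) {
    n <- sample(15:40, 1)
    Y <- matrix(rnorm(n * 4), n) %*% chol(0.4 + 0.6 * diag(4))
    age <- runif(n, 9, 18.5)
    Y <- Y + outer(age - mean(age), c(0.1, 0, -0.1, 0.05))
    res <- rm_ancova(Y, age)
    dfc <- data.frame(age_c = age - mean(age))
    mlm <- lm(Y ~ age_c, data = dfc)
    A <- car::Anova(mlm, idata = data.frame(ard = factor(1:4)),
                    idesign = ~ard, type = 3)
    s <- suppressWarnings(summary(A, multivariate = FALSE))  # benign HF eps > 1
    u <- s$univariate.tests
    expect_equal(res$effects$F[1], u["age_c", "F value"], tolerance = 1e-8)
    expect_equal(res$effects$F[2], u["ard", "F value"], tolerance = 1e-8)
    expect_equal(res$effects$F[3], u["age_c:ard", "F value"], tolerance = 1e-8)
    expect_equal(res$epsilon,
                 unname(s$pval.adjustments["ard", "GG eps"]),
                 tolerance = 1e-8)
    expect_equal(res$effects$p[2],
                 unname(s$pval.adjustments["ard", "Pr(>F[GG])"]),
                 tolerance = 1e-8)
  }
})

test_that("epsilon is near one for compound-symmetric data", {
  set.seed(6)
  eps <- vapply(1:40, function(i) {
    n <- 100                # large n: the GG estimator is biased low at small n
    subj <- rnorm(n, 0, 1)  # shared subject effect -> CS covariance
    Y <- outer(subj, rep(1, 4)) + matrix(rnorm(n * 4, 0, 1), n)
    rm_ancova(Y, runif(n, 9, 18.5))$epsilon
  }, numeric(1))
  expect_equal(mean(eps), 1, tolerance = 0.05)
})

test_that("BH FDR equals the brute-force step-up procedure", {
  expect_equal(fdr_bh(c(0.01, 0.02, 0.03, 0.04, 0.05), 0.05)$rejected,
               rep(TRUE, 5))
  expect_equal(fdr_bh(rep(1, 6), 0.05)$rejected, rep(FALSE, 6))
  expect_true(fdr_bh(0.04, 0.05)$rejected)
  expect_equal(fdr_bh(numeric(0))$adjusted, numeric(0))

  set.seed(7)
  for (i in 1:200) {
    m <- sample(1:30, 1)
    p <- runif(m)^sample(1:3, 1)
    got <- fdr_bh(p, 0.05)
    want <- oracle_bh(p, 0.05)
    expect_equal(got$adjusted, want$adjusted, tolerance = 1e-12)
    expect_identical(got$rejected, want$rejected)
  }
})

test_that("permutation p values behave like p values", {
  # identity: no permutation (except a re-drawn identity) beats r = 1
  x <- c(2, 5, 1, 9, 3, 7, 4, 12, 0, 8, 6, 11)
  res <- permutation_pearson(x, x, n_perm = 499, seed = 1)
  expect_equal(res$p_perm, 1 / 500)
  res2 <- permutation_pearson(x, x, n_perm = 499, seed = 1)
  expect_identical(res$p_perm, res2$p_perm)

  # parametric and permutation p agree under normality
  set.seed(8)
  x <- rnorm(25); y <- 0.5 * x + rnorm(25)
  res3 <- permutation_pearson(x, y, n_perm = 2000, seed = 3)
  expect_lt(abs(res3$p_perm - res3$p), 0.02)

  # roughly uniform under independence
  set.seed(9)
  ps <- vapply(1:60, function(i) {
    permutation_pearson(rnorm(12), rnorm(12), n_perm = 199, seed = i)$p_perm
  }, numeric(1))
  expect_lt(abs(mean(ps) - 0.5), 0.08)
})

test_that("analyze_cohort runs correlations, ANCOVA and FDR together", {
  cfg <- run_config(n = 20, seed = 5)
  res <- run_pipeline(cfg)
  tbl <- res$cohort
  tbl$roi_a <- 100 - 2 * tbl$age + rnorm(nrow(tbl), 0, 4)
  tbl$roi_b <- rnorm(nrow(tbl), 50, 5)
  out <- analyze_cohort(tbl, measures = c("roi_a", "roi_b"),
                        control = "age", n_perm = 199, seed = 2)
  expect_equal(nrow(out$correlations), 2)
  mc <- out$measure_correlations
  expect_equal(nrow(mc), 8)  # 2 measures x 4 outcomes
  expect_true(all(mc$df == nrow(tbl) - 3))
  expect_true(all(mc$p_fdr >= mc$p - 1e-12))
  expect_true(all(mc$p_perm > 0 & mc$p_perm <= 1))
})
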