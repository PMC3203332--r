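test_that("ridge logistic refit matches a generic penalized-likelihood optimizer", {
  for (s in 1:3) {
    ds <- random_dataset(n = 60, L = 2, seed = 110 + s)
    X <- dummy_cols_for_test(ds$genotypes,
                             data.frame(a = 1:2, b = NA_integer_))
    fit <- ridge_logistic_refit(X, ds$phenotype, ridge = 1e-4)
    expect_true(fit$converged)
    o <- oracle_ridge_logistic(X, ds$phenotype, ridge = 1e-4)
    expect_equal(fit$loglik, o$loglik, tolerance = 1e-6)
    # the stationarity condition of the penalized likelihood holds exactly
    Xt <- cbind(1, X)
    grad <- drop(crossprod(Xt, ds$phenotype - fit$fitted)) -
      c(0, rep(1e-4, ncol(X))) * fit$coef
    expect_lt(sqrt(sum(grad^2)), 1e-8)
    # near-flat ridge directions keep BFGS coefficients only loosely pinned
    expect_lt(max(abs(fit$coef - o$coef)), 0.02)
  }
})

test_that("collinear dummy blocks stay finite and a huge ridge collapses to the intercept", {
  ds <- random_dataset(n = 50, L = 1, seed = 121)
  X <- dummy_cols_for_test(ds$genotypes, data.frame(a = 1L, b = NA_integer_))
  fit <- ridge_logistic_refit(X, ds$phenotype, ridge = 1e-4)
  expect_true(all(is.finite(fit$coef)))
  big <- ridge_logistic_refit(X, ds$phenotype, ridge = 1e8)
  expect_lt(max(abs(big$coef[-1])), 1e-5)
  p0 <- mean(ds$phenotype)
  ll0 <- sum(ds$phenotype * log(p0) + (1 - ds$phenotype) * log(1 - p0))
  expect_equal(big$loglik, ll0, tolerance = 1e-6)
})

test_that("effective df hits its projection and intercept-only limits", {
  set.seed(131)
  n <- 80
  X <- matrix(rnorm(n * 4), n, 4)        # full column rank, no collinearity
  y <- rbinom(n, 1, 0.5)
  fit <- ridge_logistic_refit(X, y, ridge = 1e-10)
  expect_equal(effective_df(X, fit$fitted, 1e-10), 5, tolerance = 1e-4)
  expect_equal(effective_df(X, fit$fitted, 1e10), 1, tolerance = 1e-4)
  # one SNP's 3 collinear dummies + intercept: rank 3, not 4
  ds <- random_dataset(n = 100, L = 2, seed = 132)
  X1 <- dummy_cols_for_test(ds$genotypes, data.frame(a = 1L, b = NA_integer_))
  f1 <- ridge_logistic_refit(X1, ds$phenotype, ridge = 1e-4)
  df1 <- effective_df(X1, f1$fitted, 1e-4)
  expect_equal(df1, 3, tolerance = 0.01)
  # adding a second SNP adds ~2 effective df (the paper-style working df)
  X2 <- dummy_cols_for_test(ds$genotypes,
                            data.frame(a = 1:2, b = NA_integer_))
  f2 <- ridge_logistic_refit(X2, ds$phenotype, ridge = 1e-4)
  df2 <- effective_df(X2, f2$fitted, 1e-4)
  expect_equal(df2 - df1, 2, tolerance = 0.01)
})

test_that("Bonferroni correction multiplies and caps", {
  expect_equal(bonferroni(0.001, 100), 0.1)
  expect_equal(bonferroni(0.5, 10), 1.0)
  expect_equal(bonferroni(3e-4, 1000), 0.3)
  expect_equal(bonferroni(c(0, 1), 5), c(0, 1))
  expect_error(bonferroni(1.2, 10))
})

test_that("main-effect tests flag a strong signal and keep df in (1.5, 3)", {
  # one SNP with a large additive effect among noise
  set.seed(141)
  n <- 600
  g1 <- sample(0:2, n, replace = TRUE, prob = c(0.36, 0.48, 0.16))
  g2 <- sample(0:2, n, replace = TRUE, prob = c(0.36, 0.48, 0.16))
  y <- rbinom(n, 1, plogis(-0.5 + 1.2 * g1))
  ds <- genotype_dataset(cbind(g1, g2), y, snp_ids = c("rs1", "rs2"))
  res <- test_main_effects(ds, c("rs1", "rs2"), correction_factor = 1000)
  expect_s3_class(res, "association_result")
  expect_equal(res$group_id, c("rs1", "rs2"))
  expect_true(all(res$stat >= -1e-8))
  expect_true(all(res$df > 1.5 & res$df < 3.0))
  expect_true(res$significant[res$group_id == "rs1"])
  expect_lt(res$p_bonf[1], 1e-6)
  expect_gt(res$p_raw[2], 1e-4)   # the noise SNP carries no signal
  # empty active set -> empty result, no tests run
  expect_equal(nrow(test_main_effects(ds, integer(0))), 0)
})

test_that("null p-values of a singleton refit are roughly uniform", {
  set.seed(151)
  pvals <- replicate(60, {
    n <- 120
    g <- sample(0:2, n, replace = TRUE, prob = c(0.49, 0.42, 0.09))
    y <- sample(rep(0:1, length.out = n))
    ds <- genotype_dataset(matrix(g, n, 1), y)
    test_main_effects(ds, 1L, correction_factor = 1)$p_raw
  })
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 1e-3)
  expect_gt(mean(pvals), 0.35)
  expect_lt(mean(pvals), 0.65)
})

test_that("interaction tests are nested (stat >= 0), bracket df in (2.5, 9), and detect epistasis", {
  ds <- simulate_case_control(table2_model("M1-3"), 200, 200, 3, seed = 161)
  loci <- ds$truth$loci
  groups <- data.frame(a = loci[1], b = loci[2])
  res <- test_interactions(ds, groups, correction_factor = 10)
  expect_equal(nrow(res), 1)
  expect_gte(res$stat, -1e-8)
  expect_true(res$df > 2.5 && res$df < 9.0)
  expect_true(res$significant)
  # main-effect rows are not tested; only pairs are
  res2 <- test_interactions(ds, data.frame(a = 1L, b = NA_integer_))
  expect_equal(nrow(res2), 0)
})

test_that("a purely additive two-SNP signal shows no interaction", {
  set.seed(171)
  n <- 500
  g1 <- sample(0:2, n, replace = TRUE, prob = c(0.36, 0.48, 0.16))
  g2 <- sample(0:2, n, replace = TRUE, prob = c(0.36, 0.48, 0.16))
  y <- rbinom(n, 1, plogis(-1 + 0.8 * g1 + 0.8 * g2))
  ds <- genotype_dataset(cbind(g1, g2), y)
  # the pair group plus both main groups selected; test the pair block
  groups <- data.frame(a = c(1L, 2L, 1L), b = c(NA_integer_, NA_integer_, 2L))
  res <- test_interactions(ds, groups, correction_factor = 1)
  expect_gte(res$stat, -1e-8)
  expect_gt(res$p_raw, 0.001)   # no deviation from the main-effects model
})
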