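test_that("logistic log-likelihood matches closed forms and an independent evaluation", {
  ds <- random_dataset(n = 30, L = 3, seed = 7)
  d <- build_main_design(ds)
  y <- ds$phenotype
  expect_equal(logistic_loglik(d, 0, numeric(d$p), y), 30 * log(0.5))
  ybar <- mean(y)
  expect_equal(logistic_loglik(d, qlogis(ybar), numeric(d$p), y),
               30 * (ybar * log(ybar) + (1 - ybar) * log(1 - ybar)))
  # random coefficients against a dense-matrix evaluation
  set.seed(8)
  beta <- rnorm(d$p)
  b0 <- rnorm(1)
  eta <- drop(b0 + as.matrix(design_matrix(d)) %*% beta)
  expect_equal(logistic_loglik(d, b0, beta, y),
               sum(y * eta - log(1 + exp(eta))))
})

test_that("gamma_max is the smallest all-zero penalty and scales with the weights", {
  ds <- random_dataset(n = 60, L = 5, seed = 9)
  d <- build_main_design(ds)
  y <- ds$phenotype
  expect_equal(gamma_max(d, rep(1, 60)), 0)   # constant phenotype
  gm <- gamma_max(d, y)
  expect_gt(gm, 0)
  expect_equal(gamma_max(d, y, weights = 2), gm / 2)
  f_above <- fit_group_lasso(d, y, 1.01 * gm)
  expect_length(f_above$active_set, 0)
  expect_equal(f_above$intercept, qlogis(mean(y)), tolerance = 1e-6)
  f_below <- fit_group_lasso(d, y, 0.99 * gm)
  expect_gt(length(f_below$active_set), 0)
})

test_that("solver coefficients agree with a proximal-gradient oracle on tiny instances", {
  worst <- 0
  for (s in 1:10) {
    ds <- random_dataset(n = 50, L = 4, seed = s)
    d <- build_interaction_design(ds)    # 4 main + 6 pair groups
    y <- ds$phenotype
    gm <- gamma_max(d, y)
    for (frac in c(0.7, 0.4)) {
      f <- fit_group_lasso(d, y, frac * gm)
      oi <- oracle_inputs(d, frac * gm, rep(1, nrow(d$groups)))
      o <- oracle_group_lasso(oi$X, y, oi$groups, oi$lambda)
      worst <- max(worst,
                   max(abs(c(f$intercept - o$intercept,
                             f$beta_vector - o$beta))))
      expect_equal(f$objective, o$objective, tolerance = 1e-7)
    }
  }
  expect_lt(worst, 1e-4)
})

test_that("every fit satisfies the KKT subgradient conditions", {
  for (s in 1:5) {
    ds <- random_dataset(n = 45, L = 5, seed = 20 + s)
    d <- build_interaction_design(ds)
    y <- ds$phenotype
    gm <- gamma_max(d, y)
    for (frac in c(0.9, 0.5, 0.25)) {
      f <- fit_group_lasso(d, y, frac * gm)
      chk <- kkt_check(f, d, y)
      expect_true(chk$ok)
    }
  }
})

test_that("the unpenalized limit reproduces the maximum-likelihood logistic fit", {
  ds <- random_dataset(n = 80, L = 2, seed = 31)
  d <- build_main_design(ds)
  y <- ds$phenotype
  f <- fit_group_lasso(d, y, gamma = 0,
                       control = agl_control(tol = 1e-8, maxit_irls = 200))
  ref <- stats::glm(y ~ factor(ds$genotypes[, 1]) + factor(ds$genotypes[, 2]),
                    family = stats::binomial())
  expect_equal(logistic_loglik(d, f$intercept, f$beta_vector, y),
               as.numeric(stats::logLik(ref)), tolerance = 1e-6)
  eta <- drop(f$intercept + as.matrix(design_matrix(d)) %*% f$beta_vector)
  expect_equal(unname(stats::plogis(eta)), unname(ref$fitted.values),
               tolerance = 1e-4)
})

test_that("the active set is identical whether the path is run warm or each point cold", {
  ds <- random_dataset(n = 60, L = 6, seed = 41)
  d <- build_main_design(ds)
  y <- ds$phenotype
  gm <- gamma_max(d, y)
  grid <- gm * c(1, 0.8, 0.6, 0.45, 0.3, 0.2)
  warm <- warm_path_active_sets(d, y, grid)
  for (k in seq_along(grid)) {
    cold <- fit_group_lasso(d, y, grid[k])
    expect_setequal(cold$active_idx, warm[[k]])
  }
})

test_that("cross-validation selection is reproducible, honors a 1-point grid, and stays sparse on noise", {
  ds <- random_dataset(n = 60, L = 8, seed = 51)
  d <- build_main_design(ds)
  y <- ds$phenotype
  expect_equal(cv_select_gamma(d, y, grid = 0.37)$gamma, 0.37)
  set.seed(123)
  cv1 <- cv_select_gamma(d, y)
  set.seed(123)
  cv2 <- cv_select_gamma(d, y)
  expect_identical(cv1, cv2)
  # pure-noise data: the selected model is empty or nearly so in most runs
  empties <- 0L
  for (s in 1:5) {
    dsn <- random_dataset(n = 80, L = 30, seed = 60 + s)
    dn <- build_main_design(dsn)
    set.seed(s)
    cv <- cv_select_gamma(dn, dsn$phenotype)
    f <- fit_group_lasso(dn, dsn$phenotype, cv$gamma)
    if (length(f$active_set) <= 1) empties <- empties + 1L
  }
  expect_gte(empties, 3L)
})
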