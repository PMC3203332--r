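test_that("Hardy-Weinberg genotype probabilities are correct and normalized", {
  expect_equal(hwe_genotype_probs(0.5), c(0.25, 0.5, 0.25))
  expect_equal(hwe_genotype_probs(0.4), c(0.36, 0.48, 0.16))
  for (q in seq(0.01, 0.5, by = 0.07)) {
    p <- hwe_genotype_probs(q)
    expect_equal(sum(p), 1)
    expect_true(all(p > 0))
  }
  expect_error(hwe_genotype_probs(0), "maf")
  expect_error(hwe_genotype_probs(0.6), "maf")
  expect_error(hwe_genotype_probs(-0.1), "maf")
})

test_that("parametric penetrance tables follow the multiplicative and interference patterns", {
  m <- build_table1_model("M1-1", alpha = 0.05, theta = 0,
                          maf_a = 0.3, maf_b = 0.3)
  expect_true(all(m$table == 0.05))
  m <- build_table1_model("M1-1", alpha = 0.05, theta = 0.8,
                          maf_a = 0.3, maf_b = 0.3)
  expect_equal(m$table["Aa", "Bb"], 0.05 * 1.8^2)
  expect_equal(m$table["aa", "Bb"], 0.05 * 1.8^3)
  expect_equal(m$table["aa", "bb"], 0.05 * 1.8^4)
  expect_equal(m$table["AA", "bb"], 0.05)
  m2 <- build_table1_model("M1-2", alpha = 0.05, theta = 0.8,
                           maf_a = 0.3, maf_b = 0.3)
  expect_equal(m2$table["Aa", "Bb"], 0.05 * 1.8)
  expect_equal(m2$table["aa", "bb"], 0.05 * 1.8)
  expect_equal(sum(m2$table == 0.05), 7)
  # alpha (1 + theta)^4 > 1 must be rejected
  expect_error(build_table1_model("M1-1", alpha = 0.5, theta = 1,
                                  maf_a = 0.3, maf_b = 0.3), "exceeds 1")
})

test_that("the printed pure-epistasis tables are reproduced verbatim", {
  m3 <- table2_model("M1-3")
  expect_equal(m3$table["AA", "BB"], 0.077)
  expect_equal(m3$table["Aa", "BB"], 0.689)
  expect_equal(m3$table["AA", "Bb"], 0.763)
  expect_equal(m3$table["aa", "bb"], 0.247)
  expect_equal(table2_model("M1-6")$table["AA", "BB"], 0.005)
  expect_equal(table2_model("M1-4")$table["aa", "bb"], 0.712)
  expect_equal(m3$maf_a, 0.4)
  expect_error(table2_model("M1-7"))
})

test_that("prevalence is the HWE-weighted penetrance mean", {
  const <- penetrance_model("const", matrix(0.17, 3, 3), 0.3, 0.2)
  expect_equal(prevalence(const), 0.17)
  # independent brute-force weighted sum over the 9 cells
  brute <- function(m) {
    s <- 0
    pa <- hwe_genotype_probs(m$maf_a); pb <- hwe_genotype_probs(m$maf_b)
    for (i in 1:3) for (j in 1:3) s <- s + pa[i] * pb[j] * m$table[i, j]
    s
  }
  for (v in c("M1-3", "M1-4", "M1-5", "M1-6")) {
    m <- table2_model(v)
    expect_equal(prevalence(m), brute(m))
  }
  expect_equal(prevalence(table2_model("M1-3")), 0.4252432, tolerance = 1e-6)
  expect_equal(prevalence(table2_model("M1-6")), 0.12804, tolerance = 1e-6)
})

test_that("prevalence agrees with Monte-Carlo sampling within 3 standard errors", {
  m <- table2_model("M1-3")
  set.seed(99)
  n <- 1e6
  ga <- sample.int(3, n, replace = TRUE, prob = hwe_genotype_probs(0.4))
  gb <- sample.int(3, n, replace = TRUE, prob = hwe_genotype_probs(0.4))
  f <- m$table[cbind(ga, gb)]
  K_mc <- mean(f)                       # E f(g) under HWE sampling
  se <- stats::sd(f) / sqrt(n)
  expect_lt(abs(K_mc - prevalence(m)), 3 * se + 1e-12)
})

test_that("heritability matches the printed model headers and vanishes for flat tables", {
  headers <- c("M1-3" = 0.3, "M1-4" = 0.2, "M1-5" = 0.1, "M1-6" = 0.05)
  for (v in names(headers)) {
    expect_equal(heritability(table2_model(v)), unname(headers[v]),
                 tolerance = 0.005 / max(headers[v], 0.05))
  }
  const <- penetrance_model("const", matrix(0.3, 3, 3), 0.4, 0.4)
  expect_equal(heritability(const), 0)
  degenerate <- penetrance_model("zero", matrix(0, 3, 3), 0.4, 0.4)
  expect_error(heritability(degenerate), "prevalence")
})

test_that("case-control sampler fills quotas exactly and is seed-reproducible", {
  m <- table2_model("M1-3")
  ds <- simulate_case_control(m, 150, 120, 28, seed = 5)
  expect_equal(sum(ds$phenotype == 1L), 150)
  expect_equal(sum(ds$phenotype == 0L), 120)
  expect_equal(dim(ds$genotypes), c(270L, 30L))
  expect_length(ds$truth$loci, 2)
  ds2 <- simulate_case_control(m, 150, 120, 28, seed = 5)
  expect_identical(ds$genotypes, ds2$genotypes)
  expect_identical(ds$truth, ds2$truth)
  ds3 <- simulate_case_control(m, 150, 120, 28, seed = 6)
  expect_false(identical(ds$genotypes, ds3$genotypes))
})

test_that("degenerate penetrance tables behave deterministically or fail fast", {
  all1 <- penetrance_model("sure", matrix(1, 3, 3), 0.4, 0.4)
  ds <- simulate_case_control(all1, 50, 0, 8, seed = 3)
  expect_true(all(ds$phenotype == 1L))
  all0 <- penetrance_model("never", matrix(0, 3, 3), 0.4, 0.4)
  expect_error(simulate_case_control(all0, 10, 10, 8, seed = 3),
               "unfillable|identically")
})

test_that("case genotypes at the disease loci follow P(g) f(g)", {
  m <- table2_model("M1-3")
  ds <- simulate_case_control(m, 4000, 100, 0, seed = 21)
  cases <- ds$phenotype == 1L
  ga <- ds$genotypes[cases, ds$truth$loci[1]]
  gb <- ds$genotypes[cases, ds$truth$loci[2]]
  observed <- table(factor(ga, 0:2), factor(gb, 0:2))
  P <- outer(hwe_genotype_probs(0.4), hwe_genotype_probs(0.4)) * m$table
  expected <- P / sum(P)
  gof <- suppressWarnings(
    stats::chisq.test(as.vector(observed), p = as.vector(expected)))
  expect_gt(gof$p.value, 1e-4)
})

test_that("null simulator gives association-free data with per-SNP MAFs as drawn", {
  ds <- simulate_null(300, 500, seed = 11)
  expect_equal(dim(ds$genotypes), c(500L, 300L))
  expect_length(ds$truth$loci, 0)
  expect_equal(sum(ds$phenotype), 250)
  expect_identical(ds$genotypes, simulate_null(300, 500, seed = 11)$genotypes)
  # empirical minor-allele frequency tracks the drawn MAF
  emp <- colMeans(ds$genotypes) / 2
  drawn <- ds$meta$drawn_mafs
  se <- sqrt(drawn * (1 - drawn) / (2 * 500))
  expect_gt(mean(abs(emp - drawn) < 4 * se), 0.95)
  # single-SNP association p-values are roughly uniform
  pvals <- apply(ds$genotypes[, 1:150], 2, function(g) {
    suppressWarnings(stats::chisq.test(table(factor(g, 0:2),
                                             ds$phenotype))$p.value)
  })
  expect_gt(suppressWarnings(stats::ks.test(pvals, "punif"))$p.value, 1e-3)
})
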