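test_that("genotypes encode to the stated one-hot dummies", {
  expect_equal(encode_snp(0), c(1, 0, 0))
  expect_equal(encode_snp(1), c(0, 1, 0))
  expect_equal(encode_snp(2), c(0, 0, 1))
  expect_error(encode_snp(3), "genotype")
  expect_error(encode_snp(NA), "genotype")
  expect_equal(encode_pair(0, 0), c(1, rep(0, 8)))
  expect_equal(encode_pair(2, 2), c(rep(0, 8), 1))
  for (a in 0:2) for (b in 0:2) {
    expect_equal(encode_pair(a, b),
                 as.numeric(t(outer(encode_snp(a), encode_snp(b)))))
  }
})

test_that("main-effect design has one 3-dummy group per SNP in order", {
  ds <- genotype_dataset(matrix(c(0L, 2L), 2, 1), c(0, 1))
  d <- build_main_design(ds)
  expect_equal(unname(as.matrix(design_matrix(d))),
               rbind(c(1, 0, 0), c(0, 0, 1)))
  ds2 <- random_dataset(n = 25, L = 7, seed = 2)
  d2 <- build_main_design(ds2)
  expect_equal(d2$p, 21)
  expect_equal(nrow(d2$groups), 7)
  M <- as.matrix(design_matrix(d2))
  for (g in seq_len(7)) {
    block <- M[, d2$groups$col_start[g]:d2$groups$col_end[g]]
    expect_true(all(rowSums(block) == 1))
    # argmax decoding recovers the genotype codes exactly
    expect_equal(max.col(block) - 1L, unname(ds2$genotypes[, g]))
  }
})

test_that("interaction design holds all main groups then all pairs, lexicographic", {
  ds <- random_dataset(n = 12, L = 3, seed = 3)
  d <- build_interaction_design(ds)
  expect_equal(nrow(d$groups), 6)   # 3 main + 3 pairs
  expect_equal(d$p, 9 + 27)
  expect_equal(d$groups$a[4:6], c(1L, 1L, 2L))
  expect_equal(d$groups$b[4:6], c(2L, 3L, 3L))
  # pair dummies equal the flattened outer product of the two main blocks
  M <- as.matrix(design_matrix(d))
  for (g in 4:6) {
    a <- d$groups$a[g]; b <- d$groups$b[g]
    for (i in seq_len(12)) {
      expect_equal(unname(M[i, d$groups$col_start[g]:d$groups$col_end[g]]),
                   encode_pair(ds$genotypes[i, a], ds$genotypes[i, b]))
      expect_equal(sum(M[i, d$groups$col_start[g]:d$groups$col_end[g]]), 1)
    }
  }
  # column spans partition [1, P]
  spans <- unlist(lapply(seq_len(nrow(d$groups)), function(g) {
    d$groups$col_start[g]:d$groups$col_end[g]
  }))
  expect_equal(sort(spans), seq_len(d$p))
})

test_that("pair filter and pair counting behave as specified", {
  ds <- random_dataset(n = 10, L = 5, seed = 4)
  d_all <- build_interaction_design(ds)
  expect_equal(sum(!is.na(d_all$groups$b)), 5 * 4 / 2)
  d_one <- build_interaction_design(ds, pair_filter = function(a, b) {
    a == 1 & b == 2
  })
  pairs <- d_one$groups[!is.na(d_one$groups$b), ]
  expect_equal(nrow(pairs), 1)
  expect_equal(c(pairs$a, pairs$b), c(1L, 2L))
  L <- 1000
  expect_equal(L * (L - 1) / 2, 499500)  # full pair count at the usual scale
})

test_that("the dense-materialization guard refuses huge designs unless forced", {
  ds <- random_dataset(n = 10, L = 6, seed = 5)
  d <- build_interaction_design(ds, max_dense_cols = 20)
  expect_null(d$matrix)
  expect_error(design_matrix(d), "budget")
  M <- design_matrix(d, force = TRUE)
  expect_equal(dim(M), c(10L, d$p))
})

test_that("subsetting groups preserves labels and retiles column spans", {
  ds <- random_dataset(n = 10, L = 4, seed = 6)
  d <- build_interaction_design(ds)
  sub <- subset_groups(d, c(2L, 7L))
  expect_equal(nrow(sub$groups), 2)
  expect_equal(sub$groups$label, d$groups$label[c(2, 7)])
  expect_equal(sub$groups$col_start, c(1L, 4L))
  expect_equal(sub$p, 12)
})
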