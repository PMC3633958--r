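test_that("degenerate equal scores give p = 1", {
  d <- sim_binary_dataset(n = 60, m = 3, seed = 51)
  folds <- make_folds(60, K = 5, seed = 51)
  s <- rep(0, 60) # computed scores for a constant phenotype would all be 0
  ev <- evaluate_combination(d$geno, s, c(1L, 2L), folds)
  pv <- permutation_pvalue(d$geno, s, c(1L, 2L), folds, ev$testing_accuracy,
                           n_perm = 50, seed = 51)
  expect_equal(pv$M, 50L)
  expect_equal(pv$p_value, 1.0)
  expect_false(pv$is_bound)
})

test_that("permutation streams are reproducible and combination-specific", {
  d <- sim_binary_dataset(n = 80, m = 4, seed = 53)
  scores <- compute_scores(d$pheno)
  folds <- make_folds(80, K = 10, seed = 53, stratify_labels = d$pheno$values)
  ev <- evaluate_combination(d$geno, scores, c(1L, 3L), folds)
  p1 <- permutation_pvalue(d$geno, scores, c(1L, 3L), folds, ev$testing_accuracy,
                           n_perm = 300, seed = 7)
  p2 <- permutation_pvalue(d$geno, scores, c(1L, 3L), folds, ev$testing_accuracy,
                           n_perm = 300, seed = 7)
  expect_identical(p1$M, p2$M)
  # the block size must not change the stream's result set materially,
  # but the same seed with a different combination uses a different stream
  p3 <- permutation_pvalue(d$geno, scores, c(2L, 4L), folds, ev$testing_accuracy,
                           n_perm = 300, seed = 7)
  expect_false(identical(p1$M, p3$M) && identical(p1$p_value, p3$p_value))
})

test_that("p is monotone in the observed accuracy on a shared stream", {
  d <- sim_binary_dataset(n = 80, m = 4, seed = 55)
  scores <- compute_scores(d$pheno)
  folds <- make_folds(80, K = 10, seed = 55, stratify_labels = d$pheno$values)
  ev <- evaluate_combination(d$geno, scores, c(1L, 2L), folds)
  p_hi <- permutation_pvalue(d$geno, scores, c(1L, 2L), folds,
                             ev$testing_accuracy + 0.05, n_perm = 400, seed = 3)
  p_lo <- permutation_pvalue(d$geno, scores, c(1L, 2L), folds,
                             ev$testing_accuracy - 0.05, n_perm = 400, seed = 3)
  expect_lte(p_hi$M, p_lo$M)
})

test_that("M = 0 is reported as the bound < 1/N", {
  d <- sim_binary_dataset(n = 200, m = 3, seed = 57, model = xor_model(c(1L, 2L)), maf = 0.5)
  scores <- compute_scores(d$pheno)
  folds <- make_folds(200, K = 10, seed = 57, stratify_labels = d$pheno$values)
  ev <- evaluate_combination(d$geno, scores, c(1L, 2L), folds)
  expect_equal(ev$testing_accuracy, 1.0)
  pv <- permutation_pvalue(d$geno, scores, c(1L, 2L), folds, 1.0, n_perm = 1000, seed = 57)
  expect_equal(pv$M, 0L)
  expect_true(pv$is_bound)
  expect_equal(pv$p_value, 1e-3)
  expect_match(pv$label, "^<")
  # the add-one estimator returns a proper estimate instead
  pv2 <- permutation_pvalue(d$geno, scores, c(1L, 2L), folds, 1.0, n_perm = 199,
                            seed = 57, estimator = "add_one")
  expect_equal(pv2$p_value, (pv2$M + 1) / 200)
  expect_false(pv2$is_bound)
})

test_that("Monte-Carlo p agrees with exhaustive enumeration on 3 subjects", {
  snps <- snp_info(c("a", "b"), c("1", "2"), c(1L, 2L) * 1000000L)
  g <- genotype_matrix(rbind(c(0L, 1L), c(1L, 0L), c(2L, 2L)), snps, c("x", "y", "z"))
  s <- c(0.9, -0.4, -0.5)
  folds <- make_folds(3, K = 3, seed = 1)
  obs <- evaluate_combination(g, s, c(1L, 2L), folds)$testing_accuracy
  perms <- list(1:3, c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  accs <- vapply(perms, function(p) {
    evaluate_combination(g, s[p], c(1L, 2L), folds)$testing_accuracy
  }, 0)
  exact_p <- mean(accs >= obs - 1e-12)
  pv <- permutation_pvalue(g, s, c(1L, 2L), folds, obs, n_perm = 3000, seed = 5)
  mc_p <- pv$M / pv$N
  expect_lt(abs(mc_p - exact_p), 0.04)
})
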