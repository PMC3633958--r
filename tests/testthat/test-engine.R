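test_that("make_folds balances sizes and is deterministic", {
  f <- make_folds(100, K = 10, seed = 1)
  expect_equal(tabulate(f$fold, 10), rep(10, 10))
  f2 <- make_folds(102, K = 10, seed = 1)
  expect_setequal(tabulate(f2$fold, 10), c(rep(10, 8), 11, 11))
  expect_identical(make_folds(100, 10, seed = 3)$fold, make_folds(100, 10, seed = 3)$fold)
  expect_false(identical(make_folds(100, 10, seed = 3)$fold, make_folds(100, 10, seed = 4)$fold))
  expect_error(make_folds(5, K = 10), "cannot split")

  # stratified folds balance each label and keep total sizes within 1
  lab <- rep(c(0, 1), c(47, 55))
  fs <- make_folds(102, K = 10, seed = 2, stratify_labels = lab)
  sizes <- tabulate(fs$fold, 10)
  expect_lte(diff(range(sizes)), 1)
  per_label <- table(lab, fs$fold)
  expect_lte(max(apply(per_label, 1, function(x) diff(range(x)))), 1)
})

test_that("assign_cells encodes genotype tuples and propagates missingness", {
  v <- rbind(c(0L, 2L), c(1L, 1L), c(NA, 0L))
  snps <- snp_info(c("a", "b"), c("1", "2"), c(1L, 2L))
  g <- genotype_matrix(v, snps, c("x", "y", "z"))
  cells <- assign_cells(g, c(1L, 2L))
  expect_equal(cells, c(0 + 2 * 3 + 1, 1 + 1 * 3 + 1, NA))
  # subject z is excluded for pairs involving SNP 1 but not for SNP 2 alone
  expect_equal(assign_cells(g, 2L), c(3L, 2L, 1L))
  expect_lte(max(assign_cells(g, c(1L, 2L)), na.rm = TRUE), 9)
})

test_that("classify_cells uses the sign of the training score sum with ties low", {
  s <- c(0.5, 0.5, -0.5, 0.5, -0.5, 1)
  cells <- c(1L, 1L, 1L, 2L, 2L, 3L)
  cm <- classify_cells(s, cells, training_mask = rep(TRUE, 6), n_cells = 4)
  expect_equal(cm$risk, c("high", "low", "high", "unclassified"))
  expect_equal(cm$cell_sum[1:3], c(0.5, 0, 1))
  # all-zero scores: every occupied cell is low
  cm0 <- classify_cells(rep(0, 6), cells, rep(TRUE, 6), n_cells = 4)
  expect_equal(cm0$risk[1:3], rep("low", 3))
})

test_that("balanced_accuracy reproduces the hand-worked six-subject case", {
  s <- c(3, 1, 2, -2, -1, -3)
  cells <- c(1L, 2L, 3L, 2L, 1L, 3L) # A={+3,-1}, B={+1,-2}, C={+2,-3}
  cm <- classify_cells(s, cells, rep(TRUE, 6), n_cells = 3)
  expect_equal(cm$risk, c("high", "low", "low"))
  expect_equal(balanced_accuracy(s, cells, cm, rep(TRUE, 6)), 0.5 * (3 / 6 + 5 / 6))
})

test_that("balanced_accuracy properties: scaling, null model, perfect split", {
  set.seed(31)
  s <- rnorm(20); s <- s - mean(s)
  cells <- sample(1:4, 20, replace = TRUE)
  cm <- classify_cells(s, cells, rep(TRUE, 20), n_cells = 4)
  a <- balanced_accuracy(s, cells, cm, rep(TRUE, 20))
  for (c_scale in c(0.01, 7)) {
    cm_s <- classify_cells(s * c_scale, cells, rep(TRUE, 20), n_cells = 4)
    expect_equal(balanced_accuracy(s * c_scale, cells, cm_s, rep(TRUE, 20)), a)
  }
  # mean-zero scores all in one cell: tie rule gives low, accuracy exactly 0.5
  one <- rep(1L, 20)
  cm1 <- classify_cells(s, one, rep(TRUE, 20), n_cells = 1)
  expect_equal(cm1$risk, "low")
  expect_equal(balanced_accuracy(s, one, cm1, rep(TRUE, 20)), 0.5)
  # perfect separation scores 1
  cells_p <- ifelse(s > 0, 1L, 2L)
  cm_p <- classify_cells(s, cells_p, rep(TRUE, 20), n_cells = 2)
  expect_equal(balanced_accuracy(s, cells_p, cm_p, rep(TRUE, 20)), 1.0)
})

test_that("evaluate_combination is exact on deterministic epistasis and averages folds", {
  d <- sim_binary_dataset(n = 300, m = 4, seed = 13, model = xor_model(c(1L, 2L)), maf = 0.5)
  scores <- compute_scores(d$pheno)
  folds <- make_folds(300, K = 10, seed = 13, stratify_labels = d$pheno$values)
  ev <- evaluate_combination(d$geno, scores, c(1L, 2L), folds)
  expect_equal(ev$testing_accuracy_by_fold, rep(1, 10))
  expect_equal(ev$testing_accuracy, 1)
  expect_equal(ev$training_accuracy, rep(1, 10))
  expect_equal(ev$testing_accuracy, mean(ev$testing_accuracy_by_fold))
})

test_that("results are invariant to subject reordering with mapped folds", {
  d <- sim_binary_dataset(n = 90, m = 5, seed = 17)
  scores <- compute_scores(d$pheno)
  folds <- make_folds(90, K = 9, seed = 17)
  ev <- evaluate_combination(d$geno, scores, c(2L, 4L), folds)
  perm <- sample(90)
  g2 <- subset_genotypes(d$geno, subjects = perm)
  folds2 <- structure(list(K = 9L, fold = folds$fold[perm], seed = folds$seed),
                      class = "fold_assignment")
  ev2 <- evaluate_combination(g2, scores$values[perm], c(2L, 4L), folds2)
  expect_equal(ev2$training_accuracy, ev$training_accuracy)
  expect_equal(ev2$testing_accuracy_by_fold, ev$testing_accuracy_by_fold)
})

test_that("rank_and_select counts CVC with strict majority retention", {
  # 3 combinations, 10 folds: comb 1 always best, comb 2 best in 5 folds shadowed
  acc <- rbind(rep(0.9, 10), c(rep(0.95, 0), rep(0.8, 10)), rep(0.7, 10))
  acc[2, 1:5] <- 0.99
  combos <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L))
  sel <- rank_and_select(acc, combos, top_n = 1)
  expect_equal(sel$cvc, c(5L, 5L, 0L))
  expect_length(sel$selected, 0) # CVC 5/10 is NOT > K/2

  acc2 <- rbind(rep(0.9, 10), rep(0.8, 10), rep(0.7, 10))
  sel2 <- rank_and_select(acc2, combos, top_n = 1)
  expect_equal(sel2$cvc[1], 10L)
  expect_equal(sel2$selected, 1L)

  # ties broken lexicographically: equal accuracies select the first tuple
  acc3 <- matrix(0.5, 3, 10)
  sel3 <- rank_and_select(acc3, combos, top_n = 1)
  expect_equal(sel3$cvc, c(10L, 0L, 0L))
})

test_that("CVC values sum to K * top_n when nothing is skipped", {
  set.seed(41)
  for (top_n in c(1, 2)) {
    acc <- matrix(runif(6 * 10), 6, 10)
    sel <- rank_and_select(acc, as.list(1:6), top_n = top_n, cvc_gt = 0)
    expect_equal(sum(sel$cvc), 10 * top_n)
    expect_equal(nrow(sel$selection_table), 10 * top_n)
  }
})
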