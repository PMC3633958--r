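test_that("enumeration applies the strict within-chromosome distance filter", {
  # 4 SNPs on 4 chromosomes: all C(4,2) pairs survive
  s4 <- snp_info(paste0("s", 1:4), as.character(1:4), rep(1000000L, 4))
  expect_length(enumerate_combinations(s4, 2), 6)

  # 3 SNPs on one chromosome at 1, 500000, 2000000 bp with a 1 Mb filter
  s3 <- snp_info(paste0("s", 1:3), rep("1", 3), c(1L, 500000L, 2000000L))
  pairs <- enumerate_combinations(s3, 2, min_pair_distance_bp = 1e6)
  expect_equal(pairs, list(c(1L, 3L), c(2L, 3L)))

  # exactly 1 Mb apart passes (strict < rule)
  s2 <- snp_info(c("a", "b"), c("1", "1"), c(1L, 1000001L))
  expect_length(enumerate_combinations(s2, 2, 1e6), 1)
  s2b <- snp_info(c("a", "b"), c("1", "1"), c(1L, 1000000L))
  expect_length(enumerate_combinations(s2b, 2, 1e6), 0)

  # k = number of SNPs gives one tuple; k too large gives none
  expect_length(enumerate_combinations(s4, 4), 1)
  expect_length(enumerate_combinations(s4, 5), 0)
})

test_that("enumeration counts match a brute-force filter for many layouts", {
  set.seed(61)
  for (rep_i in 1:8) {
    m <- sample(4:12, 1)
    k <- sample(2:min(5, m), 1)
    snps <- snp_info(paste0("s", 1:m),
                     as.character(sample(1:3, m, TRUE)),
                     as.integer(sample.int(3e6, m)))
    got <- enumerate_combinations(snps, k, min_pair_distance_bp = 1e6)
    combos <- combn(m, k, simplify = FALSE)
    ok <- vapply(combos, function(cb) {
      for (a in seq_along(cb)) {
        for (b in seq_along(cb)) {
          if (a < b &&
              snps$chromosome[cb[a]] == snps$chromosome[cb[b]] &&
              abs(snps$position_bp[cb[a]] - snps$position_bp[cb[b]]) < 1e6) {
            return(FALSE)
          }
        }
      }
      TRUE
    }, TRUE)
    expect_equal(length(got), sum(ok))
    expect_equal(got, combos[ok])
  }
})

test_that("a planted interaction is found and the conditioned search matches", {
  d <- sim_binary_dataset(n = 400, m = 8, seed = 63, model = xor_model(c(2L, 5L)), maf = 0.5)
  fit <- gmdr(d$geno, d$pheno, n_perm = 200, seed = 63)
  expect_gt(nrow(fit$results), 0)
  expect_equal(fit$results$combination[[1]], c(2L, 5L))
  expect_equal(fit$results$cvc[1], 10L)
  expect_equal(fit$results$testing_accuracy[1], 1.0)

  # conditioned on all SNPs the search is identical to the exhaustive one
  fit_c <- conditioned_search(d$geno, d$pheno, snp_subset = 1:8, order = 2,
                              n_perm = 200, seed = 63)
  expect_equal(fit_c$results$snp_ids, fit$results$snp_ids)
  expect_equal(fit_c$results$testing_accuracy, fit$results$testing_accuracy)
  expect_equal(fit_c$results$p_value, fit$results$p_value)

  # a 1-SNP dataset has no pairs
  fit1 <- gmdr(subset_genotypes(d$geno, snps = 1L), d$pheno, n_perm = 0, seed = 1)
  expect_equal(nrow(fit1$results), 0)
})

test_that("harvest_top_snps unions the per-fold selections", {
  d <- sim_binary_dataset(n = 200, m = 6, seed = 65, model = xor_model(c(1L, 4L)), maf = 0.5)
  fit <- gmdr(d$geno, d$pheno, top_n = 2, n_perm = 0, seed = 65)
  st <- fit$selection_table
  expect_equal(nrow(st), 10 * 2)
  manual <- sort(unique(unlist(st$snp_indices)))
  expect_equal(harvest_top_snps(fit), manual)
  expect_true(all(c(1L, 4L) %in% manual))
  # restricting to rank 1 per fold gives a subset
  expect_true(all(harvest_top_snps(fit, top_n = 1) %in% manual))
  expect_lte(length(manual), 2 * 10 * 2)
})

test_that("significance_filter applies CVC >= and p <= rules with bound semantics", {
  df <- data.frame(
    order = c(2L, 2L, 3L, 2L, 2L),
    snp_ids = c("a,b", "a,c", "a,b,d", "c,d", "b,d"),
    chromosomes = "x",
    cvc = c(7L, 6L, 10L, 7L, 8L),
    testing_accuracy = c(0.6, 0.7, 0.65, 0.55, 0.6),
    p_value = c(1e-4, 1e-6, 2e-3, 1e-4, 5e-2),
    p_is_bound = c(TRUE, FALSE, FALSE, FALSE, FALSE),
    p_n = c(10000L, 10000L, 10000L, 10000L, 10000L),
    p_label = c("<1e-04", "1e-06", "0.002", "1e-04", "0.05"),
    stringsAsFactors = FALSE
  )
  out <- significance_filter(df, final_cvc_min = 7, final_p_max = 1e-4)
  # kept: row 1 (bound <1e-4 qualifies at alpha 1e-4), row 4; row 2 fails CVC,
  # rows 3 and 5 fail p
  expect_equal(out$snp_ids, c("a,b", "c,d"))

  # monotone: tightening thresholds never adds results
  for (a in c(1e-2, 1e-4)) {
    loose <- significance_filter(df, 7, a)
    tight <- significance_filter(df, 8, a)
    expect_true(all(tight$snp_ids %in% loose$snp_ids))
    tight_p <- significance_filter(df, 7, a / 10)
    expect_true(all(tight_p$snp_ids %in% loose$snp_ids))
  }
})

test_that("core SNPs are those supported by enough distinct models", {
  df <- data.frame(
    order = c(2L, 2L, 5L, 3L, 4L, 2L),
    snp_ids = c("s1,s2", "s1,s3", "s2,s4,s5,s6,s7", "s3,s5,s8", "s4,s5,s6,s8", "s7,s8"),
    stringsAsFactors = FALSE
  )
  core <- detect_core_snps(df, core_min_models = 2)
  # hand count: s1 x2, s2 x2, s3 x2, s4 x2, s5 x3, s6 x2, s7 x2, s8 x3
  expect_setequal(core$snp_id, paste0("s", 1:8))
  expect_equal(core$n_models[core$snp_id == "s5"], 3L)
  expect_equal(core$orders[core$snp_id == "s8"], "2,3,4")

  core3 <- detect_core_snps(df, core_min_models = 3)
  expect_setequal(core3$snp_id, c("s5", "s8"))
  # a SNP in a single model is never core
  single <- detect_core_snps(df[1, , drop = FALSE], core_min_models = 2)
  expect_equal(nrow(single), 0)
  # report is consistent with its input
  for (i in seq_len(nrow(core))) {
    expect_gte(sum(vapply(strsplit(df$snp_ids, ","), function(s) core$snp_id[i] %in% s, TRUE)),
               2)
  }
})
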