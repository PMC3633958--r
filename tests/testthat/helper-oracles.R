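# Independent brute-force oracles: explicit per-subject / per-cell loops and
# full-table enumerations, deliberately unvectorized and sharing no code with
# the package internals.

# Cell classification by looping over subjects.
brute_cell_model <- function(s, cells, train, n_cells = max(cells, na.rm = TRUE)) {
  sums <- rep(0, n_cells)
  occ <- rep(FALSE, n_cells)
  for (i in seq_along(s)) {
    if (train[i] && !is.na(cells[i])) {
      sums[cells[i]] <- sums[cells[i]] + s[i]
      occ[cells[i]] <- TRUE
    }
  }
  risk <- rep("unclassified", n_cells)
  for (cc in seq_len(n_cells)) {
    if (occ[cc]) risk[cc] <- if (sums[cc] > 0) "high" else "low"
  }
  list(sum = sums, occ = occ, risk = risk)
}

# Score-weighted balanced accuracy by looping over subjects.
brute_accuracy <- function(s, cells, risk, eval_mask) {
  pos_num <- pos_den <- neg_num <- neg_den <- 0
  for (i in seq_along(s)) {
    if (!eval_mask[i] || is.na(cells[i])) next
    r <- risk[cells[i]]
    if (r == "unclassified") r <- "low"
    if (s[i] > 0) {
      pos_den <- pos_den + s[i]
      if (r == "high") pos_num <- pos_num + s[i]
    } else if (s[i] < 0) {
      neg_den <- neg_den - s[i]
      if (r == "low") neg_num <- neg_num - s[i]
    }
  }
  tp <- if (pos_den > 0) pos_num / pos_den else 0.5
  tn <- if (neg_den > 0) neg_num / neg_den else 0.5
  0.5 * (tp + tn)
}

# Exact HWE p-value by enumerating every genotype table with the same sample
# size and allele totals.
hwe_oracle <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  nA <- 2 * n0 + n1
  if (nA == 0 || nA == 2 * n) return(1.0)
  probs <- numeric(0)
  obs <- NA_real_
  for (h1 in 0:n) {
    for (h0 in 0:(n - h1)) {
      h2 <- n - h1 - h0
      if (2 * h0 + h1 != nA) next
      p <- choose(n, h1) * choose(n - h1, h0) * 2^h1 / choose(2 * n, nA)
      probs <- c(probs, p)
      if (h0 == n0 && h1 == n1) obs <- p
    }
  }
  min(1, sum(probs[probs <= obs * (1 + 1e-9)]))
}

# Random small instance for the oracle-equivalence checks.
random_instance <- function(seed) {
  set.seed(seed)
  n <- sample(5:50, 1)
  k <- sample(1:3, 1)
  n_cells <- 3L^k
  cells <- sample(seq_len(n_cells), n, replace = TRUE)
  cells[runif(n) < 0.05] <- NA # occasional excluded subjects
  s <- round(rnorm(n), 3)
  s <- s - mean(s)
  train <- runif(n) < 0.7
  if (!any(train & !is.na(cells))) train[which(!is.na(cells))[1]] <- TRUE
  eval_mask <- !train
  if (!any(eval_mask & !is.na(cells))) eval_mask <- rep(TRUE, n)
  list(n = n, k = k, n_cells = n_cells, cells = cells, s = s,
       train = train, eval_mask = eval_mask)
}

# Small labelled dataset used across io / pipeline tests.
sim_binary_dataset <- function(n = 150, m = 8, seed = 1, model = NULL, maf = 0.3) {
  specs <- snp_spec_grid(m, maf = maf)
  geno <- simulate_genotypes(n, specs, seed = seed)
  sim <- simulate_phenotype(geno, model, trait_kind = "binary", seed = seed)
  list(geno = geno, pheno = sim$phenotype, covar = sim$covariates)
}
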