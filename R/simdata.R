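# Synthetic-data generator: independent Hardy-Weinberg genotypes and
# phenotypes under k-locus penetrance (binary) or mean-shift (quantitative)
# models, with optional covariate effects.  The canonical planted-interaction
# fixture is the XOR (checkerboard) two-locus model, which has zero marginal
# effects at MAF 0.5 and so isolates pure interaction detection.  Loci are
# simulated without linkage disequilibrium; the physical-distance filter is
# exercised through the positions, not through simulated correlation.

#' Simulate genotypes under Hardy-Weinberg equilibrium
#'
#' Independent draws per SNP with P(0,1,2) = ((1-q)^2, 2q(1-q), q^2),
#' q = MAF.
#'
#' @param n Number of subjects.
#' @param snp_specs data.frame with columns `chromosome`, `position_bp`,
#'   `maf` (each MAF in (0, 0.5]); optional `snp_id`.
#' @param seed Integer seed.
#' @return A [genotype_matrix()].
#' @export
simulate_genotypes <- function(n, snp_specs, seed = 1) {
  maf <- snp_specs$maf
  if (any(maf <= 0 | maf > 0.5)) stop("each maf must lie in (0, 0.5]")
  m <- nrow(snp_specs)
  ids <- if ("snp_id" %in% names(snp_specs)) snp_specs$snp_id else sprintf("snp%03d", seq_len(m))
  v <- with_local_seed(derive_seed(seed, c(15485863, n, m)), {
    vapply(seq_len(m), function(j) {
      q <- maf[j]
      sample(0:2, n, replace = TRUE, prob = c((1 - q)^2, 2 * q * (1 - q), q^2))
    }, integer(n))
  })
  genotype_matrix(v, snp_info(ids, snp_specs$chromosome, snp_specs$position_bp),
                  sprintf("S%05d", seq_len(n)))
}

#' Default SNP specification table
#'
#' Convenience builder placing `m` SNPs on distinct chromosomes (recycled
#' beyond 22) at well-separated positions, so the 1 Mb distance filter never
#' removes a simulated pair unless positions are overridden.
#'
#' @param m Number of SNPs.
#' @param maf MAF, recycled (default 0.3).
#' @return data.frame usable as `snp_specs` in [simulate_genotypes()].
#' @export
snp_spec_grid <- function(m, maf = 0.3) {
  data.frame(
    snp_id = sprintf("snp%03d", seq_len(m)),
    chromosome = as.character(rep_len(1:22, m)),
    position_bp = as.integer(1e6 + 5e6 * (seq_len(m) - 1) %/% 22 + 1e5 * seq_len(m)),
    maf = rep_len(maf, m),
    stringsAsFactors = FALSE
  )
}

#' Penetrance model over the cells of a k-SNP combination
#'
#' @param loci Integer SNP indices (length k).
#' @param table Numeric array of dimension `rep(3, k)` giving, per genotype
#'   cell, the penetrance (binary traits, values in `[0,1]`) or the mean
#'   shift (quantitative traits).  Cell `[i1,...,ik]` corresponds to genotype
#'   codes `(i1-1, ..., ik-1)`.
#' @return An object of class `penetrance_model`.
#' @export
penetrance_model <- function(loci, table) {
  k <- length(loci)
  table <- array(table, dim = rep(3, k))
  structure(list(loci = as.integer(loci), table = table, k = k),
            class = "penetrance_model")
}

#' Two-locus XOR (checkerboard) penetrance model
#'
#' Penetrance `high` for cells where exactly one of the two loci is
#' heterozygous, `low` otherwise.  At MAF 0.5 both loci have zero marginal
#' effect, making this the canonical pure-interaction fixture; `high = 1`,
#' `low = 0` gives a noise-free deterministic phenotype.
#'
#' @param loci Two SNP indices.
#' @param high,low Penetrances (or mean shifts) of the two cell classes.
#' @return A [penetrance_model()].
#' @export
xor_model <- function(loci = c(1L, 2L), high = 1, low = 0) {
  stopifnot(length(loci) == 2)
  tab <- array(low, dim = c(3, 3))
  for (g1 in 0:2) {
    for (g2 in 0:2) {
      if ((g1 == 1) + (g2 == 1) == 1) tab[g1 + 1, g2 + 1] <- high
    }
  }
  penetrance_model(loci, tab)
}

cell_value <- function(model, genotypes) {
  v <- genotypes$values[, model$loci, drop = FALSE]
  idx <- v %*% 3^(seq_len(model$k) - 1) + 1
  as.numeric(model$table)[idx]
}

#' Simulate a phenotype (and optional covariates) from genotypes
#'
#' Binary traits: case with probability equal to the penetrance of the
#' subject's cell; with covariate effects, penetrance (clamped away from 0/1)
#' and the covariate term combine on the logit scale.  Quantitative traits:
#' cell mean shift + covariate term + Normal(0, `noise_sd`) noise.  A `NULL`
#' model gives a phenotype independent of all genotypes (the null model):
#' constant case probability `prevalence` (binary) or mean 0 (quantitative).
#'
#' @param genotypes A [genotype_matrix()].
#' @param model A [penetrance_model()] or `NULL` for the null model.
#' @param trait_kind `"binary"` or `"quantitative"`.
#' @param noise_sd Residual SD for quantitative traits (default 1).
#' @param prevalence Case probability under the binary null model
#'   (default 0.5).
#' @param covariate_effects Optional named numeric vector of coefficients;
#'   one standard-normal covariate is generated per entry.
#' @param seed Integer seed.
#' @return List with `phenotype` ([phenotype()]) and `covariates`
#'   ([covariate_matrix()], zero columns when no effects requested).
#' @export
simulate_phenotype <- function(genotypes, model = NULL,
                               trait_kind = c("binary", "quantitative"),
                               noise_sd = 1, prevalence = 0.5,
                               covariate_effects = NULL, seed = 1) {
  trait_kind <- match.arg(trait_kind)
  n <- length(genotypes$subject_ids)
  with_local_seed(derive_seed(seed, c(32452843, n, trait_kind == "binary")), {
    p_cov <- length(covariate_effects)
    X <- matrix(stats::rnorm(n * p_cov), n, p_cov)
    cov_term <- if (p_cov > 0) as.numeric(X %*% covariate_effects) else rep(0, n)
    base <- if (is.null(model)) {
      if (trait_kind == "binary") rep(prevalence, n) else rep(0, n)
    } else {
      g <- cell_value(model, genotypes)
      if (any(is.na(g))) g[is.na(g)] <- if (trait_kind == "binary") prevalence else 0
      g
    }
    if (trait_kind == "binary") {
      pr <- if (p_cov > 0) {
        stats::plogis(stats::qlogis(pmin(pmax(base, 1e-8), 1 - 1e-8)) + cov_term)
      } else {
        base
      }
      y <- stats::rbinom(n, 1, pr)
    } else {
      y <- base + cov_term + stats::rnorm(n, 0, noise_sd)
    }
    cm <- covariate_matrix(X, names(covariate_effects))
    list(phenotype = phenotype(y, trait_kind), covariates = cm)
  })
}
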