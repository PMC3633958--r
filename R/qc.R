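# SNP-level quality control: missingness, minor allele frequency and an exact
# Hardy-Weinberg equilibrium test.  For binary traits the missingness and MAF
# rules are checked separately in cases and controls (a SNP must pass in both
# strata) and HWE is tested in controls only; for quantitative traits all
# filters use the full sample.  All threshold comparisons are strict.

#' Missing-call rate of one SNP
#'
#' @param snp_column Genotype column (0/1/2 with `NA` missing).
#' @return Fraction of missing calls in `[0, 1]`.
#' @export
missing_rate <- function(snp_column) {
  if (length(snp_column) == 0) stop("empty genotype column")
  mean(is.na(snp_column))
}

#' Minor allele frequency of one SNP
#'
#' `maf = min(f, 1 - f)` with `f = (2 n2 + n1) / (2 (n0 + n1 + n2))` computed
#' over non-missing calls only.
#'
#' @param snp_column Genotype column (0/1/2 with `NA` missing).
#' @return MAF in `[0, 0.5]`.
#' @export
minor_allele_frequency <- function(snp_column) {
  g <- snp_column[!is.na(snp_column)]
  if (length(g) == 0) stop("MAF undefined: all calls missing")
  f <- sum(g) / (2 * length(g))
  min(f, 1 - f)
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact conditional test: with the allele totals fixed, the p-value is the
#' sum of the conditional probabilities of every heterozygote count whose
#' probability does not exceed that of the observed count.  Monomorphic SNPs
#' return 1 by convention.  An asymptotic chi-square alternative (1 df,
#' no continuity correction) is available via `method`.
#'
#' @param n0,n1,n2 Counts of major-homozygous, heterozygous and
#'   minor-homozygous genotypes.
#' @param method `"exact"` (default) or `"chisq"`.
#' @return p-value in `(0, 1]`.
#' @export
hwe_test <- function(n0, n1, n2, method = c("exact", "chisq")) {
  method <- match.arg(method)
  if (n0 < 0 || n1 < 0 || n2 < 0 || n0 + n1 + n2 < 1) stop("invalid genotype counts")
  if (method == "exact") hwe_exact_p(n0, n1, n2) else hwe_chisq_p(n0, n1, n2)
}

#' @rdname hwe_test
#' @export
hwe_exact_p <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  # work with the rarer allele; the distribution of the het count is the same
  na <- min(2 * n0 + n1, 2 * n2 + n1)
  if (na == 0) return(1.0)
  nb <- 2 * n - na
  # possible het counts share the parity of the rare-allele total
  hets <- seq(na %% 2, min(na, nb), by = 2)
  # log conditional probability of each het count given allele totals
  logp <- lfactorial(n) - lfactorial((na - hets) / 2) - lfactorial(hets) -
    lfactorial((nb - hets) / 2) + hets * log(2) +
    lfactorial(na) + lfactorial(nb) - lfactorial(2 * n)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[match(n1, hets)]
  min(1, sum(p[p <= obs * (1 + 1e-12)]))
}

#' @rdname hwe_test
#' @export
hwe_chisq_p <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  q <- (2 * n2 + n1) / (2 * n)
  if (q == 0 || q == 1) return(1.0)
  e <- n * c((1 - q)^2, 2 * q * (1 - q), q^2)
  x2 <- sum((c(n0, n1, n2) - e)^2 / e)
  stats::pchisq(x2, df = 1, lower.tail = FALSE)
}

hwe_column_p <- function(g, method) {
  g <- g[!is.na(g)]
  if (length(g) == 0) return(NA_real_)
  hwe_test(sum(g == 0), sum(g == 1), sum(g == 2), method = method)
}

#' Apply SNP quality-control filters
#'
#' Removes SNPs with missing-call rate strictly above `max_missing`, minor
#' allele frequency strictly below `min_maf`, or Hardy-Weinberg p-value
#' strictly below `min_hwe_p`.  When `control_mask` is supplied (binary
#' traits) the missingness and MAF rules must hold in cases and in controls
#' separately and HWE is tested in controls; otherwise all rules use every
#' subject.  Filters are applied in the order missingness, MAF, HWE and the
#' first failing rule is recorded as the removal reason.
#'
#' @param genotypes A [genotype_matrix()].
#' @param control_mask Optional logical vector, `TRUE` for controls.
#' @param max_missing Maximum tolerated missing rate (default 0.10).
#' @param min_maf Minimum tolerated MAF (default 0.05).
#' @param min_hwe_p Minimum tolerated HWE p-value in controls (default 0.001).
#' @param hwe_method `"exact"` or `"chisq"`, see [hwe_test()].
#' @return List with `genotypes` (the filtered matrix) and `report`, a
#'   data.frame with per-SNP `missing_rate`, `maf`, `hwe_p` (full-sample or
#'   control-stratum values as used for the decision), `kept` and `reason`
#'   (`pass`, `missingness`, `maf` or `hwe`).
#' @export
apply_qc <- function(genotypes, control_mask = NULL,
                     max_missing = 0.10, min_maf = 0.05, min_hwe_p = 0.001,
                     hwe_method = c("exact", "chisq")) {
  hwe_method <- match.arg(hwe_method)
  v <- genotypes$values
  strata <- if (is.null(control_mask)) {
    list(all = rep(TRUE, nrow(v)))
  } else {
    stopifnot(is.logical(control_mask), length(control_mask) == nrow(v))
    list(cases = !control_mask, controls = control_mask)
  }
  miss_by <- sapply(strata, function(m) apply(v[m, , drop = FALSE], 2, missing_rate))
  maf_by <- sapply(strata, function(m) {
    apply(v[m, , drop = FALSE], 2, function(g) {
      if (all(is.na(g))) NA_real_ else minor_allele_frequency(g)
    })
  })
  hwe_rows <- if (is.null(control_mask)) strata$all else strata$controls
  hwe_p <- apply(v[hwe_rows, , drop = FALSE], 2, hwe_column_p, method = hwe_method)

  miss_worst <- apply(as.matrix(miss_by), 1, max)
  maf_worst <- apply(as.matrix(maf_by), 1, function(x) if (any(is.na(x))) 0 else min(x))
  fail_miss <- miss_worst > max_missing
  fail_maf <- maf_worst < min_maf
  fail_hwe <- !is.na(hwe_p) & hwe_p < min_hwe_p

  reason <- rep("pass", ncol(v))
  reason[fail_hwe] <- "hwe"
  reason[fail_maf] <- "maf"
  reason[fail_miss] <- "missingness" # order: missingness overrides maf overrides hwe
  kept <- reason == "pass"

  report <- data.frame(
    snp_id = genotypes$snps$snp_id,
    chromosome = genotypes$snps$chromosome,
    position_bp = genotypes$snps$position_bp,
    missing_rate = miss_worst,
    maf = maf_worst,
    hwe_p = hwe_p,
    kept = kept,
    reason = reason,
    stringsAsFactors = FALSE
  )
  list(genotypes = subset_genotypes(genotypes, snps = which(kept)), report = report)
}

#' Write a QC report as TSV
#'
#' @param report The `report` element of [apply_qc()]'s result.
#' @param path Output file path.
#' @export
write_qc_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
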