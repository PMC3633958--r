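# Permutation test of the observed testing accuracy (significance step).
# Scores are permuted uniformly across subjects while the genotypes and the
# fold assignment stay fixed; the cell models of every fold are re-fit, the
# testing accuracy re-averaged, and the p-value is M/N, M being the number of
# permutations whose testing accuracy is at least as high as the observed one.
# When M = 0 the result is reported as the bound "< 1/N" rather than 0.

#' Permutation p-value for one interaction model
#'
#' @param genotypes A [genotype_matrix()].
#' @param scores A [score_vector()] or numeric vector (the unpermuted scores).
#' @param combination Integer vector of SNP column indices.
#' @param folds A [make_folds()] assignment (the same one used for the
#'   observed testing accuracy).
#' @param observed_testing_accuracy The model's observed testing accuracy.
#' @param n_perm Number of permutations N (default 10^4; increase to the
#'   genome-wide scale, e.g. 10^7, when resources allow).
#' @param seed Master seed; the stream actually used is derived from
#'   `(seed, combination)` so results do not depend on evaluation order.
#' @param comparison `"ge"` (as high as, default) or `"gt"` (strictly higher).
#' @param estimator `"m_over_n"` (default; M = 0 reported as a bound) or
#'   `"add_one"` for the (M+1)/(N+1) estimator.
#' @param unseen Passed to the engine, see [balanced_accuracy()].
#' @param block Number of permutations evaluated per vectorized block.
#' @return List with `p_value`, `M`, `N`, `is_bound` (TRUE when M = 0 under
#'   `m_over_n`, in which case `p_value` is the bound 1/N), and `label`, a
#'   printable form such as `"<1e-04"`.
#' @export
permutation_pvalue <- function(genotypes, scores, combination, folds,
                               observed_testing_accuracy,
                               n_perm = 1e4, seed = 1,
                               comparison = c("ge", "gt"),
                               estimator = c("m_over_n", "add_one"),
                               unseen = "low", block = 2000) {
  comparison <- match.arg(comparison)
  estimator <- match.arg(estimator)
  stopifnot(n_perm >= 1)
  s <- if (inherits(scores, "score_vector")) scores$values else scores
  n <- length(s)
  cells <- assign_cells(genotypes, combination)
  n_cells <- 3L^length(combination)
  eps <- 1e-12 # guard against float jitter in the >= comparison
  M <- 0L
  with_local_seed(derive_seed(seed, c(7919, combination)), {
    done <- 0
    while (done < n_perm) {
      b <- min(block, n_perm - done)
      P <- vapply(seq_len(b), function(i) s[sample.int(n)], numeric(n))
      acc <- colMeans(eval_cells_by_fold(P, cells, folds, n_cells, unseen)$test_acc)
      M <- M + if (comparison == "ge") {
        sum(acc >= observed_testing_accuracy - eps)
      } else {
        sum(acc > observed_testing_accuracy + eps)
      }
      done <- done + b
    }
  })
  N <- as.integer(n_perm)
  if (estimator == "add_one") {
    p <- (M + 1) / (N + 1)
    return(list(p_value = p, M = M, N = N, is_bound = FALSE, label = format_pvalue(p, FALSE)))
  }
  is_bound <- M == 0L
  p <- if (is_bound) 1 / N else M / N
  list(p_value = p, M = M, N = N, is_bound = is_bound, label = format_pvalue(p, is_bound))
}

#' Format a permutation p-value or bound
#'
#' @param p The p-value (the bound 1/N when `is_bound`).
#' @param is_bound TRUE when no permutation reached the observed accuracy.
#' @return A string such as `"0.0023"` or `"<1e-04"`.
#' @export
format_pvalue <- function(p, is_bound = FALSE) {
  paste0(if (is_bound) "<" else "", format(p, scientific = p < 1e-3, digits = 6))
}
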