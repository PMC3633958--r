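# The GMDR engine: K-fold partitioning, genotype-cell construction, high/low
# risk classification against the score vector, score-weighted balanced
# accuracy, and per-fold ranking with cross-validation consistency (CVC).
#
# Conventions (these are the method's load-bearing assumptions):
#   * a cell is high-risk iff the sum of the training scores it holds is > 0
#     (scores are mean zero when computed with an intercept, so 0 is the
#     natural risk threshold); a tied sum of exactly 0 is low-risk;
#   * cells never seen in training are low-risk at testing time (conservative
#     toward the null); optionally such subjects can be excluded instead;
#   * accuracy is the score-weighted balanced accuracy
#       1/2 [ sum_{i in H, s_i>0} s_i / sum_{s_i>0} s_i
#           + sum_{i in L, s_i<0} |s_i| / sum_{s_i<0} |s_i| ],
#     which reduces to MDR's balanced accuracy when scores are +/- a constant
#     (binary trait, no covariates); a class with no score mass in the
#     evaluation set is vacuously half-credited (0.5).

#' K-fold cross-validation partition
#'
#' Randomly divides `n` subjects into K folds of (near-)equal size; fold sizes
#' differ by at most one, with or without stratification.  Deterministic
#' given `(n, K, seed, stratify_labels)`.
#'
#' @param n Number of subjects (`n >= K`).
#' @param K Number of folds (default 10).
#' @param seed Integer seed for the fold draw.
#' @param stratify_labels Optional per-subject labels (e.g. case/control);
#'   each label is balanced across folds.
#' @return An object of class `fold_assignment`: list with `K`, `fold`
#'   (length-n integers in 1..K), `seed`.
#' @export
make_folds <- function(n, K = 10, seed = 1, stratify_labels = NULL) {
  if (K < 2) stop("K must be at least 2")
  if (n < K) stop("cannot split ", n, " subjects into ", K, " folds")
  fold <- integer(n)
  with_local_seed(derive_seed(seed, c(104729, n, K)), {
    if (is.null(stratify_labels)) {
      fold <- sample(rep_len(1:K, n))
    } else {
      stopifnot(length(stratify_labels) == n)
      # carried-offset round robin: each stratum and the total are balanced
      offset <- 0L
      for (lev in unique(stratify_labels)) {
        idx <- which(stratify_labels == lev)
        slots <- ((offset + seq_along(idx) - 1L) %% K) + 1L
        fold[sample(idx)] <- slots
        offset <- (offset + length(idx)) %% K
      }
    }
  })
  structure(list(K = as.integer(K), fold = fold, seed = seed), class = "fold_assignment")
}

#' @export
print.fold_assignment <- function(x, ...) {
  cat("fold_assignment: n =", length(x$fold), ", K =", x$K,
      ", sizes:", paste(tabulate(x$fold, x$K), collapse = "/"), "\n")
  invisible(x)
}

#' Map subjects to multi-SNP genotype cells
#'
#' The cell of a subject for a k-SNP combination is the k-tuple of its
#' genotype codes, encoded as an integer in `1..3^k`.  A subject with a
#' missing genotype at any of the k SNPs is excluded (`NA`) for this
#' combination only.
#'
#' @param genotypes A [genotype_matrix()] or plain 0/1/2 matrix.
#' @param combination Integer vector of SNP column indices.
#' @return Integer vector of cell ids (1-based), `NA` for excluded subjects.
#' @export
assign_cells <- function(genotypes, combination) {
  v <- if (inherits(genotypes, "genotype_matrix")) genotypes$values else genotypes
  k <- length(combination)
  stopifnot(k >= 1, all(combination >= 1), all(combination <= ncol(v)))
  cell <- rep(1L, nrow(v))
  for (j in seq_len(k)) {
    cell <- cell + v[, combination[j]] * 3L^(j - 1L)
  }
  as.integer(cell)
}

#' Classify genotype cells as high- or low-risk
#'
#' Sums the scores of the training subjects in each cell; a cell is high-risk
#' iff its sum is strictly positive, low-risk if strictly negative or exactly
#' zero (tie convention), and unclassified if no training subject occupies it.
#'
#' @param scores A [score_vector()] or numeric vector.
#' @param cells Cell ids from [assign_cells()].
#' @param training_mask Logical vector selecting the training subjects.
#' @param n_cells Total number of cells (`3^k`); inferred if missing.
#' @return An object of class `cell_model`: list with `cell_sum`, `occupied`,
#'   `risk` (character: high/low/unclassified), `n_cells`.
#' @export
classify_cells <- function(scores, cells, training_mask, n_cells = max(cells, na.rm = TRUE)) {
  s <- if (inherits(scores, "score_vector")) scores$values else scores
  use <- training_mask & !is.na(cells)
  if (!any(use)) stop("training set occupies no genotype cells")
  cell_sum <- numeric(n_cells)
  occ <- logical(n_cells)
  agg <- rowsum(s[use], cells[use])
  ix <- as.integer(rownames(agg))
  cell_sum[ix] <- agg[, 1]
  occ[ix] <- TRUE
  risk <- ifelse(!occ, "unclassified", ifelse(cell_sum > 0, "high", "low"))
  structure(list(cell_sum = cell_sum, occupied = occ, risk = risk, n_cells = n_cells),
            class = "cell_model")
}

#' Score-weighted balanced accuracy
#'
#' Evaluates a fitted [classify_cells()] model on a set of subjects: the mean
#' of (i) the fraction of positive score mass falling in high-risk cells and
#' (ii) the fraction of negative score mass falling in low-risk cells.
#' Unclassified cells count as low-risk (default) or their subjects are
#' excluded.  A class absent from the evaluation set contributes 0.5.
#'
#' @param scores A [score_vector()] or numeric vector.
#' @param cells Cell ids from [assign_cells()].
#' @param cell_model A `cell_model`.
#' @param eval_mask Logical vector selecting the evaluation subjects.
#' @param unseen `"low"` (default) or `"exclude"`.
#' @return Accuracy in `[0, 1]`.
#' @export
balanced_accuracy <- function(scores, cells, cell_model, eval_mask, unseen = c("low", "exclude")) {
  unseen <- match.arg(unseen)
  s <- if (inherits(scores, "score_vector")) scores$values else scores
  use <- eval_mask & !is.na(cells)
  if (unseen == "exclude") use <- use & cell_model$occupied[cells]
  if (!any(use)) return(0.5)
  s <- s[use]
  high <- cell_model$risk[cells[use]] == "high"
  pos <- s > 0
  neg <- s < 0
  term_pos <- safe_ratio(sum(s[pos & high]), sum(s[pos]))
  term_neg <- safe_ratio(sum(-s[neg & !high]), sum(-s[neg]))
  0.5 * (term_pos + term_neg)
}

# Vectorized per-fold evaluation of one combination.  Computes, for each fold
# f: the cell model trained on subjects outside f via the total-minus-fold
# decomposition of the cell sums, the training accuracy on those subjects and
# the testing accuracy on fold-f subjects.  `S` may be a matrix (columns =
# independent score vectors, used by the permutation test).
eval_cells_by_fold <- function(S, cells, folds, n_cells, unseen = "low") {
  S <- as.matrix(S)
  B <- ncol(S)
  K <- folds$K
  ok <- !is.na(cells)
  csum <- function(M, g) {
    out <- matrix(0, n_cells, ncol(M))
    if (nrow(M) > 0) {
      agg <- rowsum(M, g)
      out[as.integer(rownames(agg)), ] <- agg
    }
    out
  }
  Pos <- pmax(S, 0); Neg <- pmax(-S, 0)
  tot_s <- csum(S[ok, , drop = FALSE], cells[ok])
  tot_p <- csum(Pos[ok, , drop = FALSE], cells[ok])
  tot_n <- csum(Neg[ok, , drop = FALSE], cells[ok])
  tot_cnt <- tabulate(cells[ok], n_cells)

  train_acc <- matrix(NA_real_, K, B)
  test_acc <- matrix(NA_real_, K, B)
  skipped <- FALSE
  for (f in seq_len(K)) {
    inf <- ok & folds$fold == f
    g <- cells[inf]
    f_s <- csum(S[inf, , drop = FALSE], g)
    f_p <- csum(Pos[inf, , drop = FALSE], g)
    f_n <- csum(Neg[inf, , drop = FALSE], g)
    f_cnt <- tabulate(g, n_cells)
    tr_s <- tot_s - f_s
    tr_cnt <- tot_cnt - f_cnt
    if (all(tr_cnt == 0)) { skipped <- TRUE; next }
    high <- tr_s > 0 # ties (sum == 0) and empty cells are low-risk
    tr_p <- tot_p - f_p
    tr_n <- tot_n - f_n
    train_acc[f, ] <- 0.5 * (safe_ratio(colSums(tr_p * high), colSums(tr_p)) +
                             safe_ratio(colSums(tr_n * !high), colSums(tr_n)))
    if (unseen == "exclude") {
      occ <- tr_cnt > 0
      f_p <- f_p * occ
      f_n <- f_n * occ
    }
    test_acc[f, ] <- 0.5 * (safe_ratio(colSums(f_p * high), colSums(f_p)) +
                            safe_ratio(colSums(f_n * !high), colSums(f_n)))
  }
  list(train_acc = train_acc, test_acc = test_acc, skipped = skipped)
}

#' Cross-validated evaluation of one SNP combination
#'
#' For each fold, fits the cell model on the other K-1 folds, and computes
#' the training accuracy on the training subjects and the testing accuracy on
#' the held-out fold.  The combination's observed testing accuracy is the
#' arithmetic mean of the per-fold testing accuracies.
#'
#' @param genotypes A [genotype_matrix()].
#' @param scores A [score_vector()] or numeric vector.
#' @param combination Integer vector of SNP column indices.
#' @param folds A [make_folds()] assignment.
#' @param unseen Handling of cells unseen in training, see
#'   [balanced_accuracy()].
#' @return List with `combination`, `training_accuracy` (length K),
#'   `testing_accuracy_by_fold` (length K), `testing_accuracy` (mean), and
#'   `skipped` (TRUE if some fold had an empty training set).
#' @export
evaluate_combination <- function(genotypes, scores, combination, folds, unseen = "low") {
  s <- if (inherits(scores, "score_vector")) scores$values else scores
  cells <- assign_cells(genotypes, combination)
  n_cells <- 3L^length(combination)
  ev <- eval_cells_by_fold(matrix(s, ncol = 1), cells, folds, n_cells, unseen)
  list(
    combination = combination,
    training_accuracy = as.numeric(ev$train_acc),
    testing_accuracy_by_fold = as.numeric(ev$test_acc),
    testing_accuracy = mean(ev$test_acc),
    skipped = ev$skipped
  )
}

#' Per-fold ranking and cross-validation consistency
#'
#' In each fold, the `top_n` combinations with the highest training accuracy
#' are selected (ties broken lexicographically by SNP index tuple, i.e. by
#' enumeration order).  The CVC of a combination is the number of folds that
#' select it.  By default, combinations with CVC strictly greater than K/2
#' are retained as candidate interaction models.
#'
#' @param train_acc Matrix of training accuracies, combinations x folds.
#' @param combinations List of SNP index tuples, in lexicographic order,
#'   parallel to the rows of `train_acc`.
#' @param top_n Number of combinations selected per fold (default 1).
#' @param cvc_gt Retain combinations with `CVC > cvc_gt` (default `K/2`);
#'   set to 0 to keep every selected combination.
#' @return List with `cvc` (per-combination counts), `selected` (indices of
#'   retained combinations, ordered by CVC then lexicographic), and
#'   `selection_table` (data.frame: fold, combination index, training
#'   accuracy, rank).
#' @export
rank_and_select <- function(train_acc, combinations, top_n = 1,
                            cvc_gt = ncol(train_acc) / 2) {
  K <- ncol(train_acc)
  n_comb <- nrow(train_acc)
  top_n <- min(top_n, n_comb)
  cvc <- integer(n_comb)
  rows <- vector("list", K)
  for (f in seq_len(K)) {
    acc <- train_acc[, f]
    ord <- order(-acc, seq_len(n_comb)) # stable: ties lexicographic
    sel <- ord[seq_len(top_n)]
    sel <- sel[!is.na(acc[sel])]
    cvc[sel] <- cvc[sel] + 1L
    rows[[f]] <- data.frame(
      fold = f, combination = sel,
      training_accuracy = acc[sel], rank = seq_along(sel)
    )
  }
  keep <- which(cvc > cvc_gt)
  keep <- keep[order(-cvc[keep], keep)]
  list(
    cvc = cvc,
    selected = keep,
    selection_table = do.call(rbind, rows)
  )
}
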