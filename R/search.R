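# The interaction search: combination enumeration with a physical-distance
# filter, the main `gmdr()` fit (exhaustive or conditioned k-way search),
# significance filtering and core-SNP detection.

#' Enumerate k-SNP combinations under a physical-distance filter
#'
#' All size-k index tuples in lexicographic order, omitting any tuple that
#' contains two SNPs on the same chromosome closer than
#' `min_pair_distance_bp` (a guard against linkage-disequilibrium artefacts).
#' SNPs on different chromosomes are never distance-filtered, and the
#' comparison is strict: a distance of exactly `min_pair_distance_bp` passes.
#'
#' @param snps SNP metadata ([snp_info()] data.frame).
#' @param k Interaction order (`k >= 1`).
#' @param min_pair_distance_bp Minimum within-chromosome distance in base
#'   pairs (default 1e6, i.e. 1 Mb); 0 disables the filter.
#' @param indices Optional subset of SNP indices to draw combinations from
#'   (used by the conditioned search); defaults to all SNPs.
#' @return List of integer index tuples.
#' @export
enumerate_combinations <- function(snps, k, min_pair_distance_bp = 1e6,
                                   indices = NULL) {
  if (is.null(indices)) indices <- seq_len(nrow(snps))
  indices <- sort(unique(as.integer(indices)))
  if (k > length(indices)) return(list())
  if (k == 1) return(as.list(indices))
  m <- length(indices)
  allowed <- matrix(TRUE, m, m)
  if (min_pair_distance_bp > 0) {
    chr <- snps$chromosome[indices]
    pos <- snps$position_bp[indices]
    same <- outer(chr, chr, "==")
    dist <- abs(outer(pos, pos, "-"))
    allowed <- !(same & dist < min_pair_distance_bp)
    diag(allowed) <- TRUE
  }
  combs <- utils::combn(m, k, simplify = FALSE)
  keep <- vapply(combs, function(cb) {
    all(allowed[t(utils::combn(cb, 2))])
  }, logical(1))
  lapply(combs[keep], function(cb) indices[cb])
}

#' Fit GMDR interaction models
#'
#' The main fitting function: computes (or accepts) per-subject scores,
#' partitions the subjects into K cross-validation folds, evaluates every
#' enumerated k-SNP combination (training accuracy per fold, testing accuracy
#' averaged over folds), selects the `top_n` combinations per fold, retains
#' candidates by cross-validation consistency, and attaches permutation
#' p-values.
#'
#' @param genotypes A [genotype_matrix()], or a `gmdr_data` bundle from
#'   [validate_dataset()] (in which case `phenotype`/`covariates` are taken
#'   from the bundle).
#' @param phenotype A [phenotype()] (ignored when a bundle is given).
#' @param covariates Optional [covariate_matrix()].
#' @param scores Optional precomputed [score_vector()]; when `NULL`, scores
#'   are computed with [compute_scores()].
#' @param family GLM family for the scores, see [compute_scores()].
#' @param order Interaction order k (default 2).
#' @param K Number of cross-validation folds (default 10).
#' @param top_n Combinations selected per fold (default 1).
#' @param candidate_cvc_gt Retain candidates with CVC strictly greater than
#'   this (default K/2).
#' @param min_pair_distance_bp Physical-distance filter, see
#'   [enumerate_combinations()] (default 1 Mb).
#' @param snp_subset Optional SNP index subset: restricts the search to
#'   combinations drawn from these SNPs (the conditioned search).
#' @param n_perm Permutations per retained candidate (default 10^4; 0 skips
#'   p-values).
#' @param seed Master seed; folds and every combination's permutation stream
#'   are derived from it.
#' @param stratify `NULL` (auto: stratify folds by case/control for binary
#'   traits, not otherwise), `TRUE` or `FALSE`.
#' @param folds Optional precomputed [make_folds()] assignment, e.g. to share
#'   folds across interaction orders.
#' @param comparison Permutation comparison, see [permutation_pvalue()].
#' @param unseen Handling of cells unseen in training, see
#'   [balanced_accuracy()].
#' @return An object of class `gmdr`; see [print.gmdr()], [summary.gmdr()],
#'   [predict.gmdr()].  Its `$results` data.frame has one row per retained
#'   candidate: `order`, `snp_ids`, `chromosomes`, `cvc`, `testing_accuracy`,
#'   `p_value`, `p_is_bound`, `p_label`, plus list columns `combination`,
#'   `training_accuracy`, `testing_accuracy_by_fold`, `cell_model` (the
#'   full-data cell classification used by `predict`).
#' @export
gmdr <- function(genotypes, phenotype = NULL, covariates = NULL, scores = NULL,
                 family = "auto", order = 2, K = 10, top_n = 1,
                 candidate_cvc_gt = K / 2, min_pair_distance_bp = 1e6,
                 snp_subset = NULL, n_perm = 1e4, seed = 1, stratify = NULL,
                 folds = NULL, comparison = "ge", unseen = "low") {
  cl <- match.call()
  if (inherits(genotypes, "gmdr_data")) {
    bundle <- genotypes
  } else {
    bundle <- validate_dataset(genotypes, phenotype, covariates, quiet = TRUE)
  }
  geno <- bundle$genotypes
  n <- length(geno$subject_ids)
  if (is.null(scores)) {
    scores <- compute_scores(bundle$phenotype, bundle$covariates, family = family)
  } else if (!inherits(scores, "score_vector")) {
    scores <- score_vector(scores, origin = "user_supplied")
  }
  if (length(scores$values) != n) stop("score length does not match subject count")
  if (is.null(stratify)) stratify <- bundle$phenotype$trait_kind == "binary"
  if (is.null(folds)) {
    labels <- if (stratify) bundle$phenotype$values else NULL
    folds <- make_folds(n, K = K, seed = seed, stratify_labels = labels)
  }
  K <- folds$K

  combos <- enumerate_combinations(geno$snps, order, min_pair_distance_bp,
                                   indices = snp_subset)
  if (length(combos) == 0) {
    message("gmdr: no combinations to evaluate at order ", order)
    return(new_gmdr(list(), integer(0), NULL, folds, scores, geno, cl,
                    order, top_n, n_perm, seed))
  }

  evals <- vector("list", length(combos))
  train_acc <- matrix(NA_real_, length(combos), K)
  for (i in seq_along(combos)) {
    ev <- evaluate_combination(geno, scores, combos[[i]], folds, unseen = unseen)
    if (ev$skipped) {
      warning("combination ", paste(combos[[i]], collapse = ","),
              " skipped: a fold had an empty training set")
      next
    }
    evals[[i]] <- ev
    train_acc[i, ] <- ev$training_accuracy
  }

  sel <- rank_and_select(train_acc, combos, top_n = top_n, cvc_gt = candidate_cvc_gt)
  attr(sel, "combos") <- combos
  results <- lapply(sel$selected, function(i) {
    ev <- evals[[i]]
    cells <- assign_cells(geno, ev$combination)
    cm <- classify_cells(scores, cells, rep(TRUE, n), n_cells = 3L^order)
    pv <- if (n_perm >= 1) {
      permutation_pvalue(geno, scores, ev$combination, folds,
                         ev$testing_accuracy, n_perm = n_perm, seed = seed,
                         comparison = comparison, unseen = unseen)
    } else {
      list(p_value = NA_real_, M = NA_integer_, N = 0L, is_bound = FALSE, label = NA_character_)
    }
    list(ev = ev, cvc = sel$cvc[i], cell_model = cm, pv = pv)
  })
  new_gmdr(results, sel$cvc, sel, folds, scores, geno, cl, order, top_n, n_perm, seed)
}

new_gmdr <- function(results, cvc, sel, folds, scores, geno, call,
                     order, top_n, n_perm, seed) {
  if (length(results) > 0) {
    df <- data.frame(
      order = order,
      snp_ids = vapply(results, function(r) {
        paste(geno$snps$snp_id[r$ev$combination], collapse = ",")
      }, ""),
      chromosomes = vapply(results, function(r) {
        paste(geno$snps$chromosome[r$ev$combination], collapse = "-")
      }, ""),
      cvc = vapply(results, function(r) as.integer(r$cvc), 0L),
      testing_accuracy = vapply(results, function(r) r$ev$testing_accuracy, 0),
      p_value = vapply(results, function(r) r$pv$p_value, 0),
      p_is_bound = vapply(results, function(r) r$pv$is_bound, FALSE),
      p_n = vapply(results, function(r) as.integer(r$pv$N), 0L),
      p_label = vapply(results, function(r) as.character(r$pv$label), ""),
      stringsAsFactors = FALSE
    )
    df$combination <- I(lapply(results, function(r) r$ev$combination))
    df$training_accuracy <- I(lapply(results, function(r) r$ev$training_accuracy))
    df$testing_accuracy_by_fold <- I(lapply(results, function(r) r$ev$testing_accuracy_by_fold))
    df$cell_model <- I(lapply(results, function(r) r$cell_model))
    ord <- order(-df$testing_accuracy, -df$cvc,
                 vapply(df$combination, function(cb) paste(sprintf("%09d", cb), collapse = ""), ""))
    df <- df[ord, , drop = FALSE]
    rownames(df) <- NULL
  } else {
    df <- empty_results_df()
  }
  # per-fold selection table with SNP tuples, for audit and candidate harvest
  sel_table <- NULL
  if (!is.null(sel) && !is.null(sel$selection_table) && nrow(sel$selection_table) > 0) {
    sel_table <- sel$selection_table
    combos <- attr(sel, "combos")
    sel_table$snp_indices <- I(combos[sel_table$combination])
    sel_table$snp_ids <- vapply(sel_table$snp_indices, function(cb) {
      paste(geno$snps$snp_id[cb], collapse = ",")
    }, "")
  }
  structure(
    list(
      results = df, cvc_all = cvc, selection_table = sel_table, folds = folds,
      scores = scores, snps = geno$snps, call = call,
      order = order, K = folds$K, top_n = top_n, n_perm = n_perm, seed = seed
    ),
    class = "gmdr"
  )
}

empty_results_df <- function() {
  df <- data.frame(
    order = integer(0), snp_ids = character(0), chromosomes = character(0),
    cvc = integer(0), testing_accuracy = numeric(0), p_value = numeric(0),
    p_is_bound = logical(0), p_n = integer(0), p_label = character(0),
    stringsAsFactors = FALSE
  )
  df$combination <- I(list())
  df$training_accuracy <- I(list())
  df$testing_accuracy_by_fold <- I(list())
  df$cell_model <- I(list())
  df
}

#' Exhaustive k-way interaction search
#'
#' Convenience wrapper around [gmdr()] over all SNPs.
#' @inheritParams gmdr
#' @param ... Passed to [gmdr()].
#' @return A `gmdr` object.
#' @export
exhaustive_search <- function(genotypes, phenotype = NULL, ..., order = 2) {
  gmdr(genotypes, phenotype, ..., order = order, snp_subset = NULL)
}

#' Conditioned higher-order search
#'
#' Runs the same machinery as the exhaustive search but only among
#' combinations drawn from `snp_subset` (normally the SNPs harvested from the
#' two-way search, see [harvest_top_snps()]).  The physical-distance filter
#' still applies.
#'
#' @inheritParams gmdr
#' @param snp_subset Integer SNP indices to condition on.
#' @param ... Passed to [gmdr()].
#' @return A `gmdr` object.
#' @export
conditioned_search <- function(genotypes, phenotype = NULL, snp_subset, order, ...) {
  if (length(snp_subset) < order) {
    warning("snp_subset smaller than the interaction order; nothing to search")
  }
  gmdr(genotypes, phenotype, ..., order = order, snp_subset = snp_subset)
}

#' Harvest the unique SNPs of the per-fold top combinations
#'
#' The union of all SNP indices appearing in the `top_n` best combinations of
#' each fold — the candidate set the higher-order searches are conditioned
#' on.
#'
#' @param fit A `gmdr` object (normally the order-2 fit with a large
#'   `top_n`).
#' @param top_n Optionally restrict to the first `top_n` ranks per fold
#'   (defaults to everything the fit selected).
#' @return Sorted integer vector of unique SNP indices.
#' @export
harvest_top_snps <- function(fit, top_n = NULL) {
  stopifnot(inherits(fit, "gmdr"))
  st <- fit$selection_table
  if (is.null(st) || nrow(st) == 0) return(integer(0))
  if (!is.null(top_n)) st <- st[st$rank <= top_n, , drop = FALSE]
  sort(unique(unlist(st$snp_indices)))
}

#' Filter interaction models by CVC and permutation p-value
#'
#' Keeps models with `cvc >= final_cvc_min` and permutation p-value
#' `<= final_p_max`.  A p-value reported as the bound "< 1/N" qualifies iff
#' `1/N <= final_p_max`.
#'
#' @param results A results data.frame (from one or several `gmdr` fits,
#'   e.g. `rbind`ed across orders), or a `gmdr` object.
#' @param final_cvc_min Minimum CVC (e.g. 7 of 10).
#' @param final_p_max Maximum p-value (e.g. 1e-7 at the genome-wide scale).
#' @return The filtered results data.frame.
#' @export
significance_filter <- function(results, final_cvc_min, final_p_max) {
  df <- if (inherits(results, "gmdr")) results$results else results
  if (nrow(df) == 0) return(df)
  resolvable <- !is.na(df$p_n) & df$p_n > 0 & 1 / df$p_n <= final_p_max
  if (!any(df$p_is_bound) && any(!resolvable)) {
    warning("permutation resolution (1/N) is coarser than final_p_max = ",
            final_p_max, " for some models; increase n_perm to certify them")
  }
  p_eff <- df$p_value # a bound "< 1/N" carries the value 1/N
  keep <- !is.na(p_eff) & df$cvc >= final_cvc_min & p_eff <= final_p_max
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect core SNPs across significant interaction models
#'
#' A SNP is a core SNP when it appears in at least `core_min_models` distinct
#' significant models, at any interaction orders — the repeatedly-implicated
#' loci a multi-order search is after.
#'
#' @param results A significant-results data.frame (rows from one or several
#'   orders; needs columns `snp_ids` and `order`).
#' @param core_min_models Minimum number of distinct supporting models
#'   (default 2).
#' @return data.frame with `snp_id`, `n_models`, `orders` (comma-joined) and
#'   `models` (semicolon-joined supporting model snp_id strings).
#' @export
detect_core_snps <- function(results, core_min_models = 2) {
  df <- if (inherits(results, "gmdr")) results$results else results
  if (nrow(df) == 0) {
    return(data.frame(snp_id = character(0), n_models = integer(0),
                      orders = character(0), models = character(0),
                      stringsAsFactors = FALSE))
  }
  per_model <- strsplit(df$snp_ids, ",", fixed = TRUE)
  snp <- unlist(per_model)
  model_idx <- rep(seq_len(nrow(df)), lengths(per_model))
  tab <- split(model_idx, snp)
  core <- names(tab)[vapply(tab, length, 0L) >= core_min_models]
  out <- do.call(rbind, lapply(core, function(s) {
    m <- tab[[s]]
    data.frame(
      snp_id = s,
      n_models = length(m),
      orders = paste(sort(unique(df$order[m])), collapse = ","),
      models = paste(df$snp_ids[m], collapse = ";"),
      stringsAsFactors = FALSE
    )
  }))
  if (is.null(out)) {
    return(data.frame(snp_id = character(0), n_models = integer(0),
                      orders = character(0), models = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- out[order(-out$n_models, out$snp_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write an interaction-results table as TSV
#'
#' @param results Results data.frame (possibly rbind-ed across orders).
#' @param path Output path.
#' @param K Number of folds (for the "c/K" CVC format).
#' @param core_snp_ids Optional character vector marking core SNPs.
#' @export
write_results_tsv <- function(results, path, K = 10, core_snp_ids = character(0)) {
  df <- if (inherits(results, "gmdr")) results$results else results
  has_core <- vapply(strsplit(df$snp_ids, ",", fixed = TRUE),
                     function(s) any(s %in% core_snp_ids), logical(1))
  out <- data.frame(
    order = df$order,
    snp_ids = df$snp_ids,
    chromosomes = df$chromosomes,
    cvc = paste0(df$cvc, "/", K),
    testing_accuracy = fmt_num(df$testing_accuracy, 4),
    p_value = df$p_label,
    core = ifelse(has_core, "yes", "no"),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the core-SNP report as TSV
#'
#' @param core_snps Output of [detect_core_snps()].
#' @param path Output path.
#' @export
write_core_snps_tsv <- function(core_snps, path) {
  utils::write.table(core_snps, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
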