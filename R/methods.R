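# S3 methods for fitted gmdr objects.

#' @export
print.gmdr <- function(x, ...) {
  cat("GMDR interaction search (order ", x$order, ", K = ", x$K,
      ", top_n = ", x$top_n, ")\n", sep = "")
  cat("Candidates retained (CVC rule):", nrow(x$results), "\n")
  if (nrow(x$results) > 0) {
    top <- utils::head(x$results, 5)
    cat("Top models:\n")
    for (i in seq_len(nrow(top))) {
      cat(sprintf("  %s  CVC %d/%d  testing accuracy %s  p %s\n",
                  top$snp_ids[i], top$cvc[i], x$K,
                  fmt_num(top$testing_accuracy[i], 4),
                  ifelse(is.na(top$p_label[i]), "-", top$p_label[i])))
    }
  }
  invisible(x)
}

#' Summarize a GMDR fit
#'
#' @param object A `gmdr` object.
#' @param ... Unused.
#' @return The object, invisibly, after printing candidate models, CVC
#'   distribution and per-fold training-accuracy ranges.
#' @export
summary.gmdr <- function(object, ...) {
  print(object)
  if (nrow(object$results) > 0) {
    cat("\nCVC distribution of retained candidates:\n")
    print(table(cvc = object$results$cvc))
    tr <- range(unlist(object$results$training_accuracy))
    cat("Training-accuracy range across retained models/folds: ",
        fmt_num(tr[1], 4), " - ", fmt_num(tr[2], 4), "\n", sep = "")
  }
  if (!is.null(object$selection_table)) {
    cat("Per-fold selections recorded:", nrow(object$selection_table), "\n")
  }
  invisible(object)
}

#' Predict high/low risk for subjects from a fitted interaction model
#'
#' Maps each subject's genotype cell for the chosen model through the
#' full-data cell classification stored in the fit.
#'
#' @param object A `gmdr` object with at least one retained model.
#' @param genotypes A [genotype_matrix()] with the same SNP columns as the
#'   training data (defaults cannot be supplied: prediction needs data).
#' @param model Row index into `object$results` (default 1 = best model).
#' @param ... Unused.
#' @return Character vector per subject: `"high"`, `"low"`, or `NA` for
#'   subjects with a missing genotype in the model's SNPs.
#' @export
predict.gmdr <- function(object, genotypes, model = 1, ...) {
  if (nrow(object$results) == 0) stop("no retained models to predict from")
  cb <- object$results$combination[[model]]
  cm <- object$results$cell_model[[model]]
  cells <- assign_cells(genotypes, cb)
  out <- rep(NA_character_, length(cells))
  okc <- !is.na(cells)
  risk <- cm$risk[cells[okc]]
  risk[risk == "unclassified"] <- "low"
  out[okc] <- risk
  out
}

#' Plot per-fold testing accuracies of the retained models
#'
#' One line per retained model across the K folds, with the 0.5 null level
#' marked.
#'
#' @param x A `gmdr` object.
#' @param max_models Plot at most this many top models (default 10).
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.gmdr <- function(x, max_models = 10, ...) {
  if (nrow(x$results) == 0) {
    warning("nothing to plot: no retained models")
    return(invisible(x))
  }
  m <- utils::head(x$results, max_models)
  acc <- do.call(cbind, m$testing_accuracy_by_fold)
  graphics::matplot(acc, type = "b", pch = 16, lty = 1,
                    xlab = "fold", ylab = "testing accuracy",
                    ylim = range(c(acc, 0.5)), ...)
  graphics::abline(h = 0.5, lty = 2, col = "grey40")
  graphics::legend("topright", legend = m$snp_ids, col = seq_len(nrow(m)),
                   lty = 1, cex = 0.7, bty = "n")
  invisible(x)
}
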