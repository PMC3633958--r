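# Core typed containers shared by every other module.
#
# Genotypes are stored as minor-allele counts {0, 1, 2} with NA as the missing
# sentinel; genotype missingness is never imputed.  Subjects with missing
# phenotype or covariates are removed globally (listwise); subjects with a
# missing genotype are excluded per SNP combination only, so the score vector
# stays defined for every retained subject.

#' SNP metadata table
#'
#' Builds and validates the per-SNP metadata used throughout the package, in
#' particular by the physical-distance filter of the interaction search.
#'
#' @param snp_id Character vector of unique SNP identifiers.
#' @param chromosome Character (or coercible) chromosome labels.
#' @param position_bp Integer base-pair positions (1-based), all `>= 1`.
#' @return A `data.frame` with columns `snp_id`, `chromosome`, `position_bp`.
#' @export
snp_info <- function(snp_id, chromosome, position_bp) {
  snp_id <- as.character(snp_id)
  chromosome <- as.character(chromosome)
  position_bp <- as.integer(position_bp)
  if (anyDuplicated(snp_id)) {
    stop("duplicated snp_id: ", paste(unique(snp_id[duplicated(snp_id)]), collapse = ", "))
  }
  if (length(chromosome) != length(snp_id) || length(position_bp) != length(snp_id)) {
    stop("snp_id, chromosome and position_bp must have equal length")
  }
  if (any(is.na(position_bp)) || any(position_bp < 1L)) {
    stop("position_bp must be a positive integer (1-based base pairs)")
  }
  data.frame(
    snp_id = snp_id, chromosome = chromosome, position_bp = position_bp,
    stringsAsFactors = FALSE
  )
}

#' Genotype matrix container
#'
#' A subjects x SNPs matrix of minor-allele counts with SNP metadata and
#' subject identifiers.  Entries must be 0, 1, 2 or `NA` (missing call).
#'
#' @param values Integer matrix, subjects in rows, SNPs in columns.
#' @param snps SNP metadata as returned by [snp_info()].
#' @param subject_ids Character vector of unique subject identifiers.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(values, snps, subject_ids) {
  values <- as.matrix(values)
  storage.mode(values) <- "integer"
  if (nrow(snps) != ncol(values)) {
    stop("number of SNPs in metadata (", nrow(snps), ") does not match genotype columns (",
         ncol(values), ")")
  }
  subject_ids <- as.character(subject_ids)
  if (length(subject_ids) != nrow(values)) {
    stop("length of subject_ids (", length(subject_ids), ") does not match genotype rows (",
         nrow(values), ")")
  }
  if (anyDuplicated(subject_ids)) stop("subject_ids must be unique")
  bad <- !is.na(values) & !(values %in% 0:2)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop("genotype value out of {0,1,2,NA} at subject ", idx[1], ", SNP ", idx[2])
  }
  dimnames(values) <- list(subject_ids, snps$snp_id)
  structure(
    list(values = values, snps = snps, subject_ids = subject_ids),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$subject_ids), "subjects x", nrow(x$snps), "SNPs\n")
  cat("  missing calls:", sum(is.na(x$values)), "\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$values)

#' Subset a genotype matrix by subjects and/or SNPs
#' @param x A `genotype_matrix`.
#' @param subjects,snps Index vectors (integer or logical) into subjects / SNPs.
#' @return A `genotype_matrix`.
#' @export
subset_genotypes <- function(x, subjects = NULL, snps = NULL) {
  if (is.null(subjects)) subjects <- seq_along(x$subject_ids)
  if (is.null(snps)) snps <- seq_len(nrow(x$snps))
  genotype_matrix(
    x$values[subjects, snps, drop = FALSE],
    x$snps[snps, , drop = FALSE],
    x$subject_ids[subjects]
  )
}

#' Phenotype container
#'
#' @param values Numeric phenotype vector (`NA` allowed, removed later by
#'   listwise deletion).
#' @param trait_kind One of `"binary"`, `"quantitative"`, `"count"`.  Binary
#'   traits may be coded with any two distinct values and are canonicalized to
#'   0/1 (the larger value becomes 1, i.e. "affected").
#' @return An object of class `phenotype` with fields `values`, `trait_kind`.
#' @export
phenotype <- function(values, trait_kind = c("binary", "quantitative", "count")) {
  trait_kind <- match.arg(trait_kind)
  values <- as.numeric(values)
  if (trait_kind == "binary") {
    lev <- sort(unique(values[!is.na(values)]))
    if (length(lev) > 2) {
      stop("binary phenotype has ", length(lev), " distinct levels: ",
           paste(lev, collapse = ", "))
    }
    if (length(lev) == 2) values <- as.numeric(values == lev[2])
    if (length(lev) == 1) values <- as.numeric(values == lev[1]) * (lev[1] != 0)
  }
  if (trait_kind == "count" && any(values[!is.na(values)] < 0)) {
    stop("count phenotype must be non-negative")
  }
  structure(list(values = values, trait_kind = trait_kind), class = "phenotype")
}

#' Covariate matrix container
#'
#' @param values Numeric matrix (subjects x covariates); zero columns allowed.
#' @param names Covariate names.
#' @return An object of class `covariate_matrix`.
#' @export
covariate_matrix <- function(values = matrix(0, 0, 0), names = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(names)) names <- if (ncol(values)) paste0("c", seq_len(ncol(values))) else character(0)
  if (length(names) != ncol(values)) stop("covariate names do not match column count")
  colnames(values) <- names
  structure(list(values = values, names = names), class = "covariate_matrix")
}

#' Per-subject score vector
#'
#' The quantity GMDR classifies and permutes: one real score per subject,
#' normally a generalized-linear-model residual (see [compute_scores()]).
#' Scores computed with an intercept-containing model are mean zero, which is
#' what makes the high/low-risk threshold of 0 meaningful; user-supplied
#' scores should be centred by the user.
#'
#' @param values Finite numeric vector, one entry per retained subject.
#' @param origin `"computed"` or `"user_supplied"`.
#' @return An object of class `score_vector`.
#' @export
score_vector <- function(values, origin = c("computed", "user_supplied")) {
  origin <- match.arg(origin)
  values <- as.numeric(values)
  if (any(!is.finite(values))) stop("scores must be finite for every subject")
  structure(list(values = values, origin = origin), class = "score_vector")
}

#' Validate and assemble a dataset bundle
#'
#' Checks dimension consistency across genotypes, phenotype and covariates and
#' performs listwise deletion of subjects with missing phenotype or covariate
#' values.  Missing genotypes are kept (they are handled per combination by
#' the engine).  Idempotent: validating an already-validated bundle's parts
#' returns the identical data.
#'
#' @param genotypes A [genotype_matrix()].
#' @param phenotype A [phenotype()].
#' @param covariates Optional [covariate_matrix()] (default: none).
#' @param quiet Suppress the removal message.
#' @return An object of class `gmdr_data`: list with `genotypes`, `phenotype`,
#'   `covariates`, `n_removed`.
#' @export
validate_dataset <- function(genotypes, phenotype, covariates = NULL, quiet = FALSE) {
  stopifnot(inherits(genotypes, "genotype_matrix"), inherits(phenotype, "phenotype"))
  if (is.null(covariates)) covariates <- covariate_matrix(matrix(0, length(genotypes$subject_ids), 0))
  stopifnot(inherits(covariates, "covariate_matrix"))
  n <- length(genotypes$subject_ids)
  if (n == 0 || nrow(genotypes$snps) == 0) stop("empty genotype matrix")
  if (length(phenotype$values) != n) {
    stop("phenotype length (", length(phenotype$values),
         ") does not match number of subjects (", n, ")")
  }
  if (ncol(covariates$values) > 0 && nrow(covariates$values) != n) {
    stop("covariate rows (", nrow(covariates$values),
         ") do not match number of subjects (", n, ")")
  }
  keep <- !is.na(phenotype$values)
  if (ncol(covariates$values) > 0) keep <- keep & stats::complete.cases(covariates$values)
  n_removed <- sum(!keep)
  if (n_removed > 0 && !quiet) {
    message("validate_dataset: removed ", n_removed,
            " subject(s) with missing phenotype/covariates (", sum(keep), " retained)")
  }
  structure(
    list(
      genotypes = subset_genotypes(genotypes, subjects = which(keep)),
      phenotype = phenotype(phenotype$values[keep], phenotype$trait_kind),
      covariates = covariate_matrix(covariates$values[keep, , drop = FALSE], covariates$names),
      n_removed = n_removed
    ),
    class = "gmdr_data"
  )
}

#' @export
print.gmdr_data <- function(x, ...) {
  cat("gmdr_data:", length(x$genotypes$subject_ids), "subjects,",
      nrow(x$genotypes$snps), "SNPs,",
      x$phenotype$trait_kind, "trait,",
      ncol(x$covariates$values), "covariate(s)\n")
  invisible(x)
}
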