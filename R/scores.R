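# Per-subject score statistics: residuals of a generalized linear model of the
# phenotype on the covariates (intercept always included).  Binary traits use
# logistic regression, quantitative traits ordinary least squares, count
# traits log-link Poisson.  Residuals are response residuals (y - fitted
# mean): for a GLM with canonical link these are proportional to the
# per-subject score contribution, and with an intercept they sum to zero, so
# the engine's high/low-risk threshold of 0 is the natural one.

#' Compute GMDR score statistics
#'
#' Fits phenotype ~ covariates (intercept only when there are no covariates)
#' and returns the response residuals `y - fitted` as the per-subject scores.
#'
#' @param phenotype A [phenotype()], no missing values (run
#'   [validate_dataset()] first).
#' @param covariates Optional [covariate_matrix()].
#' @param family `"auto"` (binary -> bernoulli, quantitative -> normal,
#'   count -> poisson), or one of `"normal"`, `"bernoulli"`, `"poisson"`.
#' @return A [score_vector()] with `origin = "computed"`.
#' @export
compute_scores <- function(phenotype, covariates = NULL,
                           family = c("auto", "normal", "bernoulli", "poisson")) {
  family <- match.arg(family)
  stopifnot(inherits(phenotype, "phenotype"))
  y <- phenotype$values
  if (any(is.na(y))) stop("phenotype contains missing values; validate the dataset first")
  if (family == "auto") {
    family <- switch(phenotype$trait_kind,
      binary = "bernoulli", quantitative = "normal", count = "poisson"
    )
  }
  if (family == "bernoulli") {
    if (length(unique(y)) < 2) stop("constant binary phenotype: scores undefined")
    if (!all(y %in% c(0, 1))) stop("bernoulli family requires a 0/1 phenotype")
  }
  X <- if (is.null(covariates)) matrix(0, length(y), 0) else covariates$values
  if (ncol(X) > 0 && nrow(X) != length(y)) stop("covariate rows do not match phenotype length")
  df <- data.frame(.y = y)
  if (ncol(X) > 0) df <- cbind(df, as.data.frame(X))
  fam <- switch(family,
    normal = stats::gaussian(),
    bernoulli = stats::binomial(),
    poisson = stats::poisson()
  )
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., data = df, family = fam),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|fitted rates numerically 0",
                conditionMessage(w))) {
        sep_warn <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  mu <- stats::fitted(fit)
  separated <- family == "bernoulli" && any(mu < 1e-10 | mu > 1 - 1e-10)
  if (!fit$converged || sep_warn || separated) {
    stop("GLM fit did not converge (possible separation) with covariates: ",
         if (ncol(X) > 0) paste(colnames(X), collapse = ", ") else "(intercept only)")
  }
  score_vector(as.numeric(y - stats::fitted(fit)), origin = "computed")
}

#' Read a user-supplied score file
#'
#' Plain text, one score per line; alternatively a two-column
#' `subject_id<TAB>score` dialect whose header line starts with `#`
#' (auto-detected).  No centring or rescaling is applied: user-supplied
#' scores should already be centred for the risk threshold of 0 to be
#' meaningful.
#'
#' @param path File path.
#' @param subject_ids Optional subject identifiers; in the two-column dialect
#'   the file order must match, and in both dialects the length must match.
#' @return A [score_vector()] with `origin = "user_supplied"`.
#' @export
load_scores <- function(path, subject_ids = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("score file is empty: ", path)
  two_col <- startsWith(lines[1], "#")
  if (two_col) {
    body <- strsplit(lines[-1], "\t", fixed = TRUE)
    if (any(lengths(body) != 2)) stop("malformed subject_id<TAB>score line in ", path)
    ids <- vapply(body, `[`, "", 1)
    vals <- suppressWarnings(as.numeric(vapply(body, `[`, "", 2)))
    if (!is.null(subject_ids) && !identical(ids, as.character(subject_ids))) {
      stop("subject ids in score file do not match dataset order")
    }
  } else {
    vals <- suppressWarnings(as.numeric(lines))
  }
  if (any(is.na(vals))) {
    stop("non-numeric score at line ", which(is.na(vals))[1] + two_col, " of ", path)
  }
  if (!is.null(subject_ids) && length(vals) != length(subject_ids)) {
    stop("score file has ", length(vals), " values but the dataset has ",
         length(subject_ids), " subjects")
  }
  score_vector(vals, origin = "user_supplied")
}

#' Write scores to a file readable by [load_scores()]
#'
#' @param scores A [score_vector()].
#' @param path Output path.
#' @param subject_ids Optional ids; when given, the two-column dialect is used.
#' @export
write_scores <- function(scores, path, subject_ids = NULL) {
  if (is.null(subject_ids)) {
    writeLines(format(scores$values, digits = 17, trim = TRUE, scientific = FALSE), path)
  } else {
    writeLines(
      c("#subject_id\tscore",
        paste(subject_ids, format(scores$values, digits = 17, trim = TRUE, scientific = FALSE),
              sep = "\t")),
      path
    )
  }
  invisible(path)
}
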