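# The staged analysis pipeline: QC -> scores -> exhaustive two-way search ->
# candidate harvest -> conditioned higher-order searches -> significance
# filter -> core-SNP report.  Every threshold and seed comes from one config;
# identical config + inputs give byte-identical output files.  Subjects are
# sorted by subject id after loading so results do not depend on input row
# order.

#' Default pipeline configuration
#'
#' Returns the full configuration list with defaults; any entry can be
#' overridden via `...` or by the YAML file read in [run_pipeline()].
#'
#' Entries: input files (`ped`/`map` or `geno_tsv`, optional `pheno_tsv`,
#' `covar_tsv`, `scores_file`), `trait_kind`, `family`, QC thresholds
#' (`max_missing` 0.10, `min_maf` 0.05, `min_hwe_p` 0.001, `hwe_method`),
#' `K` (10), `orders` (2), `top_n_per_fold` (1), `candidate_cvc_gt` (K/2),
#' `min_pair_distance_bp` (1e6), `n_perm` (1e4), `final_cvc_min` (7),
#' `final_p_max` (0.05), `core_min_models` (2), `seed` (1), `out_dir`.
#'
#' @param ... Overrides.
#' @return Named list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    ped = NULL, map = NULL, geno_tsv = NULL, pheno_tsv = NULL, covar_tsv = NULL,
    scores_file = NULL, trait_kind = "binary", family = "auto",
    max_missing = 0.10, min_maf = 0.05, min_hwe_p = 0.001, hwe_method = "exact",
    K = 10, orders = 2, top_n_per_fold = 1, candidate_cvc_gt = NULL,
    min_pair_distance_bp = 1e6, n_perm = 1e4,
    final_cvc_min = 7, final_p_max = 0.05, core_min_models = 2,
    seed = 1, out_dir = "gmdr_out"
  )
  over <- list(...)
  cfg[names(over)] <- over
  if (is.null(cfg$candidate_cvc_gt)) cfg$candidate_cvc_gt <- cfg$K / 2
  cfg
}

#' Run the full staged GMDR pipeline
#'
#' Executes QC, score computation, the exhaustive two-way search, and (for
#' `orders` beyond 2) conditioned higher-order searches among the SNPs
#' harvested from the two-way per-fold selections; applies the final
#' CVC/p-value significance filter and writes the results, core-SNP and QC
#' TSVs plus a run log to `out_dir`.
#'
#' @param config A configuration list ([pipeline_config()]) or the path of a
#'   YAML file with the same keys.
#' @return Invisibly, a list with `results` (all retained candidates),
#'   `significant`, `core_snps`, `qc_report`, `files`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    config <- do.call(pipeline_config, yaml::read_yaml(config))
  }
  cfg <- do.call(pipeline_config, config[!vapply(config, is.null, TRUE)])
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  say <- function(...) {
    msg <- paste0(...)
    message("gmdr: ", msg)
    log_lines <<- c(log_lines, msg)
  }

  # ---- load ----
  if (!is.null(cfg$ped)) {
    raw <- read_plink_text(cfg$ped, cfg$map)
    bundle <- validate_dataset(raw$genotypes, raw$phenotype, quiet = TRUE)
  } else if (!is.null(cfg$geno_tsv)) {
    bundle <- read_matrix_tsv(cfg$geno_tsv, cfg$pheno_tsv, cfg$covar_tsv,
                              trait_kind = cfg$trait_kind)
  } else {
    stop("pipeline config must name either ped/map or geno_tsv input")
  }
  ord_sub <- order(bundle$genotypes$subject_ids)
  bundle <- structure(list(
    genotypes = subset_genotypes(bundle$genotypes, subjects = ord_sub),
    phenotype = phenotype(bundle$phenotype$values[ord_sub], bundle$phenotype$trait_kind),
    covariates = covariate_matrix(bundle$covariates$values[ord_sub, , drop = FALSE],
                                  bundle$covariates$names),
    n_removed = bundle$n_removed
  ), class = "gmdr_data")
  n <- length(bundle$genotypes$subject_ids)
  say("loaded ", n, " subjects x ", nrow(bundle$genotypes$snps), " SNPs (",
      bundle$n_removed, " subjects listwise-deleted)")

  # ---- QC ----
  control_mask <- if (bundle$phenotype$trait_kind == "binary") {
    bundle$phenotype$values == 0
  } else {
    NULL
  }
  qc <- apply_qc(bundle$genotypes, control_mask,
                 max_missing = cfg$max_missing, min_maf = cfg$min_maf,
                 min_hwe_p = cfg$min_hwe_p, hwe_method = cfg$hwe_method)
  for (r in c("missingness", "maf", "hwe")) {
    say("QC removed ", sum(qc$report$reason == r), " SNP(s) for ", r)
  }
  say(sum(qc$report$kept), " SNPs remained after QC")
  bundle$genotypes <- qc$genotypes

  # ---- scores ----
  scores <- if (!is.null(cfg$scores_file)) {
    load_scores(cfg$scores_file, bundle$genotypes$subject_ids)
  } else {
    compute_scores(bundle$phenotype, bundle$covariates, family = cfg$family)
  }
  say("scores: ", scores$origin, ", mean ", format(mean(scores$values), digits = 3))

  # ---- folds, shared across orders for comparability ----
  labels <- if (bundle$phenotype$trait_kind == "binary") bundle$phenotype$values else NULL
  folds <- make_folds(n, K = cfg$K, seed = cfg$seed, stratify_labels = labels)

  # ---- searches ----
  orders <- sort(unique(as.integer(cfg$orders)))
  fits <- list()
  fit2 <- gmdr(bundle, scores = scores, order = 2, top_n = cfg$top_n_per_fold,
               candidate_cvc_gt = cfg$candidate_cvc_gt,
               min_pair_distance_bp = cfg$min_pair_distance_bp,
               n_perm = if (2 %in% orders) cfg$n_perm else 0,
               seed = cfg$seed, folds = folds)
  say("order 2: ", nrow(fit2$results), " candidate model(s) retained")
  if (2 %in% orders) fits[["2"]] <- fit2
  high_orders <- orders[orders > 2]
  if (length(high_orders) > 0) {
    subset <- harvest_top_snps(fit2)
    say("harvested ", length(subset), " unique SNP(s) from the two-way per-fold selections")
    for (k in high_orders) {
      fit_k <- gmdr(bundle, scores = scores, order = k, top_n = cfg$top_n_per_fold,
                    candidate_cvc_gt = cfg$candidate_cvc_gt,
                    min_pair_distance_bp = cfg$min_pair_distance_bp,
                    snp_subset = subset, n_perm = cfg$n_perm,
                    seed = cfg$seed, folds = folds)
      say("order ", k, ": ", nrow(fit_k$results), " candidate model(s) retained")
      fits[[as.character(k)]] <- fit_k
    }
  }

  drop_cols <- c("combination", "training_accuracy", "testing_accuracy_by_fold", "cell_model")
  all_results <- do.call(rbind, lapply(fits, function(f) {
    f$results[, setdiff(names(f$results), drop_cols), drop = FALSE]
  }))
  if (is.null(all_results)) all_results <- empty_results_df()[, !(names(empty_results_df()) %in% drop_cols)]
  rownames(all_results) <- NULL

  # ---- significance filter and core SNPs ----
  significant <- significance_filter(all_results, cfg$final_cvc_min, cfg$final_p_max)
  say(nrow(significant), " significant model(s) at CVC >= ", cfg$final_cvc_min,
      " and p <= ", format(cfg$final_p_max))
  core <- detect_core_snps(significant, core_min_models = cfg$core_min_models)
  say(nrow(core), " core SNP(s) (>= ", cfg$core_min_models, " supporting models)")

  # ---- outputs ----
  files <- list(
    results = file.path(cfg$out_dir, "results.tsv"),
    significant = file.path(cfg$out_dir, "significant.tsv"),
    core_snps = file.path(cfg$out_dir, "core_snps.tsv"),
    qc_report = file.path(cfg$out_dir, "qc_report.tsv"),
    log = file.path(cfg$out_dir, "run_log.txt")
  )
  write_results_tsv(all_results, files$results, K = cfg$K, core_snp_ids = core$snp_id)
  write_results_tsv(significant, files$significant, K = cfg$K, core_snp_ids = core$snp_id)
  write_core_snps_tsv(core, files$core_snps)
  write_qc_report(qc$report, files$qc_report)
  writeLines(c(paste0("gmdr pipeline, seed ", cfg$seed, ", K ", cfg$K,
                      ", orders ", paste(orders, collapse = ","),
                      ", n_perm ", format(cfg$n_perm)), log_lines), files$log)

  invisible(list(results = all_results, significant = significant,
                 core_snps = core, qc_report = qc$report, files = files,
                 fits = fits))
}
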