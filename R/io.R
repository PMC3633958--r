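# File input/output: PLINK text (.ped/.map) and a simple matrix-TSV dialect.
#
# PLINK allele pairs are converted to minor-allele counts by counting the
# dataset-wide minor allele per SNP (ties broken to the alphabetically first
# allele); "0" alleles mark missing calls.  The matrix-TSV dialect stores the
# already-coded 0/1/2 matrix with two metadata rows (#chrom, #pos) under the
# SNP-id header.

#' Read PLINK text files (.ped/.map)
#'
#' .map columns: chromosome, snp_id, [genetic distance,] position_bp.
#' .ped columns: FID IID PAT MAT SEX PHENOTYPE then two allele characters per
#' SNP ("0" = missing).  The phenotype column uses PLINK's 1/2 coding
#' (1 = control, 2 = case), mapped to 0/1; 0, -9 or "NA" become missing.
#'
#' @param ped_path,map_path File paths.
#' @return List with `genotypes` ([genotype_matrix()]; allele labels kept in
#'   the SNP table columns `a1` = minor, `a2` = major) and `phenotype`
#'   (binary [phenotype()]).
#' @export
read_plink_text <- function(ped_path, map_path) {
  map <- utils::read.table(map_path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (!ncol(map) %in% c(3, 4)) stop(".map must have 3 or 4 columns, found ", ncol(map))
  pos_col <- ncol(map)
  snps <- snp_info(map[[2]], map[[1]], as.integer(map[[pos_col]]))
  m <- nrow(snps)

  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "[ \t]+")
  expect <- 6 + 2 * m
  bad <- which(lengths(toks) != expect)
  if (length(bad)) {
    stop(".ped line ", bad[1], " has ", lengths(toks)[bad[1]],
         " fields, expected ", expect, " (6 + 2 x ", m, " SNPs)")
  }
  ped <- do.call(rbind, toks)
  subject_ids <- ped[, 2]
  ph_raw <- ped[, 6]
  ph <- suppressWarnings(as.numeric(ph_raw))
  y <- ifelse(is.na(ph) | ph %in% c(0, -9), NA_real_,
              ifelse(ph == 2, 1, ifelse(ph == 1, 0, NA)))
  if (any(!is.na(ph) & !ph %in% c(-9, 0, 1, 2))) {
    stop("unknown phenotype code in .ped: ",
         ph_raw[which(!ph %in% c(-9, 0, 1, 2))[1]])
  }

  n <- length(subject_ids)
  vals <- matrix(NA_integer_, n, m)
  a1 <- a2 <- character(m)
  for (j in seq_len(m)) {
    al <- cbind(ped[, 6 + 2 * j - 1], ped[, 6 + 2 * j])
    half_missing <- xor(al[, 1] == "0", al[, 2] == "0")
    if (any(half_missing)) {
      stop("half-missing genotype at .ped line ", which(half_missing)[1],
           ", SNP ", snps$snp_id[j])
    }
    obs <- al[al != "0"]
    alleles <- sort(unique(obs))
    if (length(alleles) > 2) {
      stop("SNP ", snps$snp_id[j], " has ", length(alleles), " alleles: ",
           paste(alleles, collapse = ","))
    }
    if (length(alleles) == 0) {
      a1[j] <- "A"; a2[j] <- "B"
      next
    }
    if (length(alleles) == 1) {
      # monomorphic: the observed allele is the major one, minor count 0
      a2[j] <- alleles[1]
      a1[j] <- if (alleles[1] == "A") "B" else "A"
      vals[al[, 1] != "0", j] <- 0L
      next
    }
    cnt <- c(sum(obs == alleles[1]), sum(obs == alleles[2]))
    minor <- if (cnt[1] < cnt[2]) alleles[1] else if (cnt[2] < cnt[1]) alleles[2] else alleles[1]
    major <- setdiff(alleles, minor)
    a1[j] <- minor; a2[j] <- major
    called <- al[, 1] != "0"
    vals[called, j] <- (al[called, 1] == minor) + (al[called, 2] == minor)
  }
  snps$a1 <- a1
  snps$a2 <- a2
  list(
    genotypes = genotype_matrix(vals, snps, subject_ids),
    phenotype = phenotype(y, "binary")
  )
}

#' Write PLINK text files from a genotype matrix
#'
#' Inverse of [read_plink_text()]: genotype code g becomes g copies of the
#' minor allele (SNP table columns `a1`/`a2` when present, otherwise
#' "A"/"B"); `NA` becomes "0 0".
#'
#' @param genotypes A [genotype_matrix()].
#' @param phenotype Optional binary [phenotype()] (written in 1/2 coding;
#'   `NA` as -9).
#' @param ped_path,map_path Output paths.
#' @export
write_plink_text <- function(genotypes, phenotype = NULL, ped_path, map_path) {
  snps <- genotypes$snps
  a1 <- if ("a1" %in% names(snps)) snps$a1 else rep("A", nrow(snps))
  a2 <- if ("a2" %in% names(snps)) snps$a2 else rep("B", nrow(snps))
  utils::write.table(
    data.frame(snps$chromosome, snps$snp_id, 0, snps$position_bp),
    map_path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  v <- genotypes$values
  n <- nrow(v)
  y <- if (is.null(phenotype)) rep(-9, n) else ifelse(is.na(phenotype$values), -9, phenotype$values + 1)
  lines <- vapply(seq_len(n), function(i) {
    g <- v[i, ]
    al1 <- ifelse(is.na(g), "0", ifelse(g >= 1, a1, a2))
    al2 <- ifelse(is.na(g), "0", ifelse(g == 2, a1, a2))
    paste(c(genotypes$subject_ids[i], genotypes$subject_ids[i], "0", "0", "0",
            y[i], rbind(al1, al2)), collapse = " ")
  }, "")
  writeLines(lines, ped_path)
  invisible(ped_path)
}

#' Read the matrix-TSV dialect
#'
#' Genotype file layout: header line `subject_id<TAB>snp ids...`, a `#chrom`
#' metadata row, a `#pos` metadata row, then one row per subject with values
#' in {0,1,2,NA}.  Phenotype and covariate files are TSVs keyed by
#' `subject_id` (exact-match joins); subjects missing from the covariate file
#' are listwise-deleted by [validate_dataset()].
#'
#' @param geno_path Genotype TSV path.
#' @param pheno_path Optional phenotype TSV (`subject_id`, `phenotype`).
#' @param covar_path Optional covariate TSV (`subject_id`, one column per
#'   covariate).
#' @param trait_kind Trait kind for the phenotype (default `"binary"`).
#' @return A validated `gmdr_data` bundle, or just the [genotype_matrix()]
#'   when no phenotype file is given.
#' @export
read_matrix_tsv <- function(geno_path, pheno_path = NULL, covar_path = NULL,
                            trait_kind = "binary") {
  lines <- readLines(geno_path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (header[1] != "subject_id") stop("genotype TSV must start with a subject_id header")
  snp_ids <- header[-1]
  meta <- strsplit(lines[2:3], "\t", fixed = TRUE)
  if (meta[[1]][1] != "#chrom" || meta[[2]][1] != "#pos") {
    stop("genotype TSV needs '#chrom' and '#pos' metadata rows after the header")
  }
  snps <- snp_info(snp_ids, meta[[1]][-1], as.integer(meta[[2]][-1]))
  body <- strsplit(lines[-(1:3)], "\t", fixed = TRUE)
  if (any(lengths(body) != length(header))) {
    stop("ragged genotype row at line ", which(lengths(body) != length(header))[1] + 3)
  }
  tab <- do.call(rbind, body)
  subject_ids <- tab[, 1]
  raw <- tab[, -1, drop = FALSE]
  vals <- suppressWarnings(matrix(as.integer(raw), nrow(raw), ncol(raw)))
  bad <- !is.na(vals) & !(vals %in% 0:2) | (is.na(vals) & raw != "NA")
  if (any(bad)) {
    ix <- which(bad, arr.ind = TRUE)[1, ]
    stop("invalid genotype value '", raw[ix[1], ix[2]], "' at subject ",
         subject_ids[ix[1]], ", SNP ", snp_ids[ix[2]])
  }
  geno <- genotype_matrix(vals, snps, subject_ids)
  if (is.null(pheno_path)) return(geno)

  ph <- utils::read.table(pheno_path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  miss <- setdiff(subject_ids, ph$subject_id)
  if (length(miss) > 0) {
    stop("phenotype file is missing subject id(s): ",
         paste(utils::head(miss, 10), collapse = ", "))
  }
  y <- ph[[2]][match(subject_ids, ph$subject_id)]
  cov <- NULL
  if (!is.null(covar_path)) {
    cv <- utils::read.table(covar_path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    cmat <- as.matrix(cv[match(subject_ids, cv$subject_id), -1, drop = FALSE])
    cov <- covariate_matrix(cmat, names(cv)[-1])
  }
  validate_dataset(geno, phenotype(y, trait_kind), cov, quiet = TRUE)
}

#' Write the matrix-TSV dialect
#'
#' @param genotypes A [genotype_matrix()].
#' @param geno_path Output path.
#' @export
write_matrix_tsv <- function(genotypes, geno_path) {
  v <- genotypes$values
  lines <- c(
    paste(c("subject_id", genotypes$snps$snp_id), collapse = "\t"),
    paste(c("#chrom", genotypes$snps$chromosome), collapse = "\t"),
    paste(c("#pos", genotypes$snps$position_bp), collapse = "\t"),
    vapply(seq_len(nrow(v)), function(i) {
      paste(c(genotypes$subject_ids[i], ifelse(is.na(v[i, ]), "NA", v[i, ])),
            collapse = "\t")
    }, "")
  )
  writeLines(lines, geno_path)
  invisible(geno_path)
}
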