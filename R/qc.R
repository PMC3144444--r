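#' Quality-control thresholds for SNP and phenotype editing
#'
#' Defaults follow common practice for commercial SNP panels: retain SNP
#' with minor allele frequency above 0.025, missing-call proportion below
#' 0.05 and a parent-offspring mismatch (opposing-homozygote) rate below
#' 0.05; exclude phenotype records deviating from their within-hatch
#' generation mean by more than three standard deviations.  All genotype
#' thresholds are strict inequalities.
#'
#' @param maf_min Minimum minor allele frequency (exclusive).
#' @param missing_max Maximum proportion of missing genotypes (exclusive).
#' @param mendel_mismatch_max Maximum opposing-homozygote rate among
#'   genotyped parent-offspring pairs (exclusive).
#' @param outlier_sd Phenotype outlier cut in within-group standard
#'   deviations.
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(maf_min = 0.025, missing_max = 0.05,
                          mendel_mismatch_max = 0.05, outlier_sd = 3) {
  stopifnot(maf_min >= 0, maf_min <= 1, missing_max >= 0, missing_max <= 1,
            mendel_mismatch_max >= 0, mendel_mismatch_max <= 1,
            outlier_sd > 0)
  structure(list(maf_min = maf_min, missing_max = missing_max,
                 mendel_mismatch_max = mendel_mismatch_max,
                 outlier_sd = outlier_sd),
            class = "qc_thresholds")
}

#' Apply SNP quality-control filters
#'
#' Retains SNP with minor allele frequency strictly above
#' `thresholds$maf_min`, missing proportion strictly below
#' `thresholds$missing_max`, and parent-offspring opposing-homozygote rate
#' strictly below `thresholds$mendel_mismatch_max`.  The mismatch rate for a
#' SNP is the number of genotyped parent-offspring pairs with opposing
#' homozygotes (0 vs 2) divided by the number of pairs with both calls
#' non-missing; SNP with no informative pair pass that rule.  Allele
#' frequencies are computed over all genotyped individuals after excluding
#' missing cells.
#'
#' @param genotypes Allele-count matrix (0/1/2/`NA`), rows = individuals.
#' @param pedigree Pedigree data.frame used to enumerate parent-offspring
#'   pairs among genotyped individuals.
#' @param thresholds A [qc_thresholds()] object.
#' @return list with `genotypes` (filtered matrix, cells untouched) and
#'   `report` (data.frame `snp`, `maf`, `missing_rate`, `mendel_rate`,
#'   `pass_maf`, `pass_missing`, `pass_mendel`, `pass`); the report carries
#'   attribute `mendel_skipped = TRUE` when no genotyped pair exists.
#' @export
apply_snp_qc <- function(genotypes, pedigree, thresholds = qc_thresholds()) {
  if (is.null(dim(genotypes)) || nrow(genotypes) == 0 || ncol(genotypes) == 0)
    stop("empty genotype matrix")
  ok <- genotypes %in% c(0, 1, 2) | is.na(genotypes)
  if (!all(ok)) stop("genotype cells must be 0, 1, 2 or NA")

  p <- snp_freqs(genotypes)
  maf <- pmin(p, 1 - p)
  miss <- colMeans(is.na(genotypes))

  pairs <- mendel_pairs(pedigree, rownames(genotypes))
  skipped <- nrow(pairs) == 0
  if (skipped) {
    warning("no genotyped parent-offspring pairs; Mendelian-mismatch rule skipped")
    mendel <- rep(NA_real_, ncol(genotypes))
  } else {
    gp <- genotypes[pairs$parent, , drop = FALSE]
    go <- genotypes[pairs$offspring, , drop = FALSE]
    opposing <- (gp == 0 & go == 2) | (gp == 2 & go == 0)
    informative <- !is.na(gp) & !is.na(go)
    n_inf <- colSums(informative)
    mendel <- ifelse(n_inf > 0, colSums(opposing, na.rm = TRUE) / n_inf, NA_real_)
  }

  pass_maf <- maf > thresholds$maf_min
  pass_missing <- miss < thresholds$missing_max
  pass_mendel <- is.na(mendel) | mendel < thresholds$mendel_mismatch_max
  pass <- pass_maf & pass_missing & pass_mendel

  report <- data.frame(
    snp = colnames(genotypes), maf = maf, missing_rate = miss,
    mendel_rate = mendel, pass_maf = pass_maf, pass_missing = pass_missing,
    pass_mendel = pass_mendel, pass = pass,
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(report, "mendel_skipped") <- skipped
  out <- genotypes[, pass, drop = FALSE]
  map <- attr(genotypes, "map")
  if (!is.null(map)) attr(out, "map") <- map[pass, , drop = FALSE]
  list(genotypes = out, report = report)
}

mendel_pairs <- function(pedigree, genotyped_ids) {
  gset <- as.character(genotyped_ids)
  make <- function(parent_col) {
    off <- as.character(pedigree$id)
    par <- as.character(pedigree[[parent_col]])
    keep <- !is.na(pedigree[[parent_col]]) & off %in% gset & par %in% gset
    data.frame(parent = par[keep], offspring = off[keep],
               stringsAsFactors = FALSE)
  }
  rbind(make("sire"), make("dam"))
}

#' Remove phenotype outliers within hatch-by-generation groups
#'
#' Excludes records whose value deviates from their within-hatch (nested in
#' generation) mean by more than `outlier_sd` standard deviations.  Groups
#' with fewer than two records, or with zero standard deviation, are left
#' untouched (with a warning for undersized groups).
#'
#' @param phenotypes data.frame with columns `value`, `hatch`, `generation`.
#' @param outlier_sd Cut in standard deviations (default 3).
#' @return list with `phenotypes` (retained records) and `removed` (the
#'   excluded records).
#' @export
filter_outlier_phenotypes <- function(phenotypes, outlier_sd = 3) {
  grp <- interaction(phenotypes$generation, phenotypes$hatch, drop = TRUE)
  mu <- ave(phenotypes$value, grp, FUN = mean)
  s <- ave(phenotypes$value, grp, FUN = function(v)
    if (length(v) < 2) 0 else sd(v))
  n <- ave(phenotypes$value, grp, FUN = length)
  if (any(n < 2))
    warning("groups with fewer than 2 records pass untouched: ",
            paste(unique(grp[n < 2]), collapse = ", "))
  out <- s > 0 & abs(phenotypes$value - mu) > outlier_sd * s
  list(phenotypes = phenotypes[!out, , drop = FALSE],
       removed = phenotypes[out, , drop = FALSE])
}

#' Mean-impute missing genotype calls
#'
#' Replaces a missing call at SNP *k* by `2 p_k`, the expected allele count
#' at the supplied reference frequency.  Observed calls are never altered.
#'
#' @param genotypes Allele-count matrix with `NA` for missing.
#' @param freqs Per-SNP frequencies; default computed from `genotypes`
#'   (observed calls over all genotyped individuals).
#' @return The matrix with no missing cells.
#' @export
impute_missing <- function(genotypes, freqs = snp_freqs(genotypes)) {
  all_missing <- colSums(!is.na(genotypes)) == 0
  if (any(all_missing))
    stop("SNP with all calls missing (should have been removed by QC): ",
         paste(colnames(genotypes)[all_missing], collapse = ", "))
  idx <- which(is.na(genotypes), arr.ind = TRUE)
  if (nrow(idx)) genotypes[idx] <- 2 * freqs[idx[, 2]]
  genotypes
}
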