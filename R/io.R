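#' Read and write the package's tabular formats
#'
#' Plain-text interchange: pedigree and phenotype tables as CSV (unknown
#' parents written as 0), genotypes either as a TSV dosage matrix
#' (rows = individuals, columns = SNP, cells 0/1/2/NA) or as a minimal
#' VCF with `GT` calls and one sample per individual.
#'
#' @param pedigree,phenotypes,genotypes Objects as produced by
#'   [simulate_population()].
#' @param file Path to read from / write to.
#' @name gs_io
NULL

#' @rdname gs_io
#' @export
write_pedigree <- function(pedigree, file) {
  out <- pedigree[, c("id", "sire", "dam", "generation", "sex", "hatch")]
  out$sire[is.na(out$sire)] <- 0
  out$dam[is.na(out$dam)] <- 0
  write.csv(out, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname gs_io
#' @export
read_pedigree <- function(file) {
  ped <- read.csv(file, stringsAsFactors = FALSE)
  ped$sire[ped$sire == 0] <- NA
  ped$dam[ped$dam == 0] <- NA
  ped
}

#' @rdname gs_io
#' @export
write_phenotypes <- function(phenotypes, file) {
  write.csv(phenotypes[, c("id", "trait", "value", "hatch", "generation")],
            file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname gs_io
#' @export
read_phenotypes <- function(file) {
  read.csv(file, stringsAsFactors = FALSE)
}

#' @rdname gs_io
#' @export
write_genotypes_tsv <- function(genotypes, file) {
  df <- data.frame(id = rownames(genotypes), genotypes, check.names = FALSE)
  write.table(df, file, sep = "\t", row.names = FALSE, quote = FALSE,
              na = "NA")
  invisible(file)
}

#' @rdname gs_io
#' @export
read_genotypes_tsv <- function(file) {
  df <- read.delim(file, check.names = FALSE, stringsAsFactors = FALSE)
  g <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(g) <- "double"
  rownames(g) <- as.character(df$id)
  g
}

#' @rdname gs_io
#' @param map SNP map (`snp`, `chr`, `pos` in Morgans); defaults to the
#'   matrix's `map` attribute.  Positions are written in base pairs at
#'   1 Mb per cM.
#' @export
write_genotypes_vcf <- function(genotypes, file, map = attr(genotypes, "map")) {
  if (is.null(map)) stop("a SNP map is required to write VCF")
  map <- map[match(colnames(genotypes), map$snp), ]
  gt <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  lines <- c(
    "##fileformat=VCFv4.2",
    "##source=gsPersist",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(genotypes)), collapse = "\t")
  )
  body <- vapply(seq_len(ncol(genotypes)), function(k) {
    calls <- genotypes[, k]
    calls <- ifelse(is.na(calls), "./.", gt[as.character(calls)])
    paste(c(as.character(map$chr[k]),
            as.character(round(map$pos[k] * 1e8) + 1L), map$snp[k],
            "A", "B", ".", "PASS", ".", "GT", calls), collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), file)
  invisible(file)
}

#' @rdname gs_io
#' @export
read_genotypes_vcf <- function(file) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(file, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dose <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  dose[gt %in% c("0/0", "0|0")] <- 0
  dose[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1
  dose[gt %in% c("1/1", "1|1")] <- 2
  t(dose)
}
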