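#' Pedigree BLUP (animal model)
#'
#' Solves Henderson's mixed-model equations for the single-trait animal
#' model with hatch-within-generation fixed effects and the sparse pedigree
#' inverse `A^-1 lambda`, `lambda = sigma2_e / sigma2_a`.  Breeding values
#' are returned for every pedigree member, including unphenotyped
#' validation animals (whose EBV are driven purely by relationships; an
#' animal unrelated to all records gets EBV 0).
#'
#' @param phenotypes Training records: data.frame `id`, `value`, `hatch`,
#'   `generation`.  Every id must appear in the pedigree.
#' @param pedigree Pedigree data.frame (`id`, `sire`, `dam`, ...).
#' @param vc A [varcomp()]; `sigma2_a` must be positive.
#' @return Object of class `gs_fit`: `method`, `ebv` (named, all pedigree
#'   members), `fixed_solutions` (named by hatch level), `vc`.
#' @export
fit_pblup <- function(phenotypes, pedigree, vc) {
  if (vc$sigma2_a <= 0)
    stop("sigma2_a = 0: lambda = sigma2_e / sigma2_a undefined")
  ids <- as.character(pedigree$id)
  rid <- as.character(phenotypes$id)
  if (!all(rid %in% ids)) stop("phenotyped ids missing from pedigree")
  lambda <- vc$sigma2_e / vc$sigma2_a

  Ainv <- build_A_inverse(pedigree)
  X <- hatch_design(phenotypes)
  nr <- nrow(phenotypes)
  Z <- Matrix::sparseMatrix(i = seq_len(nr), j = match(rid, ids),
                            x = 1, dims = c(nr, length(ids)))
  y <- phenotypes$value
  Xs <- Matrix::Matrix(X, sparse = TRUE)
  C <- rbind(
    cbind(Matrix::crossprod(Xs), Matrix::crossprod(Xs, Z)),
    cbind(Matrix::crossprod(Z, Xs), Matrix::crossprod(Z) + lambda * Ainv)
  )
  rhs <- c(as.vector(Matrix::crossprod(Xs, y)),
           as.vector(Matrix::crossprod(Z, y)))
  sol <- as.vector(Matrix::solve(C, rhs))
  p <- ncol(X)
  structure(list(
    method = "PBLUP",
    ebv = setNames(sol[(p + 1):(p + length(ids))], ids),
    fixed_solutions = setNames(sol[seq_len(p)], colnames(X)),
    vc = vc
  ), class = "gs_fit")
}

#' @export
print.gs_fit <- function(x, ...) {
  cat(sprintf("%s fit: %d breeding values, %d fixed level(s)\n",
              x$method, length(x$ebv), length(x$fixed_solutions)))
  invisible(x)
}

#' Genomic BLUP as a reduced animal model
#'
#' Breeding values are fitted only for genotyped animals, with covariance
#' `sigma2_a G` (VanRaden method 1).  A record on a genotyped animal enters
#' directly; a record on a non-genotyped individual whose sire and dam are
#' both genotyped is linked to the mean of its parents' breeding values,
#' with its residual variance inflated by the Mendelian-sampling term
#' `0.5 sigma2_a` (parents assumed non-inbred).  Records on individuals
#' that are neither genotyped nor have two genotyped parents are dropped
#' with a warning.
#'
#' @param phenotypes Training records (`id`, `value`, `hatch`,
#'   `generation`).
#' @param genotypes Allele-count matrix for all genotyped animals
#'   (training and validation); missing cells are mean-imputed at `freqs`.
#' @param pedigree Pedigree used to resolve parents of non-genotyped
#'   records.
#' @param vc A [varcomp()].
#' @param freqs Centering frequencies; default pooled over all genotyped
#'   animals (the full data set).
#' @param blend Proportion of the identity blended into G before inversion
#'   (`G* = (1 - blend) G + blend I`); stabilizes the inverse when G is
#'   singular.  Set to 0 for exact-equivalence comparisons on
#'   well-conditioned instances.
#' @return `gs_fit` with `method = "GBLUP"`, `ebv` for every genotyped
#'   animal, `fixed_solutions`, `vc`, and `dropped` (ids of unusable
#'   records).
#' @export
fit_gblup <- function(phenotypes, genotypes, pedigree, vc,
                      freqs = NULL, blend = 0.01) {
  if (vc$sigma2_a <= 0) stop("sigma2_a must be positive for GBLUP")
  if (is.null(freqs)) freqs <- snp_freqs(genotypes)
  if (anyNA(genotypes)) genotypes <- impute_missing(genotypes, freqs)
  gids <- rownames(genotypes)
  ped <- pedigree
  rownames(ped) <- as.character(ped$id)

  rid <- as.character(phenotypes$id)
  sire <- as.character(ped[rid, "sire"])
  dam <- as.character(ped[rid, "dam"])
  direct <- rid %in% gids
  linked <- !direct & !is.na(sire) & !is.na(dam) & sire %in% gids & dam %in% gids
  drop_ids <- rid[!direct & !linked]
  if (length(drop_ids))
    warning(length(drop_ids),
            " record(s) dropped: not genotyped and without two genotyped parents")
  keep <- direct | linked
  phe <- phenotypes[keep, , drop = FALSE]
  rid <- rid[keep]; sire <- sire[keep]; dam <- dam[keep]; direct <- direct[keep]

  q <- length(gids)
  nr <- nrow(phe)
  i_idx <- c(which(direct), which(!direct), which(!direct))
  j_idx <- c(match(rid[direct], gids),
             match(sire[!direct], gids), match(dam[!direct], gids))
  x_val <- c(rep(1, sum(direct)), rep(0.5, 2 * sum(!direct)))
  Z <- Matrix::sparseMatrix(i = i_idx, j = j_idx, x = x_val, dims = c(nr, q))

  ## relative residual variances: 1, or 1 + Mendelian sampling / sigma2_e
  w <- ifelse(direct, 1, 1 + 0.5 * vc$sigma2_a / vc$sigma2_e)
  D <- Matrix::Diagonal(x = 1 / w)

  G <- build_G(genotypes, freqs)
  Gstar <- (1 - blend) * G + blend * diag(q)
  Ginv <- solve(Gstar)
  lambda <- vc$sigma2_e / vc$sigma2_a

  X <- hatch_design(phe)
  y <- phe$value
  XtDX <- crossprod(X, as.matrix(D %*% X))
  XtDZ <- as.matrix(Matrix::crossprod(Matrix::Matrix(X, sparse = TRUE), D %*% Z))
  ZtDZ <- as.matrix(Matrix::crossprod(Z, D %*% Z))
  C <- rbind(cbind(XtDX, XtDZ),
             cbind(t(XtDZ), ZtDZ + lambda * Ginv))
  rhs <- c(crossprod(X, y / w), as.vector(Matrix::crossprod(Z, y / w)))
  sol <- solve(C, rhs)
  p <- ncol(X)
  structure(list(
    method = "GBLUP",
    ebv = setNames(sol[(p + 1):(p + q)], gids),
    fixed_solutions = setNames(sol[seq_len(p)], colnames(X)),
    vc = vc, dropped = drop_ids
  ), class = "gs_fit")
}

#' Pre-correct phenotypes for fixed-effect solutions
#'
#' Subtracts the fitted hatch-within-generation solution of each record's
#' level, as preparation for marker-effect models that carry no fixed
#' effects beyond an intercept.
#'
#' @param phenotypes data.frame with `value` and `hatch` columns.
#' @param fit A `gs_fit` whose `fixed_solutions` cover every hatch level
#'   present; an unseen level is an error.
#' @return The phenotype table with `value` replaced by the corrected
#'   value.
#' @export
precorrect_phenotypes <- function(phenotypes, fit) {
  lev <- as.character(phenotypes$hatch)
  unseen <- setdiff(lev, names(fit$fixed_solutions))
  if (length(unseen))
    stop("no fixed-effect solution for hatch level(s): ",
         paste(unique(unseen), collapse = ", "))
  phenotypes$value <- phenotypes$value - fit$fixed_solutions[lev]
  phenotypes
}

#' Full-sib family means of non-genotyped progeny
#'
#' Averages pre-corrected records of non-genotyped progeny whose sire and
#' dam are both genotyped, one record per full-sib family.  The family size
#' `n` supports the residual weighting
#' `var(mean) = (0.5 sigma2_a + sigma2_e) / n`: each sib carries its own
#' independent Mendelian-sampling deviation (variance `0.5 sigma2_a` for
#' full sibs of non-inbred parents) and its own residual, and both
#' average over the `n` records.
#'
#' @param corrected Pre-corrected phenotype table (see
#'   [precorrect_phenotypes()]).
#' @param pedigree Pedigree resolving each record's parents.
#' @param genotyped Character vector of genotyped ids.
#' @return data.frame `sire`, `dam`, `mean`, `n`.
#' @export
family_means <- function(corrected, pedigree, genotyped) {
  ped <- pedigree
  rownames(ped) <- as.character(ped$id)
  rid <- as.character(corrected$id)
  sire <- as.character(ped[rid, "sire"])
  dam <- as.character(ped[rid, "dam"])
  use <- !(rid %in% genotyped) & !is.na(sire) & !is.na(dam) &
    sire %in% genotyped & dam %in% genotyped
  if (!any(use))
    return(data.frame(sire = character(0), dam = character(0),
                      mean = numeric(0), n = integer(0),
                      stringsAsFactors = FALSE))
  key <- paste(sire[use], dam[use], sep = ":")
  mu <- tapply(corrected$value[use], key, mean)
  n <- tapply(corrected$value[use], key, length)
  parts <- strsplit(names(mu), ":", fixed = TRUE)
  data.frame(sire = vapply(parts, `[`, "", 1),
             dam = vapply(parts, `[`, "", 2),
             mean = as.vector(mu), n = as.integer(n),
             row.names = NULL, stringsAsFactors = FALSE)
}
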