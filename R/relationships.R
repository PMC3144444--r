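#' Numerator relationship matrix by the tabular method
#'
#' Builds the pedigree (expected additive) relationship matrix A with the
#' tabular recursion: with individuals ordered parents-before-offspring,
#' `a_ij = 0.5 (a_j,sire(i) + a_j,dam(i))` for j preceding i and
#' `a_ii = 1 + 0.5 a_sire(i),dam(i)`.  The diagonal is one plus the
#' inbreeding coefficient; the relationship between an outbred ancestor and
#' a direct-line descendant (unrelated mates) halves at every meiosis.
#'
#' @param pedigree data.frame `id`, `sire`, `dam` (NA or 0 = unknown);
#'   optionally `generation` used for ordering.  Must be acyclic.
#' @return Dense symmetric matrix with ids as dimnames and attribute
#'   `kind = "pedigree"`.
#' @examples
#' ped <- data.frame(id = 1:3, sire = c(NA, 1, 2), dam = c(NA, NA, NA))
#' build_A(ped)[1, 3]  # grandparent-grandchild: 0.25
#' @export
build_A <- function(pedigree) {
  ped <- order_pedigree(pedigree)
  n <- nrow(ped)
  s <- ped$sire_row
  d <- ped$dam_row
  A <- matrix(0, n, n, dimnames = list(as.character(ped$id),
                                       as.character(ped$id)))
  for (i in seq_len(n)) {
    si <- s[i]; di <- d[i]
    if (i > 1) {
      j <- seq_len(i - 1L)
      row <- numeric(i - 1L)
      if (!is.na(si)) row <- row + 0.5 * A[si, j]
      if (!is.na(di)) row <- row + 0.5 * A[di, j]
      A[i, j] <- row
      A[j, i] <- row
    }
    A[i, i] <- 1 + if (!is.na(si) && !is.na(di)) 0.5 * A[si, di] else 0
  }
  ## return in the caller's id order
  ord <- match(as.character(pedigree$id), rownames(A))
  A <- A[ord, ord, drop = FALSE]
  attr(A, "kind") <- "pedigree"
  A
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Henderson's rules with inbreeding: each individual contributes
#' `alpha_i = 1 / m_i` to its own diagonal, `-alpha_i / 2` to
#' individual-parent cells and `alpha_i / 4` to parent-parent cells, where
#' `m_i` is the Mendelian-sampling variance
#' `0.5 - 0.25 (F_s + F_d)` (both parents known),
#' `0.75 - 0.25 F_p` (one known) or 1 (founder).  Inbreeding coefficients
#' are taken from the tabular A diagonal, so the result equals the direct
#' inverse of [build_A()] up to numerical tolerance.
#'
#' @inheritParams build_A
#' @return Sparse symmetric [Matrix::Matrix] with attribute
#'   `kind = "pedigree-inverse"`, ids as dimnames, same row order as
#'   `pedigree`.
#' @export
build_A_inverse <- function(pedigree) {
  ped <- order_pedigree(pedigree)
  n <- nrow(ped)
  Fcoef <- diag(build_A(pedigree[match(ped$id, pedigree$id), ])) - 1
  ## diag above is in ped (topological) order because we re-passed it ordered
  s <- ped$sire_row
  d <- ped$dam_row
  both <- !is.na(s) & !is.na(d)
  one_s <- !is.na(s) & is.na(d)
  one_d <- is.na(s) & !is.na(d)
  m <- rep(1, n)
  m[both] <- 0.5 - 0.25 * (Fcoef[s[both]] + Fcoef[d[both]])
  m[one_s] <- 0.75 - 0.25 * Fcoef[s[one_s]]
  m[one_d] <- 0.75 - 0.25 * Fcoef[d[one_d]]
  a <- 1 / m

  i_self <- seq_len(n)
  blocks_i <- list(i_self)
  blocks_j <- list(i_self)
  blocks_x <- list(a)
  for (p in list(s, d)) {
    k <- which(!is.na(p))
    blocks_i <- c(blocks_i, list(k, p[k]))
    blocks_j <- c(blocks_j, list(p[k], k))
    blocks_x <- c(blocks_x, list(-a[k] / 2, -a[k] / 2))
    for (q in list(s, d)) {
      kk <- which(!is.na(p) & !is.na(q))
      blocks_i <- c(blocks_i, list(p[kk]))
      blocks_j <- c(blocks_j, list(q[kk]))
      blocks_x <- c(blocks_x, list(a[kk] / 4))
    }
  }
  Ainv <- Matrix::sparseMatrix(i = unlist(blocks_i), j = unlist(blocks_j),
                               x = unlist(blocks_x), dims = c(n, n),
                               dimnames = list(as.character(ped$id),
                                               as.character(ped$id)))
  ord <- match(as.character(pedigree$id), rownames(Ainv))
  Ainv <- Ainv[ord, ord, drop = FALSE]
  attr(Ainv, "kind") <- "pedigree-inverse"
  Ainv
}

#' Genomic relationship matrix (VanRaden method 1)
#'
#' `G = Z Z' / (2 sum_k p_k (1 - p_k))` with `z_ik = g_ik - 2 p_k`.  The
#' centering frequencies default to the pooled genotyped set (all
#' individuals in `genotypes`), i.e. the full data set across generations.
#'
#' @param genotypes Allele-count matrix with no missing cells (impute
#'   first), rows = genotyped individuals.
#' @param freqs Per-SNP centering/scaling frequencies.
#' @return Dense symmetric matrix with ids as dimnames and attribute
#'   `kind = "genomic"`.
#' @export
build_G <- function(genotypes, freqs = snp_freqs(genotypes)) {
  if (anyNA(genotypes)) stop("genotypes contain missing cells; impute first")
  denom <- 2 * sum(freqs * (1 - freqs))
  if (denom <= 0) stop("all SNP monomorphic at the supplied frequencies")
  Z <- sweep(genotypes, 2, 2 * freqs, "-")
  G <- tcrossprod(Z) / denom
  attr(G, "kind") <- "genomic"
  G
}

## Order a pedigree parents-before-offspring (generation if present, else a
## Kahn-style topological sort); ties broken by id.  Errors on cycles and on
## sex-inconsistent parent use when sex is available.
order_pedigree <- function(pedigree) {
  ped <- pedigree
  for (col in c("sire", "dam")) {
    v <- ped[[col]]
    v[!is.na(v) & v == 0] <- NA
    ped[[col]] <- v
  }
  n <- nrow(ped)
  id <- ped$id
  if (anyDuplicated(id)) stop("duplicate ids in pedigree")
  sr <- match(ped$sire, id)
  dr <- match(ped$dam, id)
  if (any(!is.na(ped$sire) & is.na(sr)) || any(!is.na(ped$dam) & is.na(dr)))
    stop("pedigree refers to unknown parent ids")
  ## topological order: depth = 1 + max(parent depths), NA parents resolved
  depth <- rep(NA_integer_, n)
  sr1 <- ifelse(is.na(sr), 1L, sr)  # placeholder index, masked below
  dr1 <- ifelse(is.na(dr), 1L, dr)
  repeat {
    ready <- is.na(depth) &
      (is.na(sr) | !is.na(depth[sr1])) &
      (is.na(dr) | !is.na(depth[dr1]))
    if (!any(ready)) break
    dpar <- pmax(ifelse(is.na(sr), -1L, depth[sr1]),
                 ifelse(is.na(dr), -1L, depth[dr1]))
    depth[ready] <- dpar[ready] + 1L
  }
  if (anyNA(depth)) stop("cyclic pedigree: an individual is its own ancestor")
  ord <- order(depth, id)
  out <- ped[ord, , drop = FALSE]
  out$sire_row <- match(out$sire, out$id)
  out$dam_row <- match(out$dam, out$id)
  out
}
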