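#' Variance components container
#'
#' @param sigma2_a Additive genetic variance.
#' @param sigma2_e Residual variance.
#' @return list of class `varcomp` with `sigma2_a`, `sigma2_e` and
#'   `h2 = sigma2_a / (sigma2_a + sigma2_e)`.
#' @export
varcomp <- function(sigma2_a, sigma2_e) {
  stopifnot(sigma2_a >= 0, sigma2_e >= 0, sigma2_a + sigma2_e > 0)
  structure(list(sigma2_a = sigma2_a, sigma2_e = sigma2_e,
                 h2 = sigma2_a / (sigma2_a + sigma2_e),
                 converged = NA, n_iter = NA_integer_),
            class = "varcomp")
}

#' @export
print.varcomp <- function(x, ...) {
  cat(sprintf("sigma2_a = %.6g, sigma2_e = %.6g, h2 = %.4f\n",
              x$sigma2_a, x$sigma2_e, x$h2))
  if (!is.na(x$converged))
    cat(sprintf("  EM-REML: %d iteration(s), converged: %s\n",
                x$n_iter, x$converged))
  invisible(x)
}

#' EM-REML variance components for the single-trait animal model
#'
#' Fits `y = X b + a + e` with `a ~ N(0, sigma2_a K)` and
#' `e ~ N(0, sigma2_e I)`, where `X` is the hatch-within-generation
#' incidence and `K` the relationship matrix among phenotyped individuals
#' (the animal model marginalized to the animals with records).  The EM
#' updates are computed in the eigenbasis of the fixed-effect-projected
#' relationship matrix, so each iteration is O(n) after a single
#' decomposition; the REML log-likelihood is non-decreasing over
#' iterations.
#'
#' @param phenotypes data.frame `id`, `value`, `hatch`, `generation`; one
#'   record per individual.
#' @param relmat Relationship matrix covering the phenotyped ids: a dense
#'   pedigree or genomic matrix, or a sparse pedigree inverse from
#'   [build_A_inverse()] (inverted internally).
#' @param max_iter,tol Convergence control: stop when the relative change
#'   in both components falls below `tol` (default 1e-8) or after
#'   `max_iter` (default 500) iterations; non-convergence is flagged, not
#'   an error.
#' @param init Optional starting `c(sigma2_a, sigma2_e)`; defaults to an
#'   even split of the phenotypic variance.
#' @return A [varcomp()] with convergence information and attribute
#'   `loglik` (the REML log-likelihood trace, up to an additive constant).
#' @export
em_reml <- function(phenotypes, relmat, max_iter = 500, tol = 1e-8,
                    init = NULL) {
  ids <- as.character(phenotypes$id)
  if (anyDuplicated(ids)) stop("one record per individual expected")
  kind <- attr(relmat, "kind")
  if (!is.null(kind) && grepl("inverse", kind))
    relmat <- as.matrix(Matrix::solve(relmat))
  if (!all(ids %in% rownames(relmat)))
    stop("relationship matrix does not cover all phenotyped ids")
  K <- as.matrix(relmat)[ids, ids]

  X <- hatch_design(phenotypes)
  n <- length(ids)
  p <- ncol(X)
  if (n <= p) stop("more fixed-effect levels than records")

  ## orthonormal basis of the complement of range(X)
  B <- qr.Q(qr(X), complete = TRUE)[, (p + 1):n, drop = FALSE]
  E <- eigen(crossprod(B, K %*% B), symmetric = TRUE)
  lam <- pmax(E$values, 0)
  eta <- drop(crossprod(B %*% E$vectors, phenotypes$value))
  eta2 <- eta^2

  vy <- var(phenotypes$value)
  s2a <- if (is.null(init)) vy / 2 else init[1]
  s2e <- if (is.null(init)) vy / 2 else init[2]
  if (s2a <= 0) s2a <- vy / 100
  ll <- numeric(0)
  converged <- FALSE
  it <- 0
  while (it < max_iter) {
    it <- it + 1
    v <- lam * s2a + s2e
    if (any(v <= 0)) stop("singular coefficient matrix in EM-REML")
    ll <- c(ll, -0.5 * (sum(log(v)) + sum(eta2 / v)))
    ytPKPy <- sum(lam * eta2 / v^2)
    trPK <- sum(lam / v)
    ytPPy <- sum(eta2 / v^2)
    s2a_new <- s2a + s2a^2 * (ytPKPy - trPK) / n
    s2e_new <- (s2e^2 * ytPPy + s2a * s2e * trPK) / (n - p)
    d <- max(abs(s2a_new - s2a) / max(s2a, 1e-12),
             abs(s2e_new - s2e) / max(s2e, 1e-12))
    s2a <- s2a_new
    s2e <- s2e_new
    if (d < tol) { converged <- TRUE; break }
  }
  out <- varcomp(s2a, s2e)
  out$converged <- converged
  out$n_iter <- it
  attr(out, "loglik") <- ll
  out
}

## Hatch-within-generation fixed design, cell-means coding (no intercept),
## so each column solution is directly the hatch-level effect.
hatch_design <- function(phenotypes) {
  labels <- as.character(phenotypes$hatch)
  ## hatch labels are already nested within generation in this package's
  ## simulator; fall back to generation x hatch cells when they are not
  if (anyDuplicated(unique(cbind(labels, phenotypes$generation))[, 1]))
    labels <- paste(phenotypes$generation, labels, sep = ":")
  lev <- sort(unique(labels))
  X <- matrix(0, length(labels), length(lev),
              dimnames = list(NULL, lev))
  X[cbind(seq_along(labels), match(labels, lev))] <- 1
  X
}
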