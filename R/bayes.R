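#' MCMC configuration for the marker-effect samplers
#'
#' Defaults match a production-length analysis: 160,000 iterations with the
#' first 50,000 discarded as burn-in, thinning every 10, and a
#' scaled-inverse-chi-square prior with 4.2 degrees of freedom on the
#' marker-effect variance.  For desk-scale simulation studies much shorter
#' chains are adequate; pass `chain_length`/`burn_in` accordingly.
#'
#' @param chain_length Total Gibbs iterations (default 160000).
#' @param burn_in Iterations discarded before summarizing (default 50000).
#' @param thin Keep every `thin`-th post-burn-in sample (default 10).
#' @param seed Integer seed; chains are reproducible given identical inputs
#'   and seed.
#' @param nu_a Prior degrees of freedom for the marker-effect variance
#'   (default 4.2); must exceed 2 so the prior mean is finite.
#' @param pi_fixed Optional fixed proportion of null SNP for BayesC; `NULL`
#'   (default) samples pi from its Beta full conditional under a uniform
#'   prior.
#' @param scale_override Optional prior scale for the marker-effect
#'   variance, overriding the default derived from the additive variance.
#' @param pi0 Assumed initial proportion of null SNP used to derive the
#'   BayesC-pi prior scale (default 0.95).
#' @param nu_e Prior degrees of freedom for the residual variance (default
#'   4); its scale is set so the prior mean equals the plug-in residual
#'   variance.
#' @return list of class `mcmc_config`.
#' @export
mcmc_config <- function(chain_length = 160000, burn_in = 50000, thin = 10,
                        seed = 1L, nu_a = 4.2, pi_fixed = NULL,
                        scale_override = NULL, pi0 = 0.95, nu_e = 4) {
  if (burn_in >= chain_length)
    stop("burn_in must be smaller than chain_length")
  if (nu_a <= 2) stop("nu_a must exceed 2 for a finite prior mean")
  if (!is.null(pi_fixed) && (pi_fixed < 0 || pi_fixed > 1))
    stop("pi_fixed must lie in [0, 1]")
  structure(list(chain_length = as.integer(chain_length),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 seed = as.integer(seed), nu_a = nu_a, pi_fixed = pi_fixed,
                 scale_override = scale_override, pi0 = pi0, nu_e = nu_e),
            class = "mcmc_config")
}

#' BayesA marker-effect model
#'
#' Gibbs sampler for the regression of pre-corrected records on centered
#' genotypes in which every SNP has its own effect variance with a
#' scaled-inverse-chi-square prior (`nu_a`, scale set so the prior mean of
#' each locus variance equals `sigma2_a / sum_k 2 p_k (1 - p_k)`).  All
#' SNP carry a nonzero effect at every iteration.
#'
#' @param records data.frame of corrected responses: columns `value`,
#'   optional `weight` (relative residual variance, default 1), and either
#'   `id` (a genotyped individual; its centered genotype is the design row)
#'   or `sire` + `dam` (a family mean; the design row is the mean of the
#'   parents' centered genotypes).  See [family_means()] for the weights.
#' @param genotypes Allele-count matrix covering every id referenced;
#'   missing cells are mean-imputed at `freqs`.
#' @param vc A [varcomp()] supplying the plug-in additive and residual
#'   variances.
#' @param mcmc An [mcmc_config()].
#' @param freqs Centering frequencies (default pooled from `genotypes`).
#' @return Object of class `wgr_posterior`: `alpha_mean`, `alpha_sd`,
#'   `inclusion_prob`, `pi_mean`, `sigma2_e_mean`, `gebv` (for all rows of
#'   `genotypes`), `flagged` (SNP with zero design variance, posterior mean
#'   forced 0), plus samples of pi and the variances.
#' @export
fit_bayesA <- function(records, genotypes, vc, mcmc = mcmc_config(),
                       freqs = NULL) {
  fit_wgr(records, genotypes, vc, mcmc, freqs, method = "BayesA")
}

#' BayesC-pi marker-effect model
#'
#' Gibbs sampler with a per-SNP inclusion indicator, a common effect
#' variance with scaled-inverse-chi-square prior (`nu_a = 4.2` by default),
#' and the proportion `pi` of null SNP sampled from its
#' `Beta(m - m_in + 1, m_in + 1)` full conditional under a uniform prior
#' (`m_in` = number of SNP currently in the model).  The prior scale is set
#' so the prior mean of the common variance equals
#' `sigma2_a / ((1 - pi0) sum_k 2 p_k (1 - p_k))`.
#'
#' @inheritParams fit_bayesA
#' @return `wgr_posterior`; `pi_mean` is the posterior mean proportion of
#'   null SNP and `inclusion_prob` the per-SNP posterior inclusion
#'   probability.
#' @export
fit_bayesCpi <- function(records, genotypes, vc, mcmc = mcmc_config(),
                         freqs = NULL) {
  fit_wgr(records, genotypes, vc, mcmc, freqs, method = "BayesCpi")
}

fit_wgr <- function(records, genotypes, vc, mcmc, freqs, method) {
  stopifnot(inherits(mcmc, "mcmc_config"))
  if (is.null(freqs)) freqs <- snp_freqs(genotypes)
  if (anyNA(genotypes)) genotypes <- impute_missing(genotypes, freqs)
  Zg <- sweep(genotypes, 2, 2 * freqs, "-")

  rows <- wgr_design_rows(records, Zg)
  Z <- rows$Z
  w <- rows$w
  y <- records$value

  ## zero-variance design columns are confounded with the intercept: freeze
  flagged <- apply(Z, 2, function(z) max(z) - min(z) == 0)
  if (any(flagged)) Z[, flagged] <- 0

  sum2pq <- sum(2 * freqs * (1 - freqs))
  pi0 <- if (method == "BayesA") 0 else mcmc$pi0
  scale_a <- if (!is.null(mcmc$scale_override)) mcmc$scale_override
  else (mcmc$nu_a - 2) / mcmc$nu_a * vc$sigma2_a / ((1 - pi0) * sum2pq)
  scale_e <- vc$sigma2_e * (mcmc$nu_e - 2) / mcmc$nu_e

  pi_init <- if (!is.null(mcmc$pi_fixed)) mcmc$pi_fixed else 0.5
  set.seed(mcmc$seed)
  res <- wgr_gibbs_cpp(y, Z, w,
                       method = if (method == "BayesA") 0L else 1L,
                       niter = mcmc$chain_length, burnin = mcmc$burn_in,
                       thin = mcmc$thin, nu_a = mcmc$nu_a, scale_a = scale_a,
                       pi_init = pi_init,
                       estimate_pi = method == "BayesCpi" && is.null(mcmc$pi_fixed),
                       nu_e = mcmc$nu_e, scale_e = scale_e,
                       sigma2e_init = vc$sigma2_e)

  snps <- colnames(genotypes)
  post <- structure(list(
    method = method,
    snp = snps,
    alpha_mean = setNames(res$alpha_mean, snps),
    alpha_sd = setNames(res$alpha_sd, snps),
    inclusion_prob = setNames(res$inclusion_prob, snps),
    pi_mean = if (method == "BayesCpi") mean(res$pi_samples) else NA_real_,
    pi_samples = res$pi_samples,
    sigma2_e_mean = mean(res$sigma2e_samples),
    sigma2e_samples = res$sigma2e_samples,
    sigma2alpha_samples = res$sigma2alpha_samples,
    n_samples = res$n_samples,
    flagged = snps[flagged],
    freqs = freqs,
    mcmc = mcmc
  ), class = "wgr_posterior")
  post$gebv <- gebv_from_effects(genotypes, post, freqs)
  post
}

#' @export
print.wgr_posterior <- function(x, ...) {
  cat(sprintf("%s posterior: %d SNP, %d retained samples\n",
              x$method, length(x$alpha_mean), x$n_samples))
  if (!is.na(x$pi_mean))
    cat(sprintf("  posterior mean pi = %.4f\n", x$pi_mean))
  cat(sprintf("  posterior mean sigma2_e = %.4f\n", x$sigma2_e_mean))
  invisible(x)
}

## design rows: centered genotype for own records, mean of parents' centered
## genotypes for family means; relative residual weight from the `weight`
## column (default 1).
wgr_design_rows <- function(records, Zg) {
  n <- nrow(records)
  has_id <- "id" %in% names(records) && !all(is.na(records$id))
  has_fam <- all(c("sire", "dam") %in% names(records))
  Z <- matrix(0, n, ncol(Zg), dimnames = list(NULL, colnames(Zg)))
  for (i in seq_len(n)) {
    if (has_id && !is.na(records$id[i])) {
      rid <- as.character(records$id[i])
      if (!rid %in% rownames(Zg)) stop("record id not genotyped: ", rid)
      Z[i, ] <- Zg[rid, ]
    } else if (has_fam) {
      s <- as.character(records$sire[i]); d <- as.character(records$dam[i])
      if (!all(c(s, d) %in% rownames(Zg)))
        stop("family-mean parents not genotyped: ", s, " x ", d)
      Z[i, ] <- 0.5 * (Zg[s, ] + Zg[d, ])
    } else stop("records need an `id` or `sire`/`dam` columns")
  }
  w <- if ("weight" %in% names(records)) records$weight else rep(1, n)
  if (any(w <= 0)) stop("weights must be positive")
  list(Z = Z, w = w)
}

#' Genomic breeding values from posterior-mean marker effects
#'
#' `GEBV_i = sum_k (g_ik - 2 p_k) alpha_k`, applicable to any genotyped
#' individual including validation generations, provided the SNP set and
#' centering frequencies match the training run.
#'
#' @param genotypes Allele-count matrix (imputed at `freqs` if missing
#'   cells are present).
#' @param posterior A `wgr_posterior`.
#' @param freqs Centering frequencies; defaults to those stored in the
#'   posterior.
#' @return Named vector of GEBV.
#' @export
gebv_from_effects <- function(genotypes, posterior, freqs = posterior$freqs) {
  missing_snp <- setdiff(posterior$snp, colnames(genotypes))
  if (length(missing_snp))
    stop("genotypes lack trained SNP: ",
         paste(head(missing_snp, 5), collapse = ", "),
         if (length(missing_snp) > 5) " ..." else "")
  G <- genotypes[, posterior$snp, drop = FALSE]
  if (anyNA(G)) G <- impute_missing(G, freqs[posterior$snp])
  Z <- sweep(G, 2, 2 * freqs[posterior$snp], "-")
  setNames(drop(Z %*% posterior$alpha_mean), rownames(G))
}

#' Build marker-regression records from corrected data
#'
#' Assembles the response table for [fit_bayesA()]/[fit_bayesCpi()] the way
#' the reduced-information scheme prescribes: one row per genotyped
#' individual with its own pre-corrected record (weight 1), plus one row
#' per full-sib family of non-genotyped progeny with both parents
#' genotyped, carrying the family-mean record with relative residual
#' weight `(0.5 sigma2_a + sigma2_e) / (n sigma2_e)`.
#'
#' @param corrected Pre-corrected phenotype table.
#' @param pedigree Pedigree resolving parents.
#' @param genotyped Character vector of genotyped ids.
#' @param vc A [varcomp()] used for the family weights.
#' @return data.frame with columns `id`, `sire`, `dam`, `value`, `weight`.
#' @export
build_wgr_records <- function(corrected, pedigree, genotyped, vc) {
  own <- corrected[as.character(corrected$id) %in% genotyped, , drop = FALSE]
  recs <- data.frame(id = as.character(own$id), sire = rep(NA_character_, nrow(own)),
                     dam = rep(NA_character_, nrow(own)), value = own$value,
                     weight = rep(1, nrow(own)), stringsAsFactors = FALSE)
  fam <- family_means(corrected, pedigree, genotyped)
  if (nrow(fam)) {
    recs <- rbind(recs, data.frame(
      id = NA_character_, sire = fam$sire, dam = fam$dam, value = fam$mean,
      weight = (0.5 * vc$sigma2_a + vc$sigma2_e) / (fam$n * vc$sigma2_e),
      stringsAsFactors = FALSE))
  }
  recs
}
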