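#' Configuration for the closed-population simulator
#'
#' Collects and validates every knob of the gene-dropping simulator.  The
#' defaults emulate a closed layer breeding line: about 60 sires and 310 dams
#' used per generation, discrete generations, hatches nested within
#' generation, all parents genotyped plus a fraction of progeny, and a SNP
#' panel dense enough that genomic relationships are informative.
#'
#' @param n_founders Number of founder individuals (generation 0).  Founders
#'   are produced by random mating of a finite burn-in population, so they
#'   carry linkage disequilibrium but have unknown parents in the pedigree.
#' @param n_generations Number of offspring generations after the founders.
#'   Generation labels run `0` (founders) to `n_generations`.
#' @param n_sires,n_dams Parents selected per generation.
#' @param n_progeny_per_generation Progeny born (and phenotyped) per
#'   generation.
#' @param n_hatches_per_generation Contemporary groups (hatches) per
#'   generation, fitted as fixed effects by the models.
#' @param n_chromosomes,chromosome_length Genome layout; length in Morgans.
#' @param n_snp Total SNP, spread evenly over chromosomes and equally spaced.
#' @param pi Proportion of SNP with zero effect on the trait; the number of
#'   QTL is `round((1 - pi) * n_snp)`.
#' @param h2 Narrow-sense heritability in the founder generation (0, 1].
#' @param sigma2_a Additive genetic variance among founders.  Defaults to
#'   `h2`, so the founder phenotypic variance is 1 and the residual variance
#'   is `1 - h2`.
#' @param selection_mode `"random"` (default), `"phenotype"` or `"ebv"`.
#'   Random selection is the neutral benchmark under which pedigree-based
#'   accuracy is expected to decay by sqrt(0.5) per generation.  Phenotypic
#'   selection truncates on own phenotype within sex.  `"ebv"` requires a
#'   `selection_criterion` function supplying scores (e.g. from a fitted
#'   model); the simulator itself never fits models.
#' @param selection_criterion Optional `function(candidates, population)`
#'   returning a named numeric score vector, used when
#'   `selection_mode = "ebv"`.
#' @param genotype_progeny_fraction Fraction of each generation's progeny
#'   that is genotyped in addition to all selected parents.
#' @param phenotype_founders Should founders receive phenotypes?  Mirrors a
#'   base generation with genotypes but no own records when `FALSE`.
#' @param missing_rate Rate at which observed genotype calls are masked as
#'   missing, so that quality-control filters are exercised.
#' @param burn_in_generations,burn_in_ne Random-mating burn-in used to
#'   generate founder linkage disequilibrium: effective size `burn_in_ne`
#'   for `burn_in_generations` generations, gene-dropped from random
#'   haplotypes.
#' @param seed Integer seed; identical configurations give bit-identical
#'   populations.
#'
#' @return A validated list of class `sim_config`.
#' @examples
#' cfg <- sim_config(n_founders = 100, n_generations = 2, n_sires = 10,
#'                   n_dams = 40, n_progeny_per_generation = 120,
#'                   n_snp = 200, burn_in_generations = 20, seed = 1)
#' cfg$n_sires
#' @export
sim_config <- function(n_founders = 400,
                       n_generations = 5,
                       n_sires = 60,
                       n_dams = 310,
                       n_progeny_per_generation = 600,
                       n_hatches_per_generation = 2,
                       n_chromosomes = 10,
                       chromosome_length = 1,
                       n_snp = 2000,
                       pi = 0.95,
                       h2 = 0.4,
                       sigma2_a = NULL,
                       selection_mode = c("random", "phenotype", "ebv"),
                       selection_criterion = NULL,
                       genotype_progeny_fraction = 0.3,
                       phenotype_founders = FALSE,
                       missing_rate = 0.01,
                       burn_in_generations = 100,
                       burn_in_ne = 100,
                       seed = 1L) {
  selection_mode <- match.arg(selection_mode)
  if (is.null(sigma2_a)) sigma2_a <- h2

  counts <- c(n_founders = n_founders, n_sires = n_sires, n_dams = n_dams,
              n_progeny_per_generation = n_progeny_per_generation,
              n_hatches_per_generation = n_hatches_per_generation,
              n_chromosomes = n_chromosomes, n_snp = n_snp,
              burn_in_generations = burn_in_generations,
              burn_in_ne = burn_in_ne)
  if (any(counts < 1))
    stop("all counts must be positive: ",
         paste(names(counts)[counts < 1], collapse = ", "))
  if (n_generations < 0) stop("n_generations must be >= 0")
  if (pi < 0 || pi > 1) stop("pi must lie in [0, 1]")
  if (h2 <= 0 || h2 > 1) stop("h2 must lie in (0, 1]")
  if (sigma2_a < 0) stop("sigma2_a must be >= 0")
  if (chromosome_length <= 0) stop("chromosome_length must be positive")
  if (genotype_progeny_fraction < 0 || genotype_progeny_fraction > 1)
    stop("genotype_progeny_fraction must lie in [0, 1]")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must lie in [0, 1)")
  if (n_generations > 0 &&
      n_sires + n_dams > min(n_founders, n_progeny_per_generation))
    stop("infeasible config: n_sires + n_dams exceeds the number of ",
         "candidates available per generation")
  if (selection_mode == "ebv" && !is.function(selection_criterion))
    stop("selection_mode = 'ebv' requires a selection_criterion function")

  structure(list(
    n_founders = as.integer(n_founders),
    n_generations = as.integer(n_generations),
    n_sires = as.integer(n_sires),
    n_dams = as.integer(n_dams),
    n_progeny_per_generation = as.integer(n_progeny_per_generation),
    n_hatches_per_generation = as.integer(n_hatches_per_generation),
    n_chromosomes = as.integer(n_chromosomes),
    chromosome_length = chromosome_length,
    n_snp = as.integer(n_snp),
    pi = pi, h2 = h2, sigma2_a = sigma2_a,
    selection_mode = selection_mode,
    selection_criterion = selection_criterion,
    genotype_progeny_fraction = genotype_progeny_fraction,
    phenotype_founders = phenotype_founders,
    missing_rate = missing_rate,
    burn_in_generations = as.integer(burn_in_generations),
    burn_in_ne = as.integer(burn_in_ne),
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Closed-population simulation config\n")
  cat(sprintf("  founders %d, %d offspring generation(s) of %d progeny\n",
              x$n_founders, x$n_generations, x$n_progeny_per_generation))
  cat(sprintf("  %d sires x %d dams per generation, selection: %s\n",
              x$n_sires, x$n_dams, x$selection_mode))
  cat(sprintf("  genome: %d chromosomes x %.2f M, %d SNP\n",
              x$n_chromosomes, x$chromosome_length, x$n_snp))
  cat(sprintf("  trait: pi = %.3f, h2 = %.2f, sigma2_a = %.3f\n",
              x$pi, x$h2, x$sigma2_a))
  invisible(x)
}
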