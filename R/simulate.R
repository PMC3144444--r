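#' Simulate a closed breeding population by gene dropping
#'
#' Generates a discrete-generation closed population with the structure the
#' persistence analysis assumes: founders carrying linkage disequilibrium
#' from a finite random-mating burn-in, a limited number of sires and dams
#' selected each generation, full-sib families nested within dams, hatches
#' nested within generation as fixed environmental effects, and a genotyped
#' set consisting of all parents plus a fraction of progeny.
#'
#' The trait is purely additive: `round((1 - pi) * n_snp)` of the SNP are
#' QTL with normal effects rescaled so the founder additive variance equals
#' `sigma2_a`; the true breeding value of individual *i* is
#' `sum_k alpha_k g_ik`.  Phenotypes are
#' `hatch effect + true breeding value + N(0, sigma2_e)` with
#' `sigma2_e = sigma2_a (1 - h2) / h2`.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `gs_population` with elements
#'   \describe{
#'     \item{pedigree}{data.frame `id`, `sire`, `dam` (NA = unknown),
#'       `generation`, `sex`, `hatch`, ordered parents before offspring.}
#'     \item{genotypes}{numeric matrix of observed allele counts
#'       (0/1/2/`NA`) for genotyped individuals, row names = ids, with a
#'       `map` attribute (`snp`, `chr`, `pos` in Morgans).}
#'     \item{genotypes_true}{the same matrix before missing-data masking.}
#'     \item{arch}{trait architecture: `qtl_ids`, `alpha`, `sigma2_a`,
#'       `sigma2_e`, `hatch_effects`, `founder_freq`.}
#'     \item{phenotypes}{data.frame `id`, `trait`, `value`, `hatch`,
#'       `generation`.}
#'     \item{tbv}{named vector of true breeding values for all individuals.}
#'     \item{config}{the input configuration.}
#'   }
#' @examples
#' pop <- simulate_population(sim_config(
#'   n_founders = 80, n_generations = 2, n_sires = 8, n_dams = 30,
#'   n_progeny_per_generation = 90, n_snp = 100, n_chromosomes = 2,
#'   burn_in_generations = 10, burn_in_ne = 40, seed = 42))
#' table(pop$pedigree$generation)
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  map <- genome_map(config$n_snp, config$n_chromosomes, config$chromosome_length)
  m <- config$n_snp

  ## --- founder haplotypes from a random-mating burn-in ---------------------
  H <- burnin_haplotypes(config, map)
  ne <- config$burn_in_ne
  males <- seq_len(floor(ne / 2))
  females <- setdiff(seq_len(ne), males)
  nf <- config$n_founders
  H_fnd <- .drop(H, sample(males, nf, replace = TRUE),
                 sample(females, nf, replace = TRUE), map)

  ped <- data.frame(
    id = seq_len(nf), sire = NA_integer_, dam = NA_integer_,
    generation = 0L,
    sex = sample(rep_len(c("M", "F"), nf)),
    hatch = sample(hatch_labels(0L, config$n_hatches_per_generation), nf,
                   replace = TRUE),
    stringsAsFactors = FALSE
  )

  geno_f <- hap_to_geno(H_fnd, ped$id, map)
  arch <- assign_qtl_effects(geno_f, pi = config$pi,
                             sigma2_a = config$sigma2_a, h2 = config$h2)
  all_hatches <- unlist(lapply(0:config$n_generations, hatch_labels,
                               n_hatches = config$n_hatches_per_generation))
  arch$hatch_effects <- setNames(
    rnorm(length(all_hatches), 0, sqrt(0.25 * arch$sigma2_e)), all_hatches)

  tbv <- setNames(drop(geno_f[, arch$qtl_ids, drop = FALSE] %*% arch$alpha),
                  rownames(geno_f))
  phenos <- list()
  if (config$phenotype_founders)
    phenos[["0"]] <- simulate_phenotypes(arch, ped, tbv, config)

  extra_geno <- sample(ped$id, round(config$genotype_progeny_fraction * nf))
  parent_ids <- integer(0)
  hap_by_gen <- list(`0` = H_fnd)
  gen_ids <- list(`0` = ped$id)

  ## --- offspring generations ----------------------------------------------
  for (g in seq_len(config$n_generations)) {
    prev <- ped[ped$generation == g - 1L, ]
    crit <- selection_scores(config, prev, phenos[[as.character(g - 1L)]],
                             list(pedigree = ped, tbv = tbv))
    mode <- if (is.null(crit) && config$selection_mode != "random") "random"
            else config$selection_mode
    sel <- select_parents(prev[, c("id", "sex")], criterion = crit,
                          n_sires = config$n_sires, n_dams = config$n_dams,
                          mode = mode)
    parent_ids <- c(parent_ids, sel$sires, sel$dams)

    ## one sire per dam -> progeny of a dam are full sibs
    sire_of_dam <- sample(sel$sires, config$n_dams, replace = TRUE)
    np <- config$n_progeny_per_generation
    dam_slot <- rep_len(seq_len(config$n_dams), np)
    dams_p <- sel$dams[dam_slot]
    sires_p <- sire_of_dam[dam_slot]

    prev_ids <- gen_ids[[as.character(g - 1L)]]
    Hg <- .drop(hap_by_gen[[as.character(g - 1L)]],
                match(sires_p, prev_ids), match(dams_p, prev_ids), map)
    ids <- max(ped$id) + seq_len(np)
    ped_g <- data.frame(
      id = ids, sire = sires_p, dam = dams_p, generation = g,
      sex = sample(rep_len(c("M", "F"), np)),
      hatch = sample(hatch_labels(g, config$n_hatches_per_generation), np,
                     replace = TRUE),
      stringsAsFactors = FALSE
    )
    ped <- rbind(ped, ped_g)
    geno_g <- hap_to_geno(Hg, ids, map)
    tbv_g <- setNames(drop(geno_g[, arch$qtl_ids, drop = FALSE] %*% arch$alpha),
                      rownames(geno_g))
    tbv <- c(tbv, tbv_g)
    phenos[[as.character(g)]] <- simulate_phenotypes(arch, ped_g, tbv_g, config)
    extra_geno <- c(extra_geno,
                    sample(ids, round(config$genotype_progeny_fraction * np)))
    hap_by_gen[[as.character(g)]] <- Hg
    gen_ids[[as.character(g)]] <- ids
  }

  ## --- genotyped set: all parents plus the sampled progeny fraction --------
  geno_ids <- sort(unique(c(parent_ids, extra_geno)))
  gmat <- matrix(NA_real_, length(geno_ids), m,
                 dimnames = list(as.character(geno_ids), map$snp))
  for (g in names(hap_by_gen)) {
    here <- intersect(geno_ids, gen_ids[[g]])
    if (!length(here)) next
    rows <- match(here, gen_ids[[g]])
    Hg <- hap_by_gen[[g]]
    gmat[as.character(here), ] <- Hg[2 * rows - 1L, , drop = FALSE] +
      Hg[2 * rows, , drop = FALSE]
  }
  gtrue <- gmat
  if (config$missing_rate > 0) {
    mask <- matrix(runif(length(gmat)) < config$missing_rate, nrow(gmat))
    gmat[mask] <- NA_real_
  }
  attr(gmat, "map") <- map
  attr(gtrue, "map") <- map

  pheno <- do.call(rbind, phenos)
  rownames(pheno) <- NULL

  structure(list(pedigree = ped, genotypes = gmat, genotypes_true = gtrue,
                 arch = arch, phenotypes = pheno, tbv = tbv, config = config),
            class = "gs_population")
}

#' @export
print.gs_population <- function(x, ...) {
  cat(sprintf("Simulated population: %d individuals, %d generation(s)\n",
              nrow(x$pedigree), max(x$pedigree$generation)))
  cat(sprintf("  genotyped: %d, phenotype records: %d, SNP: %d (QTL: %d)\n",
              nrow(x$genotypes), nrow(x$phenotypes), ncol(x$genotypes),
              length(x$arch$qtl_ids)))
  invisible(x)
}

#' Assign QTL positions and effects for a simulated trait
#'
#' Chooses `round((1 - pi) * m)` SNP uniformly at random as QTL, draws their
#' allele-substitution effects from a standard normal and rescales them so
#' that the additive variance at the supplied genotypes' allele frequencies,
#' `sum_k 2 p_k (1 - p_k) alpha_k^2`, equals `sigma2_a` exactly.  Only SNP
#' segregating in the supplied genotypes can become QTL.
#'
#' @param genotypes Numeric matrix of allele counts (rows = individuals,
#'   columns = SNP) used to define the reference allele frequencies;
#'   typically the founder generation.
#' @param pi Proportion of SNP with zero effect, in `[0, 1]`.
#' @param sigma2_a Target additive genetic variance.
#' @param h2 Optional heritability used to derive the residual variance
#'   `sigma2_e = sigma2_a (1 - h2) / h2` stored alongside.
#' @param seed Optional seed; by default the current RNG stream is used.
#' @return A list of class `trait_arch`: `qtl_ids`, `alpha` (named effects),
#'   `sigma2_a` (realized), `sigma2_e`, `founder_freq`, `hatch_effects`
#'   (empty; filled by the simulator).
#' @export
assign_qtl_effects <- function(genotypes, pi, sigma2_a, h2 = NULL, seed = NULL) {
  if (pi < 0 || pi > 1) stop("pi must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  m <- ncol(genotypes)
  p <- colMeans(genotypes, na.rm = TRUE) / 2
  n_qtl <- round((1 - pi) * m)
  seg <- which(p > 0 & p < 1)
  if (n_qtl > 0 && length(seg) < n_qtl)
    stop("not enough segregating SNP to place ", n_qtl, " QTL")
  qtl <- sort(sample(seg, n_qtl))
  alpha <- rnorm(n_qtl)
  realized <- 0
  if (n_qtl > 0 && sigma2_a > 0) {
    v <- sum(2 * p[qtl] * (1 - p[qtl]) * alpha^2)
    alpha <- alpha * sqrt(sigma2_a / v)
    realized <- sigma2_a
  } else {
    alpha <- rep(0, n_qtl)
  }
  qtl_ids <- colnames(genotypes)[qtl]
  if (is.null(qtl_ids)) qtl_ids <- qtl
  structure(list(
    qtl_ids = qtl_ids,
    alpha = setNames(alpha, qtl_ids),
    sigma2_a = realized,
    sigma2_e = if (is.null(h2)) NA_real_ else realized * (1 - h2) / h2,
    founder_freq = p,
    hatch_effects = numeric(0)
  ), class = "trait_arch")
}

#' Simulate phenotypes for a set of individuals
#'
#' `value = hatch effect + true breeding value + N(0, sigma2_e)` with
#' `sigma2_e = sigma2_a (1 - h2) / h2` taken from the architecture and the
#' configuration.  With `h2 = 1` the residual variance is zero and the
#' phenotype minus its hatch effect reproduces the breeding value exactly.
#'
#' @param arch A `trait_arch` with `hatch_effects` covering every hatch in
#'   `pedigree`.
#' @param pedigree Pedigree rows of the individuals to phenotype.
#' @param tbv Named vector of true breeding values covering `pedigree$id`.
#' @param config The [sim_config()] (supplies `h2`).
#' @param seed Optional seed; by default the current RNG stream is used.
#' @return data.frame `id`, `trait`, `value`, `hatch`, `generation`.
#' @export
simulate_phenotypes <- function(arch, pedigree, tbv, config, seed = NULL) {
  if (config$h2 == 0)
    stop("h2 = 0: residual variance sigma2_a (1 - h2) / h2 is undefined")
  if (!is.null(seed)) set.seed(seed)
  ids <- as.character(pedigree$id)
  if (!all(ids %in% names(tbv)))
    stop("every phenotyped individual needs a true breeding value")
  if (!all(pedigree$hatch %in% names(arch$hatch_effects)))
    stop("every phenotyped individual needs a hatch effect in `arch`")
  sigma2_e <- arch$sigma2_a * (1 - config$h2) / config$h2
  data.frame(
    id = pedigree$id, trait = "trait1",
    value = arch$hatch_effects[pedigree$hatch] + tbv[ids] +
      rnorm(nrow(pedigree), 0, sqrt(sigma2_e)),
    hatch = pedigree$hatch, generation = pedigree$generation,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Select parents from a candidate set
#'
#' Random selection samples uniformly within sex; `"phenotype"` and `"ebv"`
#' apply truncation selection on the supplied criterion within sex, with
#' ties broken by id order.
#'
#' @param candidates data.frame with columns `id` and `sex` (`"M"`/`"F"`).
#' @param criterion Named numeric scores (names = ids); required unless
#'   `mode = "random"`.
#' @param n_sires,n_dams Numbers of males and females to select.
#' @param mode `"random"`, `"phenotype"` or `"ebv"`.
#' @param seed Optional seed; by default the current RNG stream is used.
#' @return list with integer vectors `sires` and `dams` (ids).
#' @export
select_parents <- function(candidates, criterion = NULL, n_sires, n_dams,
                           mode = c("random", "phenotype", "ebv"),
                           seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  males <- candidates[candidates$sex == "M", ]
  females <- candidates[candidates$sex == "F", ]
  if (nrow(males) < n_sires || nrow(females) < n_dams)
    stop(sprintf("infeasible selection: %d males / %d females available, %d / %d requested",
                 nrow(males), nrow(females), n_sires, n_dams))
  if (mode == "random") {
    return(list(sires = sample(males$id, n_sires),
                dams = sample(females$id, n_dams)))
  }
  if (is.null(criterion))
    stop("mode '", mode, "' requires a criterion")
  if (!all(as.character(candidates$id) %in% names(criterion)))
    stop("criterion missing for some candidates")
  top <- function(df, k) {
    sc <- criterion[as.character(df$id)]
    df$id[order(-sc, df$id)][seq_len(k)]
  }
  list(sires = top(males, n_sires), dams = top(females, n_dams))
}

## ---- internal helpers ------------------------------------------------------

genome_map <- function(n_snp, n_chr, chr_len) {
  per <- rep(n_snp %/% n_chr, n_chr)
  extra <- n_snp %% n_chr
  if (extra > 0) per[seq_len(extra)] <- per[seq_len(extra)] + 1L
  chr <- rep(seq_len(n_chr), per)
  pos <- unlist(lapply(per, function(k) (seq_len(k) - 0.5) / k * chr_len))
  map <- data.frame(snp = sprintf("snp%05d", seq_len(n_snp)),
                    chr = chr, pos = pos, stringsAsFactors = FALSE)
  attr(map, "chr_first") <- as.integer(cumsum(c(0, per[-n_chr])))
  attr(map, "chr_last") <- as.integer(cumsum(per) - 1L)
  attr(map, "chr_len") <- rep(chr_len, n_chr)
  map
}

.drop <- function(H, sire_pos, dam_pos, map) {
  drop_generation_cpp(H, as.integer(sire_pos) - 1L, as.integer(dam_pos) - 1L,
                      map$pos, attr(map, "chr_first"), attr(map, "chr_last"),
                      attr(map, "chr_len"))
}

burnin_haplotypes <- function(config, map) {
  ne <- config$burn_in_ne
  m <- config$n_snp
  p0 <- runif(m, 0.05, 0.95)
  H <- matrix(rbinom(2 * ne * m, 1, rep(p0, each = 2 * ne)), 2 * ne, m)
  males <- seq_len(floor(ne / 2))
  females <- setdiff(seq_len(ne), males)
  for (g in seq_len(config$burn_in_generations)) {
    H <- .drop(H, sample(males, ne, replace = TRUE),
               sample(females, ne, replace = TRUE), map)
  }
  H
}

hap_to_geno <- function(H, ids, map) {
  n <- length(ids)
  g <- H[2 * seq_len(n) - 1L, , drop = FALSE] + H[2 * seq_len(n), , drop = FALSE]
  dimnames(g) <- list(as.character(ids), map$snp)
  storage.mode(g) <- "double"
  g
}

hatch_labels <- function(generation, n_hatches) {
  sprintf("g%d_h%d", generation, seq_len(n_hatches))
}

selection_scores <- function(config, candidates, pheno_prev, state) {
  switch(config$selection_mode,
    random = NULL,
    phenotype = {
      if (is.null(pheno_prev)) NULL
      else setNames(pheno_prev$value, as.character(pheno_prev$id))
    },
    ebv = config$selection_criterion(candidates, state)
  )
}

#' Per-SNP allele frequencies
#'
#' Frequency of the counted allele at each SNP, computed over the supplied
#' genotyped individuals with missing calls excluded.
#'
#' @param genotypes Matrix of allele counts 0/1/2 with `NA` for missing.
#' @return Named numeric vector of frequencies in `[0, 1]`.
#' @export
snp_freqs <- function(genotypes) {
  colMeans(genotypes, na.rm = TRUE) / 2
}
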