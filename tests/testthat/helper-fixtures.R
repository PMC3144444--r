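# Small populations and toy pedigrees shared across tests.

small_config <- function(seed = 1, ...) {
  defaults <- list(n_founders = 100, n_generations = 2, n_sires = 10,
                   n_dams = 40, n_progeny_per_generation = 120,
                   n_snp = 200, n_chromosomes = 4,
                   burn_in_generations = 20, burn_in_ne = 50,
                   genotype_progeny_fraction = 0.5, seed = seed)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

small_population <- function(seed = 1, ...) {
  simulate_population(small_config(seed = seed, ...))
}

# founder generation only, with phenotypes, handy for REML-style checks
founder_population <- function(seed = 1, n = 200, ...) {
  simulate_population(small_config(
    seed = seed, n_founders = n, n_generations = 0,
    phenotype_founders = TRUE, ...))
}

# pedigree with a founder pair, two full sibs, and their inbred offspring
fullsib_mating_pedigree <- function() {
  data.frame(
    id = 1:5,
    sire = c(NA, NA, 1, 1, 3),
    dam = c(NA, NA, 2, 2, 4),
    generation = c(0, 0, 1, 1, 2),
    sex = c("M", "F", "M", "F", "M"),
    hatch = c("g0_h1", "g0_h1", "g1_h1", "g1_h1", "g2_h1"),
    stringsAsFactors = FALSE
  )
}

# dense generalized-least-squares oracle for the animal model:
# y = X b + Z a + e, a ~ N(0, s2a K), e ~ N(0, s2e W)
gls_animal_oracle <- function(y, X, Z, K, s2a, s2e, w = rep(1, length(y))) {
  V <- s2a * Z %*% K %*% t(Z) + s2e * diag(w)
  Vi <- solve(V)
  b <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  a <- s2a * K %*% t(Z) %*% Vi %*% (y - X %*% b)
  list(b = drop(b), a = drop(a))
}

hatch_X <- function(pheno) {
  f <- factor(pheno$hatch)
  X <- stats::model.matrix(~ 0 + f)
  colnames(X) <- levels(f)
  X
}
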