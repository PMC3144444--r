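test_that("a zero-generation run yields founders only, with unknown parents", {
  pop <- simulate_population(small_config(seed = 3, n_generations = 0))
  expect_equal(unique(pop$pedigree$generation), 0L)
  expect_true(all(is.na(pop$pedigree$sire)))
  expect_true(all(is.na(pop$pedigree$dam)))
})

test_that("every non-founder's parents belong to the previous generation", {
  pop <- small_population(seed = 11)
  ped <- pop$pedigree
  gen_of <- setNames(ped$generation, as.character(ped$id))
  off <- ped[ped$generation > 0, ]
  expect_true(all(gen_of[as.character(off$sire)] == off$generation - 1))
  expect_true(all(gen_of[as.character(off$dam)] == off$generation - 1))
  # sires male, dams female
  sex_of <- setNames(ped$sex, as.character(ped$id))
  expect_true(all(sex_of[as.character(off$sire)] == "M"))
  expect_true(all(sex_of[as.character(off$dam)] == "F"))
})

test_that("the default configuration uses 60 sires and 310 dams per generation", {
  cfg <- sim_config()
  expect_identical(cfg$n_sires, 60L)
  expect_identical(cfg$n_dams, 310L)
})

test_that("infeasible parent numbers are rejected up front", {
  expect_error(sim_config(n_founders = 50, n_progeny_per_generation = 50,
                          n_sires = 30, n_dams = 30),
               "infeasible")
})

test_that("simulation is bit-reproducible given the seed", {
  a <- small_population(seed = 21)
  b <- small_population(seed = 21)
  expect_identical(a$pedigree, b$pedigree)
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$phenotypes, b$phenotypes)
  expect_identical(a$tbv, b$tbv)
  d <- small_population(seed = 22)
  expect_false(identical(a$genotypes, d$genotypes))
})

test_that("pedigrees are acyclic with generation-monotone parent links", {
  for (s in c(5, 6)) {
    ped <- small_population(seed = s)$pedigree
    # order_pedigree errors on cycles; build_A exercises it
    expect_silent(build_A(ped[sample(nrow(ped)), ]))
    expect_true(all(diff(ped$generation) >= 0))
  }
})

test_that("QTL count follows the deterministic rounding rule", {
  pop <- founder_population(seed = 2, n = 150)
  g <- pop$genotypes_true
  arch <- assign_qtl_effects(g, pi = 0.88, sigma2_a = 1, seed = 5)
  expect_length(arch$alpha, round((1 - 0.88) * ncol(g)))

  arch1 <- assign_qtl_effects(g, pi = 1, sigma2_a = 1, seed = 5)
  expect_length(arch1$alpha, 0)
  expect_identical(arch1$sigma2_a, 0)
  expect_error(assign_qtl_effects(g, pi = -0.1, sigma2_a = 1), "pi")
})

test_that("QTL effects are rescaled to the target additive variance", {
  pop <- founder_population(seed = 4, n = 150)
  g <- pop$genotypes_true
  arch <- assign_qtl_effects(g, pi = 0.9, sigma2_a = 0.37, seed = 6)
  p <- colMeans(g)[arch$qtl_ids] / 2
  expect_equal(sum(2 * p * (1 - p) * arch$alpha^2), 0.37, tolerance = 1e-8)
})

test_that("phenotype equals hatch effect plus breeding value when h2 = 1", {
  pop <- simulate_population(small_config(seed = 9, h2 = 1,
                                          phenotype_founders = TRUE))
  ph <- pop$phenotypes
  resid <- ph$value - pop$arch$hatch_effects[ph$hatch] -
    pop$tbv[as.character(ph$id)]
  expect_equal(max(abs(resid)), 0, tolerance = 1e-12)
})

test_that("h2 = 0 makes the residual variance undefined", {
  expect_error(sim_config(h2 = 0), "h2")
  pop <- small_population(seed = 1)
  cfg0 <- pop$config
  cfg0$h2 <- 0
  expect_error(simulate_phenotypes(pop$arch, pop$pedigree, pop$tbv, cfg0),
               "undefined")
})

test_that("shifting one hatch effect shifts that hatch's phenotype mean by c", {
  pop <- small_population(seed = 13)
  arch2 <- pop$arch
  h <- names(arch2$hatch_effects)[3]
  arch2$hatch_effects[h] <- arch2$hatch_effects[h] + 2.5
  ped_g1 <- pop$pedigree[pop$pedigree$generation == 1, ]
  p1 <- simulate_phenotypes(pop$arch, ped_g1, pop$tbv, pop$config, seed = 99)
  p2 <- simulate_phenotypes(arch2, ped_g1, pop$tbv, pop$config, seed = 99)
  delta <- p2$value - p1$value
  expect_equal(unique(round(delta[p1$hatch == h], 10)), 2.5)
  expect_equal(unique(round(delta[p1$hatch != h], 10)), 0)
})

test_that("offspring-midparent phenotype regression recovers h2", {
  # founder pairs mated at random; slope of offspring on midparent ~ h2
  slopes <- vapply(1:5, function(s) {
    pop <- simulate_population(small_config(
      seed = 100 + s, n_founders = 400, n_generations = 1, n_sires = 200,
      n_dams = 200, n_progeny_per_generation = 2000, h2 = 0.5,
      n_hatches_per_generation = 1, phenotype_founders = TRUE,
      n_snp = 200, burn_in_generations = 20, burn_in_ne = 400))
    ph <- pop$phenotypes
    val <- setNames(ph$value - pop$arch$hatch_effects[ph$hatch],
                    as.character(ph$id))
    off <- pop$pedigree[pop$pedigree$generation == 1, ]
    mid <- 0.5 * (val[as.character(off$sire)] + val[as.character(off$dam)])
    unname(coef(lm(val[as.character(off$id)] ~ mid))[2])
  }, numeric(1))
  expect_lt(abs(mean(slopes) - 0.5), 0.05)
})

test_that("truncation selection picks the top-scoring candidates within sex", {
  cand <- data.frame(id = 1:40, sex = rep(c("M", "F"), 20))
  score <- setNames(rnorm(40), as.character(1:40))
  sel <- select_parents(cand, criterion = score, n_sires = 5, n_dams = 8,
                        mode = "phenotype")
  males <- cand$id[cand$sex == "M"]
  females <- cand$id[cand$sex == "F"]
  expect_setequal(sel$sires,
                  males[order(-score[as.character(males)])][1:5])
  expect_setequal(sel$dams,
                  females[order(-score[as.character(females)])][1:8])
})

test_that("random selection is reproducible and errors without a criterion", {
  cand <- data.frame(id = 1:30, sex = rep(c("M", "F"), 15))
  s1 <- select_parents(cand, n_sires = 4, n_dams = 6, mode = "random", seed = 7)
  s2 <- select_parents(cand, n_sires = 4, n_dams = 6, mode = "random", seed = 7)
  expect_identical(s1, s2)
  expect_length(s1$sires, 4)
  expect_length(s1$dams, 6)
  expect_error(select_parents(cand, n_sires = 4, n_dams = 6,
                              mode = "phenotype"), "criterion")
  expect_error(select_parents(cand, n_sires = 20, n_dams = 6, mode = "random"),
               "infeasible")
})

test_that("phenotypic selection raises the mean breeding value of parents", {
  # selection differential on the trait translates to TBV response
  diffs <- vapply(1:20, function(s) {
    pop <- simulate_population(small_config(seed = 300 + s, h2 = 0.5,
                                            phenotype_founders = TRUE))
    ph0 <- pop$phenotypes[pop$phenotypes$generation == 0, ]
    crit <- setNames(ph0$value, as.character(ph0$id))
    fnd <- pop$pedigree[pop$pedigree$generation == 0, c("id", "sex")]
    sel <- select_parents(fnd, crit, n_sires = 10, n_dams = 20,
                          mode = "phenotype")
    mean(pop$tbv[as.character(c(sel$sires, sel$dams))]) -
      mean(pop$tbv[as.character(fnd$id)])
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})

test_that("allele-frequency drift is unbiased under random selection", {
  # founders -> one random-mating generation; mean change over replicates ~ 0
  deltas <- sapply(1:100, function(s) {
    pop <- simulate_population(small_config(
      seed = 1000 + s, n_founders = 60, n_generations = 1, n_sires = 10,
      n_dams = 25, n_progeny_per_generation = 60, n_snp = 60,
      n_chromosomes = 2, burn_in_generations = 5, burn_in_ne = 30,
      genotype_progeny_fraction = 1, missing_rate = 0))
    ids0 <- as.character(pop$pedigree$id[pop$pedigree$generation == 0])
    ids1 <- as.character(pop$pedigree$id[pop$pedigree$generation == 1])
    g <- pop$genotypes_true
    mean(colMeans(g[intersect(ids1, rownames(g)), ]) / 2) -
      mean(colMeans(g[intersect(ids0, rownames(g)), ]) / 2)
  })
  se <- sd(deltas) / sqrt(length(deltas))
  expect_lt(abs(mean(deltas)), 3 * se)
})

test_that("founder heritability is realized in within-hatch phenotypic variance", {
  pop <- simulate_population(small_config(
    seed = 55, n_founders = 2000, n_generations = 0, h2 = 0.4,
    n_hatches_per_generation = 1, phenotype_founders = TRUE,
    burn_in_ne = 400))
  ids <- as.character(pop$pedigree$id)
  ratio <- var(pop$tbv[ids]) / var(pop$phenotypes$value)
  expect_lt(abs(ratio - 0.4), 0.05)
})
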