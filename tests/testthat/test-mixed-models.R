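test_that("PBLUP solutions equal the dense GLS oracle on a toy pedigree", {
  ped <- data.frame(id = 1:10,
                    sire = c(NA, NA, NA, NA, 1, 1, 3, 3, 5, 5),
                    dam = c(NA, NA, NA, NA, 2, 4, 2, 4, 6, 8),
                    generation = c(0, 0, 0, 0, 1, 1, 1, 1, 2, 2),
                    sex = rep(c("M", "F"), 5),
                    hatch = rep(c("h1", "h2"), each = 5))
  set.seed(4)
  ph <- data.frame(id = c(5:10), value = rnorm(6),
                   hatch = rep(c("h1", "h2"), 3), generation = 1)
  vc <- varcomp(0.3, 0.7)
  fit <- fit_pblup(ph, ped, vc)

  A <- build_A(ped)
  Z <- matrix(0, 6, 10); Z[cbind(1:6, 5:10)] <- 1
  orc <- gls_animal_oracle(ph$value, hatch_X(ph), Z, A, 0.3, 0.7)
  expect_lt(max(abs(fit$ebv - orc$a)), 1e-8)
  expect_lt(max(abs(fit$fixed_solutions - orc$b)), 1e-8)
})

test_that("EBV shrink to zero as the additive variance vanishes", {
  ped <- fullsib_mating_pedigree()
  ph <- data.frame(id = 3:5, value = c(1, -2, 3), hatch = "h1", generation = 1)
  fit <- fit_pblup(ph, ped, varcomp(1e-10, 1))
  expect_lt(max(abs(fit$ebv)), 1e-6)
  expect_error(fit_pblup(ph, ped, varcomp(0, 1)), "undefined")
})

test_that("an unrelated unphenotyped animal has EBV exactly zero, and an
           unphenotyped progeny gets the parent average", {
  ped <- rbind(fullsib_mating_pedigree(),
               data.frame(id = 6, sire = NA, dam = NA, generation = 0,
                          sex = "F", hatch = "g0_h1"))
  ph <- data.frame(id = 3:4, value = c(1.2, -0.4), hatch = "h1",
                   generation = 1)
  fit <- fit_pblup(ph, ped, varcomp(0.5, 0.5))
  expect_identical(unname(fit$ebv["6"]), 0)
  # id 5 is an unphenotyped terminal progeny of 3 x 4
  expect_equal(fit$ebv[["5"]], 0.5 * (fit$ebv[["3"]] + fit$ebv[["4"]]))
})

test_that("EBV are invariant to a constant shift within one hatch", {
  pop <- small_population(seed = 17)
  ph <- pop$phenotypes
  fit1 <- fit_pblup(ph, pop$pedigree, varcomp(0.4, 0.6))
  h <- ph$hatch[1]
  ph2 <- ph
  ph2$value[ph2$hatch == h] <- ph2$value[ph2$hatch == h] + 5
  fit2 <- fit_pblup(ph2, pop$pedigree, varcomp(0.4, 0.6))
  expect_lt(max(abs(fit1$ebv - fit2$ebv)), 1e-8)
  expect_equal(fit2$fixed_solutions[[h]] - fit1$fixed_solutions[[h]], 5,
               tolerance = 1e-8)
})

test_that("EM-REML keeps the restricted likelihood non-decreasing", {
  pop <- small_population(seed = 23)
  vc <- em_reml(pop$phenotypes, build_A(pop$pedigree))
  ll <- attr(vc, "loglik")
  expect_gt(length(ll), 3)
  expect_true(all(diff(ll) > -1e-8))
  expect_true(vc$converged)
})

test_that("EM-REML sends a null additive variance toward the boundary", {
  hits <- vapply(1:6, function(s) {
    pop <- simulate_population(small_config(
      seed = 700 + s, n_founders = 200, n_generations = 1, n_sires = 20,
      n_dams = 80, n_progeny_per_generation = 600, pi = 1, h2 = 0.4,
      n_snp = 100, burn_in_generations = 10, burn_in_ne = 60))
    # pi = 1: no QTL, phenotype = hatch + noise (sigma2_e taken from config)
    ph <- pop$phenotypes
    ph$value <- ph$value + rnorm(nrow(ph))  # give the trait residual variance
    vc <- em_reml(ph, build_A(pop$pedigree), max_iter = 300, tol = 1e-6)
    vc$sigma2_a < 0.05 * vc$sigma2_e
  }, logical(1))
  expect_gte(sum(hits), 5)
})

test_that("EM-REML is unbiased on data drawn exactly from the animal model", {
  # simulate y = Xb + a + e with a ~ N(0, 0.4 A) on a real pedigree, so the
  # check isolates the estimator from the population simulator
  pop <- small_population(seed = 3, n_founders = 150, n_generations = 2,
                          n_progeny_per_generation = 400)
  A <- build_A(pop$pedigree)
  ids <- as.character(pop$pedigree$id[pop$pedigree$generation > 0])
  L <- chol(A[ids, ids])
  set.seed(99)
  ests <- vapply(1:24, function(r) {
    a <- drop(crossprod(L, rnorm(length(ids)))) * sqrt(0.4)
    hat <- rep(c(1, -1), length.out = length(ids))
    y <- 2 + hat + a + rnorm(length(ids), 0, sqrt(0.6))
    ph <- data.frame(id = ids, value = y,
                     hatch = ifelse(hat > 0, "h1", "h2"), generation = 1)
    em_reml(ph, A)$h2
  }, numeric(1))
  expect_lt(abs(mean(ests) - 0.4), 0.05)
})

test_that("GBLUP with every record genotyped equals the G-based animal model", {
  pop <- small_population(seed = 41, genotype_progeny_fraction = 1,
                          missing_rate = 0)
  ph <- pop$phenotypes
  geno <- pop$genotypes_true[as.character(sort(unique(ph$id))), ]
  vc <- varcomp(0.4, 0.6)
  fit <- fit_gblup(ph, geno, pop$pedigree, vc, blend = 0.05)
  G <- build_G(geno)
  Gs <- 0.95 * G + 0.05 * diag(nrow(G))
  ids <- rownames(geno)
  Z <- matrix(0, nrow(ph), length(ids))
  Z[cbind(seq_len(nrow(ph)), match(as.character(ph$id), ids))] <- 1
  orc <- gls_animal_oracle(ph$value, hatch_X(ph), Z, Gs, 0.4, 0.6)
  expect_lt(max(abs(fit$ebv[ids] - orc$a)), 1e-8)
})

test_that("the reduced animal model equals the full model with progeny fitted", {
  # 4 genotyped parents, 12 non-genotyped progeny with records
  pop <- simulate_population(small_config(
    seed = 43, n_founders = 40, n_generations = 1, n_sires = 2, n_dams = 2,
    n_progeny_per_generation = 12, genotype_progeny_fraction = 0,
    missing_rate = 0, n_snp = 120))
  ped <- pop$pedigree
  par_ids <- as.character(sort(unique(c(ped$sire, ped$dam))))
  par_ids <- par_ids[!is.na(par_ids)]
  geno <- pop$genotypes_true[par_ids, , drop = FALSE]
  off <- ped[ped$generation == 1, ]
  ph <- pop$phenotypes[pop$phenotypes$generation == 1, ]
  vc <- varcomp(0.5, 0.5)

  fit_red <- suppressWarnings(
    fit_gblup(ph, geno, ped, vc, blend = 0.05))

  # full model: progeny breeding values fitted explicitly with
  # u_o = 0.5(u_s + u_d) + m, var(m) = 0.5 sigma2_a
  G <- build_G(geno)
  Gs <- 0.95 * G + 0.05 * diag(nrow(G))
  Tm <- matrix(0, nrow(off), length(par_ids))
  Tm[cbind(seq_len(nrow(off)), match(as.character(off$sire), par_ids))] <- 0.5
  Tm[cbind(seq_len(nrow(off)), match(as.character(off$dam), par_ids))] <- 0.5
  K_full <- rbind(cbind(Gs, Gs %*% t(Tm)),
                  cbind(Tm %*% Gs, Tm %*% Gs %*% t(Tm) + 0.5 * diag(nrow(off))))
  Z <- cbind(matrix(0, nrow(ph), length(par_ids)), diag(nrow(off)))
  orc <- gls_animal_oracle(ph$value, hatch_X(ph), Z, K_full, 0.5, 0.5)
  expect_lt(max(abs(fit_red$ebv[par_ids] - orc$a[seq_along(par_ids)])), 1e-6)
})

test_that("records without genotype links are dropped with a warning", {
  pop <- simulate_population(small_config(
    seed = 44, n_founders = 40, n_generations = 1, n_sires = 4, n_dams = 10,
    n_progeny_per_generation = 30, genotype_progeny_fraction = 0,
    missing_rate = 0, n_snp = 100, phenotype_founders = TRUE))
  ped <- pop$pedigree
  par_ids <- as.character(unique(c(ped$sire, ped$dam)))
  par_ids <- par_ids[!is.na(par_ids)]
  geno <- pop$genotypes_true[par_ids, , drop = FALSE]
  # founder records: founders are neither genotyped nor have genotyped parents
  expect_warning(
    fit <- fit_gblup(pop$phenotypes, geno, ped, varcomp(0.4, 0.6)),
    "dropped")
  expect_setequal(fit$dropped,
                  as.character(setdiff(ped$id[ped$generation == 0], par_ids)))
})

test_that("GBLUP GEBV equal ridge regression on centered genotypes", {
  pop <- founder_population(seed = 47, n = 80, n_snp = 250, missing_rate = 0,
                            genotype_progeny_fraction = 1)
  ph <- pop$phenotypes
  geno <- pop$genotypes_true[as.character(ph$id), ]
  # external centering frequencies: with within-sample frequencies G is
  # exactly singular (the ones vector is in its null space)
  p <- snp_freqs(geno[1:40, ])
  p <- pmin(pmax(p, 0.02), 0.98)
  vc <- varcomp(0.5, 0.5)
  fit <- fit_gblup(ph, geno, pop$pedigree, vc, freqs = p, blend = 0)

  s2pq <- 2 * sum(p * (1 - p))
  Zc <- sweep(geno, 2, 2 * p, "-")
  X <- hatch_X(ph)
  lam <- vc$sigma2_e / (vc$sigma2_a / s2pq)
  C <- rbind(cbind(crossprod(X), crossprod(X, Zc)),
             cbind(crossprod(Zc, X), crossprod(Zc) + lam * diag(ncol(Zc))))
  rhs <- c(crossprod(X, ph$value), crossprod(Zc, ph$value))
  sol <- solve(C, rhs)
  gebv_rr <- drop(Zc %*% sol[-seq_len(ncol(X))])
  expect_lt(max(abs(fit$ebv[rownames(geno)] - gebv_rr)), 1e-6)
})

test_that("pre-correction subtracts the hatch solution of each record", {
  ph <- data.frame(id = 1:6, value = c(1, 2, 3, 4, 5, 6),
                   hatch = rep(c("h1", "h2"), each = 3), generation = 1)
  fit <- list(fixed_solutions = c(h1 = 10, h2 = -1))
  out <- precorrect_phenotypes(ph, fit)
  expect_equal(out$value, c(-9, -8, -7, 5, 6, 7), ignore_attr = TRUE)
  # group-mean arithmetic: corrected means are (m1 - s1) and (m2 - s2)
  expect_equal(mean(out$value[out$hatch == "h1"]), mean(1:3) - 10)
  expect_equal(mean(out$value[out$hatch == "h2"]), mean(4:6) + 1)
  # zero solutions are a no-op
  zero <- list(fixed_solutions = c(h1 = 0, h2 = 0))
  expect_identical(precorrect_phenotypes(ph, zero)$value, ph$value)
  expect_error(precorrect_phenotypes(ph, list(fixed_solutions = c(h1 = 1))),
               "h2")
})

test_that("family means average full-sib records of non-genotyped progeny", {
  ped <- data.frame(id = 1:9, sire = c(NA, NA, NA, rep(1, 5), 3),
                    dam = c(NA, NA, NA, rep(2, 5), 2),
                    generation = c(0, 0, 0, rep(1, 6)),
                    sex = "M", hatch = "h1")
  ph <- data.frame(id = 4:9, value = c(1, 2, 3, 4, 5, 10), hatch = "h1",
                   generation = 1)
  fam <- family_means(ph, ped, genotyped = c("1", "2", "3"))
  fam <- fam[order(fam$sire), ]
  expect_equal(fam$mean, c(mean(1:5), 10))
  expect_equal(fam$n, c(5L, 1L))
  # genotyped progeny are excluded from family means
  fam2 <- family_means(ph, ped, genotyped = c("1", "2", "3", "4"))
  expect_equal(fam2$mean[fam2$sire == "1"], mean(2:5))
})

test_that("family-mean variance matches the Mendelian-sampling weighting", {
  # var(family mean - midparent TBV - hatch) should be 0.5 s2a + s2e / n
  ratios <- vapply(1:10, function(s) {
    pop <- simulate_population(small_config(
      seed = 900 + s, n_founders = 300, n_generations = 1, n_sires = 75,
      n_dams = 75, n_progeny_per_generation = 300, h2 = 0.5,
      n_hatches_per_generation = 1, n_snp = 300, missing_rate = 0,
      burn_in_ne = 200, burn_in_generations = 20,
      genotype_progeny_fraction = 0))
    ped <- pop$pedigree
    ph <- pop$phenotypes
    ph$value <- ph$value - pop$arch$hatch_effects[ph$hatch]
    par_ids <- as.character(unique(c(ped$sire, ped$dam)))
    par_ids <- par_ids[!is.na(par_ids)]
    fam <- family_means(ph, ped, genotyped = par_ids)
    mid <- 0.5 * (pop$tbv[fam$sire] + pop$tbv[fam$dam])
    n <- fam$n[1]
    s2a <- pop$arch$sigma2_a
    s2e <- s2a * (1 - 0.5) / 0.5
    var(fam$mean - mid) / ((0.5 * s2a + s2e) / n)
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 1), 0.1)
})
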