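#' Replicated pedigree-accuracy decay study
#'
#' Simulates replicate closed populations under random selection, trains a
#' pedigree animal model once on all data accumulated through
#' `train_upto`, validates on each subsequent generation, and summarizes
#' how fast accuracy decays.  Because relationships halve at each meiosis,
#' the squared ratio of accuracies in consecutive validation generations
#' is expected to be 0.5.
#'
#' Accuracies are first averaged over replicates within each validation
#' generation; the decay statistic is then the mean over lags of the
#' squared consecutive-generation ratio of those means.  Averaging before
#' taking ratios avoids the upward bias a ratio of two noisy per-replicate
#' correlations would carry.
#'
#' @param n_replicates Number of simulated populations (default 30).
#' @param seed Base seed; replicate r uses `seed + r`.
#' @param config A [sim_config()]; the default is a 6-generation
#'   population (founders plus five offspring generations) with 20 sires
#'   and 100 dams per generation, 400 phenotyped offspring per generation,
#'   h2 = 0.4 and random parent selection.
#' @param train_upto Last training generation (default 1).
#' @return list: `records` (all accuracy rows), `mean_accuracy` (per
#'   validation generation), `squared_ratios` (per lag) and
#'   `mean_squared_ratio`.
#' @export
pblup_decay_study <- function(n_replicates = 30, seed = 1,
                              config = decay_study_config(seed = 1),
                              train_upto = 1) {
  vc0 <- varcomp(config$sigma2_a,
                 config$sigma2_a * (1 - config$h2) / config$h2)
  recs <- list()
  for (r in seq_len(n_replicates)) {
    cfg <- config
    cfg$seed <- as.integer(seed + r)
    pop <- simulate_population(cfg)
    res <- run_design(pop, methods = "pblup", mode = "persist",
                      varcomp_policy = "fixed", vc = vc0,
                      train_upto = train_upto)
    res$replicate <- r
    recs[[r]] <- res
  }
  records <- do.call(rbind, recs)
  mean_acc <- tapply(records$accuracy, records$validation_generation,
                     mean, na.rm = TRUE)
  gen <- as.integer(names(mean_acc))
  ord <- order(gen)
  mean_acc <- mean_acc[ord]
  ratios2 <- (mean_acc[-1] / mean_acc[-length(mean_acc)])^2
  list(records = records, mean_accuracy = mean_acc,
       squared_ratios = ratios2, mean_squared_ratio = mean(ratios2))
}

#' Default configuration of the decay study
#'
#' @param seed Seed passed through to [sim_config()].
#' @return A [sim_config()] for a 6-generation population: 400 founders,
#'   five offspring generations of 400 phenotyped progeny from 20 sires
#'   and 100 dams, random selection, h2 = 0.4, all progeny genotyped (so
#'   every phenotyped offspring can serve in validation), 500 SNP on 10
#'   chromosomes.  The burn-in population is several times larger than the
#'   founder sample so that founders are effectively unrelated, as the
#'   pedigree model assumes; the square-root-one-half expectation is a
#'   statement about correctly specified pedigree relationships.
#' @export
decay_study_config <- function(seed = 1) {
  sim_config(n_founders = 400, n_generations = 5, n_sires = 20,
             n_dams = 100, n_progeny_per_generation = 400,
             n_snp = 500, n_chromosomes = 10, pi = 0.95, h2 = 0.4,
             selection_mode = "random", genotype_progeny_fraction = 1,
             burn_in_generations = 100, burn_in_ne = 500, seed = seed)
}

#' Single-lineage chain pedigree
#'
#' Founder, its child, grandchild, and so on, each produced with a new
#' unrelated non-inbred mate.  On this pedigree the numerator relationship
#' between the founder and the generation-g descendant is exactly `0.5^g`:
#' a 50% reduction per meiosis.
#'
#' @param n_generations Number of descent steps.
#' @return list: `pedigree` (the chain plus mates) and `lineage` (ids of
#'   founder and direct-line descendants, in order).
#' @examples
#' ch <- chain_pedigree(3)
#' build_A(ch$pedigree)[1, as.character(ch$lineage)]
#' @export
chain_pedigree <- function(n_generations) {
  stopifnot(n_generations >= 1)
  ## id 1 = founder (male); each step adds a female mate and a male child
  ped <- data.frame(id = 1L, sire = NA_integer_, dam = NA_integer_,
                    generation = 0L, sex = "M", hatch = "g0_h1",
                    stringsAsFactors = FALSE)
  lineage <- 1L
  cur <- 1L
  next_id <- 2L
  for (g in seq_len(n_generations)) {
    mate <- next_id; child <- next_id + 1L
    ped <- rbind(ped,
      data.frame(id = mate, sire = NA_integer_, dam = NA_integer_,
                 generation = g - 1L, sex = "F",
                 hatch = sprintf("g%d_h1", g - 1L), stringsAsFactors = FALSE),
      data.frame(id = child, sire = cur, dam = mate, generation = g,
                 sex = "M", hatch = sprintf("g%d_h1", g),
                 stringsAsFactors = FALSE))
    lineage <- c(lineage, child)
    cur <- child
    next_id <- next_id + 2L
  }
  list(pedigree = ped, lineage = lineage)
}
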