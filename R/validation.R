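#' Accuracy of estimated breeding values in a validation set
#'
#' Accuracy is the Pearson correlation between EBV and the hatch-corrected
#' phenotype of the validation individuals, divided by the square root of
#' the heritability (the correlation an EBV would have with the phenotype
#' if it were a perfect predictor of the breeding value).
#'
#' @param ebv Named vector of (G)EBV.
#' @param phenotypes Corrected validation records (`id`, `value`); the
#'   statistic is computed over the intersection of ids.
#' @param h2 Heritability used in the denominator; must be positive.
#' @return list `correlation`, `accuracy`, `n`, `reason` (`NA` unless the
#'   correlation is undefined, e.g. `"zero variance"`).
#' @examples
#' compute_accuracy(c(a = 1, b = 2, c = 3),
#'                  data.frame(id = c("a", "b", "c"), value = c(1, 3, 2)),
#'                  h2 = 0.25)
#' @export
compute_accuracy <- function(ebv, phenotypes, h2) {
  if (h2 <= 0) stop("h2 must be positive")
  ids <- intersect(names(ebv), as.character(phenotypes$id))
  if (length(ids) < 2)
    stop("need at least 2 validation individuals with both EBV and phenotype")
  x <- ebv[ids]
  y <- phenotypes$value[match(ids, as.character(phenotypes$id))]
  if (sd(x) == 0 || sd(y) == 0)
    return(list(correlation = NA_real_, accuracy = NA_real_,
                n = length(ids), reason = "zero variance"))
  r <- cor(x, y)
  list(correlation = r, accuracy = r / sqrt(h2), n = length(ids),
       reason = NA_character_)
}

#' Expected decay of pedigree-driven accuracy
#'
#' Pedigree relationships in outbred populations halve at each meiosis, so
#' accuracy that rests only on relationships is expected to decline by
#' sqrt(0.5) per generation of separation between training and validation:
#' `base_accuracy * 0.5^(lag / 2)`.
#'
#' @param base_accuracy Accuracy at lag 0.
#' @param lag Generations separating validation from the last training
#'   generation; must be non-negative.
#' @return Expected accuracy (vectorized over `lag`).
#' @examples
#' expected_decay(0.6, 0:3)
#' @export
expected_decay <- function(base_accuracy, lag) {
  if (any(lag < 0)) stop("lag must be non-negative")
  base_accuracy * 0.5^(lag / 2)
}

#' Run a cross-generation training/validation design
#'
#' Orchestrates the two designs used to study accuracy and its
#' persistence.  `mode = "accumulate"` trains on all data accumulated up
#' to each generation `g` and validates on the genotyped progeny of
#' generation `g + 1` that have their own phenotypes (accuracy in
#' progeny).  `mode = "persist"` trains once on data accumulated through
#' `train_upto` and validates on each subsequent generation (persistence
#' of accuracy).  Validation phenotypes never enter any training fit; the
#' heritability in the accuracy denominator and the hatch corrections of
#' validation phenotypes come from the single-trait pedigree model on all
#' data, which affects only the evaluation statistic.
#'
#' @param pop A `gs_population` (or an equivalent list with `pedigree`,
#'   `genotypes`, `phenotypes`).
#' @param methods Subset of `"pblup"`, `"gblup"`, `"bayesA"`,
#'   `"bayesCpi"`.
#' @param mode `"accumulate"` or `"persist"`.
#' @param varcomp_policy `"fixed"` uses `vc` everywhere (including the
#'   accuracy denominator); `"reml"` re-estimates components by EM-REML on
#'   each training window and on the full data.
#' @param vc A [varcomp()] (required for `"fixed"`, optional starting point
#'   otherwise).
#' @param train_upto Last training generation for `mode = "persist"`
#'   (default 1).
#' @param mcmc [mcmc_config()] for the Bayesian methods.
#' @param thresholds [qc_thresholds()] applied to SNP and phenotypes before
#'   any fit; `NULL` skips QC.
#' @param blend Identity blend for the genomic relationship inverse.
#' @return data.frame of accuracy records: `method`, `trait`,
#'   `training_upto`, `validation_generation`, `n_validation`,
#'   `correlation`, `accuracy`, `h2_used`, with an `audit` attribute
#'   recording training/validation id sets per window.
#' @export
run_design <- function(pop, methods = c("pblup", "gblup"),
                       mode = c("accumulate", "persist"),
                       varcomp_policy = c("fixed", "reml"), vc = NULL,
                       train_upto = 1, mcmc = NULL,
                       thresholds = qc_thresholds(), blend = 0.01) {
  mode <- match.arg(mode)
  varcomp_policy <- match.arg(varcomp_policy)
  methods <- match.arg(tolower(methods),
                       c("pblup", "gblup", "bayesa", "bayescpi"),
                       several.ok = TRUE)
  if (varcomp_policy == "fixed" && is.null(vc))
    stop("varcomp_policy = 'fixed' requires `vc`")
  if (is.null(mcmc)) mcmc <- mcmc_config(chain_length = 4000, burn_in = 1000,
                                         thin = 2, seed = 1L)
  ped <- pop$pedigree
  geno <- pop$genotypes
  pheno <- pop$phenotypes

  ## --- quality control ------------------------------------------------------
  if (!is.null(thresholds)) {
    geno <- apply_snp_qc(geno, ped, thresholds)$genotypes
    pheno <- filter_outlier_phenotypes(pheno, thresholds$outlier_sd)$phenotypes
  }
  freqs <- snp_freqs(geno)
  geno <- impute_missing(geno, freqs)

  gens <- sort(unique(pheno$generation))
  G <- max(gens)
  A <- if (varcomp_policy == "reml") build_A(ped) else NULL

  ## --- full-data reference: h2 and hatch corrections -----------------------
  vc_full <- if (varcomp_policy == "reml") em_reml(pheno, A) else vc
  fit_full <- fit_pblup(pheno, ped, vc_full)
  corrected <- precorrect_phenotypes(pheno, fit_full)
  h2_full <- vc_full$h2

  windows <- if (mode == "accumulate") {
    lapply(gens[gens < G], function(g) list(train = g, valid = g + 1))
  } else {
    lapply(setdiff(gens[gens > train_upto], train_upto), function(v)
      list(train = train_upto, valid = v))
  }

  genotyped <- rownames(geno)
  out <- list()
  audit <- list()
  for (win in windows) {
    train <- pheno[pheno$generation <= win$train, , drop = FALSE]
    val_ids <- intersect(
      as.character(pheno$id[pheno$generation == win$valid]), genotyped)
    if (nrow(train) < 2 || length(val_ids) < 2) next
    stopifnot(length(intersect(as.character(train$id), val_ids)) == 0)
    audit[[length(audit) + 1]] <- list(
      train = win$train, valid = win$valid,
      training_ids = as.character(train$id), validation_ids = val_ids)

    vc_w <- if (varcomp_policy == "reml") em_reml(train, A) else vc
    val_pheno <- corrected[corrected$generation == win$valid &
                             as.character(corrected$id) %in% val_ids, ]

    fit_p <- NULL
    if (any(methods %in% c("pblup", "bayesa", "bayescpi")))
      fit_p <- fit_pblup(train, ped, vc_w)

    for (meth in methods) {
      ebv <- switch(meth,
        pblup = fit_p$ebv,
        gblup = fit_gblup(train, geno, ped, vc_w, freqs, blend)$ebv,
        bayesa = ,
        bayescpi = {
          ctr <- precorrect_phenotypes(train, fit_p)
          recs <- build_wgr_records(ctr, ped, genotyped, vc_w)
          fitter <- if (meth == "bayesa") fit_bayesA else fit_bayesCpi
          post <- fitter(recs, geno, vc_w, mcmc, freqs)
          post$gebv
        })
      acc <- compute_accuracy(ebv, val_pheno, h2_full)
      out[[length(out) + 1]] <- data.frame(
        method = c(pblup = "PBLUP", gblup = "GBLUP", bayesa = "BayesA",
                   bayescpi = "BayesCpi")[meth],
        trait = "trait1", training_upto = win$train,
        validation_generation = win$valid, n_validation = acc$n,
        correlation = acc$correlation, accuracy = acc$accuracy,
        h2_used = h2_full, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "audit") <- audit
  res
}
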