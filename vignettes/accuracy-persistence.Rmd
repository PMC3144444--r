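---
title: "Persistence of genomic prediction accuracy: models, simulator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Persistence of genomic prediction accuracy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The question

In a closed breeding population, how fast does the predictive accuracy of
estimated breeding values erode as validation animals become more remote
from the training data?  Pedigree relationships between an outbred ancestor
and its descendants halve at every meiosis, so accuracy that rests only on
pedigree is expected to decline by a factor of $\sqrt{0.5}$ per generation
of separation.  Marker-based predictions capture, in addition to pedigree
relationships, associations between SNP and QTL through linkage
disequilibrium (LD) and linkage, which erode more slowly; their accuracy
should therefore be more *persistent*.  This package provides every piece
needed to study that question end to end on simulated data, or on a user's
own pedigree/phenotype/genotype files: a population simulator, the editing
rules, the relationship matrices, four estimation methods, the two
training/validation designs, and the meta-model relating accuracy to trait
architecture.

# Models

## Animal models

The single-trait animal model is
$$ y = Xb + Za + e, \qquad a \sim N(0, \sigma^2_a K), \quad
   e \sim N(0, \sigma^2_e I), $$
with $X$ the incidence of hatch nested within generation (cell-means
coding, so each fixed solution is directly a hatch-level effect), and $K$
either the pedigree numerator relationship matrix $A$ (PBLUP, `fit_pblup()`)
or the genomic relationship matrix (GBLUP).  $A$ is built by the tabular
recursion, its sparse inverse by Henderson's rules with inbreeding
coefficients taken from the tabular diagonal, and
$G = ZZ^\top / 2\sum_k p_k(1-p_k)$ from genotypes centered at twice the
allele frequencies of the pooled genotyped set (VanRaden's first method).
Mixed-model equations are solved sparsely ($A^{-1}\lambda$,
$\lambda = \sigma^2_e/\sigma^2_a$).

GBLUP is implemented as a *reduced* animal model (`fit_gblup()`): breeding
values are fitted only for genotyped animals.  A record on a non-genotyped
individual whose sire and dam are both genotyped enters through the mean of
its parents' breeding values, with residual variance inflated by the
Mendelian-sampling term $0.5\sigma^2_a$ (parents assumed non-inbred).  This
is the device that lets phenotypes of non-genotyped progeny of genotyped
parents contribute to training.

## Variance components

`em_reml()` estimates $(\sigma^2_a, \sigma^2_e)$ by EM-REML.  The animal
model is first marginalized to the phenotyped individuals (the breeding
values of unphenotyped relatives integrate out, leaving
$K$ = relationship submatrix among records).  Projecting out the fixed
effects with an orthonormal complement basis $B$ and eigendecomposing
$B^\top K B$ once makes every EM iteration $O(n)$; the updates are the
standard EM-REML ones, so the restricted likelihood is non-decreasing over
iterations (a property the test suite asserts).  Convergence is declared at
a relative change below $10^{-8}$ in both components, with a 500-iteration
cap; non-convergence is flagged, not thrown.

## Marker-effect models

`fit_bayesA()` and `fit_bayesCpi()` are single-site Gibbs samplers for
$$ y_i = \mu + \sum_k z_{ik}\alpha_k + e_i,\qquad
   e_i \sim N(0, w_i\,\sigma^2_e), $$
on pre-corrected records ($y$ minus the PBLUP hatch solutions,
`precorrect_phenotypes()`), with $z$ the centered genotype (or, for a
family-mean record, the mean of the parents' centered genotypes).  BayesA
gives every SNP its own variance with a scaled-inverse-$\chi^2(\nu_a, S)$
prior; BayesC$\pi$ fits a per-SNP inclusion indicator, a common effect
variance with the same prior form, and samples $\pi$ (the proportion of
null SNP) from its Beta full conditional under a uniform prior,
$\mathrm{Beta}(m - m_+ + 1,\; m_+ + 1)$ with $m_+$ the number of SNP
currently in the model.  Defaults are $\nu_a = 4.2$, a 160,000-iteration
chain with 50,000 burn-in, thinning 10.  The residual is updated after
every locus, so a sweep costs $O(nm)$; samplers are compiled and use R's
RNG, so chains are bit-reproducible under a seed.

The prior scale is chosen so the prior mean of the effect variance matches
the per-locus share of the additive variance,
$$ S = \frac{\nu_a - 2}{\nu_a}\,
       \frac{\sigma^2_a}{(1-\pi_0)\sum_k 2p_k(1-p_k)}, $$
with $\pi_0 = 0.95$ for BayesC$\pi$ and $\pi_0 = 0$ for BayesA, and can be
overridden (`scale_override`).  Zero-variance design columns (monomorphic
SNP that escaped QC) are confounded with the intercept; they are frozen at
zero and flagged rather than sampled.

### Family means and their weights

`family_means()` averages the pre-corrected records of each full-sib family
of non-genotyped progeny with two genotyped parents.  Because every sib
carries its own independent Mendelian-sampling deviation (variance
$0.5\sigma^2_a$ for full sibs of non-inbred parents) and its own residual,
the variance of a mean of $n$ sib records around the parent average is
$$ \mathrm{var}(\bar y_{fam}) = \frac{0.5\sigma^2_a + \sigma^2_e}{n}, $$
which is the relative weight attached by `build_wgr_records()`.  A
Monte-Carlo check (family means minus mid-parent true breeding values over
replicate simulations) sits within 10% of this formula; an alternative
sometimes written, $0.5\sigma^2_a + \sigma^2_e/n$, treats the
Mendelian-sampling deviation as shared by the whole family and overstates
the variance several-fold for families of moderate size.  Weights are a
`weight` column on the records, so any other scheme can be supplied.

## Accuracy and the two designs

Accuracy (`compute_accuracy()`) is the Pearson correlation of (G)EBV with
the hatch-corrected phenotype of validation animals, divided by
$\sqrt{h^2}$.  `run_design()` orchestrates:

* **accumulate** — for each generation $g$, train on all data through $g$,
  validate on the genotyped progeny of generation $g+1$ that have their own
  records (accuracy in progeny, growing training sets);
* **persist** — train once on data through `train_upto` (default 1) and
  validate on every later generation (persistence of accuracy).

Validation phenotypes never enter any training fit; an audit attribute
records the training and validation id sets of every window, and the suite
asserts their intersection is empty.  The heritability in the denominator
and the hatch corrections of validation phenotypes are taken from the
single-trait pedigree model on *all* data: this is the one permitted use of
full-data information, and it affects only the evaluation statistic, never
training.  Whether variance components are re-estimated by REML per
training window or fixed is a policy switch (`varcomp_policy`); the package
re-estimates when asked, and uses supplied components otherwise.
`expected_decay()` supplies the $0.5^{\mathrm{lag}/2}$ reference curve for
overlay.

## The accuracy meta-model

`fit_accuracy_model()` fits, by ordinary least squares with $t$-based
p-values,
$$ \text{acc}_{ijk} = b_0 + b_1 h^2_k + b_2 \pi_k + b_3 j + b_4 j^2
   + b_5\, h^2_k j + b_6\, \pi_k j + \varepsilon_{ijk}, $$
seven coefficients in all, for method $i$, validation generation $j$ and
trait $k$.  Dropping all $\pi$ terms (equivalent to fitting the average
$\pi$) is an option, since most methods do not estimate $\pi$; when $\pi$
terms are present, accuracies from pedigree-based methods are excluded,
because they are not expected to depend on $\pi$.  Whether method should
enter as a factor is genuinely open (no method coefficient is reported in
the motivating analyses); it is available via `method_factor` and off by
default.  `ls_means()` evaluates the fit on a user grid (say,
$\pi \in \{0.88, 0.99\}$ at $h^2 = 0.5$ over generations), holding every
model term not pinned by the grid at its data mean — with the consequence,
used as a test oracle, that the no-grid prediction equals the grand mean of
fitted values exactly.

# The simulator

`simulate_population()` builds a closed line by gene dropping:

* **Founder LD** comes from a random-mating burn-in population of effective
  size `burn_in_ne` (default 100) run for `burn_in_generations` (default
  100) from random haplotypes; founders are drawn from its final
  generation.  This reproduces the LD-plus-linkage information structure
  that the persistence argument requires without external haplotype data.
  The real line's effective size and LD extent are unknown, so these are
  tunable rather than calibrated parameters.
* **Genome**: 10 chromosomes of 1 Morgan by default, SNP equally spaced,
  Haldane mapping (Poisson crossovers, no interference), no mutation, no
  dominance or epistasis.
* **Structure**: discrete generations; each generation selects `n_sires`
  (default 60) and `n_dams` (default 310) from the previous one — at
  random, on own phenotype, or on externally supplied scores — each dam is
  mated to one sire, and progeny are assigned to dams cyclically, giving
  full-sib families; two hatches per generation by default, with effects
  drawn $N(0, 0.25\sigma^2_e)$ (no magnitudes are dictated by data, so
  this is a package choice).  Parents are genotyped; a configurable
  fraction of progeny is genotyped too; genotype calls are masked missing
  at 1% by default so QC has something to do.
* **Trait**: `round((1 - pi) * n_snp)` QTL drawn among segregating SNP,
  normal effects rescaled so the founder additive variance equals
  $\sigma^2_a$ exactly (the QTL count is deterministic so examples are
  exact); phenotype = hatch effect + true breeding value +
  $N(0, \sigma^2_a(1-h^2)/h^2)$.

What the simulator does *not* emulate: overlapping generations, selection
on many traits at once, genotyping-error structure, non-additive genetic
variance, and real-genome LD idiosyncrasies.  Passing tests therefore show
that the estimation and validation machinery behaves correctly under the
stated generative assumptions, not that any particular real population
will show the same accuracy levels.

Two behaviours of the simulator matter when interpreting parameter
recovery.  First, founders drawn from a small burn-in population are
related and slightly inbred while the pedigree treats them as unrelated
founders, so REML estimates from such data drift above the nominal $h^2$;
recovery experiments therefore use a burn-in population several times
larger than the founder sample.  Second, with few QTL the realized founder
additive variance varies around its target because of sampled LD between
QTL; recovery experiments use polygenic architectures, where the
rescaling concentrates tightly.

# Quality control

`apply_snp_qc()` retains SNP with minor allele frequency strictly above
0.025, missing-call proportion strictly below 0.05, and parent-offspring
opposing-homozygote rate strictly below 0.05 — all three thresholds as
strict inequalities, frequencies computed over all genotyped individuals
with missing cells excluded.  The mismatch rule is per SNP (it is a panel
filter): opposing homozygote pairs over genotyped parent-offspring pairs
with both calls present; with no genotyped pairs the rule is skipped with
a warning flag.  No genotype-quality-score editing is performed.
`filter_outlier_phenotypes()` removes records more than three standard
deviations from their within-hatch (nested in generation) mean; groups
with fewer than two records or zero spread pass untouched.
`impute_missing()` mean-imputes a missing call as $2p_k$ — the minimal
treatment that makes the matrix algebra well defined; no phasing or
model-based imputation is attempted.

# Numerical choices

* $G$ built with within-sample centering frequencies is exactly singular
  (the ones vector lies in its null space), and duplicated genotypes or
  $n > m$ make it worse; before inversion the package blends
  $G^* = 0.99\,G + 0.01 I$ (the `blend` argument; set it to 0 for exact
  algebraic comparisons on well-conditioned instances).
* Pedigrees are ordered topologically (parents before offspring, ties by
  id); cycles are detected and rejected.
* EM-REML eigenvalues are clipped at zero; the marginalized likelihood is
  evaluated in the rotated basis, so iteration cost does not grow with
  pedigree depth.
* Truncation selection breaks ties by id order, so selections are
  reproducible even with tied scores.
* Degenerate accuracy inputs (constant EBV or phenotypes) are returned as
  missing with a reason code and excluded from averages, never silently
  zeroed.

# Problem sizes used by the shipped experiments

The packaged studies are sized for a desk machine.  The decay study
(`pblup_decay_study()`) runs 30 replicates of a 6-generation population
(400 founders; five offspring generations of 400 phenotyped progeny from
20 sires and 100 dams; $h^2 = 0.4$; random selection; 500 SNP), trains on
generations $\le 1$ and validates on generations 2–5.  Its founders are
drawn from a burn-in population larger than the founder sample
(`burn_in_ne = 500`), so they are effectively unrelated, as the pedigree
model assumes — the $\sqrt{0.5}$ expectation is a statement about
correctly specified pedigree relationships, and founders with substantial
hidden relatedness blur it.  Accuracies are
averaged over replicates within each validation generation *before* taking
consecutive-generation ratios: a ratio of two per-replicate correlations
with means this small carries an upward bias of order the squared
coefficient of variation of its denominator, which the
average-then-ratio order avoids.  The squared ratio of the replicate-mean
accuracies then sits at $0.5$, the relationship-halving expectation, and
since the same $\sqrt{h^2}$ divides numerator and denominator the statistic
is invariant to the heritability used in the accuracy denominator.
Recovery experiments use $n = 2000$ records for REML (20 replicates) and
$n = 400$–$800$ individuals with 500–1000 SNP for the samplers (10
replicates, chains of 4–5 thousand sweeps), and the persistence/
accumulation comparison uses twelve replicates of a 300-founder,
5-generation population with 800 SNP at $\pi = 0.95$, $h^2 = 0.5$.

# Known limitations

* Single trait at a time; no bivariate or repeated-records models.
* The reduced animal model assumes non-inbred genotyped parents when it
  inflates residuals by $0.5\sigma^2_a$; with appreciable parental
  inbreeding the weight is mildly misspecified.
* Mean imputation ignores LD; with the default 1% missingness this is
  immaterial, with heavy missingness it is not.
* The $\pi$ estimate from BayesC$\pi$ is prior-sensitive in small data
  (polygenic architectures at modest $n$ yield $\hat\pi$ well above the
  generating value, though the *ordering* across architectures is
  reliable, which is what the meta-model consumes).
* `selection_mode = "ebv"` expects scores supplied by the caller (e.g.
  from a previous `fit_pblup()`); the simulator deliberately does not fit
  models inside the generation loop.
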