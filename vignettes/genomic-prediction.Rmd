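---
title: "Genomic prediction of a binary trait under the liability threshold model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic prediction of a binary trait under the liability threshold model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

`gprisk` implements a complete pipeline for predicting a binary,
complex-genetic disease phenotype — the motivating case is anterior cruciate
ligament (ACL) rupture in the Labrador Retriever — from SNP genotypes and a
small set of clinical covariates (body weight, sex, neuter status). The
pipeline covers cohort simulation, marker quality control, LD pruning,
within-fold feature selection, five Bayesian whole-genome probit
regressions, four classification learners, two ensemble layers, and
repeated cross-validated AUC scoring, together with the analytic ceiling on
AUC implied by heritability and prevalence.

## The liability threshold model

All of the package's generative and analytic reasoning is on the liability
scale. Each individual carries a latent liability

$$ l_i = g_i + x_i'b + \varepsilon_i, \qquad
   g_i = \sum_j m_{ij}\alpha_j, \qquad \varepsilon_i \sim N(0, \sigma^2_e), $$

where $m_{ij} \in \{0,1,2\}$ counts minor alleles, and the individual is a
case when $l_i$ exceeds a threshold fixed by the prevalence $K$. The
heritability $h^2$ is the liability-scale variance fraction of $g$.

Two consequences the package exposes directly:

* **`max_liability_auc(K, rho2)`** — for a predictor explaining a fraction
  $\rho^2$ of liability variance, the maximum attainable AUC is
  $\Phi\!\big((i - v)\rho^2 \big/
  \sqrt{\rho^2[(1-\rho^2 i(i-T)) + (1-\rho^2 v(v-T))]}\big)$ with
  $T = \Phi^{-1}(1-K)$, $z = \phi(T)$, $i = z/K$, $v = -z/(1-K)$. At the
  Labrador Retriever prevalence $K = 0.0579$ this gives 0.86 for a profile
  capturing all genetic variance at $h^2 = 0.4$, and 0.69 for one
  capturing a quarter of it — the reference points against which any
  empirical AUC from this kind of cohort should be read.
* **`simulate_cohort()`** — cohorts generated at a given $h^2$ and $K$
  reproduce that bound empirically: at $n = 50{,}000$ the Mann–Whitney AUC
  of the true genetic score is within Monte-Carlo error of the analytic
  value, which is the package's primary end-to-end calibration.

## The synthetic cohort generator

`simulate_cohort()` is first-class, tested code: every downstream stage is
exercised against cohorts whose generative truth is known.

**Genotypes.** SNPs live in haplotype blocks (default 20 SNPs; at one SNP
per kb this matches the ~20 kb average block of the Labrador Retriever,
a breed with comparatively short LD). Each block has a pool of 20 founder
haplotypes whose alleles follow a first-order Markov copying process along
the block; individuals draw two haplotypes per block from the pool, and
each copied allele is redrawn at the block allele frequency with
probability 0.02 (a "mutation" that decorrelates). The copy-persistence
probability is set to $r/(1-m)^2$ so the adjacent-SNP dosage correlation
approximates the target `within_block_r` (default 0.7), while cross-block
correlation is at the $1/\sqrt{n}$ noise floor. A single frequency per
block (drawn from `maf_range`) keeps marginal allele frequencies coherent
with the copying process. This produces realistically blocky LD without
coalescent machinery; it does *not* produce recombination gradients,
allele-frequency spectra, or pedigree/breed structure, so passing tests
say nothing about confounding by relatedness in real cohorts.

**Liability and phenotype.** Causal SNPs are drawn uniformly; their effects
are rescaled so the sample variance of the genetic score is exactly
$h^2$ (default 0.4, inside the published 0.3–0.5 range for canine ACL
rupture). The covariate score is centred, and residual noise completes a
total liability variance of 1; a configuration whose $h^2$ plus covariate
variance exceeds 1 is refused. Cases are samples above the *realized*
$(1-K)$ liability quantile rather than the theoretical Normal quantile, so
finite cohorts match the target prevalence exactly. Missing genotype calls
are masked only after the genetic score is formed.

**Covariates.** Sex is Bernoulli(0.5); neuter status Bernoulli(0.7);
weight is Normal with female mean 30 kg, male mean 34 kg, SD 4 kg —
Labrador-plausible constants, configurable. Default liability effects are
`weight = 0.08` per kg, `sex = 0.25`, `neuter = 0.45`, which together
contribute ≈ 0.16 of liability variance; through the AUC formula that
corresponds to a covariate-only discrimination in the low 0.7s, the
regime reported for clinical risk factors of this disease.

**Prevalence vs composition.** The population prevalence 0.0579 enters the
analytic bound and the large-sample calibration. The CV experiments in
the test suite instead simulate cohorts with ~40% cases, matching the
case-control *sample composition* of a realistic genotyping study
(247 cases / 375 controls); at a few hundred samples a 5.8% case rate
would leave 2–3 cases per fold and make fold-level AUCs meaningless.

## Quality control and LD pruning

`apply_qc()` removes SNPs in a fixed order — call rate $\le$ 0.95, then
MAF $\le$ 0.05, then exact Hardy–Weinberg $p < 10^{-7}$ — so every removal
is attributed to exactly one filter and the operation is idempotent. Two
readings deserve note: the MAF exclusion is *inclusive* (a SNP at exactly
0.05 is removed), and the HWE test is the two-sided exact test on the
conditional distribution of the heterozygote count, without mid-p
correction. The test suite checks the exact test against an independent
recurrence-based enumeration for every genotype configuration with up to
200 samples.

`ld_prune()` interprets "window of 50 SNPs with overlap of 5" as the
standard `--indep-pairwise 50 5 0.7` idiom: a 50-SNP window advanced 5
SNPs at a time within each chromosome, removing the lower-MAF member of
the worst $r^2 > 0.7$ pair (ties: the later position) until no pair
remains. The literal alternative — windows overlapping by 5 SNPs, i.e. a
step of 45 — was considered and rejected because the stated parameters are
verbatim the signature of the pruning tool they originate from. $r^2$ is
computed on mean-imputed dosages. Pruning is performed once on the full
dataset before fold splitting (as in the motivating study); the
within-fold alternative is a flag away since pruning is unsupervised with
respect to the phenotype and leaks nothing label-related.

**Missing genotypes** are retained in storage and mean-imputed per SNP at
model-fitting time, always with training-fold means; no imputation rule is
part of the data format itself.

## Feature selection inside the folds

Two univariate filters rank SNPs using training samples only:

* `"gwas"` — an EMMAX-style linear mixed model scan: the 0/1 phenotype is
  treated as quantitative (the filter is a ranking device, and at the
  ranking level the linear and logistic scans are nearly monotone in each
  other); variance components are estimated once per fold by REML through
  the eigendecomposition of the VanRaden GRM built from the fold's
  training genotypes, and each SNP gets a Wald t-test in the rotated,
  whitened regression. With an identity kinship this reduces exactly to
  the OLS t-test, which the tests assert to $10^{-6}$. Covariates are
  included in the ranking model when the downstream model uses them
  (whether the original analysis did so is unstated; it is switchable).
* `"meandiff"` — absolute case/control allele-frequency difference,
  $|f_{\text{case}} - f_{\text{ctrl}}|$ with
  $f = \sum m_{ij} / (2 n_{\text{nonmissing}})$.

Ties in either score break on lexicographic SNP id so rankings are
reproducible across platforms. `select_top_k()` takes the best $k$; the
grids used in practice run from 5 to 15,000 SNPs.

The test suite demonstrates *why* selection must be fold-internal: on a
zero-heritability cohort, fold-internal selection calibrates to AUC 0.5,
while selecting the top-5 mean-difference SNPs on the complete data before
CV inflates the apparent AUC well above 0.55. One measurement subtlety:
fold-level AUCs within one CV run share labels and overlapping training
sets, so a single cohort draw carries roughly ±0.04 of correlated noise in
the mean AUC; the calibration check therefore averages over replicate
cohorts rather than trusting one draw.

## The Bayesian probit alphabet

`bayes_probit()` is the package's core estimator: a Gibbs sampler for
$P(y_i = 1) = \Phi(\mu + x_i'b + \textstyle\sum_j m_{ij}\alpha_j)$ using
the classical latent-liability augmentation (truncated-Normal draws for
$l_i$, sampled tail-robustly through log-scale inverse CDFs). Two
identification choices are fixed rather than sampled: the residual
variance is 1 (it is not likelihood-identified in a probit) and the
case/control threshold is 0 with a free intercept (threshold and intercept
are not jointly identified). The linear predictor's residual term and the
latent-variable residual are one and the same unit-variance probit
residual.

The five members differ only in the marker-effect prior: BRR (Gaussian,
common variance), Bayesian LASSO (Laplace via exponential scale mixture,
Gamma hyperprior on $\lambda^2$), BayesA (scaled-t via per-marker
scaled-inverse-$\chi^2$ variances), BayesB (spike at zero + scaled-t slab),
BayesCpi (spike + common-variance Gaussian slab). In the mixture models
$\pi$ is the probability a marker has *no* effect, with prior
Beta$(P_0\pi_0, P_0(1-\pi_0))$ at the weakly-informative defaults
$\pi_0 = 0.5$, $P_0 = 10$; its Beta full conditional is sampled each
sweep.

Hyperprior scales follow the usual default rules: scaled-t components use
5 degrees of freedom with the scale solved so the markers' prior variance
contribution matches an `R2` heuristic of 0.5 against the variance carried
by the centred dosage columns (scaled by the expected inclusion fraction
in the mixture models); the LASSO $\lambda^2$ gets a Gamma prior whose
mode matches the same heuristic. Dosages are centred (not scaled) before
fitting — the intercept absorbs the mean, and prediction re-applies the
training centres — but left unscaled so an effect keeps its per-allele
meaning.

Chain defaults are 52,000 iterations with 6,000 burn-in; thinning (default
5) is this package's addition for storage economy. The test suite and the
examples below use far shorter chains — a few hundred to a few thousand
iterations — because the latent-probit Gibbs sampler mixes quickly at
these problem sizes; the defaults remain the recorded full-length values.
Correctness is anchored two ways: an intercept-only fit recovers the case
fraction through $\Phi(\hat\mu)$, and a single-SNP fit with the slab
variance held fixed (the `fixed_marker_var` validation knob) matches a 2-D
quadrature of the exact posterior to ±0.05. On sparse simulated
architectures the mixture models place visibly higher inclusion
probability on causal than on non-causal SNPs; on polygenic cohorts all
five members score statistically indistinguishable CV AUCs — both patterns
are asserted in the acceptance tests.

## Classifiers

Four learners consume the selected SNPs, optionally with covariates
appended (sex and neuter status as 0/1, weight standardized by training
statistics):

* **wRF** — weighted subspace random forest: candidate features at each
  split are sampled with probabilities proportional to the absolute
  point-biserial correlation of each feature with the class (floored at
  $10^{-6}$, normalized), so informative features enter tree subspaces
  more often. This is realised through the forest backend's weighted
  candidate-variable sampling at the node level rather than drawing one
  subspace per tree; the node-level variant preserves the method's idea,
  runs on a mature forest implementation, and reduces to an ordinary
  random forest under uniform weights (an asserted invariant). 1000 trees,
  $\lfloor\sqrt{p}\rfloor$ candidates per split. The weighting statistic
  itself (correlation vs $\chi^2$) is a package choice; correlation is the
  default.
* **GBT** — gradient boosted trees at the stated tuned values: learning
  rate 0.05, minimum loss reduction 0.3, depth 10, column and row
  subsampling 0.8, 1000 rounds, binary classification error as the
  training metric, no early stopping (the round count is treated as
  already tuned).
* **NB** — naive Bayes with dosage, sex and neuter columns as categorical
  and weight Gaussian. Laplace smoothing of 1 is applied: with three
  genotype categories over a few hundred samples, empty cells are routine
  and unsmoothed likelihoods collapse scores to 0/1.
* **KNN** — five nearest neighbours by Euclidean distance on
  fully-standardized features (training-fold statistics); the score is the
  case fraction among the neighbours. Whether to standardize for KNN/NB is
  a package decision; unstandardized Euclidean distance would let raw
  weight in kg dwarf the dosage axes.

All scores live in $[0,1]$ so AUC applies uniformly.

## Ensembles

Eight base models (4 classifiers × 2 filters) are combined two ways, both
consuming *out-of-fold* base scores so no supervisor sees a label its
features were trained on:

* **n-agreement** — positive call iff at least $n$ of 8 base calls are
  positive; the call threshold on scores is 0.5 (a package choice — no
  threshold is inherent to the base scores). `best_n_per_fold()` scans
  $n = 1..8$ per fold and reports the argmax (ties to the smaller $n$);
  note the per-fold maximum is an optimistically-biased statistic by
  construction, which is why it is reported averaged with its SD rather
  than asserted against a point value.
* **stacking** — base scores are shuffled (seeded) into 10 fresh folds and
  a supervisor (logistic regression, or a 500-tree random forest — the
  supervisor's size is a package default, none being stated for it)
  predicts each held-out fold from the other nine.

## Evaluation

`make_folds()` produces seeded folds with sizes differing by at most one,
stratified by case status by default. Stratification is a deliberate
deviation from plain random splitting: at a few hundred samples,
unstratified folds risk single-class test partitions, and a fold plan that
cannot be scored poisons every model compared on it. A flag restores plain
splitting. Fold plans are fixed across models within a repeat so model
comparisons share partition noise.

`run_cv()` reports two statistics per run: the mean of per-fold AUCs
(the headline, with SD across repeats and across folds — the published
"AUC (SD)" convention is ambiguous between the two, so both are exposed)
and the AUC of aggregated out-of-fold predictions. On balanced simulations
the two agree closely; they diverge when folds are small or imbalanced,
which is itself a useful diagnostic. The covariate-only logistic baseline
(`covariate_logistic_baseline()`) runs the same machinery on the three
clinical covariates; age is deliberately excluded as a predictor because
in the motivating design case/control eligibility was itself age-dependent.

## Numerical choices

* Truncated-Normal draws via log-scale inverse CDF, stable to $|\eta|$
  far beyond the range the sampler visits.
* The inverse-Gaussian draw for the LASSO scale mixture guards
  $|\alpha_j| \ge 10^{-10}$ and floors the result.
* Monomorphic (zero-variance) SNP columns: skipped by the samplers,
  assigned $p = 1$ by the GWAS scan, floor weight by `feature_weights()`,
  and refused as an all-monomorphic GRM.
* All stochastic components (simulation, folds, chains, forests, boosting,
  stacking shuffles) are seeded; identical seeds give identical results to
  the byte.
* Degenerate inputs fail loudly: single-class phenotypes, infeasible
  variance partitions, unordered SNP tables, layout mismatches between
  training and prediction.

## Problem sizes

The test suite runs cohorts of 60–400 samples and up to 2,000 SNPs with
shortened chains, plus one 50,000-sample, 2,000-SNP cohort for the
generative AUC calibration and a 20,000-sample cohort for prevalence and
heritability calibration; these sizes give each check a comfortable margin
between its tolerance and its Monte-Carlo noise. The package defaults
(622 samples, 100,000 SNPs, 52,000-iteration chains) describe the
full-scale study design.

## Limitations

* The simulator's LD is blockwise and stationary; no relatedness,
  population structure, or genotyping-error model beyond uniform
  missingness, so structure-driven confounding of the GWAS filter is not
  exercised.
* The LMM filter is linear on a 0/1 response; it is validated as a ranking
  device, not as a calibrated association test.
* Probabilities from the classifiers are not calibrated; only their
  ranking (AUC) is used.
* Real-data results from the motivating study (its cross-validated AUC
  tables and covariate baseline) depend on the deposited dog cohort and
  are outside what the simulation-based tests can or do reproduce.
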