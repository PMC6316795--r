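---
title: "Classifying a binary phenotype from untargeted metabolomics: PLS-DA versus conditional Gaussian Bayesian networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying a binary phenotype from untargeted metabolomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metabnet)
```

## The problem

Untargeted plasma metabolomics measures hundreds of named metabolites per
subject. When the question is whether those profiles predict a binary
clinical phenotype (here, the template is childhood asthma at age three in a
cohort of 411 children, 59 cases and 352 controls, profiled on 481
metabolites in two batches), two families of classifiers are commonly put
head to head:

* **PLS-DA** — partial least squares regression against the 0/1 class
  indicator, a workhorse of metabolomics that projects the metabolite matrix
  onto a few latent components maximising covariance with the class label;
* **conditional Gaussian Bayesian networks (CGBN)** — a directed acyclic
  graph with one discrete phenotype node and Gaussian metabolite nodes,
  learned by Bayesian model selection, which classifies through the Markov
  neighborhood of the phenotype.

The scientific interest is not only which model scores higher, but which is
more trustworthy: with p ≈ 433 metabolites and n ≈ 411 subjects both
procedures can fit noise, and the package's permutation machinery is built
to expose exactly that.

`metabnet` implements the complete workflow — QC, batch merging, bootstrap
class balancing, both classifiers, ROC-convex-hull evaluation, DeLong
comparison, cross-validated hyperparameter selection, and permutation
testing — together with a synthetic cohort generator with known ground
truth, so that every stage is testable end to end without access to any
particular study's data.

## Quality control and preprocessing

The QC pipeline mirrors standard practice for two-batch untargeted panels:

1. **Batch merging.** For each metabolite, every non-reference batch is
   multiplied by `median(reference controls) / median(batch controls)`, so
   the control groups' medians agree across batches. Factors are computed on
   control samples only; a metabolite whose control median is zero or
   entirely missing in some batch is flagged and left unscaled.
2. **Missingness filter.** A metabolite missing in 50% or more of the
   samples of *any* batch is dropped. The boundary is inclusive.
3. **Log transform.** Natural log. (Only "log transformed" is conventional
   in the source methods; the base is a free choice and does not affect any
   rank-based or threshold-selected result downstream except the loading
   scale, which we document.)
4. **Zero-IQR filter.** Constant (on the log scale) metabolites are
   uninformative and dropped.
5. **Skewness filter.** Metabolites with bias-corrected sample skewness
   (adjusted Fisher–Pearson, the default in most statistical software)
   above 2 or below −2 on the log scale are dropped. Computing skewness
   *after* the log transform is a deliberate decision; heavy-tailed raw
   intensities that become symmetric after logging are exactly the ones the
   transform is meant to rescue.

Remaining missing values are left-censored below-detection measurements, so
they are imputed with the metabolite's minimum observed value halved
(minimum log-value minus log 2). The source methods are silent on
imputation; half-minimum is the common choice for left-censored
mass-spectrometry data and is recorded in the QC report so runs are
auditable.

**Bootstrap balancing.** With 59 cases and 352 controls, most classifiers
drift toward the majority class. The minority class is therefore resampled
with replacement up to the majority count, each majority row kept exactly
once: 59/352 becomes 704 records (352/352). Balancing is applied to
*training* data only — evaluation folds are never resampled, because scoring
duplicated rows would inflate the apparent AUC. (The source wording,
"bootstrap-balancing on each fold", is ambiguous on this point; the
implementation records this reading.)

## PLS-DA by SIMPLS

`fit_simpls()` implements the SIMPLS sequence directly: weight vectors are
extracted to maximise covariance between `X w` and the centered response
under orthogonality of successive scores, with the cross-covariance vector
deflated against an orthonormal basis of x-loadings. Two algebraic
identities pin the implementation and are enforced in the tests:

* the one-component weight vector is the normalised cross-covariance
  `X'y` (tolerance 1e-10);
* at `k = rank(X)` the regression coefficients equal ordinary least squares
  (tolerance 1e-8).

**Scaling.** Columns are autoscaled (z-scored) before fitting, and the
response is mean-centered; predictions are anchored at the 0/1 coding so
scores read as (unclipped) case probabilities. Scores are clipped to [0, 1]
for reporting only, never before ROC construction.

**Influential loadings.** Metabolites with a first-component x-loading at or
beyond ±2 (closed threshold: exactly ±2 is selected) are reported, split by
sign and ordered by magnitude. The exact loading convention behind published
loading magnitudes is generally not recoverable from a paper (weights versus
x-loadings, and the scaling, differ across software); the rule here is
applied to x-loadings as produced by this pipeline, and the threshold is a
configurable argument for that reason. With autoscaled columns and
unit-norm scores, an x-loading is `sqrt(n - 1)` times the metabolite–score
correlation, which at study scale puts the ±2 rule at |r| ≈ 0.075 — a
loose, inclusive screen, as intended.

**Component count.** `select_n_components()` evaluates a grid (1–70 by
default, capped at feasibility) by stratified 5-fold cross-validation (or a
single stratified 2:1 holdout), with training folds balanced and held-out
scores pooled into one ROC; the AUCCH-maximising count wins and ties go to
the smallest `k`. Selection by cross-validated AUCCH is noisy whenever
nearby component counts perform almost equally — the tests therefore
exercise it on a deep one-dimensional signature, where extra components can
only fit noise and `k = 1` is selected reliably.

## The conditional Gaussian Bayesian network

### Evidence

Every Gaussian family (a metabolite given its parents) carries a
normal-inverse-gamma prior: coefficients (including the intercept) are
`N(0, s2 / nu)` and the residual variance is `IG(alpha/2, alpha*sigma2/2)`,
with defaults `nu = 10`, `alpha = 10`, `sigma2 = 1`. The marginal likelihood
is the closed-form multivariate-t evidence; an empty dataset has evidence 1.
Only the triple `(nu, alpha, sigma2)` is conventional in the source
methods; the exact parameterization is pinned here (and verified against
numeric integration in the tests) so results are reproducible against this
package's definition. Metabolites are z-scored before learning, which makes
`sigma2 = 1` a sensible prior scale and renders the single-edge Bayes
factors invariant to the units of the raw intensities. Discrete families
use Dirichlet-multinomial evidence with total concentration
`dirichlet_alpha` (default `alpha`) spread evenly over the child's levels.

A discrete node never has continuous parents (the classical
conditional-Gaussian restriction); metabolites associated with the
phenotype therefore appear as its children, consistent with the
phenotype-first ordering below.

### Structure search

`k2_search()` is the K2 greedy search over a fixed ordering: the phenotype
first, then any discrete covariates, then metabolites ranked by the log
Bayes factor of the single-edge phenotype→metabolite model (ties broken by
name). Each node greedily acquires the predecessor parent with the largest
incremental log Bayes factor while that log BF clears the edge threshold
and the node has fewer than `max_parents = 2` parents. Candidate parents are
all predecessors in the ordering (the alternative — restricting candidates
to the phenotype plus higher-ranked metabolites — is not what a plain K2
over the ordering does, and the unrestricted reading is implemented).
Because edges only run from earlier to later nodes the graph is acyclic by
construction; acyclicity is nevertheless verified on every constructed
network. Bayes factors and the threshold are in natural-log units.

Two properties fall out of the greedy structure and are load-bearing for
efficiency: the greedy choice sequence per node does not depend on the
threshold (the threshold only truncates it), so a single search at the
smallest threshold yields the exact network at every larger threshold; and
the evidence needs only Gram matrices per discrete configuration, so each
candidate evaluation is O(1) after one pass over the data.

### Prediction

Only the Markov neighborhood of the phenotype — its parents, children, and
the children's other parents — can influence prediction.
`predict_phenotype()` applies Bayes' rule across the phenotype's values:
prior (smoothed class frequencies) times the product of each child's
conditional Gaussian density with the phenotype clamped. Posterior-mean
parameters are used throughout (ridge-like coefficients with prior
precision `nu`; posterior-mean variance); a discrete-parent configuration
with no samples falls back to the prior. The tests verify the posterior
against brute-force evaluation of the full joint density and that
perturbing any node outside the neighborhood leaves predictions
bit-identical.

### Threshold selection

`select_bf_threshold()` cross-validates the edge threshold over 2–30 (unit
steps by default) exactly as for PLS-DA components, with ties going to the
*larger* threshold — the sparser model — mirroring the parsimony rationale
for preferring fewer PLS components.

## Evaluation

**AUCCH.** Performance is summarised by the area under the convex hull of
the empirical ROC (anchored at (0,0) and (1,1)): every hull vertex is
realizable by randomising between adjacent operating points, so the hull is
the achievable frontier. AUCCH ≥ AUC always, and AUCCH ≥ 0.5 because the
chance chord joins the anchors. Note a finite-sample consequence used when
interpreting nulls below: for a random score vector the *hull* has positive
bias of order 1.36/sqrt(n) (about 0.53 at n = 704, about 0.51 at n = 3000).

**Confidence intervals.** A Wald interval using the DeLong
structural-components variance of the empirical AUC, applied around the
AUCCH point estimate and truncated to [0, 1]. (The CI method behind
published AUCCH intervals is typically unstated; DeLong-Wald is this
package's convention, cross-checked against a bootstrap percentile interval
in the tests.)

**Model comparison.** `delong_compare()` implements the DeLong test for
paired AUCs from structural components computed via midranks (tie-safe);
the AUCCH values of both score vectors are reported alongside. The z and p
agree with `pROC::roc.test()` to 1e-10, and the variance of the difference
agrees with a 2000-replicate paired bootstrap within 10%.

**Operating point.** The hull vertex maximising Youden's J
(sensitivity + specificity − 1), ties resolved toward higher specificity.
The selection rule behind published sensitivity/specificity pairs is
typically unstated; Youden on the hull is this package's convention.

**Permutation test.** `permutation_test()` shuffles the labels over the
original subjects, re-balances, refits with hyperparameters frozen, and
computes the full-data AUCCH of the refitted model on its own balanced
training data, `realizations` times (1000 in the template study; the tests
use 100). The p-value is the rank formula `(1 + #{null ≥ observed}) /
(R + 1)`. Evaluating the refitted model on its own training data is
deliberate: it is the only reading under which a high-dimensional
procedure's null concentrates far above 0.5, which is the overfitting
signature the test exists to measure. With 433 candidate metabolites and
411 subjects, a one-component PLS-DA null sits well above 0.6 — the
qualitative phenomenon reported for both classifiers in the template study
(null means around 75–76%).

**Baseline characteristics.** `baseline_characteristics()` reproduces the
usual Table-1 workflow: Pearson chi-square without continuity correction
for categorical covariates, Welch's t for continuous ones, plus
`chisq_from_counts()` and `welch_from_summary()` for testing printed
tables. On the template study's printed race table (controls 119/159/74,
cases 15/40/4) the chi-square with 2 df gives p = 0.0027, printing as
0.003.

## The synthetic cohort generator

`generate_cohort()` simulates, on the natural-log scale, the data features
the pipeline must survive; the defaults are the template study's shape —
59 cases / 352 controls, 481 metabolites in two batches of 245 and 166
samples, of which QC retains 433:

* **Signal metabolites** (default 15) with a class-dependent mean shift of
  `effect_size` standard deviations (default 0.4). Neither the number of
  truly associated metabolites nor their effect sizes are recoverable from
  the template study; the defaults give a Bayes-optimal AUC near 0.90
  (computable in closed form via `oracle_auc()`), i.e. a strong but
  imperfect metabolomic signature, which is what such cohorts look like.
* **Co-parent pairs** (default 5): pairs `(A, B)` sharing a large latent
  component with opposite signs, with the phenotype shifting `B` so that
  the *sum* `A + B` moves by `effect_size` standard deviations while each
  member alone is only weakly informative. This mirrors the observation
  motivating network models — two metabolites jointly far more informative
  than either separately — and gives the CGBN's two-parent families
  something real to find.
* **Correlated noise blocks** (default size 10, equicorrelation 0.5),
  because metabolite panels are strongly blocked by pathway and lipid
  class.
* **Batch factors**: per-metabolite log-normal multipliers on the raw
  scale (sdlog 0.2), making the control-median merge exactly invertible in
  expectation.
* **Left-censoring**: values below each metabolite's `missing_rate`
  quantile (default 5%) are removed — detection-limit missingness, which
  makes the ≥50% filter and half-minimum imputation meaningful.
* **Constant and heavily skewed columns** (defaults 8 and 40): fodder for
  the zero-IQR and skewness filters; 8 + 40 dropped from 481 leaves the
  433 the template pipeline retained.

`oracle_scores()` returns the exact posterior case probability under the
generating model (verified against numeric integration over the latent pair
factor), and `oracle_auc()` its closed-form optimal AUC — the yardsticks
for parameter-recovery tests.

**What the generator does not emulate:** drug/treatment confounding,
retention-time or m/z structure, batch-specific detection limits,
non-Gaussian (beyond the planted skewed columns) intensity distributions,
and any real correlation structure of a particular cohort — the block
pattern is stated, not fitted. Passing tests therefore demonstrate correct
and calibrated *machinery*, not biological validity on any real dataset.

## Numerical choices and degenerate inputs

* Rank-deficient `X` stops SIMPLS early with a warning and a reduced `k`;
  a constant response is an error.
* Zero-variance columns are named in errors by both `standardize()` and
  `fit_simpls()`.
* Evidence computations guard `b_n` against tiny negative round-off and use
  Cholesky solves; all candidate scans use closed-form 2×2/3×3 solves on
  Gram entries.
* Ties: ranking ties break by column name; K2 candidate ties by ordering
  position; component-count ties toward smaller `k`; threshold ties toward
  larger thresholds; operating-point ties toward higher specificity. All
  deterministic.
* Every stage derives its seed from the master seed, so a `run_pipeline()`
  report is a pure function of its configuration.

## Problem sizes in the test suite

The packaged tests run the full study scale — 411 subjects, 481→433
metabolites, 5-fold cross-validation over the full grids (components 1–70,
thresholds 2–30) and 100 permutation realizations per classifier — in a few
minutes on one core; smaller fixtures cover the algebraic oracles.
Chance-level calibration of the permutation null is assessed at n = 3000
balanced records, where the hull statistic's finite-sample bias (see above)
is within ±0.03 of one half; at study scale the same bias is about +0.03
and must not be mistaken for signal.

## Known limitations

* The CGBN restricts discrete nodes to discrete parents and allows at most
  two parents per node; no latent variables, no model averaging over
  orderings, no discretisation of metabolites.
* Batch merging implements control-median scaling only — no empirical-Bayes
  batch correction (deliberately, to stay within the template pipeline).
* The permutation test refits with hyperparameters frozen; re-running the
  full cross-validated selection inside every permutation would be the
  stricter (and far costlier) design.
* PLS-DA is plain SIMPLS: no OPLS, sparse, multilevel or multiblock
  variants.
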