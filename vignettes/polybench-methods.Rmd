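---
title: "Methods: smooth-threshold genetic prediction and its benchmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: smooth-threshold genetic prediction and its benchmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polybench)
```

## The problem

Polygenic phenotypes — depressive symptoms are a canonical example — are
influenced by very many variants of very small effect. A genome-wide
association study (GWAS) at attainable sample sizes cannot cleanly separate
the truly associated variants from the vast majority of null ones, and
prediction models built from such scans overfit: their apparent
(resubstitution) accuracy on the training cohort is high while their
accuracy in an independent cohort is near zero. `polybench` implements one
estimator designed to limit that overfitting — smooth-threshold
multivariate genetic prediction (STMGP) — together with the standard
comparators and a phenotype simulator with controlled heritability, so the
whole comparison can be run end to end on synthetic genotypes.

## The phenotype model

Genotypes are biallelic dosages \(x_{ij} \in \{0,1,2\}\) (sample \(j\),
variant \(i\)) with counted-allele frequency \(p_i\), standardized as

\[ w_{ij} = \frac{x_{ij} - 2p_i}{\sqrt{2p_i(1-p_i)}}. \]

A phenotype is simulated over all individuals (training and test together)
as

\[ y_j = \sum_{i=1}^{k} w_{ij}\, b_i + e_j, \]

with \(k\) causal variants drawn at random subject to pairwise
\(r^2 < 0.05\) (approximate linkage equilibrium), effects \(b_i\) i.i.d.
with mean 0 and variance 1, and residuals
\(e_j \sim N\!\big(0,\; \widehat{\mathrm{Var}}(g)\,(1/h^2 - 1)\big)\) where
\(g_j = \sum_i w_{ij} b_i\) and \(h^2\) is the nominal heritability. Using
the *empirical* variance of \(g\) makes the realized heritability
\(\mathrm{Var}(g)/\mathrm{Var}(y)\) concentrate tightly at \(h^2\); the
acceptance suite verifies the calibration to Monte-Carlo precision.

Three effect-size families are provided, all scaled analytically to unit
variance:

* **normal** — the infinitesimal benchmark;
* **Laplace** — heavier tails, scale \(1/\sqrt2\);
* **NEG** (normal–exponential–gamma) — a Laplace distribution whose rate is
  gamma-distributed: \(\lambda^2 \sim \Gamma(\theta,\, 2/(\theta-1))\),
  then \(b \mid \lambda \sim \mathrm{Laplace}(0, 1/\lambda)\). Smaller
  shapes \(\theta\) give heavier tails; the family approaches the Laplace
  as \(\theta \to \infty\). The gamma scale is pinned by the unit-variance
  constraint, which also forces \(\theta > 1\); the hierarchical form fixes
  only the shape, so this is the one place a parameterization had to be
  chosen, and the variance constraint determines it completely.

The genotype generator draws each variant's MAF uniformly in
\([0.01, 0.5]\) and genotypes as binomial(2, p): Hardy–Weinberg
proportions, linkage equilibrium, no missingness. It emulates a
QC-filtered SNP array panel; it does **not** emulate local LD blocks,
genotyping error, relatedness, or population structure. Tests that pass on
these panels therefore validate the estimators' statistical behavior, not
their robustness to LD misspecification — clumping and the \(r^2\) screen
are exercised on explicitly constructed correlated blocks instead.

## STMGP

Training proceeds in four stages on the training cohort only:

1. **Marginal scan.** For each variant, OLS of \(y\) on the intercept,
   covariates and that variant; coefficients are reported per standard
   deviation of dosage, with \(t\) statistics and two-sided P values.
2. **Smooth thresholding.** For a candidate P-value cutoff \(c\), let
   \(\lambda\) be the \(|t|\) value whose two-sided P equals \(c\). The
   selected set is \(A = \{j : P_j \le c\}\), and each selected variant
   receives a weight
   \(\delta_j = \min\{1-\varepsilon, (\lambda/|t_j|)^{1+\gamma}\}\):
   near 1 at the selection boundary (near-total shrinkage), decaying to 0
   as the association evidence grows. \(\gamma = 1\) is the default, the
   usual adaptive-lasso exponent. This replaces the hard include/exclude
   rule of classical polygenic scores.
3. **Generalized ridge.** Minimize
   \(\lVert y - Cb_c - X_A\beta_A\rVert^2 + \tau \sum_{j\in A} d_j
   \beta_j^2\) with \(d_j = \delta_j/(1-\delta_j)\); covariates are never
   penalized. The overall penalty defaults to
   \(\tau = N/\sqrt{\log N}\) — the loss is a residual sum of squares and
   grows with \(N\), so \(\tau\) must track it — with \(N/0.1\), \(N/1\),
   \(N/10\) available as sensitivity presets.
4. **Cutoff selection by Mallows' Cp.** Over a cutoff grid,
   \(C_p(c) = \mathrm{RSS}(c) + 2\hat\sigma^2 \mathrm{df}(c)\), where
   \(\hat\sigma^2\) is the residual variance of the covariate-only model —
   the only fit free of selection effects at every cutoff. The
   Cp-minimizing cutoff wins; ties go to the smaller cutoff (the sparser
   model). No cross-validation is needed, which is the practical point of
   the criterion.

   The degrees of freedom must be *unbiased for the selection*. The
   conditional hat-matrix trace of the ridge smoother on the selected set
   understates the optimism dramatically: the selected variants are
   selected because their t statistics are inflated, so RSS falls faster
   than that trace accounts for, and Cp would drift to the largest cutoff.
   Because the smooth-threshold weight reaches exactly 1 at the selection
   boundary, the fitted values are *continuous* in \(y\), and an unbiased
   SURE-type df exists: in a near-orthogonal panel each selected variant
   contributes \(a_j + t_j\,\partial a_j/\partial t_j\), where
   \(a_j = c_j/(c_j + \tau d_j)\) is its shrinkage factor
   (\(c_j = w_j^\top w_j\)). The derivative term,
   \((1+\gamma)\,\tau c_j \delta_j / (c_j(1-\delta_j) + \tau\delta_j)^2\),
   is the per-variant price of selection — about \(2c_j/\tau\) for a
   variant at the boundary, vanishing for overwhelming evidence. `polybench`
   uses the conditional trace plus this selection term; the covariate block
   contributes its column count exactly. With it, the criterion selects
   hold-out-optimal cutoffs (verified against an exhaustive test-RSS
   oracle), typically in the \(10^{-4}\)–\(10^{-3}\) range on the
   benchmark scenarios.

Prediction standardizes the test genotypes of the selected variants with
the **training** allele frequencies and applies the linear score; no
test-sample statistic enters the model, which the suite enforces by
mutating test data after fitting.

### Numerical choices

* The smooth-threshold weight form is the simplest function satisfying the
  three constraints that define the method: smooth (not hard)
  thresholding, weights decreasing in the marginal evidence, and
  \(\gamma\)-equivalence with adaptive-lasso weighting;
  \(\varepsilon = 10^{-8}\) keeps the ridge weights finite. Any
  replacement must preserve those constraints and the
  \(\delta/(1-\delta)\) mapping into the penalty.
* The default cutoff grid is geometric with 20 points from \(1/(2m)\) to
  0.05, plus the Bonferroni point \(0.05/m\) — it brackets the cutoffs
  such screens select in practice; the grid is configurable.
* Candidate sets for the grid are nested (variants sorted by P), so the
  cross-product matrix is assembled once for the largest cutoff and each
  smaller cutoff solves a leading subblock.
* With an empty selected set at every cutoff the fit degrades to the
  covariate-only model with a warning rather than an error.
* Cp selection was benchmarked against an exhaustive hold-out oracle on
  small instances: its mean excess test RSS over the oracle's choice is
  under 1%, and two independent test halves disagree with each other about
  as often as Cp disagrees with either — at that problem size Cp is
  statistically indistinguishable from hold-out selection.

## Baselines

* **PRS** — clumping (greedy, P-ordered, \(r^2 \ge 0.1\) within 250 kb by
  default; ties broken by position) followed by P-value thresholding of
  per-allele marginal betas. The cutoff is tuned on the training cohort by
  maximizing the correlation between the score and the
  covariate-residualized phenotype over the grid
  \(\{5\times10^{-8}, 10^{-6}, 10^{-4}, 10^{-3}, 0.01, 0.05, 0.1, 0.5,
  1\}\); the rule is configurable, and a fixed cutoff can be forced to
  reproduce "modified-PRS" comparisons.
* **GBLUP** — REML variance components on the genomic relationship matrix
  \(WW^\top/M\) (average-information updates with an EM fallback, all
  iterations in the eigenbasis of the GRM), then best linear unbiased
  prediction of test genetic values. The ridge–BLUP duality (equality with
  ridge regression on standardized genotypes at penalty
  \(\lambda = M\sigma_e^2/\sigma_g^2\)) is asserted to \(10^{-6}\).
* **SBLUP** — joint coefficients from marginal ones by solving
  \((R + \frac{m(1-h^2)}{n h^2} I)\beta = \beta_{\text{marginal}}\) with
  an LD correlation matrix \(R\); the shrinkage constant is the standard
  derivation, with \(h^2\) supplied by GREML. The joint solve is cubic in
  the candidate count, so the pipeline caps the candidate set at the top
  2000 clumped variants by P (configurable).
* **Ridge on clumped markers** — covariates by OLS, then kernel-form ridge
  of the residuals on standardized clumped genotypes, with the penalty
  chosen by generalized cross-validation over a log-spaced grid. The
  two-step fit is exact when the genotype columns are orthogonal to the
  covariate span and is the standard practice otherwise.

A Bayesian mixture-prior comparator is intentionally absent: published
comparisons run it through its own external software, and reproducing that
sampler is out of scope here.

## Quality control

`variant_qc` (call rate < 0.99, HWE exact P < \(10^{-4}\), MAF < 0.01 —
all strict), `sample_qc` (call rate < 0.98) and `ibd_prune` (PI_HAT >
0.09375, dropping the lower-call-rate member of each pair; ties drop the
later-ordered one) reproduce standard array-cohort cleaning. The HWE test
is the exact probability-mass convention used by PLINK. IBD uses plain
method-of-moments estimates with falling-factorial (unbiased) expectation
terms; component shares are clamped only in the final PI_HAT, because
truncating the mean-zero component estimates individually would bias
PI_HAT upward for unrelated pairs. Principal components come from the GRM
eigendecomposition, with significant components counted by the sequential
Tracy–Widom test (\(\beta = 1\) quantiles tabulated; effective marker
count estimated from the remaining spectrum, Patterson-style). The
tabulated quantiles resolve P values between 0.001 and 0.99, ample for a
significance screen.

## Evaluation statistics

Predictive accuracy is the Pearson correlation between prediction and
phenotype in the independent test half (PCC), with the partial correlation
(df \(= n-2-c\)) when covariates are controlled; overfitting is the
training-minus-test gap. Differences between two models' correlations with
the same observed phenotype use Williams' t (determinant form,
df \(= n-3\)). Calibration is the slope of observed on predicted.
Replicate **power** is the share of replicates whose test correlation has
P < 0.05. Sensitivity transforms: Box–Cox with grid-profiled likelihood
(+1 shift when zeros are present, as bounded scores admit 0), and
adjusted-boxplot outlier fences tilted by the medcouple (exponents
\(-4/3\), swapped for left skew). Cohort-table comparisons use Fisher's
exact test (probability-mass two-sided convention) and pooled-variance t
tests from summary statistics.

## Benchmark design and problem sizes

`run_benchmark` crosses scenarios (k, effect family, NEG shape, h²),
simulates each replicate's panel and phenotype jointly across the training
and test halves, fits every method on the training half only, and
aggregates mean/SD/power over replicates. All randomness derives from one
root seed through named substreams (MAF, genotypes, causal set, effects,
residuals, covariates), so any replicate is reproducible in isolation;
with an output directory, completed replicates are cached as JSON and
re-runs resume.

The package's reference scenario keeps the cohort sizes of a two-prefecture
array study — 3685 training and 3048 test samples, 20 replicates, h² in
{0.05, 0.10}, k in {100, ..., 5000} — while scaling the marker panel from
~615k array variants down to m = 20000 simulated variants in linkage
equilibrium. The scaling choice keeps per-variant signal identical and
reduces only the multiple-testing burden of the screen, so published
full-panel accuracies act as lower bounds for the scaled runs. Train and
test genotype blocks are drawn separately from the shared per-variant MAF
draw, which is distributionally identical to drawing jointly and
splitting.

## Known limitations

* No local-LD genotype model; LD-dependent behavior is tested only on
  constructed blocks.
* Quantitative traits only (no liability-threshold/case-control path).
* The SBLUP candidate cap trades exactness for tractability on wide
  panels.
* `ibd_prune` forms dense pair matrices; it is meant for cohort-scale QC,
  not biobank-scale data.
* Tracy–Widom P values are interpolated from a fixed quantile table, not
  computed from the Painlevé representation.
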