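# polybench

Benchmarking penalized polygenic prediction on simulated GWAS data.

Predicting a polygenic quantitative trait — depressive-symptom scores are
the motivating case — from genome-wide SNP data is dominated by one
failure mode: overfitting. A GWAS at realistic sample sizes cannot
separate the handful of truly associated variants from hundreds of
thousands of null ones, and models that keep too many null variants look
excellent on the training cohort and useless on an independent one.

`polybench` implements, end to end, a simulation benchmark of predictors
that attack this problem, centered on **smooth-threshold multivariate
genetic prediction (STMGP)**. For standardized genotypes
`w_ij = (x_ij - 2p_i)/sqrt(2p_i(1-p_i))`, STMGP

1. runs a marginal GWAS scan of the training phenotype,
2. screens variants at a P-value cutoff and gives each selected variant a
   smooth-threshold weight `delta_j = (lambda/|t_j|)^(1+gamma)` (near 1 at
   the selection boundary, near 0 for overwhelming evidence),
3. fits a generalized ridge regression
   `min ||y - C b - X_A beta||^2 + tau * sum_j delta_j/(1-delta_j) beta_j^2`
   with unpenalized covariates and `tau = N/sqrt(log N)` by default, and
4. picks the cutoff by Mallows' Cp, `RSS + 2*sigma2*df`, instead of
   cross-validation.

The package also provides the comparators (clumping+thresholding PRS,
GBLUP via eigen-space AI-REML, summary-statistic BLUP, GCV-tuned ridge on
clumped markers), PLINK1 .bed/.bim/.fam input/output with array-cohort QC
(call rate, Hardy-Weinberg exact test, MAF, PI_HAT relatedness pruning),
a phenotype simulator with controlled heritability and normal / Laplace /
normal-exponential-gamma effect distributions, and the evaluation
statistics (predictive and partial correlations, Williams' test for
dependent correlations, calibration slope, replicate power, Box-Cox and
adjusted-boxplot sensitivity tools).

## Worked example

Simulate a cohort, fit STMGP, and evaluate on an independent test half:

```r
library(polybench)

G <- simulate_genotypes(n = 2000, m = 3000, seed = 42)
causal <- select_causal(G, k = 50, r2_max = 0.05, seed = 1)
b <- sample_effects(50, "laplace", seed = 2)
W <- standardize_genotypes(G)
phen <- simulate_phenotype(W, b, h2 = 0.3, causal = causal, seed = 3)

tr <- 1:1200; te <- 1201:2000
fit <- stmgp_fit(G$dosages[tr, ], phen$y[tr])
fit
#> <stmgp> trained on 1200 samples
#>   tau = 450.667, gamma = 1
#>   Cp-selected P cutoff: 0.00184 (15 variants)

pred <- predict(fit, G$dosages[te, ])
pcc(pred, phen$y[te])[c("r", "p_value")]
#> $r
#> [1] 0.4785198
#>
#> $p_value
#> [1] 5.10514e-47
```

The Cp criterion screens 3000 variants down to 15 (the strongest of the
50 causal ones), keeps them with evidence-adaptive shrinkage, and predicts
the held-out phenotype with correlation ~0.48 — against a theoretical
ceiling of sqrt(0.3) ≈ 0.55 at h² = 0.3.

A full method comparison over replicated scenarios:

```r
cfg <- benchmark_config(n_train = 400, n_test = 300, m = 2000, k = 50,
                        effect_dist = "laplace", h2 = 0.3, n_reps = 5,
                        methods = c("stmgp", "prs", "gblup", "ridge"),
                        seed = 7)
run_benchmark(cfg)$summary
#>   scenario method  k effect_dist neg_shape  h2 mean_pcc sd_pcc power
#> 1        1  gblup 50     laplace        NA 0.3    0.111 0.0922   0.4
#> 2        1    prs 50     laplace        NA 0.3    0.111 0.0907   0.4
#> 3        1  ridge 50     laplace        NA 0.3    0.110 0.0922   0.4
#> 4        1  stmgp 50     laplace        NA 0.3    0.291 0.1350   0.8
#>   mean_train_r mean_overfit_gap n_reps n_failed
#> 1        0.952            0.841      5        0
#> 2        0.920            0.809      5        0
#> 3        1.000            0.890      5        0
#> 4        0.412            0.121      5        0
```

Per method and scenario: mean and SD of the test-set predictive
correlation, the replicate power (share of replicates with P < 0.05), the
mean training correlation and the overfitting gap (train minus test). At
this desk scale the comparison already shows the mechanism of interest:
the unpenalized or weakly tuned baselines reach near-perfect training
correlations and give most of it back on the test half, while the
smooth-threshold model trains at 0.41 and keeps 0.29 of it.

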