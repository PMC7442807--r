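# Baseline predictors: PRS, GRM/GREML, GBLUP-ridge duality, SBLUP
# shrinkage, clumped ridge with GCV.

test_that("PRS tracks a single overwhelming causal variant", {
  set.seed(101)
  G <- simulate_genotypes(500, 60, seed = 101)
  W <- standardize_genotypes(G)
  y <- 2 * W[, 30] + rnorm(500, 0, 0.5)
  tr <- 1:250; te <- 251:500
  Gtr <- G[tr, ]
  gw <- gwas_scan(Gtr, y[tr])
  fit <- prs_fit(gw, Gtr, y[tr])
  expect_true("snp30" %in% fit$variant_ids)
  pred <- predict(fit, G[te, ])
  oracle <- cor(G$dosages[te, 30], y[te])
  expect_equal(cor(pred, y[te]), oracle, tolerance = 0.01)
  # cutoff grid {1} scores every clumped variant
  fit1 <- prs_fit(gw, Gtr, y[tr], cutoff_grid = 1)
  expect_equal(length(fit1$variant_ids), fit1$clumped_n)
  # forcing a cutoff reproduces the modified-PRS experiment
  fitf <- prs_fit(gw, Gtr, y[tr], forced_cutoff = 0.37)
  expect_equal(fitf$selected_cutoff, 0.37)
  # scoring identities
  fit0 <- fit
  fit0$beta[] <- 0
  expect_equal(predict(fit0, G[te, ]), rep(0, 250))
  perm <- sample(60)
  Gperm <- G[te, ][, perm]
  expect_equal(predict(fit, Gperm), pred)
})

test_that("the GRM has unit mean diagonal and flags duplicate samples", {
  set.seed(102)
  G <- simulate_genotypes(100, 800, maf_low = 0.1, seed = 102)
  W <- standardize_genotypes(G)
  K <- make_grm(W)
  expect_equal(mean(diag(K)), 1, tolerance = 0.05)
  off <- K[upper.tri(K)]
  expect_lt(abs(mean(off)), 0.02)
  Wd <- rbind(W, W[1, ])
  Kd <- make_grm(Wd)
  expect_gt(Kd[1, 101], 0.9)
  expect_error(make_grm(W[, 0]), "no variants")
})

test_that("GREML recovers heritability and degrades gracefully to the null", {
  set.seed(103)
  n <- 500; m <- 1000
  G <- simulate_genotypes(n, m, maf_low = 0.05, seed = 103)
  W <- standardize_genotypes(G)
  K <- make_grm(W)
  # true h2 = 0.5 with fully polygenic architecture
  h2_hat <- vapply(1:8, function(r) {
    set.seed(1030 + r)
    b <- rnorm(m) * sqrt(0.5 / m)
    y <- as.vector(W %*% b) + rnorm(n, 0, sqrt(0.5))
    greml(y, K)$h2
  }, numeric(1))
  one <- greml({
    set.seed(1039)
    b <- rnorm(m) * sqrt(0.5 / m)
    as.vector(W %*% b) + rnorm(n, 0, sqrt(0.5))
  }, K)
  expect_lt(abs(one$h2 - 0.5), 2 * one$se["h2"] + 0.05)
  expect_lt(abs(mean(h2_hat) - 0.5), 3 * sd(h2_hat) / sqrt(length(h2_hat)) + 0.03)
  # pure noise: h2 estimate near zero
  set.seed(104)
  null_fit <- greml(rnorm(n), K)
  expect_lt(null_fit$h2, 2 * null_fit$se["h2"] + 0.05)
  # pure EM never decreases the restricted likelihood
  set.seed(105)
  em_fit <- greml(rnorm(n), K, method = "em", max_iter = 30)
  expect_true(all(diff(em_fit$loglik_trace) > -1e-6))
})

test_that("GBLUP equals ridge on standardized genotypes (duality)", {
  for (case in 1:3) {
    set.seed(110 + case)
    ntr <- 50 * case; nte <- 30; m <- 200 * case
    G <- simulate_genotypes(ntr + nte, m, seed = 110 + case)
    W <- standardize_genotypes(G)
    Wtr <- W[seq_len(ntr), , drop = FALSE]
    Wte <- W[ntr + seq_len(nte), , drop = FALSE]
    y <- rnorm(ntr)
    vc <- list(sigma_g2 = runif(1, 0.2, 0.8))
    vc$sigma_e2 <- 1 - vc$sigma_g2
    gp <- gblup_predict(vc, make_grm(Wtr), tcrossprod(Wte, Wtr) / m, y)
    # explicit primal ridge with the dual penalty and the GLS intercept
    V <- vc$sigma_g2 * make_grm(Wtr) + vc$sigma_e2 * diag(ntr)
    ones <- matrix(1, ntr, 1)
    b0 <- solve(crossprod(ones, solve(V, ones)),
                crossprod(ones, solve(V, y)))
    r <- y - as.vector(ones %*% b0)
    lam <- m * vc$sigma_e2 / vc$sigma_g2
    beta <- solve(crossprod(Wtr) + diag(lam, m), crossprod(Wtr, r))
    expect_equal(gp, as.vector(b0) + as.vector(Wte %*% beta),
                 tolerance = 1e-6)
  }
  # sigma_g2 -> 0 collapses to the covariate fit
  set.seed(114)
  G <- simulate_genotypes(80, 100, seed = 114)
  W <- standardize_genotypes(G)
  y <- rnorm(80)
  gp0 <- gblup_predict(list(sigma_g2 = 1e-12, sigma_e2 = 1),
                       make_grm(W), make_grm(W), y)
  expect_equal(gp0, rep(mean(y), 80), tolerance = 1e-6)
})

test_that("GBLUP predicts simulated heritable phenotypes", {
  set.seed(115)
  wins <- vapply(1:10, function(r) {
    sim <- make_sim(n = 360, m = 400, k = 40, h2 = 0.5, seed = 1150 + r)
    tr <- 1:240; te <- 241:360
    ptr <- allele_freq(sim$G$dosages[tr, ])
    Wtr <- standardize_genotypes(sim$G$dosages[tr, ], freq = ptr)
    Wte <- standardize_genotypes(sim$G$dosages[te, ], freq = ptr)
    vc <- greml(sim$y[tr], make_grm(Wtr))
    pred <- gblup_predict(vc, make_grm(Wtr), tcrossprod(Wte, Wtr) / 400,
                          sim$y[tr])
    cor(pred, sim$y[te]) > 0
  }, logical(1))
  expect_gte(sum(wins), 8)
})

test_that("SBLUP shrinkage behaves analytically and approximates GBLUP", {
  b <- c(0.5, -0.3, 0.1)
  lam <- 3 * (1 - 0.4) / (100 * 0.4)
  expect_equal(sblup_coefficients(b, diag(3), n = 100, h2 = 0.4),
               b / (1 + lam))
  expect_equal(sblup_coefficients(b, diag(3), n = 1e-6, h2 = 1e-6),
               rep(0, 3), tolerance = 1e-4)
  expect_error(sblup_coefficients(b, diag(3), 100, h2 = 0), "h2")
  # duality check on a common instance: SBLUP from in-sample LD and
  # marginal betas approximates the GBLUP/ridge test prediction
  set.seed(121)
  ntr <- 300; nte <- 100; m <- 150; h2 <- 0.5
  sim <- make_sim(n = ntr + nte, m = m, k = 30, h2 = h2, seed = 121)
  tr <- seq_len(ntr); te <- ntr + seq_len(nte)
  ptr <- allele_freq(sim$G$dosages[tr, ])
  Wtr <- standardize_genotypes(sim$G$dosages[tr, ], freq = ptr)
  Wte <- standardize_genotypes(sim$G$dosages[te, ], freq = ptr)
  y <- sim$y
  gw <- gwas_scan(sim$G$dosages[tr, ], y[tr])
  R <- crossprod(Wtr) / (ntr - 1)
  bj <- sblup_coefficients(gw$beta, R, ntr, h2, m = m)
  pred_sblup <- as.vector(Wte %*% bj)
  vc <- list(sigma_g2 = h2, sigma_e2 = 1 - h2)
  pred_gblup <- gblup_predict(vc, make_grm(Wtr),
                              tcrossprod(Wte, Wtr) / m, y[tr])
  expect_lt(abs(cor(pred_sblup, y[te]) - cor(pred_gblup, y[te])), 0.05)
})

test_that("clumped ridge selects a finite GCV penalty and nests limits", {
  set.seed(122)
  sim <- make_sim(n = 200, m = 100, k = 20, h2 = 0.5, seed = 122)
  fit <- ridge_clumped(sim$G, sim$y)
  expect_true(is.finite(fit$penalty) && fit$penalty > 0)
  expect_true(all(is.finite(fit$beta)))
  # enormous penalty collapses to the covariate-only fit
  fit_inf <- ridge_clumped(sim$G, sim$y, penalty = 1e12)
  pred_inf <- predict(fit_inf, sim$G)
  expect_equal(pred_inf, rep(mean(sim$y), 200), tolerance = 1e-4)
  # the dual (kernel) solution equals the primal generalized-ridge solve
  # with uniform weights on the same matrix (cross-module identity)
  W <- standardize_genotypes(sim$G)
  r <- sim$y - mean(sim$y)
  tau <- 50; delta <- 0.5
  lam <- tau * delta / (1 - delta)
  f_dual <- ridge_clumped(sim$G, sim$y, penalty = lam)
  f_primal <- fit_generalized_ridge(NULL, W, r, tau = tau, delta = delta,
                                    intercept = FALSE)
  expect_equal(unname(f_primal$beta_snp), f_dual$beta, tolerance = 1e-6)
})
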