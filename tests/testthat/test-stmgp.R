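# STMGP: penalty default, smooth-threshold weights, generalized ridge,
# Cp selection and end-to-end fit/predict behavior.

test_that("default tau follows N/sqrt(log N) with the alternate presets", {
  expect_equal(default_tau(exp(1)), exp(1))          # log = 1
  expect_equal(default_tau(3685), 3685 / sqrt(log(3685)))
  expect_equal(default_tau(3685), 1285.8, tolerance = 1e-4)
  expect_equal(default_tau(3685, "N/10"), 368.5)
  expect_equal(default_tau(100, "N/0.1"), 1000)
  expect_error(default_tau(1), ">= 2")
})

test_that("smooth-threshold weights decay with association strength", {
  df <- 500
  cutoff <- 0.01
  lambda <- qt(1 - cutoff / 2, df)
  t_stats <- c(lambda * 2, lambda * 1.0001, lambda / 2, 200)
  w <- smooth_threshold_weights(t_stats, cutoff, gamma = 1, df = df)
  expect_setequal(w$selected, c(1, 2, 4))
  # gamma = 1, |t| = 2 lambda -> delta = (1/2)^2
  expect_equal(w$delta[w$selected == 1], 0.25, tolerance = 1e-6)
  # delta -> 1 at the selection boundary, -> 0 for overwhelming evidence
  expect_gt(w$delta[w$selected == 2], 0.99)
  expect_lt(w$delta[w$selected == 4], 1e-3)
  expect_true(all(w$delta >= 0 & w$delta < 1))
  # delta is nonincreasing in |t|
  ord <- order(abs(t_stats[w$selected]))
  expect_true(all(diff(w$delta[order(w$selected)][ord]) <= 0))
  # cutoff 1 selects everything
  expect_equal(smooth_threshold_weights(t_stats, 1, df = df)$selected, 1:4)
  expect_error(smooth_threshold_weights(rep(2, 5), 0.5, df = df),
               "zero variance")
})

test_that("generalized ridge nests OLS and standard ridge", {
  set.seed(91)
  n <- 120; p <- 8
  X <- matrix(rnorm(n * p), n, p)
  C <- cbind(age = rnorm(n))
  y <- rnorm(n) + X[, 1]
  # tau = 0: exact OLS
  f0 <- fit_generalized_ridge(C, X, y, tau = 0, delta = rep(0.5, p))
  ols <- unname(coef(lm(y ~ C + X)))
  expect_equal(unname(f0$coefficients), ols, tolerance = 1e-8)
  expect_equal(f0$df, p + 2, tolerance = 1e-8)  # hat-matrix trace, exact
  # uniform delta = standard ridge at penalty tau * d (closed form)
  tau <- 7; delta <- 0.4
  f1 <- fit_generalized_ridge(NULL, X, y, tau = tau, delta = delta,
                              intercept = FALSE)
  lam <- tau * delta / (1 - delta)
  closed <- solve(crossprod(X) + diag(lam, p), crossprod(X, y))
  expect_equal(unname(f1$beta_snp), as.vector(closed), tolerance = 1e-8)
  # delta_j -> 1 forces beta_j -> 0 while the rest approach the reduced fit
  dd <- rep(0.01, p); dd[3] <- 1 - 1e-10
  f2 <- fit_generalized_ridge(NULL, X, y, tau = 1, delta = dd,
                              intercept = FALSE)
  expect_lt(abs(f2$beta_snp[3]), 1e-6)
  # delta -> 0 recovers OLS on the selected set
  f3 <- fit_generalized_ridge(NULL, X, y, tau = 1, delta = 1e-8,
                              intercept = FALSE)
  ols2 <- solve(crossprod(X), crossprod(X, y))
  expect_equal(unname(f3$beta_snp), as.vector(ols2), tolerance = 1e-6)
})

test_that("Cp degrees of freedom shrink with tau and track holdout error", {
  set.seed(92)
  n <- 150; p <- 10
  X <- matrix(rnorm(n * p), n, p)
  y <- X[, 1] * 0.5 + rnorm(n)
  dfs <- vapply(c(0, 1, 10, 100, 1000), function(tau)
    fit_generalized_ridge(NULL, X, y, tau = tau, delta = 0.5)$df,
    numeric(1))
  expect_true(all(diff(dfs) < 1e-10))
  expect_equal(dfs[1], p + 1)
  expect_error(cp_criterion(y, y, n + 1, 1), "df_model")
  # over replicates, Cp selection tracks the cutoff minimizing the RSS on
  # an independent test half: it agrees with the test-optimal cutoff at
  # least as often as the sampling noise of the test RSS itself allows,
  # and never lands on the worst cutoff
  grid <- c(1e-4, 0.01, 0.1, 0.5, 1)
  picks <- t(vapply(1:50, function(r) {
    G <- simulate_genotypes(400, 100, maf_low = 0.1, seed = 900 + r)
    W <- standardize_genotypes(G)
    causal <- select_causal(G, 5, r2_max = 0.2, seed = 901 + r)
    b <- sample_effects(5, "normal", seed = 902 + r)
    y <- simulate_phenotype(W, b, 0.2, causal = causal, seed = 903 + r)$y
    tr <- 1:200; te <- 201:400
    fit <- suppressWarnings(stmgp_fit(G$dosages[tr, ], y[tr],
                                      cutoff_grid = grid))
    test_rss <- vapply(grid, function(cut) {
      f <- suppressWarnings(stmgp_fit(G$dosages[tr, ], y[tr],
                                      cutoff_grid = cut))
      sum((y[te] - predict(f, G$dosages[te, ]))^2)
    }, numeric(1))
    c(cp = fit$selected_cutoff, best = grid[which.min(test_rss)],
      worst = grid[which.max(test_rss)],
      regret = (test_rss[match(fit$selected_cutoff, grid)] -
                  min(test_rss)) / min(test_rss))
  }, numeric(4)))
  expect_gte(mean(picks[, "cp"] == picks[, "best"]), 0.6)
  expect_equal(mean(picks[, "cp"] == picks[, "worst"]), 0)
  expect_lt(mean(picks[, "regret"]), 0.05)
  if (sd(picks[, "cp"]) > 0 && sd(picks[, "best"]) > 0)
    expect_gt(cor(rank(picks[, "cp"]), rank(picks[, "best"])), 0)
})

test_that("stmgp_fit recovers strong signals and stays null under noise", {
  set.seed(93)
  # a single overwhelming causal variant is selected essentially always
  hits <- vapply(1:10, function(r) {
    G <- simulate_genotypes(300, 40, seed = 930 + r)
    W <- standardize_genotypes(G)
    y <- 1.2 * W[, 17] + rnorm(300)
    fit <- stmgp_fit(G, y)
    17 %in% fit$selected
  }, logical(1))
  expect_gte(mean(hits), 0.9)
  # null phenotype: test-set correlations centered at zero
  rs <- vapply(1:12, function(r) {
    G <- simulate_genotypes(260, 120, seed = 940 + r)
    y <- rnorm(260)
    fit <- stmgp_fit(G$dosages[1:130, ], y[1:130])
    pred <- predict(fit, G$dosages[131:260, ])
    if (sd(pred) == 0) 0 else cor(pred, y[131:260])
  }, numeric(1))
  expect_lt(abs(mean(rs)), 3 * sd(rs) / sqrt(length(rs)) + 0.02)
  # defaults recorded on the model object
  G <- simulate_genotypes(150, 30, seed = 95)
  y <- rnorm(150)
  fit <- stmgp_fit(G, y)
  expect_equal(fit$tau, default_tau(150))
  expect_equal(fit$gamma, 1)
  expect_true(fit$selected_cutoff %in% fit$cutoff_grid)
  expect_equal(fit$cp_path$cp[match(fit$selected_cutoff,
                                    fit$cp_path$cutoff)],
               min(fit$cp_path$cp))
})

test_that("stmgp predictions are consistent, equivariant and test-isolated", {
  set.seed(96)
  sim <- make_sim(n = 240, m = 80, k = 10, h2 = 0.5, seed = 96)
  C <- cbind(age = rnorm(240))
  tr <- 1:160; te <- 161:240
  fit <- stmgp_fit(sim$G$dosages[tr, ], sim$y[tr], C[tr, , drop = FALSE])
  # in-sample prediction reproduces the fitted values of the final model
  pred_tr <- predict(fit, sim$G$dosages[tr, ], C[tr, , drop = FALSE])
  path_row <- match(fit$selected_cutoff, fit$cp_path$cutoff)
  expect_equal(sum((sim$y[tr] - pred_tr)^2), fit$cp_path$rss[path_row],
               tolerance = 1e-8)
  # adding a constant to y shifts only the intercept
  fit2 <- stmgp_fit(sim$G$dosages[tr, ], sim$y[tr] + 5,
                    C[tr, , drop = FALSE])
  expect_equal(fit2$beta_snp, fit$beta_snp, tolerance = 1e-8)
  expect_equal(unname(fit2$covar_coef[1] - fit$covar_coef[1]), 5,
               tolerance = 1e-8)
  # test isolation: a prediction depends only on that sample's own row
  pred_te <- predict(fit, sim$G$dosages[te, ], C[te, , drop = FALSE])
  mangled <- sim$G$dosages[te, ]
  mangled[2:80, ] <- sample(0:2, 79 * 80, replace = TRUE)
  pred_mangled <- predict(fit, mangled, C[te, , drop = FALSE])
  expect_equal(pred_mangled[1], pred_te[1])
  # genotype_matrix input matches by variant id, errors when absent
  Gte <- sim$G[te, ]
  expect_equal(predict(fit, Gte, C[te, , drop = FALSE]), pred_te)
  if (length(fit$selected)) {
    Gmiss <- Gte[, setdiff(seq_len(80), fit$selected[1])]
    expect_error(predict(fit, Gmiss, C[te, , drop = FALSE]), "missing")
  }
})

test_that("an empty selection falls back to the covariate-only model", {
  set.seed(97)
  G <- simulate_genotypes(120, 40, seed = 97)
  y <- rnorm(120)
  expect_warning(fit <- stmgp_fit(G, y, cutoff_grid = 1e-12),
                 "covariate-only")
  expect_equal(length(fit$selected), 0)
  expect_equal(predict(fit, G), rep(unname(fit$covar_coef[1]), 120))
})

test_that("smooth thresholding overfits less than OLS on the same set", {
  set.seed(98)
  gaps <- t(vapply(1:10, function(r) {
    sim <- make_sim(n = 400, m = 120, k = 15, h2 = 0.3, seed = 980 + r,
                    dist = "laplace")
    tr <- 1:200; te <- 201:400
    fit <- stmgp_fit(sim$G$dosages[tr, ], sim$y[tr])
    if (!length(fit$selected)) return(c(0, 0))
    pr_tr <- predict(fit, sim$G$dosages[tr, ])
    pr_te <- predict(fit, sim$G$dosages[te, ])
    gap_stmgp <- cor(pr_tr, sim$y[tr]) -
      (if (sd(pr_te) > 0) cor(pr_te, sim$y[te]) else 0)
    W_tr <- standardize_genotypes(sim$G$dosages[tr, fit$selected,
                                                drop = FALSE])
    ols <- lm.fit(cbind(1, W_tr), sim$y[tr])
    W_te <- standardize_genotypes(
      sim$G$dosages[te, fit$selected, drop = FALSE],
      freq = allele_freq(sim$G$dosages[tr, fit$selected, drop = FALSE]))
    pr_ols_te <- as.vector(cbind(1, W_te) %*% ols$coefficients)
    gap_ols <- cor(ols$fitted.values, sim$y[tr]) -
      (if (sd(pr_ols_te) > 0) cor(pr_ols_te, sim$y[te]) else 0)
    c(stmgp = gap_stmgp, ols = gap_ols)
  }, numeric(2)))
  expect_lt(mean(gaps[, 1]), mean(gaps[, 2]))
})
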