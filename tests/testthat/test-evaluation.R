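# Correlation metrics, Williams' test, calibration, power, transforms,
# outlier fences and the demographic-table tests.

test_that("predictive correlation and its t-based P value", {
  y <- rnorm(50)
  expect_equal(pcc(y, y)$r, 1)
  expect_equal(pcc(-y, y)$r, -1)
  # at n = 3048 a correlation of ~0.0355 sits at the 0.05 boundary
  set.seed(131)
  n <- 3048; r_target <- 0.0355
  tval <- r_target * sqrt((n - 2) / (1 - r_target^2))
  expect_equal(2 * pt(-tval, n - 2), 0.05, tolerance = 0.002)
  x <- rnorm(n)
  yb <- r_target * x + sqrt(1 - r_target^2) * rnorm(n)
  res <- pcc(x, yb)
  expect_equal(res$p_value,
               2 * pt(-abs(res$r) * sqrt((n - 2) / (1 - res$r^2)), n - 2))
  expect_error(pcc(rep(1, 10), rnorm(10)), "constant")
})

test_that("partial correlation matches the recursive closed form", {
  set.seed(132)
  n <- 400
  z <- rnorm(n)
  x <- 0.5 * z + rnorm(n)
  y <- 0.3 * z + rnorm(n)
  got <- partial_correlation(x, y, cbind(z = z))
  rxy <- cor(x, y); rxz <- cor(x, z); ryz <- cor(y, z)
  expected <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  expect_equal(got$r, expected, tolerance = 1e-10)
  expect_equal(got$df, n - 3)
  # no covariates reduces to pcc
  expect_equal(partial_correlation(x, y)$r, pcc(x, y)$r)
  # a prediction that is purely covariate signal has partial r ~ 0
  expect_lt(abs(partial_correlation(2 * z + 1, y, cbind(z = z))$r), 0.1)
  # invariance to affine transforms of the covariates
  got2 <- partial_correlation(x, y, cbind(z = 3 * z - 7))
  expect_equal(got2$r, got$r, tolerance = 1e-10)
})

test_that("Williams' test is calibrated, powered and antisymmetric", {
  expect_equal(williams_test(0.3, 0.3, 0.5, 100)$t, 0)
  expect_equal(williams_test(0.3, 0.3, 0.5, 100)$p_value, 1)
  a <- williams_test(0.4, 0.1, 0.3, 200)
  b <- williams_test(0.1, 0.4, 0.3, 200)
  expect_equal(a$t, -b$t)
  expect_error(williams_test(0.9, -0.9, 0.9, 50), "positive definite")
  # simulation: power under a true difference, size under the null
  simulate_rates <- function(r12, r13, r23, n, reps) {
    S <- matrix(c(1, r12, r13, r12, 1, r23, r13, r23, 1), 3)
    L <- chol(S)
    mean(vapply(seq_len(reps), function(i) {
      Z <- matrix(rnorm(3 * n), n, 3) %*% L
      williams_test(cor(Z[, 1], Z[, 2]), cor(Z[, 1], Z[, 3]),
                    cor(Z[, 2], Z[, 3]), n)$p_value < 0.05
    }, logical(1)))
  }
  set.seed(133)
  expect_gt(simulate_rates(0.3, 0.0, 0.5, 500, 200), 0.5)
  size <- simulate_rates(0.2, 0.2, 0.3, 300, 200)
  expect_gt(size, 0.01)
  expect_lt(size, 0.10)
})

test_that("calibration slope identities", {
  set.seed(134)
  y <- rnorm(100)
  exact <- calibration_slope(y, y)
  expect_equal(exact$slope, 1)
  expect_equal(exact$se, 0)
  expect_equal(calibration_slope(y, y / 2)$slope, 2)
  # in-sample OLS predictions give slope exactly 1 (normal equations)
  X <- cbind(rnorm(100), rnorm(100))
  yy <- X %*% c(1, -1) + rnorm(100)
  pred <- fitted(lm(yy ~ X))
  expect_equal(calibration_slope(yy, pred)$slope, 1, tolerance = 1e-10)
  expect_error(calibration_slope(y, rep(2, 100)), "constant")
})

test_that("replicate power summaries are simple shares", {
  r <- c(0.1, 0.2, 0.05)
  expect_equal(power_summary(r, c(0.01, 0.2, 0.04))$power, 2 / 3)
  expect_equal(power_summary(r, rep(0.01, 3))$power, 1)
  expect_equal(power_summary(r, rep(0.5, 3))$power, 0)
  expect_equal(power_summary(r, runif(3), alpha = 1)$power, 1)
  s <- power_summary(seq(0, 0.19, 0.01), c(rep(0.01, 17), rep(0.5, 3)))
  expect_equal(s$power, 0.85)
  expect_equal(s$n_reps, 20)
})

test_that("Box-Cox profiles the likelihood correctly", {
  set.seed(135)
  y <- rlnorm(3000)
  bc <- boxcox_transform(y)
  expect_lt(abs(bc$lambda), 0.1)
  if (requireNamespace("MASS", quietly = TRUE)) {
    prof <- MASS::boxcox(y ~ 1, lambda = seq(-0.5, 0.5, 0.01),
                         plotit = FALSE)
    expect_equal(bc$lambda, prof$x[which.max(prof$y)], tolerance = 0.02)
  }
  # already-normal data keep lambda near 1 and an affine transform
  z <- rnorm(2000, 10, 1)
  bcz <- boxcox_transform(z)
  expect_lt(abs(bcz$lambda - 1), 0.35)
  # right-skewed data become less skewed
  skew <- function(v) mean((v - mean(v))^3) / sd(v)^3
  ys <- rexp(2000)
  expect_lt(abs(skew(boxcox_transform(ys)$y_transformed)), abs(skew(ys)))
  # zeros trigger the +1 shift
  expect_equal(boxcox_transform(c(0, 1, 2, 5, 9))$shift, 1)
  expect_error(boxcox_transform(c(-1, 1)), "nonnegative")
})

test_that("medcouple matches brute force and tilts the fences", {
  expect_equal(medcouple(1:9), 0)                  # exactly symmetric
  expect_equal(medcouple(c(1, 2, 3, 4, 100)), medcouple_brute(c(1, 2, 3, 4, 100)))
  set.seed(136)
  for (i in 1:5) {
    x <- rnorm(200) + rexp(200) * (i %% 2)
    expect_equal(medcouple(x), medcouple_brute(x), tolerance = 1e-12)
  }
  # symmetric data: adjusted fences reduce to the classical 1.5 IQR rule
  xs <- c(seq(-3, 3, length.out = 200), -9, 9)
  out <- adjusted_boxplot_outliers(xs)
  mc <- attr(out, "medcouple")
  expect_lt(abs(mc), 0.02)
  q <- quantile(xs, c(0.25, 0.75), names = FALSE)
  classical <- c(q[1] - 1.5 * exp(-4 * mc) * (q[2] - q[1]),
                 q[2] + 1.5 * exp(3 * mc) * (q[2] - q[1]))
  expect_equal(attr(out, "fences"), classical)
  expect_true(out[201] && out[202])
  # right-skewed data: the upper fence moves out
  set.seed(137)
  xr <- rexp(500)
  fr <- attr(adjusted_boxplot_outliers(xr), "fences")
  qr <- quantile(xr, c(0.25, 0.75), names = FALSE)
  expect_gt(fr[2], qr[2] + 1.5 * (qr[2] - qr[1]))
})

test_that("Fisher's exact test agrees with enumeration and is symmetric", {
  expect_equal(fisher_exact_2x2(10, 90, 10, 90), 1)
  expect_equal(fisher_exact_2x2(3, 7, 9, 1),
               fisher_exact_2x2(3, 9, 7, 1))        # transpose invariance
  expect_equal(fisher_exact_2x2(5, 0, 0, 5), fisher_enum_p(5, 0, 0, 5),
               tolerance = 1e-12)
  set.seed(138)
  for (i in 1:20) {
    tab <- as.vector(rmultinom(1, sample(10:50, 1), runif(4, 0.05, 1)))
    expect_equal(do.call(fisher_exact_2x2, as.list(tab)),
                 do.call(fisher_enum_p, as.list(tab)), tolerance = 1e-12)
  }
  expect_equal(fisher_exact_2x2(0, 0, 3, 5), 1)     # zero margin
})

test_that("summary t test matches the pooled-variance formula and raw data", {
  expect_equal(ttest_from_summary(1, 1, 50, 1, 1, 60)$t, 0)
  expect_equal(ttest_from_summary(1, 1, 50, 1, 1, 60)$p_value, 1)
  expect_equal(ttest_from_summary(1, 1, 100, 0, 1, 100)$t, 7.071,
               tolerance = 1e-3)
  set.seed(139)
  a <- rnorm(40, 1, 2); b <- rnorm(55, 0, 2)
  got <- ttest_from_summary(mean(a), sd(a), 40, mean(b), sd(b), 55)
  ref <- t.test(a, b, var.equal = TRUE)
  expect_equal(got$t, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
  expect_error(ttest_from_summary(1, 0, 10, 0, 1, 10), "positive SDs")
})
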