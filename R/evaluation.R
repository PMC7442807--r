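# Performance metrics and statistical comparisons: predictive and partial
# correlations, Williams' test for dependent correlations, calibration
# slope, replicate power, Box-Cox transform, adjusted-boxplot outliers,
# Fisher's exact test and summary-statistic t tests.

#' Predictive correlation coefficient
#'
#' Pearson correlation between predictions and observations, with a
#' two-sided P value from t = r sqrt((n-2)/(1-r^2)).
#'
#' @param pred,y numeric vectors of equal length >= 3, both non-constant.
#' @return List with `r`, `p_value`, `n`.
#' @export
pcc <- function(pred, y) {
  n <- length(y)
  stopifnot(length(pred) == n, n >= 3)
  if (sd(pred) == 0 || sd(y) == 0)
    stop("constant vector: correlation undefined", call. = FALSE)
  r <- cor(pred, y)
  p <- if (abs(r) >= 1) 0 else {
    tval <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(-abs(tval), n - 2)
  }
  list(r = r, p_value = p, n = n)
}

#' Partial correlation controlling for covariates
#'
#' Correlates the residuals of `pred` and `y` after regressing each on
#' \[1, C\]; the P value uses df = n - 2 - c, discounting the covariate
#' dimensions.
#'
#' @param pred,y numeric vectors.
#' @param C covariate matrix/data frame (full rank); `NULL` reduces to
#'   [pcc()].
#' @return List with `r`, `p_value`, `n`, `df`.
#' @export
partial_correlation <- function(pred, y, C = NULL) {
  n <- length(y)
  stopifnot(length(pred) == n)
  Cm <- .as_covariate_matrix(C, n)
  c_dim <- if (is.null(Cm)) 0L else ncol(Cm)
  rp <- .residualize(pred, Cm)
  ry <- .residualize(y, Cm)
  if (sd(rp) == 0 || sd(ry) == 0)
    stop("residualized vector is constant", call. = FALSE)
  r <- cor(rp, ry)
  df <- n - 2L - c_dim
  p <- if (abs(r) >= 1) 0 else {
    tval <- r * sqrt(df / (1 - r^2))
    2 * pt(-abs(tval), df)
  }
  list(r = r, p_value = p, n = n, df = df)
}

#' Williams' test for two dependent correlations sharing a variable
#'
#' Tests H0: rho12 = rho13 given the correlation r23 between the two
#' non-shared variables, with the t2 statistic (determinant-of-correlation-
#' matrix form) on n - 3 degrees of freedom.
#'
#' @param r12,r13 the two correlations being compared (sharing variable 1).
#' @param r23 correlation between variables 2 and 3.
#' @param n sample size (> 3).
#' @return List with `t`, `p_value`, `df`.
#' @export
williams_test <- function(r12, r13, r23, n) {
  for (r in c(r12, r13, r23))
    if (!is.finite(r) || abs(r) >= 1)
      stop("correlations must lie in (-1, 1)", call. = FALSE)
  if (n <= 3) stop("n must exceed 3", call. = FALSE)
  detR <- 1 - r12^2 - r13^2 - r23^2 + 2 * r12 * r13 * r23
  if (detR <= 0)
    stop("correlation triple is not positive definite", call. = FALSE)
  rbar <- (r12 + r13) / 2
  tval <- (r12 - r13) *
    sqrt((n - 1) * (1 + r23) /
           (2 * detR * (n - 1) / (n - 3) + rbar^2 * (1 - r23)^3))
  list(t = tval, p_value = 2 * pt(-abs(tval), n - 3), df = n - 3)
}

#' Calibration slope
#'
#' Ordinary least-squares slope of the observed phenotype on the predicted
#' values, with its standard error. A well-calibrated predictor has slope
#' 1; in-sample OLS-based predictions give slope exactly 1 by the normal
#' equations.
#'
#' @param y observed phenotype.
#' @param pred predicted values (non-constant).
#' @return List with `slope`, `se`, `intercept`.
#' @export
calibration_slope <- function(y, pred) {
  n <- length(y)
  stopifnot(length(pred) == n, n >= 3)
  if (sd(pred) == 0) stop("constant predictions", call. = FALSE)
  sxx <- sum((pred - mean(pred))^2)
  slope <- sum((pred - mean(pred)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(pred)
  rss <- sum((y - intercept - slope * pred)^2)
  se <- sqrt(rss / (n - 2) / sxx)
  list(slope = slope, se = se, intercept = intercept)
}

#' Summarize replicate prediction results
#'
#' Mean and standard deviation of the per-replicate correlations and the
#' replicate power: the share of replicates whose correlation P value is
#' below `alpha`.
#'
#' @param r per-replicate correlation coefficients.
#' @param p per-replicate P values.
#' @param alpha significance level (default 0.05).
#' @return List with `mean_r`, `sd_r`, `power`, `n_reps`.
#' @export
power_summary <- function(r, p, alpha = 0.05) {
  stopifnot(length(r) == length(p), length(r) >= 1)
  list(mean_r = mean(r), sd_r = if (length(r) > 1) sd(r) else NA_real_,
       power = mean(p < alpha), n_reps = length(r))
}

#' Box-Cox transformation with maximum-likelihood lambda
#'
#' Profiles the Box-Cox log-likelihood of a location model over a bounded
#' lambda grid and returns the transformed values at the maximizing
#' lambda: (y^lambda - 1)/lambda, or log(y) at lambda = 0. A +1 shift is
#' applied when zeros are present (and recorded); negative values are an
#' error.
#'
#' @param y nonnegative, non-constant values.
#' @param lambda_grid candidate lambdas (default seq(-2, 2, 0.01)).
#' @return List with `y_transformed`, `lambda`, `shift`.
#' @export
boxcox_transform <- function(y, lambda_grid = seq(-2, 2, by = 0.01)) {
  if (any(!is.finite(y))) stop("y must be finite", call. = FALSE)
  if (sd(y) == 0) stop("constant y", call. = FALSE)
  if (min(y) < 0) stop("y must be nonnegative", call. = FALSE)
  shift <- if (min(y) == 0) 1 else 0
  z <- y + shift
  n <- length(z)
  slog <- sum(log(z))
  ll <- vapply(lambda_grid, function(l) {
    w <- if (l == 0) log(z) else (z^l - 1) / l
    -n / 2 * log(sum((w - mean(w))^2) / n) + (l - 1) * slog
  }, numeric(1))
  lambda <- lambda_grid[which.max(ll)]
  w <- if (lambda == 0) log(z) else (z^lambda - 1) / lambda
  list(y_transformed = w, lambda = lambda, shift = shift)
}

#' Medcouple robust skewness
#'
#' The median of the kernel h(xi, xj) = ((xi - med) - (med - xj))/(xi - xj)
#' over pairs with xi >= med >= xj, with the standard sign kernel for ties
#' at the median. Direct O(n^2) evaluation, adequate for cohort-scale
#' vectors.
#'
#' @param x numeric vector (n >= 3).
#' @return The medcouple, in \[-1, 1\].
#' @export
medcouple <- function(x) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  if (n < 3) stop("need at least 3 values", call. = FALSE)
  med <- median(x)
  xp <- x[x >= med]
  xm <- x[x <= med]
  H <- outer(xp, xm, function(a, b) {
    h <- ((a - med) - (med - b)) / (a - b)
    h[a == b] <- NA_real_
    h
  })
  # values tied with the median appear in both groups; the pair kernel on
  # the tied block is the sign kernel h(i, j) = sign(i + j - 1 - k), with k
  # tied values, i indexed in the upper group and j in the lower group
  k_tie <- sum(x == med)
  if (k_tie > 0) {
    ti <- seq_len(k_tie)                         # first k rows of xp
    tj <- length(xm) - k_tie + seq_len(k_tie)    # last k columns of xm
    H[ti, tj] <- outer(ti, seq_len(k_tie),
                       function(i, j) sign(i + j - 1 - k_tie))
  }
  median(H, na.rm = TRUE)
}

#' Adjusted-boxplot outlier detection for skewed data
#'
#' Boxplot fences tilted by the medcouple MC: for MC >= 0 the fences are
#' \[Q1 - 1.5 exp(-4 MC) IQR, Q3 + 1.5 exp(3 MC) IQR\]; for MC < 0 the
#' exponents swap to (-3, 4). MC = 0 recovers the classical 1.5 IQR rule.
#'
#' @param y numeric vector (n >= 10).
#' @return Logical mask of outliers, with attributes `fences` and
#'   `medcouple`.
#' @export
adjusted_boxplot_outliers <- function(y) {
  if (length(y) < 10) stop("need at least 10 values", call. = FALSE)
  mc <- medcouple(y)
  q <- quantile(y, c(0.25, 0.75), names = FALSE)
  iqr <- q[2] - q[1]
  fences <- if (mc >= 0)
    c(q[1] - 1.5 * exp(-4 * mc) * iqr, q[2] + 1.5 * exp(3 * mc) * iqr)
  else
    c(q[1] - 1.5 * exp(-3 * mc) * iqr, q[2] + 1.5 * exp(4 * mc) * iqr)
  out <- y < fences[1] | y > fences[2]
  attr(out, "fences") <- fences
  attr(out, "medcouple") <- mc
  out
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided exact P by the probability-mass convention (the sum of
#' hypergeometric probabilities not exceeding that of the observed table),
#' delegating to [stats::fisher.test()]. A zero margin returns P = 1.
#'
#' @param a,b,c,d cell counts, row-wise.
#' @return Two-sided P value.
#' @export
#' @examples
#' fisher_exact_2x2(104, 3581, 81, 2967)
fisher_exact_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts)))
    stop("cell counts must be nonnegative integers", call. = FALSE)
  tab <- matrix(counts, 2L, 2L, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(1)
  fisher.test(tab)$p.value
}

#' Two-sample t test from summary statistics
#'
#' Pooled-variance Student's t test from group means, standard deviations
#' and sizes, with df = n1 + n2 - 2.
#'
#' @param m1,sd1,n1 mean, SD and size of group 1.
#' @param m2,sd2,n2 mean, SD and size of group 2.
#' @return List with `t`, `p_value`, `df`.
#' @export
ttest_from_summary <- function(m1, sd1, n1, m2, sd2, n2) {
  if (sd1 <= 0 || sd2 <= 0 || n1 < 2 || n2 < 2)
    stop("need positive SDs and group sizes >= 2", call. = FALSE)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  tval <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = tval, p_value = 2 * pt(-abs(tval), df), df = df)
}
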