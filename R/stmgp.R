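# Smooth-Threshold Multivariate Genetic Prediction (STMGP).
#
# Four-stage procedure: (1) marginal GWAS scan; (2) for each candidate
# P-value cutoff, smooth-threshold weights from the marginal t statistics
# and a generalized ridge fit with unpenalized covariates; (3) Mallows' Cp
# over the cutoff grid; (4) prediction on independent samples with
# training-frequency standardization.

#' Default overall penalty for STMGP
#'
#' The recommended sample-size-adaptive penalty tau = N / sqrt(log N);
#' the loss is a residual sum of squares and grows proportionally to N, so
#' tau must track N. Presets `"N/0.1"`, `"N/1"` and `"N/10"` expose the
#' alternate grid used in sensitivity analyses.
#'
#' @param n training sample count (>= 2).
#' @param preset one of `"auto"` (N/sqrt(log N)), `"N/0.1"`, `"N/1"`,
#'   `"N/10"`.
#' @return The penalty value.
#' @export
#' @examples
#' default_tau(3685)            # ~1285.8
#' default_tau(3685, "N/10")    # 368.5
default_tau <- function(n, preset = c("auto", "N/0.1", "N/1", "N/10")) {
  preset <- match.arg(preset)
  if (!is.numeric(n) || length(n) != 1L || n < 2)
    stop("n must be a single sample count >= 2", call. = FALSE)
  switch(preset,
         "auto" = n / sqrt(log(n)),
         "N/0.1" = n / 0.1,
         "N/1" = n / 1,
         "N/10" = n / 10)
}

#' Smooth-threshold selection and penalty weights
#'
#' Implements the smooth (rather than hard) thresholding of marginal
#' association evidence. Let lambda be the absolute t value whose two-sided
#' P equals `cutoff` at `df` degrees of freedom. Variants with P <= cutoff
#' form the selected set A; each selected variant receives the weight
#' delta_j = min(1 - eps, (lambda / |t_j|)^(1 + gamma)), which approaches 1
#' at the selection boundary (near-complete shrinkage) and 0 as |t_j| grows
#' (association certainty removes the penalty). `gamma = 1` corresponds to
#' the usual adaptive-lasso weighting exponent. Unselected variants are
#' fully thresholded out (implicit delta = 1).
#'
#' @param t_stats marginal t statistics, one per variant.
#' @param cutoff P-value cutoff in (0, 1\].
#' @param gamma weight exponent (> 0, default 1).
#' @param df residual degrees of freedom of the marginal scan.
#' @param eps guard keeping delta strictly below 1 (default 1e-8).
#' @return List with `selected` (indices of A), `delta` (weights for A),
#'   and `lambda` (the t-scale cutoff).
#' @export
smooth_threshold_weights <- function(t_stats, cutoff, gamma = 1, df,
                                     eps = 1e-8) {
  if (!is.numeric(cutoff) || cutoff <= 0 || cutoff > 1)
    stop("cutoff must be in (0, 1]", call. = FALSE)
  if (gamma <= 0) stop("gamma must be positive", call. = FALSE)
  if (length(t_stats) > 1L && sd(t_stats) == 0)
    stop("t statistics have zero variance", call. = FALSE)
  p <- 2 * pt(-abs(t_stats), df)
  selected <- which(p <= cutoff)
  lambda <- qt(1 - cutoff / 2, df)
  at <- abs(t_stats[selected])
  delta <- ifelse(at > 0, pmin(1 - eps, (lambda / at)^(1 + gamma)), 1 - eps)
  list(selected = selected, delta = delta, lambda = lambda)
}

#' Generalized ridge regression with unpenalized covariates
#'
#' Minimizes ||y - C b_c - X beta||^2 + tau * sum_j d_j beta_j^2 with
#' d_j = delta_j / (1 - delta_j), solved by the blocked normal equations.
#' The intercept and covariate block is never penalized. `tau = 0` recovers
#' ordinary least squares; a uniform delta recovers standard ridge at
#' penalty tau * d.
#'
#' @param C covariate matrix or `NULL` (an intercept is always included
#'   unless `intercept = FALSE`).
#' @param X predictor matrix (standardized genotypes of the selected set).
#' @param y response vector.
#' @param tau overall penalty (>= 0).
#' @param delta per-column weights in \[0, 1); recycled if scalar.
#' @param intercept include an intercept (default `TRUE`).
#' @return List with `coefficients` (named: intercept, covariates, then
#'   predictors), `beta_snp`, `fitted`, `rss`, and `df` (trace of the
#'   smoother matrix; equals the column count when tau = 0).
#' @export
fit_generalized_ridge <- function(C, X, y, tau, delta, intercept = TRUE) {
  n <- length(y)
  X <- as.matrix(X)
  Cm <- .as_covariate_matrix(C, n)
  if (length(delta) == 1L) delta <- rep(delta, ncol(X))
  stopifnot(nrow(X) == n, length(delta) == ncol(X), tau >= 0)
  if (any(delta < 0 | delta >= 1))
    stop("delta must lie in [0, 1)", call. = FALSE)
  d <- delta / (1 - delta)
  M <- cbind(if (intercept) rep(1, n), Cm, X)
  n_free <- ncol(M) - ncol(X)
  MtM <- crossprod(M)
  pen <- c(rep(0, n_free), tau * d)
  A <- MtM + diag(pen, nrow = ncol(M))
  coef <- tryCatch(solve(A, crossprod(M, y)),
                   error = function(e) stop("singular penalized system: ",
                                            conditionMessage(e),
                                            call. = FALSE))
  coef <- as.vector(coef)
  fitted <- as.vector(M %*% coef)
  names(coef) <- c(if (intercept) "(Intercept)", colnames(Cm),
                   colnames(X) %||% sprintf("x%d", seq_len(ncol(X))))
  list(coefficients = coef,
       beta_snp = coef[seq.int(n_free + 1L, length.out = ncol(X))],
       fitted = fitted,
       rss = sum((y - fitted)^2),
       df = sum(diag(solve(A, MtM))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Mallows' Cp prediction-error criterion
#'
#' Cp = RSS + 2 * sigma2_hat * df_model, an unbiased estimate (up to a
#' constant) of prediction error that replaces cross-validation. `df_model`
#' is the trace of the smoother matrix mapping y to fitted values; for an
#' unpenalized least-squares fit it equals the number of predictors.
#'
#' @param y observed response.
#' @param fitted fitted values.
#' @param df_model effective model degrees of freedom (0 <= df <= n).
#' @param sigma2_hat external error-variance estimate (> 0).
#' @return The Cp value.
#' @export
cp_criterion <- function(y, fitted, df_model, sigma2_hat) {
  n <- length(y)
  stopifnot(length(fitted) == n, sigma2_hat > 0)
  if (df_model < 0 || df_model > n)
    stop("df_model must lie in [0, n]", call. = FALSE)
  sum((y - fitted)^2) + 2 * sigma2_hat * df_model
}

# Default cutoff grid: geometric from 1/(2m) to 0.05 plus the Bonferroni
# point, bracketing the cutoffs such screens select in practice.
.default_cutoff_grid <- function(m, n_points = 20) {
  lo <- 1 / (2 * m)
  hi <- 0.05
  g <- if (lo >= hi) hi else exp(seq(log(lo), log(hi), length.out = n_points))
  sort(unique(c(g, min(0.05 / m, 1))))
}

#' Fit the STMGP prediction model
#'
#' Runs the full training procedure: marginal GWAS scan, smooth-threshold
#' weights and generalized ridge fit at every cutoff of the grid, Mallows'
#' Cp over the grid (the error variance is estimated from the
#' covariate-only model, the only fit free of selection effects at every
#' cutoff), and returns the model at the Cp-minimizing cutoff with the full
#' Cp path retained. Ties prefer the smaller cutoff (sparser model).
#'
#' @param geno training genotypes: a [genotype_matrix()] or dosage matrix.
#' @param y training phenotype.
#' @param covariates optional covariates (unpenalized).
#' @param tau overall penalty; default [default_tau()] of the sample count.
#' @param gamma smooth-threshold weight exponent (default 1).
#' @param cutoff_grid candidate P-value cutoffs; default geometric grid
#'   from 1/(2m) to 0.05 plus the Bonferroni point.
#' @param gwas optionally, a precomputed [gwas_scan()] result for `geno`
#'   and `y` (avoids rescanning in pipelines).
#' @param max_selected cap on the size of the largest candidate set
#'   (default `min(m, 2n)`), protecting against degenerate grids.
#' @return An object of class `stmgp`; see `print.stmgp` and
#'   [predict.stmgp()].
#' @export
stmgp_fit <- function(geno, y, covariates = NULL, tau = NULL, gamma = 1,
                      cutoff_grid = NULL, gwas = NULL, max_selected = NULL) {
  X <- .dosage_matrix(geno)
  n <- nrow(X)
  m <- ncol(X)
  stopifnot(length(y) == n)
  Cm <- .as_covariate_matrix(covariates, n)
  n_cov <- if (is.null(Cm)) 0L else ncol(Cm)
  if (is.null(tau)) tau <- default_tau(n)
  if (is.null(cutoff_grid)) cutoff_grid <- .default_cutoff_grid(m)
  cutoff_grid <- sort(unique(cutoff_grid))
  if (is.null(max_selected)) max_selected <- min(m, 2L * n)
  freq <- allele_freq(X)
  if (is.null(gwas)) gwas <- gwas_scan(X, y, covariates)
  df_scan <- attr(gwas, "df")
  ids <- if (inherits(geno, "genotype_matrix")) geno$variants$id else gwas$id

  # covariate-only fit: intercept + covariates, for sigma2_hat and fallback
  Q <- .covariate_basis(Cm, n)
  resid0 <- as.vector(y - Q %*% crossprod(Q, y))
  sigma2_hat <- sum(resid0^2) / (n - ncol(Q))
  if (sigma2_hat <= 0) sigma2_hat <- .Machine$double.eps

  ord <- order(gwas$p)            # candidate sets are prefixes of this order
  p_sorted <- gwas$p[ord]
  k_max <- min(sum(p_sorted <= max(cutoff_grid)), max_selected)
  yty <- sum(y^2)

  if (k_max == 0L) {
    fit0 <- fit_generalized_ridge(Cm, matrix(numeric(0), n, 0), y, tau,
                                  numeric(0))
    warning("no variants selected at any cutoff; returning covariate-only ",
            "model", call. = FALSE)
    return(.stmgp_model(tau, gamma, cutoff_grid, NULL, max(cutoff_grid),
                        integer(0), character(0), numeric(0), numeric(0),
                        fit0$coefficients, numeric(0), sigma2_hat, freq,
                        ids, n, n_cov, gwas))
  }

  A_max <- ord[seq_len(k_max)]
  # standardize only the candidate columns (training frequencies)
  W_A <- standardize_genotypes(X[, A_max, drop = FALSE], freq = freq[A_max])
  M <- cbind(rep(1, n), Cm, W_A)
  MtM <- crossprod(M)
  Mty <- as.vector(crossprod(M, y))
  n_free <- 1L + n_cov
  t_sorted <- gwas$t[ord[seq_len(k_max)]]

  path <- data.frame(cutoff = cutoff_grid, n_selected = NA_integer_,
                     df = NA_real_, rss = NA_real_, cp = NA_real_)
  best <- NULL
  for (ci in seq_along(cutoff_grid)) {
    cutoff <- cutoff_grid[ci]
    k_c <- min(sum(p_sorted <= cutoff), k_max)
    lambda <- qt(1 - cutoff / 2, df_scan)
    if (k_c == 0L) {
      # covariate-only candidate
      K <- n_free
      Asub <- MtM[seq_len(K), seq_len(K), drop = FALSE]
      coef <- solve(Asub, Mty[seq_len(K)])
      df_c <- K
      delta_c <- numeric(0)
    } else {
      K <- n_free + k_c
      at <- abs(t_sorted[seq_len(k_c)])
      delta_c <- ifelse(at > 0, pmin(1 - 1e-8, (lambda / at)^(1 + gamma)),
                        1 - 1e-8)
      dpen <- tau * delta_c / (1 - delta_c)
      MtM_k <- MtM[seq_len(K), seq_len(K), drop = FALSE]
      Asub <- MtM_k + diag(c(rep(0, n_free), dpen), nrow = K)
      sol <- solve(Asub, cbind(Mty[seq_len(K)], MtM_k))
      coef <- sol[, 1L]
      # Unbiased (SURE-type) degrees of freedom: the smooth-threshold fit
      # is continuous in y, so its df is the full derivative trace. Beyond
      # the conditional hat-matrix trace, each selected variant pays for
      # the dependence of its own weight on its t statistic:
      # d(a_j b_j)/db_j = a_j + t_j da_j/dt_j with a_j = c_j/(c_j + tau d_j)
      # (near-orthogonal approximation). Without this term Cp ignores
      # selection bias and drifts to the largest cutoff.
      cjj <- diag(MtM_k)[seq.int(n_free + 1L, length.out = k_c)]
      sel_cost <- (1 + gamma) * tau * cjj * delta_c /
        (cjj * (1 - delta_c) + tau * delta_c)^2
      df_c <- sum(diag(sol[, -1L, drop = FALSE])) + sum(sel_cost)
    }
    rss <- yty - 2 * sum(coef * Mty[seq_len(K)]) +
      sum(coef * (MtM[seq_len(K), seq_len(K)] %*% coef))
    rss <- max(rss, 0)
    cp <- rss + 2 * sigma2_hat * df_c
    path$n_selected[ci] <- k_c
    path$df[ci] <- df_c
    path$rss[ci] <- rss
    path$cp[ci] <- cp
    if (is.null(best) || cp < best$cp) {
      best <- list(cp = cp, cutoff = cutoff, k = k_c, coef = coef,
                   delta = delta_c)
    }
  }

  sel <- if (best$k > 0L) A_max[seq_len(best$k)] else integer(0)
  coef <- best$coef
  beta_snp <- if (best$k > 0L) coef[seq.int(n_free + 1L,
                                            length.out = best$k)]
              else numeric(0)
  covar_coef <- coef[seq_len(n_free)]
  names(covar_coef) <- c("(Intercept)", colnames(Cm))
  .stmgp_model(tau, gamma, cutoff_grid, path, best$cutoff, sel,
               ids[sel], beta_snp, best$delta, covar_coef, freq[sel],
               sigma2_hat, freq, ids, n, n_cov, gwas)
}

.stmgp_model <- function(tau, gamma, cutoff_grid, cp_path, selected_cutoff,
                         selected, selected_ids, beta_snp, delta,
                         covar_coef, freq_selected, sigma2_hat, freq, ids,
                         n_train, n_cov, gwas) {
  structure(list(tau = tau, gamma = gamma, cutoff_grid = cutoff_grid,
                 cp_path = cp_path, selected_cutoff = selected_cutoff,
                 selected = selected, selected_ids = selected_ids,
                 beta_snp = beta_snp, delta = delta,
                 covar_coef = covar_coef, freq_selected = freq_selected,
                 sigma2_hat = sigma2_hat, n_train = n_train,
                 n_cov = n_cov,
                 gwas_df = attr(gwas, "df")),
            class = "stmgp")
}

#' @export
print.stmgp <- function(x, ...) {
  cat("<stmgp> trained on ", x$n_train, " samples\n", sep = "")
  cat("  tau = ", format(x$tau, digits = 6), ", gamma = ", x$gamma, "\n",
      sep = "")
  cat("  Cp-selected P cutoff: ", format(x$selected_cutoff, digits = 4),
      " (", length(x$selected), " variants)\n", sep = "")
  invisible(x)
}

#' Predict phenotypes from a fitted STMGP model
#'
#' Linear score: intercept + covariate terms + standardized test genotypes
#' of the selected variants times their penalized coefficients. Test
#' genotypes are standardized with the TRAINING allele frequencies, so no
#' test-sample statistic enters the prediction.
#'
#' @param object a fitted `stmgp` model.
#' @param geno test genotypes: a [genotype_matrix()] (variants matched by
#'   id) or a dosage matrix with the training column layout.
#' @param covariates test covariates, same columns as at training.
#' @param ... unused.
#' @return Numeric vector of predicted scores.
#' @export
predict.stmgp <- function(object, geno, covariates = NULL, ...) {
  Xsel <- .match_model_columns(geno, object$selected, object$selected_ids)
  n <- nrow(Xsel)
  Cm <- .as_covariate_matrix(covariates, n)
  n_cov_given <- if (is.null(Cm)) 0L else ncol(Cm)
  if (n_cov_given != object$n_cov)
    stop("model was trained with ", object$n_cov, " covariates, got ",
         n_cov_given, call. = FALSE)
  pred <- rep(unname(object$covar_coef[1L]), n)
  if (object$n_cov > 0L)
    pred <- pred + as.vector(Cm %*% object$covar_coef[-1L])
  if (length(object$selected)) {
    W <- standardize_genotypes(Xsel, freq = object$freq_selected)
    pred <- pred + as.vector(W %*% object$beta_snp)
  }
  pred
}

# Extract the model's selected variant columns from test genotypes,
# matching by id for genotype_matrix input and by position otherwise.
.match_model_columns <- function(geno, selected, selected_ids) {
  if (inherits(geno, "genotype_matrix")) {
    idx <- match(selected_ids, geno$variants$id)
    if (anyNA(idx))
      stop("test data are missing model variants: ",
           paste(selected_ids[is.na(idx)], collapse = ", "), call. = FALSE)
    geno$dosages[, idx, drop = FALSE]
  } else {
    X <- .dosage_matrix(geno)
    if (length(selected) && max(selected) > ncol(X))
      stop("test matrix has fewer columns than the training panel",
           call. = FALSE)
    X[, selected, drop = FALSE]
  }
}

#' Serialize an STMGP model to JSON and TSV
#'
#' @param model a fitted `stmgp` model.
#' @param prefix output path prefix; writes `prefix.json` and
#'   `prefix.coef.tsv`.
#' @return Invisibly, the paths written.
#' @export
write_stmgp <- function(model, prefix) {
  js <- paste0(prefix, ".json")
  tsv <- paste0(prefix, ".coef.tsv")
  jsonlite::write_json(
    list(tau = model$tau, gamma = model$gamma,
         selected_cutoff = model$selected_cutoff,
         covar_coef = as.list(model$covar_coef),
         variants = data.frame(id = model$selected_ids,
                               beta = model$beta_snp,
                               delta = model$delta,
                               freq = model$freq_selected)),
    js, auto_unbox = TRUE, digits = NA)
  .write_tsv(data.frame(term = c(names(model$covar_coef),
                                 model$selected_ids),
                        estimate = c(unname(model$covar_coef),
                                     model$beta_snp)), tsv)
  invisible(c(js, tsv))
}
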