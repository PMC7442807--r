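# Comparator predictors: P-value-threshold polygenic scores with clumping,
# GBLUP via REML variance components, summary-statistic BLUP, and ridge
# regression on clumped markers.

#' Fit a clumping + P-value-threshold polygenic score
#'
#' Clumps the panel, converts marginal standardized-scale coefficients to
#' the per-allele (dosage) scale, and for each cutoff of the grid scores the
#' training samples and correlates the score with the phenotype
#' residualized on the covariates; the cutoff maximizing that training
#' correlation is selected. Set `forced_cutoff` to score at a fixed cutoff
#' (e.g. the cutoff chosen by another model).
#'
#' @param gwas a [gwas_scan()] result for the training panel.
#' @param geno training [genotype_matrix()].
#' @param y training phenotype.
#' @param covariates optional training covariates.
#' @param cutoff_grid candidate P-value cutoffs.
#' @param r2_clump,window_kb clumping parameters (see [clump_variants()]).
#' @param forced_cutoff optional fixed cutoff overriding the selection.
#' @return An object of class `prs`: selected cutoff, scored variant ids,
#'   per-allele betas, allele codes and training frequencies, plus the
#'   per-cutoff training correlations (`grid`).
#' @export
prs_fit <- function(gwas, geno, y, covariates = NULL,
                    cutoff_grid = c(5e-8, 1e-6, 1e-4, 1e-3, 0.01, 0.05,
                                    0.1, 0.5, 1),
                    r2_clump = 0.1, window_kb = 250, forced_cutoff = NULL) {
  stopifnot(inherits(geno, "genotype_matrix"))
  X <- geno$dosages
  clumped <- clump_variants(gwas, geno, r2_clump, window_kb)
  p <- allele_freq(X)
  s <- sqrt(2 * p * (1 - p))
  beta_dosage <- ifelse(s > 0, gwas$beta / s, 0)
  y_resid <- .residualize(y, covariates)
  grid <- sort(unique(if (is.null(forced_cutoff)) cutoff_grid
                      else forced_cutoff))
  r_train <- rep(NA_real_, length(grid))
  sets <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    set <- clumped[gwas$p[clumped] <= grid[i]]
    sets[[i]] <- set
    if (!length(set)) next
    score <- .prs_score(X[, set, drop = FALSE], beta_dosage[set], p[set])
    if (sd(score) > 0) r_train[i] <- cor(score, y_resid)
  }
  if (all(is.na(r_train))) {
    warning("no variant passes any cutoff; falling back to the largest ",
            "cutoff", call. = FALSE)
    best <- length(grid)
  } else best <- which.max(r_train)
  set <- sets[[best]]
  structure(list(selected_cutoff = grid[best],
                 variant_ids = geno$variants$id[set],
                 variant_idx = set,
                 beta = beta_dosage[set],
                 allele1 = geno$variants$allele1[set],
                 freq = p[set],
                 grid = data.frame(cutoff = grid,
                                   n_variants = lengths(sets),
                                   r_train = r_train),
                 clumped_n = length(clumped)),
            class = "prs")
}

# dosage %*% beta with missing dosages imputed at 2 * training frequency
.prs_score <- function(X, beta, freq) {
  if (!length(beta)) return(numeric(nrow(X)))
  if (anyNA(X)) {
    idx <- which(is.na(X), arr.ind = TRUE)
    X[idx] <- 2 * freq[idx[, 2L]]
  }
  as.vector(X %*% beta)
}

#' @export
print.prs <- function(x, ...) {
  cat("<prs> cutoff ", format(x$selected_cutoff, digits = 4), ", ",
      length(x$variant_ids), " variants (", x$clumped_n,
      " after clumping)\n", sep = "")
  invisible(x)
}

#' Score test samples with a polygenic score model
#'
#' Sum over model variants of per-allele beta times counted-allele dosage.
#' Variants are matched by id and the counted allele is checked.
#'
#' @param object a fitted `prs` model.
#' @param geno test genotypes: [genotype_matrix()] (matched by id) or a
#'   dosage matrix in the training column layout.
#' @param ... unused.
#' @return Numeric vector of scores.
#' @export
predict.prs <- function(object, geno, ...) {
  if (inherits(geno, "genotype_matrix")) {
    idx <- match(object$variant_ids, geno$variants$id)
    if (anyNA(idx))
      stop("test data are missing PRS variants: ",
           paste(object$variant_ids[is.na(idx)], collapse = ", "),
           call. = FALSE)
    if (!all(geno$variants$allele1[idx] == object$allele1))
      stop("counted-allele mismatch between model and test data",
           call. = FALSE)
    X <- geno$dosages[, idx, drop = FALSE]
  } else {
    X <- .dosage_matrix(geno)[, object$variant_idx, drop = FALSE]
  }
  .prs_score(X, object$beta, object$freq)
}

#' Genomic relationship matrix
#'
#' G = W W' / M over M standardized variants; symmetric with mean diagonal
#' near 1 for Hardy-Weinberg genotypes.
#'
#' @param W standardized genotype matrix (see [standardize_genotypes()]).
#' @return n x n relationship matrix.
#' @export
make_grm <- function(W) {
  W <- as.matrix(W)
  if (ncol(W) == 0) stop("no variants", call. = FALSE)
  tcrossprod(W) / ncol(W)
}

#' REML variance components from a genomic relationship matrix
#'
#' Fits y = C b + g + e with g ~ N(0, G sigma_g^2), e ~ N(0, I sigma_e^2)
#' by restricted maximum likelihood. Updates are average-information steps
#' with an EM fallback whenever an AI step would leave the parameter
#' space; all per-iteration work is done in the eigenbasis of G (one
#' eigendecomposition up front, diagonal algebra thereafter). Variances
#' are floored at 1e-8; standard errors come from the inverse
#' average-information matrix, with a delta-method SE for the heritability
#' ratio. Non-convergence is flagged, not raised.
#'
#' @param y phenotype vector.
#' @param grm genomic relationship matrix (positive semidefinite).
#' @param C optional covariates (an intercept is always included).
#' @param method `"ai"` (average information with EM fallback) or `"em"`
#'   (pure EM, monotone in the restricted likelihood).
#' @param max_iter,tol iteration cap and restricted-log-likelihood
#'   convergence tolerance.
#' @return An object of class `greml`: `sigma_g2`, `sigma_e2`, `h2`, `se`
#'   (named vector), `loglik`, `loglik_trace`, `converged`, `n_iter`,
#'   `beta` (GLS covariate coefficients).
#' @export
greml <- function(y, grm, C = NULL, method = c("ai", "em"),
                  max_iter = 100L, tol = 1e-8) {
  method <- match.arg(method)
  n <- length(y)
  stopifnot(nrow(grm) == n, ncol(grm) == n)
  Cm <- .as_covariate_matrix(C, n)
  Xf <- cbind(`(Intercept)` = rep(1, n), Cm)
  eig <- eigen(grm, symmetric = TRUE)
  lam <- pmax(eig$values, 0)
  U <- eig$vectors
  yt <- as.vector(crossprod(U, y))
  Xt <- crossprod(U, Xf)
  floor_v <- 1e-8
  ones <- rep(1, n)

  # All REML quantities at (sg, se): V = sg*G + se*I is diagonal (d) in the
  # eigenbasis of G; P = V^-1 - V^-1 X (X'V^-1X)^-1 X'V^-1.
  parts_at <- function(sg, se) {
    d <- sg * lam + se
    XtDX <- crossprod(Xt, Xt / d)
    alpha <- solve(XtDX, crossprod(Xt, yt / d))
    Pyt <- (yt - as.vector(Xt %*% alpha)) / d
    ll <- -0.5 * (sum(log(d)) + determinant(XtDX)$modulus[1] +
                    sum(yt * Pyt))
    trP <- function(a) {   # tr(P A), A = diag(a) in the eigenbasis
      B <- crossprod(Xt, Xt * (a / d^2))
      sum(a / d) - sum(diag(solve(XtDX, B)))
    }
    bilin <- function(u, v) {   # u' P v
      au <- crossprod(Xt, u / d)
      av <- crossprod(Xt, v / d)
      sum(u * v / d) - sum(au * solve(XtDX, av))
    }
    list(d = d, Pyt = Pyt, ll = ll, trP = trP, bilin = bilin,
         alpha = as.vector(alpha))
  }

  vy <- max(var(y), floor_v)
  sg <- se <- vy / 2
  parts <- parts_at(sg, se)
  ll_trace <- parts$ll
  converged <- FALSE
  AI <- diag(2)
  n_iter <- 0L
  for (it in seq_len(max_iter)) {
    n_iter <- it
    Pyt <- parts$Pyt
    yPGPy <- sum(lam * Pyt^2)
    yPPy <- sum(Pyt^2)
    trPG <- parts$trP(lam)
    trPI <- parts$trP(ones)
    score <- 0.5 * c(yPGPy - trPG, yPPy - trPI)
    uG <- lam * Pyt
    uI <- Pyt
    AI <- 0.5 * matrix(c(parts$bilin(uG, uG), parts$bilin(uG, uI),
                         parts$bilin(uG, uI), parts$bilin(uI, uI)), 2L)
    proposal <- NULL
    if (method == "ai") {
      step <- tryCatch(solve(AI, score), error = function(e) NULL)
      if (!is.null(step)) {
        cand <- c(sg, se) + as.vector(step)
        if (all(is.finite(cand)) && all(cand > 0)) proposal <- cand
      }
    }
    if (is.null(proposal)) {   # EM fallback (or pure EM)
      proposal <- c(sg + sg^2 * (yPGPy - trPG) / n,
                    se + se^2 * (yPPy - trPI) / n)
    }
    proposal <- pmax(proposal, floor_v)
    new_parts <- parts_at(proposal[1L], proposal[2L])
    ll_trace <- c(ll_trace, new_parts$ll)
    done <- abs(new_parts$ll - parts$ll) < tol * (1 + abs(parts$ll))
    sg <- proposal[1L]
    se <- proposal[2L]
    parts <- new_parts
    if (done) {
      converged <- TRUE
      break
    }
  }
  vcov2 <- tryCatch(solve(AI), error = function(e) matrix(NA_real_, 2, 2))
  tot <- sg + se
  grad <- c(se, -sg) / tot^2
  se_h2 <- sqrt(max(as.vector(t(grad) %*% vcov2 %*% grad), 0))
  beta <- parts$alpha
  names(beta) <- colnames(Xf)
  structure(list(sigma_g2 = sg, sigma_e2 = se, h2 = sg / tot,
                 se = c(sigma_g2 = sqrt(max(vcov2[1, 1], 0)),
                        sigma_e2 = sqrt(max(vcov2[2, 2], 0)),
                        h2 = se_h2),
                 loglik = parts$ll, loglik_trace = ll_trace,
                 converged = converged, n_iter = n_iter, beta = beta),
            class = "greml")
}

#' @export
print.greml <- function(x, ...) {
  cat("<greml> h2 = ", format(x$h2, digits = 4), " (SE ",
      format(x$se["h2"], digits = 3), "), sigma_g2 = ",
      format(x$sigma_g2, digits = 4), ", sigma_e2 = ",
      format(x$sigma_e2, digits = 4),
      if (!x$converged) "  [NOT CONVERGED]", "\n", sep = "")
  invisible(x)
}

#' GBLUP prediction for test samples
#'
#' Best linear unbiased prediction of the genetic values of test samples:
#' g_test = G_{test,train} (G_{train,train} + (sigma_e2/sigma_g2) I)^-1
#' (y_train - C b), with b the GLS covariate coefficients, plus the test
#' covariate terms. When sigma_g2 is (numerically) zero the prediction
#' collapses to the covariate fit.
#'
#' @param vc a [greml()] fit (or any list with `sigma_g2`, `sigma_e2`).
#' @param grm_train train x train relationship matrix.
#' @param grm_test_train test x train relationship block.
#' @param y_train training phenotype.
#' @param C_train,C_test covariates for each set (same columns).
#' @return Numeric vector of predicted test phenotypes.
#' @export
gblup_predict <- function(vc, grm_train, grm_test_train, y_train,
                          C_train = NULL, C_test = NULL) {
  n <- length(y_train)
  n_test <- nrow(grm_test_train)
  Cm_tr <- .as_covariate_matrix(C_train, n)
  Cm_te <- .as_covariate_matrix(C_test, n_test)
  Xtr <- cbind(rep(1, n), Cm_tr)
  Xte <- cbind(rep(1, n_test), Cm_te)
  if (ncol(Xte) != ncol(Xtr))
    stop("train and test covariates differ in columns", call. = FALSE)
  sg <- vc$sigma_g2
  se <- vc$sigma_e2
  if (sg < 1e-10) {
    b <- qr.coef(qr(Xtr), y_train)
    return(as.vector(Xte %*% b))
  }
  V <- sg * grm_train + se * diag(n)
  Vinv_X <- solve(V, Xtr)
  b <- solve(crossprod(Xtr, Vinv_X), crossprod(Vinv_X, y_train))
  resid <- y_train - as.vector(Xtr %*% b)
  ghat <- as.vector(grm_test_train %*%
                      solve(grm_train + (se / sg) * diag(n), resid))
  as.vector(Xte %*% b) + ghat
}

#' Summary-statistic BLUP joint coefficients
#'
#' Shrinks marginal standardized-scale coefficients toward a joint solution
#' using an LD correlation matrix: solves
#' (R + m (1 - h2) / (n h2) I) beta = beta_marginal. With an identity R
#' this is pure shrinkage by 1 / (1 + lambda').
#'
#' @param beta_marginal marginal coefficients on the standardized scale.
#' @param ld positive semidefinite correlation matrix of the candidate
#'   variants.
#' @param n GWAS sample count.
#' @param h2 trait heritability in (0, 1).
#' @param m marker count for the shrinkage constant; defaults to the
#'   candidate count.
#' @return Numeric vector of joint coefficients (standardized scale).
#' @export
sblup_coefficients <- function(beta_marginal, ld, n, h2,
                               m = length(beta_marginal)) {
  if (!is.numeric(h2) || h2 <= 0 || h2 >= 1)
    stop("h2 must be in (0, 1)", call. = FALSE)
  k <- length(beta_marginal)
  stopifnot(nrow(ld) == k, ncol(ld) == k)
  lambda <- m * (1 - h2) / (n * h2)
  as.vector(solve(ld + diag(lambda, k), beta_marginal))
}

#' Ridge regression on (clumped) standardized genotypes
#'
#' Standard ridge with unpenalized covariates, fit two-step: covariates by
#' ordinary least squares, then ridge of the covariate residuals on the
#' standardized genotypes. The penalty is chosen by generalized
#' cross-validation (GCV) over a log-spaced grid unless given. When
#' p > n the dual (kernel) form is used, so genome-wide panels are
#' feasible.
#'
#' @param geno training [genotype_matrix()] or dosage matrix (typically
#'   already clumped).
#' @param y training phenotype.
#' @param covariates optional covariates.
#' @param penalty a fixed ridge penalty, or `"gcv"` (default).
#' @param penalty_grid candidate penalties for GCV (default 30 log-spaced
#'   values bracketing n and p scales).
#' @return An object of class `ridge_model` with per-variant standardized
#'   coefficients, the chosen penalty, and the GCV path.
#' @export
ridge_clumped <- function(geno, y, covariates = NULL, penalty = "gcv",
                          penalty_grid = NULL) {
  X <- .dosage_matrix(geno)
  n <- nrow(X)
  m <- ncol(X)
  freq <- allele_freq(X)
  W <- standardize_genotypes(X, freq = freq)
  Cm <- .as_covariate_matrix(covariates, n)
  Q <- .covariate_basis(Cm, n)
  cov_coef <- qr.coef(qr(cbind(rep(1, n), Cm)), y)
  r <- as.vector(y - Q %*% crossprod(Q, y))
  n_free <- ncol(Q)
  # dual-form ridge: beta = W'(WW' + lambda I)^-1 r, df = sum ev/(ev+lambda)
  K <- tcrossprod(W)
  eigK <- eigen(K, symmetric = TRUE)
  ev <- pmax(eigK$values, 0)
  rt <- as.vector(crossprod(eigK$vectors, r))
  if (identical(penalty, "gcv")) {
    if (is.null(penalty_grid))
      penalty_grid <- 10^seq(log10(max(m * 1e-4, 1)), log10(m * 1e3),
                             length.out = 30)
    gcv <- vapply(penalty_grid, function(l) {
      a <- ev / (ev + l)
      rss <- sum(((1 - a) * rt)^2)
      df <- sum(a) + n_free
      n * rss / (n - min(df, n - 1))^2
    }, numeric(1))
    lambda <- penalty_grid[which.min(gcv)]
    gcv_path <- data.frame(penalty = penalty_grid, gcv = gcv)
  } else {
    lambda <- penalty
    gcv_path <- NULL
  }
  dual <- eigK$vectors %*% (rt / (ev + lambda))
  beta <- as.vector(crossprod(W, dual))
  structure(list(beta = beta, penalty = lambda, cov_coef = cov_coef,
                 freq = freq, gcv_path = gcv_path,
                 df = sum(ev / (ev + lambda)) + n_free,
                 variant_ids = if (inherits(geno, "genotype_matrix"))
                   geno$variants$id else colnames(X)),
            class = "ridge_model")
}

#' @export
print.ridge_model <- function(x, ...) {
  cat("<ridge_model> ", length(x$beta), " variants, penalty ",
      format(x$penalty, digits = 4), ", effective df ",
      format(x$df, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Predict from a clumped-ridge model
#'
#' @param object a `ridge_model`.
#' @param geno test genotypes in the training column layout (matched by id
#'   for [genotype_matrix()] input).
#' @param covariates test covariates (same columns as training).
#' @param ... unused.
#' @return Numeric vector of predicted phenotypes.
#' @export
predict.ridge_model <- function(object, geno, covariates = NULL, ...) {
  if (inherits(geno, "genotype_matrix") && !is.null(object$variant_ids)) {
    idx <- match(object$variant_ids, geno$variants$id)
    if (anyNA(idx))
      stop("test data are missing model variants", call. = FALSE)
    X <- geno$dosages[, idx, drop = FALSE]
  } else X <- .dosage_matrix(geno)
  W <- standardize_genotypes(X, freq = object$freq)
  n <- nrow(W)
  Cm <- .as_covariate_matrix(covariates, n)
  Xte <- cbind(rep(1, n), Cm)
  as.vector(Xte %*% object$cov_coef) + as.vector(W %*% object$beta)
}
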