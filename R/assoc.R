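# Marginal association scan and LD clumping: the shared upstream of the
# STMGP predictor and of all baseline predictors.

# Core scan on a dosage matrix. Never materializes the standardized n x m
# matrix: with Q an orthonormal basis of [1, C] and y* the projected
# phenotype, the per-variant OLS coefficient of the projected column x* is
# x*'y* / x*'x*, with x*'y* = x'y* and x*'x* = x'x - ||Q'x||^2. Scaling a
# column by s multiplies its coefficient by 1/s, so standardized-scale
# estimates follow from the dosage-scale ones.
.gwas_core <- function(X, y, C = NULL, freq = NULL,
                       scale = c("hwe", "none")) {
  scale <- match.arg(scale)
  n <- nrow(X)
  m <- ncol(X)
  stopifnot(length(y) == n)
  if (anyNA(X)) {
    # mean-imputed missing dosages
    mu <- colMeans(X, na.rm = TRUE)
    idx <- which(is.na(X), arr.ind = TRUE)
    X[idx] <- mu[idx[, 2L]]
  }
  Cm <- .as_covariate_matrix(C, n)
  Q <- .covariate_basis(Cm, n)
  ystar <- as.vector(y - Q %*% crossprod(Q, y))
  xty <- as.vector(crossprod(X, ystar))
  QtX <- crossprod(Q, X)
  wss <- as.vector(colSums(X^2)) - colSums(QtX^2)
  df <- n - ncol(Q) - 1L
  if (df < 1) stop("not enough residual degrees of freedom", call. = FALSE)
  yss <- sum(ystar^2)
  bad <- !is.finite(wss) | wss <= n * 1e-12
  wss[bad] <- NA_real_
  beta_raw <- xty / wss
  rss <- pmax(yss - beta_raw * xty, 0)
  se_raw <- sqrt(rss / df / wss)
  tval <- ifelse(se_raw > 0, beta_raw / se_raw, Inf * sign(beta_raw))
  pval <- pmax(2 * pt(-abs(tval), df), 1e-300)
  s <- if (scale == "hwe") {
    p <- if (is.null(freq)) colMeans(X) / 2 else freq
    sqrt(pmax(2 * p * (1 - p), 0))
  } else rep(1, m)
  beta <- beta_raw * s
  se <- se_raw * s
  beta[bad] <- 0
  se[bad] <- NA_real_
  tval[bad] <- 0
  pval[bad] <- 1
  list(beta = beta, se = se, t = tval, p = pval, df = df, n = n,
       sigma2_null = yss / (n - ncol(Q)))
}

#' Genome-wide marginal association scan
#'
#' For each variant, fits ordinary least squares of the phenotype on
#' intercept, covariates and that variant, and reports the variant
#' coefficient on the standardized-genotype scale with its standard error,
#' t statistic and two-sided P value (t distribution with the residual
#' degrees of freedom).
#'
#' @param geno a [genotype_matrix()] or dosage matrix (columns are counted
#'   alleles 0/1/2; missing entries are mean-imputed).
#' @param y numeric phenotype vector.
#' @param covariates optional covariate matrix/data frame (never includes
#'   the intercept, which is added internally).
#' @param scale `"hwe"` (default) reports coefficients per standard
#'   deviation sqrt(2p(1-p)) of the counted-allele dosage; `"none"` reports
#'   them on the scale of the supplied columns (use for pre-standardized
#'   input).
#' @return A data frame of class `gwas_result` with columns `id`, `beta`,
#'   `se`, `t`, `p`, plus attributes `df` (residual degrees of freedom of
#'   the scan), `n` and `freq`.
#' @export
gwas_scan <- function(geno, y, covariates = NULL, scale = "hwe") {
  X <- .dosage_matrix(geno)
  freq <- if (identical(scale, "hwe")) allele_freq(X) else NULL
  core <- .gwas_core(X, y, covariates, freq = freq, scale = scale)
  ids <- if (inherits(geno, "genotype_matrix")) geno$variants$id
         else if (!is.null(colnames(X))) colnames(X)
         else paste0("snp", seq_len(ncol(X)))
  out <- data.frame(id = ids, beta = core$beta, se = core$se, t = core$t,
                    p = core$p, stringsAsFactors = FALSE)
  attr(out, "df") <- core$df
  attr(out, "n") <- core$n
  attr(out, "freq") <- freq
  attr(out, "sigma2_null") <- core$sigma2_null
  class(out) <- c("gwas_result", "data.frame")
  out
}

#' Write a GWAS result as a PLINK-style association table
#'
#' Columns SNP, CHR, BP, BETA, SE, T, P, column-compatible with PLINK
#' `--linear` output.
#'
#' @param gwas a `gwas_result` from [gwas_scan()].
#' @param G the [genotype_matrix()] that was scanned (for positions).
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_gwas_tsv <- function(gwas, G, path) {
  out <- data.frame(SNP = gwas$id, CHR = G$variants$chrom,
                    BP = G$variants$pos, BETA = gwas$beta, SE = gwas$se,
                    T = gwas$t, P = gwas$p)
  .write_tsv(out, path)
}

#' Greedy LD clumping
#'
#' Standard P-value-ordered clumping: repeatedly retain the most significant
#' remaining variant and discard all variants within `window_kb` kilobases
#' whose squared dosage correlation with it is at least `r2_clump`. P-value
#' ties are broken by genomic position, making the result independent of
#' input order.
#'
#' @param gwas a `gwas_result` aligned with `geno`.
#' @param geno a [genotype_matrix()] (positions and dosages are needed).
#' @param r2_clump squared-correlation threshold (default 0.1).
#' @param window_kb window half-width in kilobases (default 250).
#' @return Sorted integer indices of retained variants.
#' @export
clump_variants <- function(gwas, geno, r2_clump = 0.1, window_kb = 250) {
  stopifnot(inherits(geno, "genotype_matrix"))
  X <- geno$dosages
  chrom <- geno$variants$chrom
  pos <- geno$variants$pos
  m <- ncol(X)
  stopifnot(nrow(gwas) == m)
  ord <- order(gwas$p, chrom, pos)
  active <- rep(TRUE, m)
  kept <- logical(m)
  win <- window_kb * 1000
  for (j in ord) {
    if (!active[j]) next
    kept[j] <- TRUE
    active[j] <- FALSE
    cand <- which(active & chrom == chrom[j] & abs(pos - pos[j]) <= win)
    if (length(cand)) {
      r <- suppressWarnings(cor(X[, j], X[, cand, drop = FALSE],
                                use = "pairwise.complete.obs"))
      r[is.na(r)] <- 0
      active[cand[r^2 >= r2_clump]] <- FALSE
    }
  }
  which(kept)
}
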