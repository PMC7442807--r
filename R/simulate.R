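# Synthetic-data generator: genotypes in Hardy-Weinberg proportions,
# effect sizes from unit-variance families (normal / Laplace / NEG), causal
# sets in approximate linkage equilibrium, and phenotypes with a controlled
# heritability.

#' Simulate unlinked genotypes in Hardy-Weinberg proportions
#'
#' Each variant draws its minor-allele frequency uniformly in
#' \[`maf_low`, `maf_high`\] and genotypes are binomial(2, p) per sample, so
#' variants are in Hardy-Weinberg proportions and mutually independent
#' (linkage equilibrium). This emulates a QC-filtered array panel; it does
#' not model local LD, genotyping error or missingness (add missingness by
#' masking entries if needed).
#'
#' @param n,m sample and variant counts.
#' @param maf_low,maf_high frequency bounds, within (0, 0.5\].
#' @param seed optional integer seed for reproducibility.
#' @return A [genotype_matrix()] with variants placed 1 kb apart on
#'   chromosome 1.
#' @export
simulate_genotypes <- function(n, m, maf_low = 0.01, maf_high = 0.5,
                               seed = NULL) {
  stopifnot(n >= 1, m >= 1)
  if (!(maf_low > 0 && maf_high <= 0.5 && maf_low <= maf_high))
    stop("maf bounds must satisfy 0 < maf_low <= maf_high <= 0.5",
         call. = FALSE)
  .maybe_seed(seed)
  p <- runif(m, maf_low, maf_high)
  X <- .simulate_dosages(n, p)
  genotype_matrix(X, validate = FALSE)
}

# Dosage matrix only (pipeline fast path). Binomial(2, p) per entry via the
# inverse CDF on one uniform draw, generated in column blocks to bound
# temporary allocations at genome-wide panel sizes.
.simulate_dosages <- function(n, p) {
  m <- length(p)
  X <- matrix(0, n, m)
  block <- max(1L, as.integer(2e6 / n))
  for (s in seq(1L, m, by = block)) {
    cols <- s:min(m, s + block - 1L)
    u <- matrix(runif(n * length(cols)), n)
    q0 <- rep((1 - p[cols])^2, each = n)     # P(dosage = 0)
    hi <- rep(1 - p[cols]^2, each = n)       # P(dosage <= 1)
    X[, cols] <- (u >= q0) + (u >= hi)
  }
  X
}

#' Draw causal-variant effect sizes
#'
#' I.i.d. draws with mean 0 and variance exactly 1 from one of three
#' families:
#' \describe{
#'   \item{normal}{standard normal.}
#'   \item{laplace}{Laplace with scale 1/sqrt(2).}
#'   \item{neg}{normal-exponential-gamma: a Laplace distribution whose rate
#'     is gamma-distributed. Drawn hierarchically as
#'     lambda^2 ~ Gamma(shape = `neg_shape`, scale = 2/(`neg_shape` - 1)),
#'     then b | lambda ~ Laplace(0, 1/lambda). The gamma scale is pinned by
#'     the unit-variance constraint; tails get heavier as `neg_shape`
#'     decreases and the family approaches the Laplace as `neg_shape` grows.}
#' }
#'
#' @param k number of effects.
#' @param dist one of `"normal"`, `"laplace"`, `"neg"`.
#' @param neg_shape gamma shape for the NEG family; must exceed 1 (the
#'   compound variance is undefined otherwise).
#' @param seed optional integer seed.
#' @return Numeric vector of length `k`.
#' @export
sample_effects <- function(k, dist = c("normal", "laplace", "neg"),
                           neg_shape = 3, seed = NULL) {
  dist <- match.arg(dist)
  stopifnot(k >= 1)
  .maybe_seed(seed)
  switch(dist,
    normal = rnorm(k),
    laplace = (rexp(k) - rexp(k)) / sqrt(2),
    neg = {
      if (!is.numeric(neg_shape) || neg_shape <= 1)
        stop("neg_shape must exceed 1 for a finite-variance NEG",
             call. = FALSE)
      lambda <- sqrt(rgamma(k, shape = neg_shape,
                            scale = 2 / (neg_shape - 1)))
      (rexp(k) - rexp(k)) / lambda
    })
}

#' Select causal variants in approximate linkage equilibrium
#'
#' Scans variants in random order, accepting a variant iff its squared
#' Pearson dosage correlation with every already-accepted variant is below
#' `r2_max`, until `k` variants are accepted.
#'
#' @param geno a [genotype_matrix()] or dosage matrix.
#' @param k number of causal variants required.
#' @param r2_max pairwise squared-correlation bound (default 0.05).
#' @param seed optional integer seed for the scan order.
#' @return Integer vector of `k` selected variant indices (in acceptance
#'   order).
#' @export
select_causal <- function(geno, k, r2_max = 0.05, seed = NULL) {
  X <- .dosage_matrix(geno)
  .maybe_seed(seed)
  .select_causal_core(X, k, r2_max)
}

.select_causal_core <- function(X, k, r2_max) {
  n <- nrow(X)
  m <- ncol(X)
  stopifnot(k >= 1)
  if (k > m) stop("k exceeds the number of variants", call. = FALSE)
  ord <- sample.int(m)
  accepted <- integer(0)
  Z <- matrix(0, n, k)  # standardized accepted columns
  for (j in ord) {
    x <- X[, j]
    if (anyNA(x)) x[is.na(x)] <- mean(x, na.rm = TRUE)
    s <- sd(x)
    if (!is.finite(s) || s == 0) next
    z <- (x - mean(x)) / s
    if (length(accepted)) {
      r <- crossprod(Z[, seq_along(accepted), drop = FALSE], z) / (n - 1)
      if (max(r^2) >= r2_max) next
    }
    Z[, length(accepted) + 1L] <- z
    accepted <- c(accepted, j)
    if (length(accepted) == k) return(accepted)
  }
  stop("could not find ", k, " variants at r2 < ", r2_max,
       " (achieved ", length(accepted), ")", call. = FALSE)
}

#' Simulate a phenotype with controlled heritability
#'
#' Builds the genetic score g = W b over the causal columns and adds a
#' normal residual whose variance is var(g) * (1/h2 - 1), where var(g) is
#' the empirical variance of the genetic score over all simulated
#' individuals. The realized heritability var(g)/var(y) therefore
#' concentrates tightly at the nominal `h2`.
#'
#' @param W standardized genotype matrix (see [standardize_genotypes()]),
#'   covering all individuals (train and test together).
#' @param b effect sizes, one per causal variant.
#' @param h2 nominal heritability in (0, 1\].
#' @param causal optional column indices of `W` carrying the effects; by
#'   default `b` aligns with all columns of `W`.
#' @param seed optional integer seed for the residual draw.
#' @return An object of class `simulated_phenotype`: list with `y`, `g`,
#'   `e`, `realized_h2` and the nominal `h2`.
#' @export
simulate_phenotype <- function(W, b, h2, causal = NULL, seed = NULL) {
  if (!is.numeric(h2) || length(h2) != 1L || h2 <= 0 || h2 > 1)
    stop("h2 must be in (0, 1]", call. = FALSE)
  if (!is.null(causal)) W <- W[, causal, drop = FALSE]
  if (ncol(W) != length(b))
    stop("length(b) must match the number of causal columns", call. = FALSE)
  g <- as.vector(W %*% b)
  vg <- var(g)
  if (vg == 0 && h2 < 1)
    stop("genetic score has zero variance; cannot calibrate residuals",
         call. = FALSE)
  .maybe_seed(seed)
  e <- if (h2 == 1) numeric(length(g)) else
    rnorm(length(g), 0, sqrt(vg * (1 / h2 - 1)))
  y <- g + e
  structure(list(y = y, g = g, e = e,
                 realized_h2 = if (var(y) > 0) vg / var(y) else 1,
                 h2 = h2),
            class = "simulated_phenotype")
}

#' @export
print.simulated_phenotype <- function(x, ...) {
  cat("<simulated_phenotype> n = ", length(x$y),
      ", nominal h2 = ", x$h2,
      ", realized h2 = ", format(x$realized_h2, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Simulate demographic covariates
#'
#' Age as a uniform integer and sex as Bernoulli, emulating the covariates
#' of an adult population cohort. Optionally inject additive covariate
#' effects into a phenotype with [inject_covariate_effect()].
#'
#' @param n sample count.
#' @param age_range inclusive integer bounds for age (default 35-85).
#' @param p_female probability of sex = 1 (female; default 0.65).
#' @param seed optional integer seed.
#' @return data.frame with integer columns `age` and `sex`.
#' @export
simulate_covariates <- function(n, age_range = c(35L, 85L), p_female = 0.65,
                                seed = NULL) {
  stopifnot(n >= 1, length(age_range) == 2L, age_range[1] <= age_range[2])
  .maybe_seed(seed)
  data.frame(age = sample(seq(age_range[1], age_range[2]), n, replace = TRUE),
             sex = rbinom(n, 1L, p_female))
}

#' @rdname simulate_covariates
#' @param y phenotype vector.
#' @param covariates data frame or matrix of covariates.
#' @param coefficients named or positional numeric vector, one per covariate
#'   column; the linear combination is added to `y`.
#' @export
inject_covariate_effect <- function(y, covariates, coefficients) {
  C <- .as_covariate_matrix(covariates, length(y))
  if (is.null(C)) return(y)
  if (!is.null(names(coefficients)))
    coefficients <- coefficients[colnames(C)]
  stopifnot(length(coefficients) == ncol(C))
  as.vector(y + C %*% coefficients)
}

#' Export a simulated dataset to PLINK-convention files
#'
#' Writes the genotype triplet, a phenotype table and a covariate table
#' (tab-delimited, keyed by FID/IID) plus a truth table of causal variants
#' for oracle testing.
#'
#' @param G a [genotype_matrix()].
#' @param phen a `simulated_phenotype`.
#' @param causal causal variant indices.
#' @param b causal effect sizes.
#' @param dir output directory (created if absent).
#' @param covariates optional covariate data frame.
#' @param basename file prefix (default "sim").
#' @return Invisibly, the paths written.
#' @export
export_simulation <- function(G, phen, causal, b, dir,
                              covariates = NULL, basename = "sim") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  prefix <- file.path(dir, basename)
  write_plink(G, prefix)
  key <- data.frame(FID = G$samples$fid, IID = G$samples$iid)
  paths <- paste0(prefix, c(".pheno.tsv", ".covar.tsv", ".truth.tsv"))
  .write_tsv(cbind(key, PHENO = phen$y), paths[1L])
  if (!is.null(covariates)) .write_tsv(cbind(key, covariates), paths[2L])
  .write_tsv(data.frame(id = G$variants$id[causal], b = b,
                        realized_h2 = phen$realized_h2), paths[3L])
  invisible(c(paste0(prefix, c(".bed", ".bim", ".fam")), paths))
}
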