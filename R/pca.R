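# Principal components of the genomic relationship matrix and
# Tracy-Widom-based selection of significant components, in the style of
# Eigensoft's smartpca/twstats.

# Published quantiles of the Tracy-Widom distribution with beta = 1.
# P values are obtained by linear interpolation; outside the tabulated
# range they are clamped to the extreme tabulated probabilities, which is
# ample resolution for a significance screen at conventional alpha.
.TW1_QUANTILES <- data.frame(
  prob = c(0.01, 0.05, 0.10, 0.30, 0.50, 0.70, 0.90, 0.95, 0.975, 0.99,
           0.999),
  x = c(-3.9139, -3.1808, -2.7824, -1.9104, -1.2686, -0.5923, 0.4501,
        0.9793, 1.4538, 2.0234, 3.2724)
)

# Upper-tail P value of the Tracy-Widom (beta = 1) law.
.ptw1_upper <- function(x) {
  cdf <- approx(.TW1_QUANTILES$x, .TW1_QUANTILES$prob, xout = x,
                rule = 2)$y
  1 - cdf
}

#' Tracy-Widom selection of significant principal components
#'
#' Sequential test in the Eigensoft style: at each step the leading
#' remaining eigenvalue is standardized with the Tracy-Widom (beta = 1)
#' centering and scaling, using a moment-based estimate of the effective
#' number of markers from the remaining spectrum, and compared with the
#' tabulated TW quantiles. Testing stops at the first non-significant
#' component.
#'
#' @param eigenvalues eigenvalues of the genomic relationship matrix, in
#'   decreasing order.
#' @param alpha significance level (default 0.05); `alpha = 0` selects
#'   nothing.
#' @return Integer count of significant leading components.
#' @references Patterson, Price & Reich (2006), PLoS Genetics 2:e190.
#' @export
tracy_widom_select <- function(eigenvalues, alpha = 0.05) {
  .stopifnot_prob(alpha, "alpha")
  if (alpha == 0) return(0L)
  ev <- eigenvalues[eigenvalues > 1e-10]
  if (is.unsorted(rev(ev))) stop("eigenvalues must be decreasing",
                                 call. = FALSE)
  L <- length(ev)
  n_sig <- 0L
  for (i in seq_len(L)) {
    rem <- ev[i:L]
    p <- length(rem)
    if (p < 3) break
    S1 <- sum(rem)
    S2 <- sum(rem^2)
    denom <- (p - 1) * S2 - S1^2
    if (denom <= 0) break
    n_eff <- (p + 1) * S1^2 / denom
    if (n_eff <= 1) break
    l1 <- p * rem[1] / S1
    a <- sqrt(n_eff - 1)
    b <- sqrt(p)
    mu <- (a + b)^2 / n_eff
    sig <- (a + b) / n_eff * (1 / a + 1 / b)^(1 / 3)
    pval <- .ptw1_upper((l1 - mu) / sig)
    if (pval < alpha) n_sig <- n_sig + 1L else break
  }
  n_sig
}

#' Principal components of standardized genotypes
#'
#' Eigendecomposition of the genomic relationship matrix W W' / m of
#' standardized genotypes (GRM-based PCA). Scores are the sample
#' eigenvectors; run it on training and test samples jointly when the same
#' axes must serve both sets.
#'
#' @param geno a [genotype_matrix()], dosage matrix, or an
#'   already-standardized matrix with `standardized = TRUE`.
#' @param n_components number of score columns to return.
#' @param alpha significance level for [tracy_widom_select()].
#' @param standardized set `TRUE` if `geno` is already standardized.
#' @return An object of class `pca_result`: `scores` (samples x
#'   components), `eigenvalues` (all, decreasing), `n_significant`,
#'   `n_samples`, `n_variants`.
#' @export
grm_pca <- function(geno, n_components = 10, alpha = 0.05,
                    standardized = FALSE) {
  W <- if (standardized) as.matrix(geno) else standardize_genotypes(geno)
  n <- nrow(W)
  m <- ncol(W)
  if (n_components > min(n, m))
    stop("n_components exceeds min(n_samples, n_variants)", call. = FALSE)
  K <- tcrossprod(W) / m
  if (!all(is.finite(K))) stop("degenerate genotype matrix", call. = FALSE)
  eig <- eigen(K, symmetric = TRUE)
  ev <- pmax(eig$values, 0)
  structure(list(scores = eig$vectors[, seq_len(n_components), drop = FALSE],
                 eigenvalues = ev,
                 n_significant = tracy_widom_select(ev, alpha = alpha),
                 n_samples = n, n_variants = m),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("<pca_result> ", x$n_samples, " samples, ", x$n_variants,
      " variants\n  significant components (Tracy-Widom): ",
      x$n_significant, "\n", sep = "")
  invisible(x)
}

#' Write principal-component scores as an Eigensoft-style table
#'
#' @param pca a `pca_result`.
#' @param ids sample identifiers.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_evec_tsv <- function(pca, ids, path) {
  out <- data.frame(ID = ids, pca$scores)
  colnames(out) <- c("ID", paste0("PC", seq_len(ncol(pca$scores))))
  .write_tsv(out, path)
}
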