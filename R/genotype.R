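#' Genotype matrix container
#'
#' A light-weight container for a samples x variants dosage matrix with
#' variant and sample metadata, the common currency of all other modules.
#' Dosages count copies of `allele1` (0, 1, 2 or `NA` for missing).
#'
#' @param dosages numeric matrix, samples in rows and variants in columns;
#'   entries must be 0, 1, 2 or `NA`.
#' @param variants optional data frame with one row per variant and columns
#'   `id`, `chrom`, `pos`, `allele1`, `allele2`. Generated when omitted.
#' @param samples optional data frame with one row per sample and columns
#'   `fid`, `iid`, `sex`. Generated when omitted.
#' @param validate check that all non-missing dosages are in \{0, 1, 2\}
#'   (skip only for trusted, freshly simulated input).
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosages`, `variants` and `samples`.
#' @seealso [allele_freq()], [standardize_genotypes()], [read_plink()]
#' @export
#' @examples
#' G <- genotype_matrix(matrix(c(0, 1, 2, 1), 2, 2))
#' allele_freq(G)
genotype_matrix <- function(dosages, variants = NULL, samples = NULL,
                            validate = TRUE) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  n <- nrow(dosages)
  m <- ncol(dosages)
  if (validate) {
    v <- dosages[!is.na(dosages)]
    if (length(v) && !all(v == 0 | v == 1 | v == 2))
      stop("non-missing dosages must be 0, 1 or 2", call. = FALSE)
  }
  if (is.null(variants)) {
    variants <- data.frame(
      id = if (!is.null(colnames(dosages))) colnames(dosages)
           else sprintf("snp%d", seq_len(m)),
      chrom = rep(1L, m),
      pos = seq_len(m) * 1000L,
      allele1 = rep("A", m),
      allele2 = rep("B", m),
      stringsAsFactors = FALSE
    )
  }
  if (anyDuplicated(variants$id))
    stop("duplicate variant ids", call. = FALSE)
  if (is.null(samples)) {
    samples <- data.frame(
      fid = paste0("F", seq_len(n)),
      iid = paste0("I", seq_len(n)),
      sex = rep(0L, n),
      stringsAsFactors = FALSE
    )
  }
  stopifnot(nrow(variants) == m, nrow(samples) == n)
  structure(list(dosages = dosages, variants = variants, samples = samples),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("<genotype_matrix> ", nrow(x$dosages), " samples x ",
      ncol(x$dosages), " variants\n", sep = "")
  miss <- mean(is.na(x$dosages))
  cat("  missingness: ", format(miss, digits = 3), "\n", sep = "")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Subset a genotype matrix
#'
#' @param x a [genotype_matrix()].
#' @param i,j sample and variant indices.
#' @param ... unused.
#' @return A `genotype_matrix` restricted to the selected samples/variants.
#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$dosages))
  if (missing(j)) j <- seq_len(ncol(x$dosages))
  genotype_matrix(x$dosages[i, j, drop = FALSE],
                  variants = x$variants[j, , drop = FALSE],
                  samples = x$samples[i, , drop = FALSE],
                  validate = FALSE)
}

.dosage_matrix <- function(geno) {
  if (inherits(geno, "genotype_matrix")) return(geno$dosages)
  if (is.matrix(geno) && is.double(geno)) return(geno)
  x <- as.matrix(geno)
  storage.mode(x) <- "double"
  x
}

#' Allele frequency of the counted allele
#'
#' Frequency of `allele1` per variant, computed from non-missing dosages as
#' (mean dosage) / 2.
#'
#' @param geno a [genotype_matrix()] or dosage matrix.
#' @return Numeric vector of frequencies in \[0, 1\], one per variant.
#' @export
allele_freq <- function(geno) {
  X <- .dosage_matrix(geno)
  colMeans(X, na.rm = TRUE) / 2
}

#' Per-variant and per-sample call rates
#'
#' Fraction of non-missing genotypes along each axis.
#'
#' @param geno a [genotype_matrix()] or dosage matrix.
#' @return Numeric vector of call rates in \[0, 1\].
#' @export
variant_call_rate <- function(geno) {
  X <- .dosage_matrix(geno)
  1 - colMeans(is.na(X))
}

#' @rdname variant_call_rate
#' @export
sample_call_rate <- function(geno) {
  X <- .dosage_matrix(geno)
  1 - rowMeans(is.na(X))
}

#' Standardize genotypes to unit Hardy-Weinberg variance
#'
#' Transforms dosages x to w = (x - 2p) / sqrt(2p(1-p)), the scale on which
#' all model fitting operates. Missing dosages contribute w = 0
#' (mean imputation). When `freq` is supplied (e.g. training-sample
#' frequencies at prediction time) it overrides the frequencies estimated
#' from `geno`.
#'
#' @param geno a [genotype_matrix()] or dosage matrix.
#' @param freq optional per-variant allele frequencies to standardize by.
#' @return Numeric matrix of standardized genotypes, same shape as the input.
#' @export
standardize_genotypes <- function(geno, freq = NULL) {
  X <- .dosage_matrix(geno)
  p <- if (is.null(freq)) allele_freq(X) else freq
  if (length(p) != ncol(X))
    stop("freq length does not match variant count", call. = FALSE)
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1))
    stop("monomorphic variant (p = 0 or 1): remove by QC before standardizing",
         call. = FALSE)
  s <- sqrt(2 * p * (1 - p))
  W <- sweep(X, 2L, 2 * p, `-`)
  W <- sweep(W, 2L, s, `/`)
  W[is.na(W)] <- 0
  W
}
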