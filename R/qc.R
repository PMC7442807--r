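# Sample/variant quality control: Hardy-Weinberg exact test, call-rate and
# MAF filters, and method-of-moments identity-by-descent pruning.

#' Hardy-Weinberg equilibrium exact test
#'
#' Two-sided exact test for departure from Hardy-Weinberg proportions from
#' genotype counts, using the probability-mass convention: the P value is the
#' sum of probabilities of all heterozygote counts (with the observed allele
#' counts fixed) whose probability does not exceed that of the observed
#' count. This matches the convention of PLINK's `--hwe` exact test
#' (Wigginton et al. 2005).
#'
#' @param n_AA,n_Aa,n_aa nonnegative integer genotype counts (the two
#'   homozygote classes and the heterozygote class).
#' @return Exact two-sided P value in (0, 1\].
#' @export
#' @examples
#' hwe_exact_p(25, 50, 25)   # perfect HW proportions
#' hwe_exact_p(50, 0, 50)    # extreme heterozygote deficit
hwe_exact_p <- function(n_AA, n_Aa, n_aa) {
  counts <- c(n_AA, n_Aa, n_aa)
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts)))
    stop("genotype counts must be nonnegative integers", call. = FALSE)
  n <- sum(counts)
  if (n < 1) stop("at least one genotype required", call. = FALSE)
  rare <- 2 * min(n_AA, n_aa) + n_Aa
  if (rare == 0) return(1)
  hets <- seq(rare %% 2, rare, by = 2)
  probs <- numeric(length(hets))
  # start at (roughly) the modal heterozygote count and fill by recurrence
  mid <- floor(rare * (2 * n - rare) / (2 * n))
  if (mid %% 2 != rare %% 2) mid <- mid + 1
  mid_i <- match(mid, hets)
  probs[mid_i] <- 1
  if (mid_i > 1L) {
    for (i in seq(mid_i, 2L)) {
      h <- hets[i]
      hom_r <- (rare - h) / 2
      hom_c <- n - h - hom_r
      probs[i - 1L] <- probs[i] * h * (h - 1) /
        (4 * (hom_r + 1) * (hom_c + 1))
    }
  }
  if (mid_i < length(hets)) {
    for (i in seq(mid_i, length(hets) - 1L)) {
      h <- hets[i]
      hom_r <- (rare - h) / 2
      hom_c <- n - h - hom_r
      probs[i + 1L] <- probs[i] * 4 * hom_r * hom_c / ((h + 2) * (h + 1))
    }
  }
  probs <- probs / sum(probs)
  p_obs <- probs[match(n_Aa, hets)]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-10)]))
}

.qc_report <- function(removed_samples, removed_variants, n_before, m_before,
                       pairs = NULL) {
  structure(list(removed_samples = removed_samples,
                 removed_variants = removed_variants,
                 relatedness_pairs = pairs,
                 n_samples_before = n_before,
                 n_samples_after = n_before - nrow(removed_samples),
                 n_variants_before = m_before,
                 n_variants_after = m_before - nrow(removed_variants)),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report>\n")
  cat("  samples:  ", x$n_samples_before, " -> ", x$n_samples_after,
      " (", nrow(x$removed_samples), " removed)\n", sep = "")
  cat("  variants: ", x$n_variants_before, " -> ", x$n_variants_after,
      " (", nrow(x$removed_variants), " removed)\n", sep = "")
  invisible(x)
}

.empty_removed <- function() {
  data.frame(id = character(0), reason = character(0),
             stringsAsFactors = FALSE)
}

#' Variant quality control
#'
#' Removes variants failing any of: call rate below `call_min`, exact
#' Hardy-Weinberg P value below `hwe_min`, or minor-allele frequency below
#' `maf_min` (all strict inequalities). The defaults are the standard
#' array-QC thresholds for population cohorts.
#'
#' @param G a [genotype_matrix()].
#' @param call_min minimum variant call rate retained (default 0.99).
#' @param hwe_min minimum HWE exact P value retained (default 1e-4).
#' @param maf_min minimum minor-allele frequency retained (default 0.01).
#' @return A list with elements `genotypes` (the filtered
#'   [genotype_matrix()]) and `report` (a `qc_report`).
#' @export
variant_qc <- function(G, call_min = 0.99, hwe_min = 1e-4, maf_min = 0.01) {
  stopifnot(inherits(G, "genotype_matrix"))
  .stopifnot_prob(call_min, "call_min")
  .stopifnot_prob(hwe_min, "hwe_min")
  .stopifnot_prob(maf_min, "maf_min")
  X <- G$dosages
  cr <- variant_call_rate(X)
  p <- allele_freq(X)
  maf <- pmin(p, 1 - p)
  maf[is.nan(maf)] <- 0  # all-missing column
  hwe <- vapply(seq_len(ncol(X)), function(j) {
    x <- X[, j]
    x <- x[!is.na(x)]
    if (!length(x)) return(1)
    hwe_exact_p(sum(x == 2), sum(x == 1), sum(x == 0))
  }, numeric(1))
  fail_cr <- cr < call_min
  fail_hwe <- hwe < hwe_min
  fail_maf <- maf < maf_min
  drop <- which(fail_cr | fail_hwe | fail_maf)
  reason <- vapply(drop, function(j) {
    paste(c("call_rate", "hwe", "maf")[c(fail_cr[j], fail_hwe[j],
                                         fail_maf[j])], collapse = ",")
  }, character(1))
  removed <- data.frame(id = G$variants$id[drop], reason = reason,
                        stringsAsFactors = FALSE)
  keep <- setdiff(seq_len(ncol(X)), drop)
  list(genotypes = G[, keep],
       report = .qc_report(.empty_removed(), removed, nrow(X), ncol(X)))
}

#' Sample quality control
#'
#' Removes samples whose genotype call rate is strictly below `call_min`.
#'
#' @param G a [genotype_matrix()].
#' @param call_min minimum sample call rate retained (default 0.98).
#' @return A list with elements `genotypes` and `report`, as [variant_qc()].
#' @export
sample_qc <- function(G, call_min = 0.98) {
  stopifnot(inherits(G, "genotype_matrix"))
  .stopifnot_prob(call_min, "call_min")
  cr <- sample_call_rate(G$dosages)
  drop <- which(cr < call_min)
  removed <- data.frame(id = G$samples$iid[drop],
                        reason = rep("call_rate", length(drop)),
                        stringsAsFactors = FALSE)
  keep <- setdiff(seq_len(nrow(G$dosages)), drop)
  list(genotypes = G[keep, ],
       report = .qc_report(removed, .empty_removed(), nrow(G$dosages),
                           ncol(G$dosages)))
}

#' Relatedness pruning by identity-by-descent
#'
#' Method-of-moments IBD estimation for every sample pair: observed
#' identity-by-state counts are compared with their Hardy-Weinberg
#' expectations given the sample allele frequencies, yielding
#' P(IBD = 0/1/2) and PI_HAT = P(IBD = 2) + P(IBD = 1)/2. For each pair with
#' PI_HAT above the threshold, the member with the lower genotype call rate
#' is removed (on ties, the later-ordered member).
#'
#' The estimator uses the plain moment expectations without finite-sample
#' bias corrections, which is accurate for the panel sizes this package
#' simulates (thousands of variants).
#'
#' @param G a [genotype_matrix()] with at least two samples.
#' @param pihat_max PI_HAT threshold above which a pair is considered
#'   related (default 0.09375, halfway between second- and third-degree
#'   relative expectations).
#' @return A list with `keep` (retained sample indices), `removed`
#'   (data frame of removed samples), and `pairs` (data frame of flagged
#'   pairs with their PI_HAT).
#' @export
ibd_prune <- function(G, pihat_max = 0.09375) {
  stopifnot(inherits(G, "genotype_matrix"))
  X <- G$dosages
  n <- nrow(X)
  if (n < 2) stop("at least two samples required", call. = FALSE)
  p <- allele_freq(X)
  ok <- is.finite(p) & p > 0 & p < 1
  X <- X[, ok, drop = FALSE]
  if (!ncol(X)) stop("no polymorphic variants for IBD estimation",
                     call. = FALSE)
  # IBS-state expectations under IBD 0/1 from allele counts, using
  # falling-factorial (sampling-without-replacement) estimates of the
  # frequency products so that plug-in bias from estimating p on the same
  # samples cancels (the PLINK convention)
  xc <- colSums(X, na.rm = TRUE)               # counted-allele count
  tc <- 2 * colSums(!is.na(X))                 # total allele count
  yc <- tc - xc
  d4 <- tc * (tc - 1) * (tc - 2) * (tc - 3)
  d3 <- tc * (tc - 1) * (tc - 2)
  e0_i0 <- 2 * xc * (xc - 1) * yc * (yc - 1) / d4          # P(IBS0 | IBD0)
  e1_i0 <- (4 * xc * (xc - 1) * (xc - 2) * yc +
              4 * xc * yc * (yc - 1) * (yc - 2)) / d4      # P(IBS1 | IBD0)
  e2_i0 <- 1 - e0_i0 - e1_i0                               # P(IBS2 | IBD0)
  e1_i1 <- (2 * xc * (xc - 1) * yc + 2 * xc * yc * (yc - 1)) /
    d3                                                     # P(IBS1 | IBD1)
  e2_i1 <- 1 - e1_i1                                       # P(IBS2 | IBD1)
  has_missing <- anyNA(X)
  I0 <- (X == 0) * 1; I0[is.na(I0)] <- 0
  I1 <- (X == 1) * 1; I1[is.na(I1)] <- 0
  I2 <- (X == 2) * 1; I2[is.na(I2)] <- 0
  N_ibs0 <- tcrossprod(I0, I2); N_ibs0 <- N_ibs0 + t(N_ibs0)
  N_ibs2 <- tcrossprod(I0) + tcrossprod(I1) + tcrossprod(I2)
  if (has_missing) {
    V <- (!is.na(X)) * 1
    pair_sum <- function(a) tcrossprod(sweep(V, 2L, a, `*`), V)
    S <- tcrossprod(V)
    E0_0 <- pair_sum(e0_i0); E1_0 <- pair_sum(e1_i0); E2_0 <- pair_sum(e2_i0)
    E1_1 <- pair_sum(e1_i1); E2_1 <- pair_sum(e2_i1)
  } else {
    S <- matrix(ncol(X), n, n)
    E0_0 <- matrix(sum(e0_i0), n, n); E1_0 <- matrix(sum(e1_i0), n, n)
    E2_0 <- matrix(sum(e2_i0), n, n); E1_1 <- matrix(sum(e1_i1), n, n)
    E2_1 <- matrix(sum(e2_i1), n, n)
  }
  N_ibs1 <- S - N_ibs0 - N_ibs2
  P0 <- N_ibs0 / E0_0
  P1 <- (N_ibs1 - P0 * E1_0) / E1_1
  P2 <- (N_ibs2 - P0 * E2_0 - P1 * E2_1) / S
  # clamp only the final share: truncating the (noisy, mean-zero) component
  # estimates individually would bias PI_HAT upward for unrelated pairs
  pihat <- pmin(pmax(P2 + 0.5 * P1, 0), 1)
  cr <- sample_call_rate(G$dosages)
  flag <- which(upper.tri(pihat) & pihat > pihat_max, arr.ind = TRUE)
  pairs <- data.frame(i = flag[, 1L], j = flag[, 2L],
                      iid_i = G$samples$iid[flag[, 1L]],
                      iid_j = G$samples$iid[flag[, 2L]],
                      pihat = pihat[flag])
  pairs <- pairs[order(-pairs$pihat), , drop = FALSE]
  dropped <- logical(n)
  for (r in seq_len(nrow(pairs))) {
    i <- pairs$i[r]; j <- pairs$j[r]
    if (dropped[i] || dropped[j]) next
    # drop the lower-call-rate member; ties drop the later-ordered one
    dropped[if (cr[i] < cr[j]) i else j] <- TRUE
  }
  keep <- which(!dropped)
  removed <- data.frame(id = G$samples$iid[dropped],
                        reason = rep("relatedness", sum(dropped)),
                        stringsAsFactors = FALSE)
  list(keep = keep, removed = removed, pairs = pairs)
}
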