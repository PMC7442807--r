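# Shared fixture builders; everything is generated in code at test time.

# Small genotype panel with a phenotype of known architecture.
make_sim <- function(n = 200, m = 60, k = 10, h2 = 0.5, seed = 1,
                     dist = "normal") {
  G <- simulate_genotypes(n, m, maf_low = 0.1, seed = seed)
  W <- standardize_genotypes(G)
  causal <- select_causal(G, k, r2_max = 0.2, seed = seed + 1)
  b <- sample_effects(k, dist, seed = seed + 2)
  phen <- simulate_phenotype(W, b, h2, causal = causal, seed = seed + 3)
  list(G = G, W = W, causal = causal, b = b, phen = phen, y = phen$y)
}

# Exact HWE probability oracle by direct multinomial enumeration:
# P(het = h | n genotypes, nr rare alleles) via log-factorials.
hwe_enum_p <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nr <- 2 * min(n_AA, n_aa) + n_Aa
  hets <- seq(nr %% 2, nr, by = 2)
  logp <- vapply(hets, function(h) {
    hr <- (nr - h) / 2
    hc <- n - h - hr
    lgamma(n + 1) - lgamma(hr + 1) - lgamma(h + 1) - lgamma(hc + 1) +
      h * log(2) + lgamma(nr + 1) + lgamma(2 * n - nr + 1) -
      lgamma(2 * n + 1)
  }, numeric(1))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[match(n_Aa, hets)]
  min(1, sum(p[p <= obs * (1 + 1e-10)]))
}

# Independent O(n^2) medcouple via an explicit double loop (no ties).
medcouple_brute <- function(x) {
  x <- sort(x)
  med <- median(x)
  xp <- x[x >= med]
  xm <- x[x <= med]
  h <- c()
  for (a in xp) for (b in xm) {
    if (a > b) h <- c(h, ((a - med) - (med - b)) / (a - b))
    else if (a == b && a == med) h <- c(h, 0)  # single tie at the median
  }
  median(h)
}

# Fisher two-sided P by full enumeration of tables with fixed margins.
fisher_enum_p <- function(a, b, c, d) {
  r1 <- a + b
  c1 <- a + c
  n <- a + b + c + d
  lo <- max(0, c1 - (n - r1))
  hi <- min(r1, c1)
  k <- lo:hi
  logp <- lgamma(r1 + 1) - lgamma(k + 1) - lgamma(r1 - k + 1) +
    lgamma(n - r1 + 1) - lgamma(c1 - k + 1) -
    lgamma(n - r1 - (c1 - k) + 1) -
    (lgamma(n + 1) - lgamma(c1 + 1) - lgamma(n - c1 + 1))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[match(a, k)]
  min(1, sum(p[p <= obs * (1 + 1e-7)]))
}
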