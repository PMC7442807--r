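# Internal helpers shared across modules.

# Deterministic substream seed derived from a root seed, a stream name and an
# index, so that any replicate of a benchmark is reproducible in isolation.
# Kept below 2^31 - 1 (R integers are 32-bit).
.substream_seed <- function(root, name, index = 0L) {
  chars <- utf8ToInt(name)
  h <- sum(chars * seq_along(chars)) %% 65521
  s <- (as.double(root) %% 2147483647) * 48271 + h * 7919 + as.double(index) * 104729
  as.integer(s %% 2147483629 + 1)
}

# Set the RNG only when a seed is supplied.
.maybe_seed <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}

# Coerce covariates (NULL, vector, data.frame or matrix) to a numeric matrix
# with useful column names, or NULL when empty.
.as_covariate_matrix <- function(C, n = NULL) {
  if (is.null(C)) return(NULL)
  if (is.data.frame(C)) C <- as.matrix(C)
  if (is.vector(C) && !is.list(C)) C <- matrix(C, ncol = 1L)
  if (!is.numeric(C)) stop("covariates must be numeric", call. = FALSE)
  if (ncol(C) == 0L) return(NULL)
  if (is.null(colnames(C))) colnames(C) <- paste0("cov", seq_len(ncol(C)))
  if (!is.null(n) && nrow(C) != n)
    stop("covariate rows (", nrow(C), ") do not match samples (", n, ")",
         call. = FALSE)
  C
}

# QR basis of [1, C]; errors on rank deficiency, naming the offending columns.
.covariate_basis <- function(C, n) {
  X <- cbind(`(Intercept)` = rep(1, n), C)
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    bad <- colnames(X)[qrx$pivot[(qrx$rank + 1L):ncol(X)]]
    stop("covariate matrix is rank deficient (collinear: ",
         paste(bad, collapse = ", "), ")", call. = FALSE)
  }
  qr.Q(qrx)
}

# Residuals of y after regressing on [1, C] (ordinary least squares).
.residualize <- function(y, C = NULL) {
  n <- length(y)
  Q <- .covariate_basis(.as_covariate_matrix(C, n), n)
  as.vector(y - Q %*% crossprod(Q, y))
}

.write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.stopifnot_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(name, " must be a single value in [0, 1]", call. = FALSE)
  invisible(x)
}
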