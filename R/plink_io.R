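# PLINK1 binary triplet reader/writer.
#
# .bed layout: magic bytes 0x6C 0x1B, mode byte 0x01 (SNP-major), then
# ceiling(n/4) bytes per variant, 2 bits per genotype, sample pairs packed
# LSB-first. 2-bit codes: 00 = two copies of allele1 (dosage 2),
# 01 = missing, 10 = heterozygote (dosage 1), 11 = two copies of allele2
# (dosage 0). Dosages count allele1 of the .bim record.

.BED_CODES <- c(2, NA, 1, 0)           # 2-bit value (0..3) -> dosage
.BED_PACK <- c(`2` = 0L, `1` = 2L, `0` = 3L)  # dosage -> 2-bit value

# 256 x 4 lookup: byte value (0-based row index - 1) -> 4 dosages.
.bed_lut <- local({
  b <- 0:255
  cbind(.BED_CODES[bitwAnd(b, 3L) + 1L],
        .BED_CODES[bitwAnd(bitwShiftR(b, 2L), 3L) + 1L],
        .BED_CODES[bitwAnd(bitwShiftR(b, 4L), 3L) + 1L],
        .BED_CODES[bitwAnd(bitwShiftR(b, 6L), 3L) + 1L])
})

#' Read a PLINK1 binary genotype triplet
#'
#' Reads `prefix.bed` / `prefix.bim` / `prefix.fam` into a
#' [genotype_matrix()]. Only the SNP-major layout (mode byte 0x01), the
#' format written by PLINK 1.x and by [write_plink()], is supported.
#' Dosages count `allele1` (the first allele column of the .bim record).
#'
#' @param prefix path prefix of the triplet (without extension).
#' @return A [genotype_matrix()].
#' @export
#' @seealso [write_plink()]
read_plink <- function(prefix) {
  paths <- paste0(prefix, c(".bed", ".bim", ".fam"))
  missing_files <- paths[!file.exists(paths)]
  if (length(missing_files))
    stop("missing PLINK files: ", paste(missing_files, collapse = ", "),
         call. = FALSE)
  fam <- utils::read.table(paths[3L], header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("fid", "iid", "pat", "mat", "sex",
                                         "pheno"))
  bim <- utils::read.table(paths[2L], header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("chrom", "id", "cm", "pos",
                                         "allele1", "allele2"))
  n <- nrow(fam)
  m <- nrow(bim)
  raw <- readBin(paths[1L], "raw", n = file.size(paths[1L]))
  if (length(raw) < 3L || raw[1L] != as.raw(0x6c) || raw[2L] != as.raw(0x1b))
    stop("not a PLINK1 .bed file (bad magic bytes)", call. = FALSE)
  if (raw[3L] != as.raw(0x01))
    stop("unsupported .bed mode byte (only SNP-major 0x01 is handled)",
         call. = FALSE)
  bpv <- ceiling(n / 4)
  if (length(raw) - 3L != bpv * m)
    stop(".bed is truncated or padded: expected ", bpv * m,
         " data bytes, found ", length(raw) - 3L, call. = FALSE)
  body <- as.integer(raw[-(1:3)]) + 1L
  # decode all bytes at once, then drop the per-variant padding rows
  dec <- t(.bed_lut[body, , drop = FALSE])        # 4 x (bpv * m)
  dim(dec) <- c(4L * bpv, m)
  X <- dec[seq_len(n), , drop = FALSE]
  colnames(X) <- bim$id
  genotype_matrix(X,
                  variants = bim[, c("id", "chrom", "pos", "allele1",
                                     "allele2")],
                  samples = fam[, c("fid", "iid", "sex")],
                  validate = FALSE)
}

#' Write a PLINK1 binary genotype triplet
#'
#' Writes the SNP-major PLINK1 format readable by [read_plink()] and by
#' standard tooling. Round-trips bit-exactly, including missing genotypes.
#'
#' @param G a [genotype_matrix()].
#' @param prefix output path prefix.
#' @return Invisibly, the three file paths written.
#' @export
write_plink <- function(G, prefix) {
  stopifnot(inherits(G, "genotype_matrix"))
  if (anyDuplicated(G$variants$id))
    stop("duplicate variant ids", call. = FALSE)
  X <- G$dosages
  n <- nrow(X)
  m <- ncol(X)
  bpv <- ceiling(n / 4)
  # dosage -> 2-bit code; missing -> 01; padding -> 00
  codes <- matrix(0L, nrow = 4L * bpv, ncol = max(m, 1L))
  if (m > 0L && n > 0L) {
    v <- as.integer(X)
    code <- integer(length(v))
    code[is.na(v)] <- 1L
    code[!is.na(v)] <- .BED_PACK[as.character(v[!is.na(v)])]
    codes[seq_len(n), ] <- matrix(code, nrow = n)
  }
  i <- seq(1L, 4L * bpv, by = 4L)
  bytes <- codes[i, , drop = FALSE] +
    4L * codes[i + 1L, , drop = FALSE] +
    16L * codes[i + 2L, , drop = FALSE] +
    64L * codes[i + 3L, , drop = FALSE]
  if (m == 0L) bytes <- bytes[, 0, drop = FALSE]
  paths <- paste0(prefix, c(".bed", ".bim", ".fam"))
  con <- file(paths[1L], "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  if (length(bytes)) writeBin(as.raw(as.vector(bytes)), con)
  bim <- data.frame(chrom = G$variants$chrom, id = G$variants$id,
                    cm = rep(0, m), pos = G$variants$pos,
                    allele1 = G$variants$allele1,
                    allele2 = G$variants$allele2)
  utils::write.table(bim, paths[2L], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  fam <- data.frame(fid = G$samples$fid, iid = G$samples$iid,
                    pat = rep(0L, n), mat = rep(0L, n),
                    sex = G$samples$sex, pheno = rep(-9, n))
  utils::write.table(fam, paths[3L], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(paths)
}
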