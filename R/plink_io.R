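# PLINK 1 binary genotype I/O.
#
# .bed is SNP-major: 3 magic bytes (0x6c 0x1b 0x01) then ceiling(n/4) bytes
# per SNP, 2 bits per sample, lowest-order bits first. Dose counts copies of
# the .bim A1 allele: code 00 -> 2, 10 -> 1, 11 -> 0, 01 -> missing.

.bed_magic <- as.raw(c(0x6c, 0x1b, 0x01))

# 256 x 4 dose lookup, row = byte value + 1, col = sample slot within byte
.bed_decode_table <- local({
  codes <- c(2L, NA_integer_, 1L, 0L) # 2-bit values 0..3
  tab <- matrix(NA_integer_, 256L, 4L)
  for (b in 0:255) {
    tab[b + 1L, ] <- codes[bitwAnd(bitwShiftR(b, c(0L, 2L, 4L, 6L)), 3L) + 1L]
  }
  tab
})

#' Read PLINK 1 binary genotypes
#'
#' Reads a `.bed`/`.bim`/`.fam` trio into a `genotype_matrix`: an n x m
#' allele-dose matrix (0, 1, 2 or `NA`) plus SNP and sample metadata. The
#' dose counts copies of the `.bim` A1 allele; standardization downstream is
#' sign-symmetric so results do not depend on this convention.
#'
#' @param prefix Path prefix; `<prefix>.bed`, `.bim` and `.fam` must exist.
#' @return A `genotype_matrix` with elements `calls` (n x m integer matrix
#'   with sample/SNP dimnames), `snps` (data.frame: id, chrom, pos, allele1,
#'   allele2) and `samples` (character vector of individual IDs).
#' @export
read_plink <- function(prefix) {
  paths <- paste0(prefix, c(".bed", ".bim", ".fam"))
  for (p in paths) {
    if (!file.exists(p)) stop("missing PLINK file: ", p)
  }
  bim <- utils::read.table(paths[2], header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("chrom", "id", "cm", "pos", "allele1", "allele2"),
                           colClasses = c("character", "character", "numeric",
                                          "integer", "character", "character"))
  fam <- utils::read.table(paths[3], header = FALSE, stringsAsFactors = FALSE)
  n <- nrow(fam)
  m <- nrow(bim)
  samples <- as.character(fam[[2]])
  if (anyDuplicated(samples)) stop("duplicate sample IDs in .fam")
  if (anyDuplicated(bim$id)) stop("duplicate SNP IDs in .bim")

  sz <- file.size(paths[1])
  raw <- readBin(paths[1], "raw", n = sz)
  if (length(raw) < 3L || !identical(raw[1:3], .bed_magic)) {
    stop("malformed .bed magic number in ", paths[1])
  }
  bps <- ceiling(n / 4)
  if (length(raw) != 3L + bps * m) {
    stop("truncated .bed: expected ", 3L + bps * m, " bytes, found ", length(raw))
  }
  payload <- raw[-(1:3)]
  doses <- t(.bed_decode_table[as.integer(payload) + 1L, , drop = FALSE])
  dim(doses) <- c(4L * bps, m)
  calls <- doses[seq_len(n), , drop = FALSE]
  dimnames(calls) <- list(samples, bim$id)
  new_genotype_matrix(calls, bim[, c("id", "chrom", "pos", "allele1", "allele2")], samples)
}

new_genotype_matrix <- function(calls, snps, samples) {
  structure(list(calls = calls, snps = snps, samples = samples),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$samples), "samples x", nrow(x$snps), "SNPs\n")
  miss <- mean(is.na(x$calls))
  cat(sprintf("  missing rate: %.4f\n", miss))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Write PLINK 1 binary genotypes
#'
#' Inverse of [read_plink()]: `read_plink(write_plink(G, prefix))` recovers
#' `G` exactly, including missing calls.
#'
#' @param G A `genotype_matrix`.
#' @param prefix Output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(G, prefix) {
  stopifnot(inherits(G, "genotype_matrix"))
  n <- length(G$samples)
  m <- nrow(G$snps)
  bps <- ceiling(n / 4)
  # dose -> 2-bit code: 2 -> 0, NA -> 1, 1 -> 2, 0 -> 3
  code <- matrix(0L, 4L * bps, m)
  x <- G$calls
  cd <- ifelse(is.na(x), 1L, c(3L, 2L, 0L)[x + 1L])
  code[seq_len(n), ] <- cd
  dim(code) <- c(4L, bps * m)
  bytes <- as.raw(code[1L, ] + 4L * code[2L, ] + 16L * code[3L, ] + 64L * code[4L, ])
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(.bed_magic, con)
  writeBin(bytes, con)
  utils::write.table(
    data.frame(G$snps$chrom, G$snps$id, 0, G$snps$pos, G$snps$allele1, G$snps$allele2),
    paste0(prefix, ".bim"),
    quote = FALSE, row.names = FALSE, col.names = FALSE, sep = "\t")
  utils::write.table(
    data.frame(G$samples, G$samples, 0, 0, 0, -9),
    paste0(prefix, ".fam"),
    quote = FALSE, row.names = FALSE, col.names = FALSE, sep = "\t")
  invisible(prefix)
}

#' Subset a genotype matrix
#'
#' @param G A `genotype_matrix`.
#' @param samples Sample IDs (character) or indices; `NULL` keeps all.
#' @param snps SNP IDs (character) or indices; `NULL` keeps all.
#' @return A `genotype_matrix` restricted to the requested rows/columns.
#' @export
subset_genotypes <- function(G, samples = NULL, snps = NULL) {
  stopifnot(inherits(G, "genotype_matrix"))
  ri <- seq_along(G$samples)
  ci <- seq_len(nrow(G$snps))
  if (!is.null(samples)) {
    ri <- if (is.character(samples)) match(samples, G$samples) else samples
    if (anyNA(ri)) stop("unknown sample IDs: ",
                        paste(samples[is.na(match(samples, G$samples))], collapse = ", "))
  }
  if (!is.null(snps)) {
    ci <- if (is.character(snps)) match(snps, G$snps$id) else snps
    if (anyNA(ci)) stop("unknown SNP IDs requested")
  }
  new_genotype_matrix(G$calls[ri, ci, drop = FALSE],
                      G$snps[ci, , drop = FALSE],
                      G$samples[ri])
}
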