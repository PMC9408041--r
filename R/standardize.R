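# Column standardization of allele doses and phenotype/SNP-set loaders.

#' Standardize genotype columns
#'
#' Converts allele doses to the unit-variance scale used by the genomic
#' relationship matrix: column j becomes `(dose - 2*f_j) / sqrt(2*f_j*(1-f_j))`
#' with `f_j` the A1 allele frequency. By default `f_j` is estimated from the
#' non-missing calls of `G` itself; passing `ref_freqs` (e.g. training-set
#' frequencies when standardizing a test set) reproduces the reference
#' centering, which keeps backsolved training effects applicable to test
#' genotypes. Missing doses are mean-imputed, i.e. standardized to exactly 0.
#'
#' The scaling uses the Hardy-Weinberg expected variance `2f(1-f)`, so the
#' empirical column variance is 1 in expectation under HWE, not identically.
#'
#' @param G A `genotype_matrix`.
#' @param snps Optional SNP IDs or column indices to standardize (default all).
#' @param ref_freqs Optional per-SNP allele frequencies; either named by SNP
#'   ID or positional in the order of the selected columns.
#' @return A `std_geno`: list with `values` (n x m numeric matrix), `freqs`
#'   (frequencies used) and `snp_ids`.
#' @export
standardize <- function(G, snps = NULL, ref_freqs = NULL) {
  stopifnot(inherits(G, "genotype_matrix"))
  if (!is.null(snps)) G <- subset_genotypes(G, snps = snps)
  x <- G$calls
  ids <- G$snps$id
  if (is.null(ref_freqs)) {
    f <- colMeans(x, na.rm = TRUE) / 2
  } else {
    f <- if (!is.null(names(ref_freqs))) {
      fr <- ref_freqs[ids]
      if (anyNA(fr)) stop("ref_freqs missing for SNPs: ",
                          paste(ids[is.na(fr)], collapse = ", "))
      unname(fr)
    } else {
      if (length(ref_freqs) != ncol(x)) stop("ref_freqs length mismatch")
      ref_freqs
    }
  }
  bad <- !is.finite(f) | f <= 0 | f >= 1
  if (any(bad)) {
    stop("cannot standardize monomorphic SNP(s): ",
         paste(utils::head(ids[bad], 5), collapse = ", "))
  }
  z <- sweep(x, 2L, 2 * f, "-")
  z <- sweep(z, 2L, sqrt(2 * f * (1 - f)), "/")
  z[is.na(z)] <- 0
  dimnames(z) <- dimnames(x)
  new_std_geno(z, f, ids)
}

new_std_geno <- function(values, freqs, snp_ids) {
  names(freqs) <- snp_ids
  structure(list(values = values, freqs = freqs, snp_ids = snp_ids),
            class = "std_geno")
}

#' @export
print.std_geno <- function(x, ...) {
  cat("std_geno:", nrow(x$values), "samples x", ncol(x$values), "SNPs\n")
  invisible(x)
}

#' @export
dim.std_geno <- function(x) dim(x$values)

subset_std_geno <- function(Zs, snps) {
  ci <- if (is.character(snps)) match(snps, Zs$snp_ids) else snps
  if (anyNA(ci)) stop("unknown SNP IDs requested from std_geno")
  new_std_geno(Zs$values[, ci, drop = FALSE], unname(Zs$freqs[ci]), Zs$snp_ids[ci])
}

#' Read a phenotype table
#'
#' Whitespace-delimited table with a header row; the first column holds
#' sample IDs, missing values encoded as `NA`. Returns a named numeric
#' vector, optionally reordered to a requested sample order and optionally
#' standardized to mean 0, variance 1.
#'
#' @param file Path to the phenotype file.
#' @param trait Column name of the trait (default: the second column).
#' @param ids Optional sample IDs defining the output order; an error lists
#'   any requested ID absent from the file.
#' @param standardize If `TRUE`, center and scale to unit sample variance.
#' @return Named numeric vector with attribute `standardized`.
#' @export
read_phenotype <- function(file, trait = NULL, ids = NULL, standardize = FALSE) {
  tab <- utils::read.table(file, header = TRUE, stringsAsFactors = FALSE,
                           na.strings = "NA")
  if (ncol(tab) < 2) stop("phenotype file needs an ID column and a trait column")
  if (is.null(trait)) trait <- names(tab)[2]
  if (!trait %in% names(tab)) stop("trait column not found: ", trait)
  y <- as.numeric(tab[[trait]])
  names(y) <- as.character(tab[[1]])
  if (!is.null(ids)) {
    miss <- setdiff(ids, names(y))
    if (length(miss)) stop("samples missing from phenotype file: ",
                           paste(miss, collapse = ", "))
    y <- y[ids]
  }
  if (standardize) y <- standardize_phenotype(y)
  attr(y, "standardized") <- standardize
  y
}

#' Standardize a phenotype vector to mean 0, variance 1
#'
#' @param y Numeric vector (sample standard deviation must be positive).
#' @return Standardized vector with attributes `center` and `scale`.
#' @export
standardize_phenotype <- function(y) {
  if (anyNA(y)) stop("phenotype contains missing values")
  s <- stats::sd(y)
  if (!is.finite(s) || s == 0) stop("phenotype has zero variance; cannot standardize")
  out <- (y - mean(y)) / s
  attr(out, "center") <- mean(y)
  attr(out, "scale") <- s
  attr(out, "standardized") <- TRUE
  out
}

#' Read a SNP-set file
#'
#' One SNP ID per line; blank lines and `#` comments are ignored; duplicate
#' IDs are collapsed with a warning.
#'
#' @param file Path.
#' @return Character vector of unique SNP IDs.
#' @export
read_snp_set <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty SNP-set file: ", file)
  if (anyDuplicated(lines)) {
    warning("duplicate SNP IDs collapsed in ", file)
    lines <- unique(lines)
  }
  lines
}

#' Write a SNP-set file
#'
#' @param ids Character vector of SNP IDs.
#' @param file Path.
#' @return `file`, invisibly.
#' @export
write_snp_set <- function(ids, file) {
  writeLines(as.character(ids), file)
  invisible(file)
}
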