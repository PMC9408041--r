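# Genomic relationship matrices and the phenotypic covariance V.

#' Compute a genomic relationship matrix
#'
#' `A = Z Z' / m` over column-standardized genotypes, the realized
#' relationship estimator on the unit-variance scale. Used both for the
#' all-SNP kernel and for the prior-subset kernel of the partitioned model.
#'
#' @param Zs A `std_geno` with at least one SNP column.
#' @return A `grm`: list with `matrix` (n x n symmetric), `n_snps`,
#'   `sample_ids`.
#' @export
compute_grm <- function(Zs) {
  stopifnot(inherits(Zs, "std_geno"))
  m <- ncol(Zs$values)
  if (m < 1) stop("GRM requires at least one SNP")
  A <- tcrossprod(Zs$values) / m
  A <- (A + t(A)) / 2
  structure(list(matrix = A, n_snps = m, sample_ids = rownames(Zs$values)),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat("grm:", nrow(x$matrix), "samples,", x$n_snps, "SNPs; mean diagonal",
      sprintf("%.4f\n", mean(diag(x$matrix))))
  invisible(x)
}

#' Assemble the phenotypic covariance V
#'
#' `V = sum_k A_k * sigma2_k + I * sigma2_e`. Positive definiteness is
#' verified via a Cholesky factorization.
#'
#' @param grms List of `grm` objects sharing the same sample order.
#' @param variances Non-negative variance for each GRM.
#' @param residual_variance Positive residual variance on the diagonal.
#' @return List with `matrix` (n x n) and `components` (the weights used).
#' @export
assemble_V <- function(grms, variances, residual_variance) {
  stopifnot(length(grms) == length(variances), all(variances >= 0),
            residual_variance > 0)
  ids <- grms[[1]]$sample_ids
  n <- nrow(grms[[1]]$matrix)
  V <- diag(residual_variance, n)
  for (k in seq_along(grms)) {
    g <- grms[[k]]
    if (!identical(g$sample_ids, ids)) stop("GRMs have mismatched sample order")
    V <- V + variances[k] * g$matrix
  }
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) stop("assembled V is not positive definite")
  list(matrix = V,
       components = list(variances = variances,
                         residual_variance = residual_variance))
}

#' Write a GRM in the 3-file GCTA binary dialect
#'
#' `prefix.grm.bin` (float32 lower triangle including the diagonal, row by
#' row), `prefix.grm.N.bin` (float32 SNP count per pair) and
#' `prefix.grm.id`. Provided for interoperability; not used internally.
#'
#' @param grm A `grm`.
#' @param prefix Output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_gcta_grm <- function(grm, prefix) {
  stopifnot(inherits(grm, "grm"))
  n <- nrow(grm$matrix)
  lower <- grm$matrix[upper.tri(grm$matrix, diag = TRUE)]
  # column-major upper triangle == row-major lower triangle
  con <- file(paste0(prefix, ".grm.bin"), "wb")
  writeBin(as.numeric(lower), con, size = 4L)
  close(con)
  con <- file(paste0(prefix, ".grm.N.bin"), "wb")
  writeBin(rep(as.numeric(grm$n_snps), length(lower)), con, size = 4L)
  close(con)
  ids <- grm$sample_ids
  if (is.null(ids)) ids <- as.character(seq_len(n))
  utils::write.table(data.frame(ids, ids), paste0(prefix, ".grm.id"),
                     quote = FALSE, row.names = FALSE, col.names = FALSE,
                     sep = "\t")
  invisible(prefix)
}
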