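# BLUP of genetic values, SNP-effect backsolving and test-set prediction.
#
# Training individuals: g_small = A  * sigma2_small * V^-1 (y - mu)
#                       g_large = A1 * sigma2_large * V^-1 (y - mu)
# SNP effects:          u  = Z'  (Z Z')^+  g_small
#                       u1 = Z1' (Z1 Z1')^+ g_large
# Test individuals:     yhat = Z_test u + Z1_test u1   (the GEBV)
# where mu is the GLS intercept (zero for standardized phenotypes) and the
# test matrices are standardized with training-set allele frequencies.

# symmetric pseudo-inverse with relative eigenvalue cutoff
.pinv_sym <- function(M, rel_tol = 1e-10) {
  eg <- eigen(M, symmetric = TRUE)
  keep <- eg$values > rel_tol * max(abs(eg$values))
  if (!any(keep)) return(matrix(0, nrow(M), ncol(M)))
  U <- eg$vectors[, keep, drop = FALSE]
  U %*% (t(U) / eg$values[keep])
}

#' BLUP of the two genetic components
#'
#' Best linear unbiased prediction of the all-SNP ("small") and prior-set
#' ("large") genetic values of the training individuals given fitted
#' variance components. The phenotype is centered by its GLS intercept
#' before shrinkage, so unstandardized input is valid.
#'
#' @param y Numeric phenotype vector of the training individuals.
#' @param A All-SNP `grm`.
#' @param A1 Prior-subset `grm`, or `NULL` for the single-kernel model.
#' @param fit `reml_fit` with components matching the supplied kernels.
#' @return A `genetic_values`: `g_small`, `g_large` (zero vector when `A1`
#'   is `NULL` or its variance is zero).
#' @export
blup_genetic_values <- function(y, A, A1 = NULL, fit) {
  stopifnot(inherits(A, "grm"), inherits(fit, "reml_fit"))
  y <- as.numeric(y)
  n <- length(y)
  K <- if (is.null(A1)) 1L else 2L
  if (length(fit$sigma2) != K + 1L) {
    stop("fit has ", length(fit$sigma2) - 1L, " genetic components but ",
         K, " kernel(s) supplied")
  }
  s2 <- fit$sigma2
  grms <- if (is.null(A1)) list(A) else list(A, A1)
  V <- assemble_V(grms, s2[seq_len(K)], s2[[K + 1L]])$matrix
  ch <- chol(V)
  Viy <- backsolve(ch, forwardsolve(t(ch), y))
  Vi1 <- backsolve(ch, forwardsolve(t(ch), rep(1, n)))
  mu <- sum(Vi1 * y) / sum(Vi1)
  Vr <- Viy - mu * Vi1                   # V^-1 (y - mu)
  g_small <- drop(s2[[1]] * (A$matrix %*% Vr))
  g_large <- if (is.null(A1)) rep(0, n) else drop(s2[[2]] * (A1$matrix %*% Vr))
  structure(list(g_small = g_small, g_large = g_large, mu = mu,
                 sample_ids = A$sample_ids),
            class = "genetic_values")
}

#' Backsolve per-SNP effects from genetic values
#'
#' Recovers marker effects that exactly reproduce the fitted genetic values
#' on the training rows: `u = Z' (Z Z')^+ g_small` (and likewise `u1` for
#' the prior subset). `(Z Z')^+` is a Moore-Penrose pseudo-inverse with a
#' relative eigenvalue cutoff of 1e-10, so the identity `Z u = g_small`
#' holds also when `Z Z'` is rank-deficient, because the BLUP vectors lie in
#' its range by construction.
#'
#' @param Zs Training `std_geno` (all SNPs).
#' @param Z1s Training `std_geno` of the prior subset, or `NULL`.
#' @param g A `genetic_values`.
#' @return A `snp_effects`: `u_small` (named m-vector), `u_large` (named
#'   p-vector, length 0 when there is no prior subset).
#' @export
backsolve_snp_effects <- function(Zs, Z1s = NULL, g) {
  stopifnot(inherits(Zs, "std_geno"), inherits(g, "genetic_values"))
  if (nrow(Zs$values) != length(g$g_small)) stop("dimension mismatch: Z rows vs g")
  u_small <- drop(crossprod(Zs$values, .pinv_sym(tcrossprod(Zs$values)) %*% g$g_small))
  names(u_small) <- Zs$snp_ids
  if (is.null(Z1s)) {
    u_large <- numeric(0)
  } else {
    stopifnot(inherits(Z1s, "std_geno"))
    u_large <- drop(crossprod(Z1s$values,
                              .pinv_sym(tcrossprod(Z1s$values)) %*% g$g_large))
    names(u_large) <- Z1s$snp_ids
  }
  structure(list(u_small = u_small, u_large = u_large),
            class = "snp_effects")
}

#' Predict held-out phenotypes from backsolved effects
#'
#' `yhat = Z_test u + Z1_test u1`, the genomic estimated breeding value
#' (GEBV) of each test individual on the standardized-phenotype scale.
#' Test matrices must be standardized with training-set frequencies and
#' carry the same SNP order as the effect vectors.
#'
#' @param Zt Test `std_geno` (all SNPs).
#' @param Z1t Test `std_geno` of the prior subset, or `NULL`.
#' @param effects A `snp_effects`.
#' @return Named numeric vector of GEBVs.
#' @export
predict_gebv <- function(Zt, Z1t = NULL, effects) {
  stopifnot(inherits(Zt, "std_geno"), inherits(effects, "snp_effects"))
  if (!identical(Zt$snp_ids, names(effects$u_small))) {
    stop("SNP-ID mismatch between test genotypes and effects")
  }
  yhat <- drop(Zt$values %*% effects$u_small)
  if (length(effects$u_large)) {
    if (is.null(Z1t)) stop("effects carry a prior-set component but Z1t is missing")
    if (!identical(Z1t$snp_ids, names(effects$u_large))) {
      stop("SNP-ID mismatch between prior-set test genotypes and effects")
    }
    yhat <- yhat + drop(Z1t$values %*% effects$u_large)
  }
  names(yhat) <- rownames(Zt$values)
  yhat
}

#' Single-kernel GBLUP training and prediction
#'
#' Fits the one-GRM mixed model by REML on the training set, backsolves SNP
#' effects and predicts the test set. Identical to the partitioned pipeline
#' with the prior-set component removed.
#'
#' @param y Training phenotype vector.
#' @param Ztrain Training `std_geno`.
#' @param Ztest Test `std_geno` (standardized with training frequencies).
#' @param fit Optional pre-computed `reml_fit` (one kernel).
#' @return List: `prediction` (GEBV vector), `fit`, `effects`,
#'   `genetic_values`.
#' @export
gblup <- function(y, Ztrain, Ztest, fit = NULL) {
  A <- compute_grm(Ztrain)
  if (is.null(fit)) fit <- fit_reml(y, list(g = A))
  gv <- blup_genetic_values(y, A, NULL, fit)
  eff <- backsolve_snp_effects(Ztrain, NULL, gv)
  pred <- predict_gebv(Ztest, NULL, eff)
  list(prediction = pred, fit = fit, effects = eff, genetic_values = gv)
}

#' Partitioned GBLUP (pGBLUP) training and prediction
#'
#' Two-kernel mixed model: an all-SNP GRM with variance `sigma2_small` and a
#' prior-subset GRM with variance `sigma2_large`. Fits REML on the training
#' set, computes the two BLUP components, backsolves effects and predicts
#' the test set. Also reports the fold of enrichment of the prior set.
#'
#' @param y Training phenotype vector.
#' @param Ztrain,Ztest `std_geno` for all SNPs (test standardized with
#'   training frequencies).
#' @param Z1train,Z1test `std_geno` for the prior subset.
#' @param fit Optional pre-computed two-kernel `reml_fit`.
#' @return List: `prediction`, `fit`, `effects`, `genetic_values`,
#'   `enrichment`.
#' @export
pgblup <- function(y, Ztrain, Z1train, Ztest, Z1test, fit = NULL) {
  if (!all(Z1train$snp_ids %in% Ztrain$snp_ids)) {
    stop("prior-set SNPs must be a subset of the full panel")
  }
  A <- compute_grm(Ztrain)
  A1 <- compute_grm(Z1train)
  if (is.null(fit)) fit <- fit_reml(y, list(small = A, large = A1))
  gv <- blup_genetic_values(y, A, A1, fit)
  eff <- backsolve_snp_effects(Ztrain, Z1train, gv)
  pred <- predict_gebv(Ztest, Z1test, eff)
  p <- ncol(Z1train$values)
  m <- ncol(Ztrain$values)
  # with Z1 = Z the components are unidentifiable in direction and the
  # enrichment statistic is undefined; predictions remain well-defined
  enr <- if (p < m) fold_of_enrichment(fit, p = p, m = m) else NULL
  list(prediction = pred, fit = fit, effects = eff, genetic_values = gv,
       enrichment = enr)
}

#' Write effect and GEBV tables
#'
#' Tab-delimited tables with headers: `<prefix>.effects.tsv` (snp_id,
#' component, effect) and, when predictions are given, `<prefix>.gebv.tsv`
#' (sample_id, gebv).
#'
#' @param effects A `snp_effects`.
#' @param prediction Optional named GEBV vector.
#' @param prefix Output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_prediction_tables <- function(effects, prediction = NULL, prefix) {
  tab <- data.frame(
    snp_id = c(names(effects$u_small), names(effects$u_large)),
    component = c(rep("small", length(effects$u_small)),
                  rep("large", length(effects$u_large))),
    effect = c(unname(effects$u_small), unname(effects$u_large)))
  utils::write.table(tab, paste0(prefix, ".effects.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(prediction)) {
    utils::write.table(
      data.frame(sample_id = names(prediction), gebv = unname(prediction)),
      paste0(prefix, ".gebv.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(prefix)
}
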