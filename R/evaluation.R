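# Five-fold cross-validation harness over GBLUP / pGBLUP / BayesR,
# predictive-correlation summaries and enrichment reports.

#' Assign samples to cross-validation folds
#'
#' Random permutation followed by a block split: the first `n %% k` folds
#' receive `ceiling(n/k)` samples, the rest `floor(n/k)`, so fold sizes
#' differ by at most one (e.g. 412 samples in 5 folds gives 83/83/82/82/82;
#' 5024 gives 1005 x 4 and 1004).
#'
#' @param n Number of samples.
#' @param k Number of folds (default 5).
#' @param seed Integer RNG seed.
#' @return Integer vector of fold labels in `1..k`, one per sample.
#' @export
make_folds <- function(n, k = 5L, seed) {
  stopifnot(k >= 1, k <= n)
  set.seed(seed)
  perm <- sample.int(n)
  base <- n %/% k
  extra <- n %% k
  sizes <- c(rep(base + 1L, extra), rep(base, k - extra))
  fold <- integer(n)
  fold[perm] <- rep(seq_len(k), times = sizes)
  fold
}

# standardize training and test genotype blocks with training frequencies,
# dropping SNPs monomorphic within the training fold
.fold_standardize <- function(G, train_idx, test_idx, snps = NULL) {
  Gt <- subset_genotypes(G, samples = train_idx, snps = snps)
  f <- colMeans(Gt$calls, na.rm = TRUE) / 2
  keep <- which(is.finite(f) & f > 0 & f < 1)
  if (!length(keep)) stop("all SNPs monomorphic in a training fold")
  Gt <- subset_genotypes(Gt, snps = keep)
  Ztr <- standardize(Gt)
  Gte <- subset_genotypes(G, samples = test_idx, snps = Gt$snps$id)
  Zte <- standardize(Gte, ref_freqs = Ztr$freqs)
  list(train = Ztr, test = Zte)
}

#' Cross-validated genomic prediction
#'
#' For each fold: standardize genotypes on the training samples (training
#' allele frequencies are reused for the test block), standardize the
#' training phenotype, fit the requested method on the training fold only,
#' predict the held-out fold and record the Pearson correlation between
#' predictions and observed phenotypes. Folds whose predictions are constant
#' yield an undefined correlation, recorded as `NA` with a warning and
#' excluded from the mean.
#'
#' @param method `"gblup"`, `"pgblup"` or `"bayesr"`.
#' @param G A `genotype_matrix`.
#' @param y Phenotype vector aligned with (or named by) `G$samples`.
#' @param z1 Prior-set SNP IDs (character) or column indices; required for
#'   `"pgblup"`.
#' @param folds Fold labels from [make_folds()].
#' @param bayesr_cfg A `bayesr_config` (required for `"bayesr"`).
#' @return A `cv_result`: `method`, `fold_cor` (one per fold), `mean`, `sd`
#'   (dispersion of the fold correlations), `se` (`sd/sqrt(k)`), `fits`
#'   (per-fold fitted objects), `enrichments` (pGBLUP only).
#' @export
run_cv <- function(method = c("gblup", "pgblup", "bayesr"), G, y, z1 = NULL,
                   folds, bayesr_cfg = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(G, "genotype_matrix"))
  n <- length(G$samples)
  if (!is.null(names(y))) {
    if (!all(G$samples %in% names(y))) stop("phenotype missing some samples")
    y <- y[G$samples]
  }
  y <- as.numeric(y)
  stopifnot(length(y) == n, length(folds) == n)
  if (method == "pgblup" && is.null(z1)) stop("pgblup requires a prior SNP set z1")
  if (method == "bayesr" && is.null(bayesr_cfg)) {
    stop("bayesr requires a bayesr_config (seed included)")
  }
  if (is.character(z1)) {
    miss <- setdiff(z1, G$snps$id)
    if (length(miss)) stop("prior-set SNPs absent from panel: ",
                           paste(utils::head(miss, 5), collapse = ", "))
  } else if (!is.null(z1)) {
    z1 <- G$snps$id[z1]
  }
  ks <- sort(unique(folds))
  fold_cor <- rep(NA_real_, length(ks))
  fits <- vector("list", length(ks))
  enrichments <- vector("list", length(ks))
  for (i in seq_along(ks)) {
    test_idx <- which(folds == ks[i])
    train_idx <- which(folds != ks[i])
    zz <- .fold_standardize(G, train_idx, test_idx)
    ytr <- standardize_phenotype(y[train_idx])
    if (method == "gblup") {
      res <- gblup(ytr, zz$train, zz$test)
      fits[[i]] <- res$fit
      pred <- res$prediction
    } else if (method == "pgblup") {
      z1_here <- intersect(z1, zz$train$snp_ids)
      if (!length(z1_here)) stop("prior set empty after fold standardization")
      res <- pgblup(ytr, zz$train, subset_std_geno(zz$train, z1_here),
                    zz$test, subset_std_geno(zz$test, z1_here))
      fits[[i]] <- res$fit
      enrichments[[i]] <- res$enrichment
      pred <- res$prediction
    } else {
      cfg <- bayesr_cfg
      cfg$seed <- cfg$seed + i - 1L  # distinct chain per fold, still seeded
      fit <- fit_bayesr(ytr, zz$train, cfg)
      fits[[i]] <- fit
      pred <- bayesr_predict(fit, zz$test)
    }
    if (stats::sd(pred) == 0 || stats::sd(y[test_idx]) == 0) {
      warning("constant predictions or phenotypes in fold ", ks[i],
              "; correlation recorded as NA")
    } else {
      fold_cor[i] <- stats::cor(pred, y[test_idx])
    }
  }
  ok <- !is.na(fold_cor)
  structure(list(method = method,
                 fold_cor = fold_cor,
                 mean = mean(fold_cor[ok]),
                 sd = stats::sd(fold_cor[ok]),
                 se = stats::sd(fold_cor[ok]) / sqrt(sum(ok)),
                 n_folds = length(ks),
                 fits = fits,
                 enrichments = if (method == "pgblup") enrichments else NULL),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%s cross-validation (%d folds)\n", x$method, x$n_folds))
  cat("  fold correlations:", sprintf("%.4f", x$fold_cor), "\n")
  cat(sprintf("  mean %.4f  sd %.4f  se %.4f\n", x$mean, x$sd, x$se))
  invisible(x)
}

#' Summarize a CV result with its heritability-implied ceiling
#'
#' Annotates the fold-correlation summary with `sqrt(h2)`, the maximum
#' correlation any genomic prediction can reach at that heritability. When
#' `h2` is not given it is taken from the mean of the per-fold REML fits.
#'
#' @param result A `cv_result`.
#' @param h2 Optional heritability to use for the ceiling.
#' @return data.frame with method, mean, sd, se, h2, max_achievable.
#' @export
summarize_cv <- function(result, h2 = NULL) {
  stopifnot(inherits(result, "cv_result"))
  if (is.null(h2)) {
    h2s <- vapply(result$fits, function(f) {
      if (inherits(f, "reml_fit")) heritability(f) else NA_real_
    }, numeric(1))
    h2 <- mean(h2s, na.rm = TRUE)
  }
  data.frame(method = result$method, mean = result$mean, sd = result$sd,
             se = result$se, h2 = h2,
             max_achievable = if (is.finite(h2)) max_achievable_correlation(h2)
                              else NA_real_)
}

#' Predictive accuracy gain over a baseline
#'
#' `100 * (mean_method - mean_baseline) / mean_baseline`, in percent.
#' Undefined (with a warning) when the baseline mean is not positive.
#'
#' @param result,baseline `cv_result`s computed on the same folds and
#'   phenotype.
#' @return Percent gain (scalar, possibly `NA`).
#' @export
accuracy_gain <- function(result, baseline) {
  stopifnot(inherits(result, "cv_result"), inherits(baseline, "cv_result"))
  if (!is.finite(baseline$mean) || baseline$mean <= 0) {
    warning("baseline mean correlation is not positive; gain undefined")
    return(NA_real_)
  }
  100 * (result$mean - baseline$mean) / baseline$mean
}

#' Heritability enrichment of a prior SNP set
#'
#' Two-kernel REML fit (all-SNP GRM + prior-subset GRM) followed by the
#' fold-of-enrichment statistic, either on all individuals at once or on
#' each training fold of a cross-validation split.
#'
#' @param G A `genotype_matrix`.
#' @param y Phenotype vector aligned with `G$samples`.
#' @param z1 Prior-set SNP IDs or indices (a proper non-empty subset).
#' @param mode `"all_individuals"` or `"per_training_fold"`.
#' @param folds Fold labels (required for `"per_training_fold"`).
#' @return An `enrichment_result`, or a list of one per fold.
#' @export
enrichment_report <- function(G, y, z1,
                              mode = c("all_individuals", "per_training_fold"),
                              folds = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(G, "genotype_matrix"))
  if (!is.character(z1)) z1 <- G$snps$id[z1]
  if (!length(z1)) stop("prior set is empty")
  if (length(z1) >= nrow(G$snps)) stop("prior set must be a proper subset")
  if (!is.null(names(y))) y <- y[G$samples]
  y <- as.numeric(y)
  one_fit <- function(sample_idx) {
    zz <- .fold_standardize(G, sample_idx, sample_idx[1])
    Z1 <- subset_std_geno(zz$train, intersect(z1, zz$train$snp_ids))
    fit <- fit_reml(standardize_phenotype(y[sample_idx]),
                    list(small = compute_grm(zz$train),
                         large = compute_grm(Z1)))
    fold_of_enrichment(fit, p = ncol(Z1$values), m = ncol(zz$train$values))
  }
  if (mode == "all_individuals") {
    one_fit(seq_along(G$samples))
  } else {
    if (is.null(folds)) stop("per_training_fold mode requires folds")
    lapply(sort(unique(folds)), function(f) one_fit(which(folds != f)))
  }
}

#' Multi-trait, multi-method CV report
#'
#' Runs the CV harness for each trait column and each method and assembles
#' the standard report schema: one row per (trait, method) with the mean and
#' dispersion of the fold correlations.
#'
#' @param G A `genotype_matrix`.
#' @param phenos data.frame of trait columns (rows aligned with
#'   `G$samples`).
#' @param z1 Prior SNP set for pGBLUP.
#' @param methods Methods to run (default all three).
#' @param folds Fold labels from [make_folds()].
#' @param bayesr_cfg `bayesr_config` used when `"bayesr"` is requested.
#' @return data.frame: trait, method, mean, sd, se.
#' @export
cv_report <- function(G, phenos, z1, methods = c("gblup", "pgblup", "bayesr"),
                      folds, bayesr_cfg = NULL) {
  rows <- list()
  for (trait in names(phenos)) {
    for (method in methods) {
      res <- run_cv(method, G, phenos[[trait]],
                    z1 = if (method == "pgblup") z1 else NULL,
                    folds = folds, bayesr_cfg = bayesr_cfg)
      rows[[length(rows) + 1L]] <- data.frame(
        trait = trait, method = method, mean = res$mean, sd = res$sd,
        se = res$se, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Write CV results as CSV + JSON summary
#'
#' @param result A `cv_result`.
#' @param prefix Output path prefix; writes `<prefix>.cv.csv` (method, fold,
#'   correlation) and `<prefix>.cv.json`.
#' @return `prefix`, invisibly.
#' @export
write_cv_result <- function(result, prefix) {
  stopifnot(inherits(result, "cv_result"))
  utils::write.csv(
    data.frame(method = result$method, fold = seq_along(result$fold_cor),
               correlation = result$fold_cor),
    paste0(prefix, ".cv.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(method = result$method, mean = result$mean, sd = result$sd,
         se = result$se, fold_cor = result$fold_cor),
    paste0(prefix, ".cv.json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}
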