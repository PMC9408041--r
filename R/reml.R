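# Restricted maximum likelihood for the multi-kernel linear mixed model
#
#   y = 1*mu + sum_k g_k + e,   g_k ~ N(0, A_k sigma2_k),  e ~ N(0, I sigma2_e)
#
# fitted by average-information (AI) REML with EM fallback steps. For the
# partitioned model the two kernels are the all-SNP GRM (variance
# "sigma2_small") and the prior-subset GRM (variance "sigma2_large"). A lone
# intercept is always projected out, so unstandardized phenotypes are valid
# input; on a standardized phenotype the projection is inert.

# Internal: V, its Cholesky, V^-1, P = V^-1 - V^-1 1 (1'V^-1 1)^-1 1'V^-1,
# and the restricted log-likelihood. Returns NULL if V is not PD.
.reml_workspace <- function(y, Ks, theta) {
  n <- length(y)
  V <- diag(theta[length(theta)], n)
  for (k in seq_along(Ks)) V <- V + theta[k] * Ks[[k]]
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  Vinv <- chol2inv(ch)
  w <- rowSums(Vinv)            # V^-1 %*% 1
  s <- sum(w)                   # 1' V^-1 1
  P <- Vinv - tcrossprod(w) / s
  Py <- drop(P %*% y)
  logdetV <- 2 * sum(log(diag(ch)))
  ll <- -0.5 * ((n - 1) * log(2 * pi) + logdetV + log(s) + sum(y * Py))
  list(P = P, Py = Py, loglik = ll)
}

#' Restricted log-likelihood of a multi-kernel LMM
#'
#' Evaluates the REML log-likelihood at a given variance-component vector,
#' with a single intercept column projected out:
#' `-0.5 * ((n-1) log(2 pi) + log|V| + log(1' V^-1 1) + y' P y)` where
#' `V = sum_k A_k sigma2_k + I sigma2_e`. Exposed as the objective surface
#' behind [fit_reml()], e.g. for grid-search cross-checks.
#'
#' @param y Numeric phenotype vector.
#' @param grms List of `grm` objects (may be empty).
#' @param variances Numeric vector: one variance per GRM followed by the
#'   residual variance (length `length(grms) + 1`).
#' @return The restricted log-likelihood (scalar).
#' @export
restricted_loglik <- function(y, grms, variances) {
  stopifnot(length(variances) == length(grms) + 1L,
            variances[length(variances)] > 0)
  Ks <- lapply(grms, function(g) g$matrix)
  ws <- .reml_workspace(as.numeric(y), Ks, variances)
  if (is.null(ws)) stop("V is not positive definite at these variances")
  ws$loglik
}

#' Fit variance components by AI-REML
#'
#' Estimates one variance per supplied GRM plus a residual variance. Updates
#' use the average-information matrix with step-halving, and fall back to an
#' EM step whenever the AI proposal leaves the feasible region or decreases
#' the restricted likelihood. Components are floored at
#' `floor_frac * var(y)` so that derived enrichment statistics stay in their
#' valid range. Standard errors come from the inverse AI matrix at the
#' optimum.
#'
#' @param y Numeric phenotype vector (standardized or not; estimates scale
#'   accordingly).
#' @param grms List of 1 or 2 (or more) `grm` objects; for the partitioned
#'   model supply `list(small = A, large = A1)`.
#' @param max_iter Maximum iterations (default 100).
#' @param tol_loglik Relative log-likelihood convergence tolerance (1e-8).
#' @param tol_update Absolute parameter-update tolerance (1e-6).
#' @param floor_frac Variance floor as a fraction of `var(y)` (1e-8).
#' @param verbose Print per-iteration progress.
#' @return A `reml_fit`: `sigma2` (named, residual last), `se`, `loglik`,
#'   `n_iter`, `converged`.
#' @export
fit_reml <- function(y, grms, max_iter = 100L, tol_loglik = 1e-8,
                     tol_update = 1e-6, floor_frac = 1e-8, verbose = FALSE) {
  y <- as.numeric(y)
  n <- length(y)
  K <- length(grms)
  stopifnot(K >= 1L, n > K + 1L)
  Ks <- lapply(grms, function(g) {
    stopifnot(inherits(g, "grm"))
    g$matrix
  })
  comp_names <- names(grms)
  if (is.null(comp_names) || any(!nzchar(comp_names))) {
    comp_names <- if (K == 1L) "g" else paste0("g", seq_len(K))
  }
  comp_names <- c(comp_names, "e")
  vy <- stats::var(y)
  floor_v <- floor_frac * vy
  theta <- rep(vy / (K + 1L), K + 1L)

  ws <- .reml_workspace(y, Ks, theta)
  if (is.null(ws)) stop("initial V is not positive definite")
  converged <- FALSE
  AI <- NULL
  iter <- 0L
  max_step <- Inf
  for (iter in seq_len(max_iter)) {
    P <- ws$P
    Py <- ws$Py
    # gradients, traces and AI matrix over all K+1 components (residual = I)
    KPy <- vector("list", K + 1L)
    trPK <- numeric(K + 1L)
    yPKPy <- numeric(K + 1L)
    for (k in seq_len(K)) {
      KPy[[k]] <- drop(Ks[[k]] %*% Py)
      trPK[k] <- sum(P * Ks[[k]])
      yPKPy[k] <- sum(Py * KPy[[k]])
    }
    KPy[[K + 1L]] <- Py
    trPK[K + 1L] <- sum(diag(P))
    yPKPy[K + 1L] <- sum(Py * Py)
    grad <- -0.5 * (trPK - yPKPy)
    AI <- matrix(0, K + 1L, K + 1L)
    PKPy <- lapply(KPy, function(v) drop(P %*% v))
    for (k in seq_len(K + 1L)) {
      for (l in k:(K + 1L)) {
        AI[k, l] <- AI[l, k] <- 0.5 * sum(KPy[[k]] * PKPy[[l]])
      }
    }

    em_step <- theta + theta^2 * (yPKPy - trPK) / n
    delta <- tryCatch(solve(AI, grad), error = function(e) NULL)
    accepted <- FALSE
    if (!is.null(delta)) {
      step <- 1
      for (h in 1:6) {
        prop <- pmax(theta + step * delta, floor_v)
        ws_new <- .reml_workspace(y, Ks, prop)
        if (!is.null(ws_new) && ws_new$loglik >= ws$loglik - 1e-10) {
          accepted <- TRUE
          break
        }
        step <- step / 2
      }
    }
    if (!accepted) {
      prop <- pmax(em_step, floor_v)
      ws_new <- .reml_workspace(y, Ks, prop)
      if (is.null(ws_new)) stop("REML: V became non-positive-definite")
    }
    max_step <- max(abs(prop - theta))
    rel_ll <- abs(ws_new$loglik - ws$loglik) / (abs(ws$loglik) + 1)
    theta <- prop
    ws <- ws_new
    if (verbose) {
      message(sprintf("iter %d  ll %.8f  theta %s", iter, ws$loglik,
                      paste(sprintf("%.6g", theta), collapse = " ")))
    }
    if (rel_ll < tol_loglik && max_step < tol_update) {
      converged <- TRUE
      break
    }
  }
  se <- rep(NA_real_, K + 1L)
  AIinv <- tryCatch(solve(AI), error = function(e) NULL)
  if (!is.null(AIinv)) se <- sqrt(pmax(diag(AIinv), 0))
  names(theta) <- names(se) <- comp_names
  if (!converged) warning("REML did not converge in ", max_iter, " iterations")
  structure(list(sigma2 = theta, se = se, loglik = ws$loglik,
                 n_iter = iter, converged = converged, n = n),
            class = "reml_fit")
}

#' @export
print.reml_fit <- function(x, ...) {
  cat("REML variance components (", x$n_iter, " iterations, ",
      if (x$converged) "converged" else "NOT converged", ")\n", sep = "")
  tab <- data.frame(component = names(x$sigma2), estimate = unname(x$sigma2),
                    se = unname(x$se))
  print(tab, row.names = FALSE, digits = 5)
  cat(sprintf("restricted logLik: %.4f   h2: %.4f\n", x$loglik, heritability(x)))
  invisible(x)
}

#' Write a REML report (text + JSON)
#'
#' @param fit A `reml_fit`.
#' @param prefix Output path prefix; writes `<prefix>.reml.txt` and
#'   `<prefix>.reml.json`.
#' @return `prefix`, invisibly.
#' @export
write_reml_report <- function(fit, prefix) {
  stopifnot(inherits(fit, "reml_fit"))
  txt <- paste0(prefix, ".reml.txt")
  con <- file(txt, "w")
  sink(con)
  print(fit)
  sink()
  close(con)
  jsonlite::write_json(
    list(sigma2 = as.list(fit$sigma2), se = as.list(fit$se),
         loglik = fit$loglik, n_iter = fit$n_iter, converged = fit$converged,
         h2 = heritability(fit)),
    paste0(prefix, ".reml.json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

.genetic_variances <- function(v) {
  s <- if (inherits(v, "reml_fit")) v$sigma2 else as.numeric(v)
  list(genetic = unname(s[-length(s)]), residual = s[[length(s)]])
}

#' Narrow-sense heritability from variance components
#'
#' `h2 = (sum of genetic variances) / (total variance)`.
#'
#' @param v A `reml_fit`, or a numeric vector of variances with the residual
#'   last.
#' @return Heritability in \[0, 1\].
#' @export
heritability <- function(v) {
  parts <- .genetic_variances(v)
  tot <- sum(parts$genetic) + parts$residual
  if (tot <= 0) stop("total variance must be positive")
  sum(parts$genetic) / tot
}

#' Fold of enrichment of the prior SNP set
#'
#' Quantifies how much extra per-SNP heritability the prior set of p SNPs
#' (out of m) carries:
#' `fe = (sigma2_large / (sigma2_large + sigma2_small)) / (p/m) + 1`.
#' With non-negative components fe >= 1 always; fe substantially above 1
#' flags the prior set as heritability-enriched. Note the additive `+1`
#' (this statistic is 1, not 0, for an uninformative set), which differs
#' from conventional enrichment ratios; it is computed exactly as defined.
#'
#' @param v A `reml_fit` from a two-kernel fit (first component = all-SNP
#'   "small" variance, second = prior-set "large" variance), or a numeric
#'   vector `c(sigma2_small, sigma2_large)`.
#' @param p Number of SNPs in the prior set (0 < p < m; fractional values
#'   are accepted since only the ratio p/m enters).
#' @param m Total number of SNPs.
#' @return An `enrichment_result`: `fe`, `p`, `m`, `h2` (when the residual
#'   variance is available), `sigma2_small`, `sigma2_large`.
#' @export
fold_of_enrichment <- function(v, p, m) {
  stopifnot(p > 0, p < m)
  if (inherits(v, "reml_fit")) {
    if (length(v$sigma2) != 3L) {
      stop("fold_of_enrichment needs a two-kernel fit (small, large, residual)")
    }
    s_small <- v$sigma2[[1]]
    s_large <- v$sigma2[[2]]
    h2 <- heritability(v)
  } else {
    s_small <- v[[1]]
    s_large <- v[[2]]
    h2 <- if (length(v) >= 3L) heritability(v) else NA_real_
  }
  if (s_small + s_large <= 0) stop("total genetic variance must be positive")
  fe <- (s_large / (s_large + s_small)) / (p / m) + 1
  structure(list(fe = fe, p = p, m = m, h2 = h2,
                 sigma2_small = s_small, sigma2_large = s_large),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("fold of enrichment: %.4f  (p = %s of m = %s SNPs", x$fe,
              format(x$p), format(x$m)))
  if (is.finite(x$h2)) cat(sprintf(", h2 = %.4f", x$h2))
  cat(")\n")
  invisible(x)
}

#' Heritability-implied ceiling on predictive correlation
#'
#' The correlation between a genomic prediction and the phenotype cannot
#' exceed `sqrt(h2)`, the accuracy attained by the true genetic values
#' themselves; CV summaries are annotated with this ceiling.
#'
#' @param h2 Heritability in \[0, 1\].
#' @return `sqrt(h2)`.
#' @export
max_achievable_correlation <- function(h2) {
  stopifnot(all(h2 >= 0), all(h2 <= 1))
  sqrt(h2)
}
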