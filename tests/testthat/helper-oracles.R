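# Independent oracles used across the suite.

# HWE exact p by direct log-factorial enumeration of all genotype
# configurations compatible with the observed allele counts (no recurrence).
hwe_oracle_p <- function(n_het, n_hom1, n_hom2) {
  n <- n_het + n_hom1 + n_hom2
  n1 <- 2 * n_hom1 + n_het # allele-1 count
  n2 <- 2 * n - n1
  hs <- seq.int(n1 %% 2, min(n1, n2), by = 2)
  logp <- vapply(hs, function(h) {
    a <- (n1 - h) / 2
    c_ <- (n2 - h) / 2
    lfactorial(n) - lfactorial(a) - lfactorial(h) - lfactorial(c_) +
      h * log(2) + lfactorial(n1) + lfactorial(n2) - lfactorial(2 * n)
  }, numeric(1))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[hs == n_het]
  sum(p[p <= obs * (1 + 1e-12)])
}

# all-pairs brute-force interval join on 0-based half-open coordinates
brute_pairs <- function(a, b, window) {
  out <- list()
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] != b$chrom[j]) next
      gap <- max(a$start[i] - b$end[j], b$start[j] - a$end[i], 0)
      if (gap <= window) out[[length(out) + 1L]] <- c(i, j)
    }
  }
  if (!length(out)) return(matrix(integer(0), 0, 2))
  do.call(rbind, out)
}

# construct a genotype_matrix from a dose matrix (tests only)
toy_genotypes <- function(calls) {
  n <- nrow(calls)
  m <- ncol(calls)
  ids <- sprintf("s%03d", seq_len(m))
  samples <- sprintf("i%03d", seq_len(n))
  dimnames(calls) <- list(samples, ids)
  pgblup:::new_genotype_matrix(
    calls,
    data.frame(id = ids, chrom = "1", pos = seq_len(m) * 100L,
               allele1 = "A", allele2 = "B", stringsAsFactors = FALSE),
    samples)
}

# random dose matrix under HWE with given frequencies
random_genotypes <- function(n, m, seed, f = NULL) {
  set.seed(seed)
  if (is.null(f)) f <- runif(m, 0.1, 0.45)
  calls <- sapply(f, function(fj) rbinom(n, 2L, fj))
  toy_genotypes(matrix(as.integer(calls), n, m))
}

# std_geno wrapper around an explicit value matrix (tests only)
toy_std_geno <- function(values, freqs = NULL) {
  m <- ncol(values)
  ids <- sprintf("s%03d", seq_len(m))
  if (is.null(rownames(values))) rownames(values) <- sprintf("i%03d", seq_len(nrow(values)))
  colnames(values) <- ids
  if (is.null(freqs)) freqs <- rep(0.5, m)
  pgblup:::new_std_geno(values, freqs, ids)
}

# hand-built reml_fit with fixed variance components (tests only)
fixed_fit <- function(sigma2) {
  structure(list(sigma2 = sigma2, se = rep(NA_real_, length(sigma2)),
                 loglik = NA_real_, n_iter = 0L, converged = TRUE,
                 n = NA_integer_),
            class = "reml_fit")
}
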