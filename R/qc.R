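# Per-SNP quality control: Hardy-Weinberg exact test, call rate, MAF.

#' Hardy-Weinberg exact test p-value
#'
#' Two-sided exact test for Hardy-Weinberg equilibrium from genotype counts,
#' computed by summing the probabilities of all heterozygote counts (given
#' the observed allele counts) that are no more likely than the observed one.
#' Uses the standard stable recurrence over heterozygote counts.
#'
#' @param n_het Count of heterozygotes.
#' @param n_hom1,n_hom2 Counts of the two homozygote classes.
#' @return p-value in (0, 1].
#' @export
hwe_exact_p <- function(n_het, n_hom1, n_hom2) {
  stopifnot(n_het >= 0, n_hom1 >= 0, n_hom2 >= 0)
  n <- n_het + n_hom1 + n_hom2
  if (n == 0) return(1)
  rare <- 2L * min(n_hom1, n_hom2) + n_het
  if (rare == 0L) return(1)
  # feasible het counts share the parity of the rare-allele count
  h_min <- rare %% 2L
  h_max <- min(rare, 2L * n - rare)
  hs <- seq.int(h_min, h_max, by = 2L)
  probs <- numeric(length(hs))
  # start the recurrence at the modal region: h near rare*(2n-rare)/(2n)
  mid <- rare * (2 * n - rare) / (2 * n)
  i0 <- which.min(abs(hs - mid))
  probs[i0] <- 1
  if (i0 < length(hs)) {
    for (i in i0:(length(hs) - 1L)) {
      h <- hs[i]
      hom_r <- (rare - h) / 2
      hom_c <- (2 * n - rare - h) / 2
      # P(h+2)/P(h)
      probs[i + 1L] <- probs[i] * 4 * hom_r * hom_c / ((h + 2) * (h + 1))
    }
  }
  if (i0 > 1L) {
    for (i in i0:2L) {
      h <- hs[i]
      hom_r <- (rare - h) / 2
      hom_c <- (2 * n - rare - h) / 2
      # P(h-2)/P(h)
      probs[i - 1L] <- probs[i] * h * (h - 1) / (4 * (hom_r + 1) * (hom_c + 1))
    }
  }
  probs <- probs / sum(probs)
  obs <- which(hs == n_het)
  min(1, sum(probs[probs <= probs[obs] * (1 + 1e-12)]))
}

#' QC thresholds
#'
#' Bundle of the three per-SNP retention thresholds. A SNP is kept iff its
#' HWE exact p-value is >= `hwe_p_min`, its call rate is >= `call_rate_min`
#' and its minor allele frequency is >= `maf_min` (computed on non-missing
#' calls). Defaults are the 90K-array profile; `qc_preset()` exposes both
#' profiles used for dairy-cattle and buffalo panels.
#'
#' @param hwe_p_min Lower bound on the HWE exact-test p-value.
#' @param call_rate_min Lower bound on the fraction of non-missing calls.
#' @param maf_min Lower bound on minor allele frequency.
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(hwe_p_min = 1e-5, call_rate_min = 0.97, maf_min = 0.05) {
  stopifnot(hwe_p_min >= 0, hwe_p_min <= 1,
            call_rate_min >= 0, call_rate_min <= 1,
            maf_min >= 0, maf_min <= 1)
  structure(list(hwe_p_min = hwe_p_min, call_rate_min = call_rate_min,
                 maf_min = maf_min), class = "qc_thresholds")
}

#' @param name `"holstein"` (HWE 1e-4, call rate 0.95, MAF 0.01) or
#'   `"buffalo"` (HWE 1e-5, call rate 0.97, MAF 0.05).
#' @rdname qc_thresholds
#' @export
qc_preset <- function(name = c("buffalo", "holstein")) {
  switch(match.arg(name),
         holstein = qc_thresholds(1e-4, 0.95, 0.01),
         buffalo  = qc_thresholds(1e-5, 0.97, 0.05))
}

#' Filter SNPs by QC thresholds
#'
#' Computes HWE exact p, call rate and MAF for every SNP on the raw matrix,
#' then applies all three thresholds jointly (no sequential recomputation).
#' The exclusion report states the first failing criterion per excluded SNP,
#' checked in the order HWE, call rate, MAF.
#'
#' @param G A `genotype_matrix` with at least 2 samples.
#' @param thresholds A `qc_thresholds`.
#' @return List with `genotypes` (filtered `genotype_matrix`) and `report`
#'   (data.frame: snp, hwe_p, call_rate, maf, excluded, reason).
#' @export
qc_filter <- function(G, thresholds = qc_thresholds()) {
  stopifnot(inherits(G, "genotype_matrix"), inherits(thresholds, "qc_thresholds"))
  n <- length(G$samples)
  if (n < 2) stop("qc_filter requires at least 2 samples")
  x <- G$calls
  n_obs <- colSums(!is.na(x))
  call_rate <- n_obs / n
  n2 <- colSums(x == 2L, na.rm = TRUE)
  n1 <- colSums(x == 1L, na.rm = TRUE)
  n0 <- colSums(x == 0L, na.rm = TRUE)
  f <- ifelse(n_obs > 0, (2 * n2 + n1) / (2 * n_obs), NA_real_)
  maf <- pmin(f, 1 - f)
  maf[is.na(maf)] <- 0
  hwe_p <- vapply(seq_len(ncol(x)),
                  function(j) hwe_exact_p(n1[j], n2[j], n0[j]), numeric(1))
  fail_hwe <- hwe_p < thresholds$hwe_p_min
  fail_cr <- call_rate < thresholds$call_rate_min
  fail_maf <- maf < thresholds$maf_min
  excluded <- fail_hwe | fail_cr | fail_maf
  reason <- rep(NA_character_, ncol(x))
  reason[fail_maf] <- "maf"
  reason[fail_cr] <- "call_rate"
  reason[fail_hwe] <- "hwe"
  report <- data.frame(snp = G$snps$id, hwe_p = hwe_p, call_rate = call_rate,
                       maf = maf, excluded = excluded, reason = reason,
                       stringsAsFactors = FALSE)
  if (all(excluded)) stop("qc_filter excluded every SNP")
  list(genotypes = subset_genotypes(G, snps = which(!excluded)), report = report)
}
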