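# Segment-structured trait simulator with known causal architecture.
#
# The design: the SNP panel is cut into approximately equal contiguous
# segments; s segments are drawn as causal and the 10 central SNPs of each
# receive additional "large" effects on top of genome-wide "small" effects,
# giving a trait with total heritability 0.5 split equally between the two
# effect classes. The true fold of enrichment of the causal segments follows
# in closed form.

#' Partition SNPs into contiguous segments
#'
#' Deterministic layout: the first `m %% n_segments` segments have
#' `ceiling(m / n_segments)` SNPs, the rest `floor(m / n_segments)`, so e.g.
#' 42,551 SNPs in 1000 segments gives 551 segments of 43 and 449 of 42.
#'
#' @param m Total SNP count.
#' @param n_segments Number of segments (<= m).
#' @return A `segment_map`: data.frame `boundaries` (1-based inclusive
#'   `start`, `end`), `n_segments`, `m`.
#' @export
partition_segments <- function(m, n_segments) {
  stopifnot(n_segments >= 1, n_segments <= m)
  base <- as.integer(m %/% n_segments)
  extra <- as.integer(m %% n_segments)
  sizes <- c(rep(base + 1L, extra), rep(base, as.integer(n_segments) - extra))
  ends <- as.integer(cumsum(sizes))
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  structure(list(boundaries = data.frame(start = starts, end = ends,
                                         size = sizes),
                 n_segments = as.integer(n_segments), m = as.integer(m)),
            class = "segment_map")
}

#' Select causal segments and their central causal SNPs
#'
#' Draws `s` distinct segments uniformly without replacement; within each,
#' the 10 consecutive SNPs starting at offset `floor((size - 10) / 2)` are
#' causal (the segment center), so `k = 10 * s` causal SNPs in total. The
#' union of all SNPs in the causal segments is recorded as the natural prior
#' set for partitioned-model runs.
#'
#' @param seg A `segment_map` whose segments all have >= `n_central` SNPs.
#' @param s Number of causal segments.
#' @param seed Integer RNG seed.
#' @param n_central Causal SNPs per segment (default 10).
#' @return A `causal_spec`: `causal_segments`, `causal_snps` (indices),
#'   `z1_snps` (all SNPs in causal segments), `k`, `seed`.
#' @export
select_causal <- function(seg, s, seed, n_central = 10L) {
  stopifnot(inherits(seg, "segment_map"), s >= 1, s <= seg$n_segments)
  if (any(seg$boundaries$size < n_central)) {
    stop("every segment must hold at least ", n_central, " SNPs")
  }
  set.seed(seed)
  segs <- sort(sample.int(seg$n_segments, s))
  b <- seg$boundaries
  causal <- unlist(lapply(segs, function(i) {
    off <- (b$size[i] - n_central) %/% 2L
    seq.int(b$start[i] + off, length.out = n_central)
  }))
  z1 <- unlist(lapply(segs, function(i) seq.int(b$start[i], b$end[i])))
  structure(list(causal_segments = segs, causal_snps = causal,
                 z1_snps = z1, k = length(causal), seed = seed),
            class = "causal_spec")
}

#' Simulate genotypes with block-local linkage disequilibrium
#'
#' Synthetic stand-in for a real livestock SNP panel. Per-SNP allele
#' frequencies are Uniform(lo, hi); each of the two haplotypes per
#' individual follows a first-order copying chain along the SNP axis: with
#' probability `ld_rho` the allele is copied from the previous SNP's
#' haplotype, otherwise drawn fresh at that SNP's frequency — giving
#' adjacent-SNP haplotype correlation near `ld_rho` (exactly `ld_rho` when
#' frequencies are equal). Doses are the sum of the two haplotypes. Columns
#' that come out monomorphic are repaired by flipping one haplotype allele
#' so standardization stays defined.
#'
#' @param n Individuals.
#' @param m SNPs.
#' @param maf_range `(lo, hi)` with `0 < lo <= hi < 0.5`.
#' @param ld_rho Copying probability in `[0, 1)` (default 0.7).
#' @param seed Integer RNG seed.
#' @return A `genotype_matrix` (no missing calls).
#' @export
simulate_genotypes <- function(n, m, maf_range = c(0.05, 0.45), ld_rho = 0.7,
                               seed) {
  stopifnot(n >= 1, m >= 1, length(maf_range) == 2,
            maf_range[1] > 0, maf_range[1] <= maf_range[2], maf_range[2] < 0.5,
            ld_rho >= 0, ld_rho < 1)
  set.seed(seed)
  f <- stats::runif(m, maf_range[1], maf_range[2])
  H <- matrix(0L, 2L * n, m)
  H[, 1L] <- stats::rbinom(2L * n, 1L, f[1L])
  if (m > 1L) {
    for (j in 2:m) {
      copy <- stats::runif(2L * n) < ld_rho
      fresh <- stats::rbinom(2L * n, 1L, f[j])
      H[, j] <- ifelse(copy, H[, j - 1L], fresh)
    }
  }
  calls <- H[seq_len(n), , drop = FALSE] + H[n + seq_len(n), , drop = FALSE]
  mono <- colSums(calls) %in% c(0L, 2L * n)
  for (j in which(mono)) {
    i <- sample.int(n, 1L)
    calls[i, j] <- if (calls[i, j] == 0L) 1L else calls[i, j] - 1L
  }
  ids <- sprintf("snp%05d", seq_len(m))
  samples <- sprintf("ind%05d", seq_len(n))
  dimnames(calls) <- list(samples, ids)
  snps <- data.frame(id = ids, chrom = "1", pos = seq_len(m) * 1000L,
                     allele1 = "A", allele2 = "B", stringsAsFactors = FALSE)
  new_genotype_matrix(calls, snps, samples)
}

#' Simulate a segment-structured quantitative trait
#'
#' Small effects `u ~ N(0, sigma2_small / m)` on every SNP, additional large
#' effects `u1 ~ N(0, sigma2_large / k)` on the k causal SNPs, residuals
#' `N(0, sigma2_e)`; the phenotype is their exact sum, so with the defaults
#' the expected total heritability is 0.5. The true fold of enrichment of
#' the causal-segment SNP set (p SNPs) is
#' `(sigma2_large / (sigma2_large + sigma2_small)) / (p/m) + 1`.
#'
#' @param Zs Standardized genotypes (`std_geno`).
#' @param spec A `causal_spec` consistent with `ncol(Zs$values)`.
#' @param sigma2_small Variance of the genome-wide component (default 0.25).
#' @param sigma2_large Variance of the causal component (default 0.25).
#' @param sigma2_e Residual variance (default 0.5).
#' @param seed Integer RNG seed.
#' @return A `simulated_trait`: `y` (named), `u_true`, `u1_true`, `eps`,
#'   `g_small`, `g_large`, `true_fe`, `true_h2` (expected), `seed`.
#' @export
simulate_trait <- function(Zs, spec, sigma2_small = 0.25, sigma2_large = 0.25,
                           sigma2_e = 0.5, seed) {
  stopifnot(inherits(Zs, "std_geno"), inherits(spec, "causal_spec"))
  m <- ncol(Zs$values)
  if (max(spec$z1_snps) > m) stop("causal_spec refers to SNPs beyond the panel")
  k <- spec$k
  if (k == 0) stop("causal_spec has no causal SNPs")
  set.seed(seed)
  u <- stats::rnorm(m, 0, sqrt(sigma2_small / m))
  u1 <- stats::rnorm(k, 0, sqrt(sigma2_large / k))
  eps <- stats::rnorm(nrow(Zs$values), 0, sqrt(sigma2_e))
  g_small <- drop(Zs$values %*% u)
  g_large <- drop(Zs$values[, spec$causal_snps, drop = FALSE] %*% u1)
  y <- g_small + g_large + eps
  names(y) <- rownames(Zs$values)
  p <- length(spec$z1_snps)
  true_fe <- (sigma2_large / (sigma2_large + sigma2_small)) / (p / m) + 1
  structure(list(y = y, u_true = u, u1_true = u1, eps = eps,
                 g_small = g_small, g_large = g_large,
                 true_fe = true_fe,
                 true_h2 = (sigma2_small + sigma2_large) /
                   (sigma2_small + sigma2_large + sigma2_e),
                 seed = seed),
            class = "simulated_trait")
}

#' Compose a mixed causal/non-causal prior SNP set
#'
#' Builds a prior set from `t_causal` randomly chosen causal segments and
#' `t_total - t_causal` randomly chosen non-causal segments (all SNPs of
#' each chosen segment), the design used to probe how prediction degrades
#' as the prior set dilutes away from the truth.
#'
#' @param spec A `causal_spec`.
#' @param seg The matching `segment_map`.
#' @param t_causal Number of causal segments to include
#'   (`<= min(t_total, s)`).
#' @param t_total Total number of segments in the set.
#' @param seed Integer RNG seed.
#' @return Integer vector of SNP indices.
#' @export
make_z1 <- function(spec, seg, t_causal, t_total, seed) {
  stopifnot(inherits(spec, "causal_spec"), inherits(seg, "segment_map"),
            t_causal >= 0, t_causal <= t_total)
  s <- length(spec$causal_segments)
  if (t_causal > s) stop("t_causal exceeds the number of causal segments")
  non_causal <- setdiff(seq_len(seg$n_segments), spec$causal_segments)
  if (t_total - t_causal > length(non_causal)) {
    stop("not enough non-causal segments available")
  }
  set.seed(seed)
  pick_c <- if (t_causal > 0) sample(spec$causal_segments, t_causal) else integer(0)
  pick_n <- if (t_total - t_causal > 0) {
    sample(non_causal, t_total - t_causal)
  } else integer(0)
  b <- seg$boundaries
  sort(unlist(lapply(sort(c(pick_c, pick_n)),
                     function(i) seq.int(b$start[i], b$end[i]))))
}

#' Write simulation truth files
#'
#' Emits the genotypes as a PLINK trio, the phenotype as a two-column table,
#' the causal-segment prior set as a SNP-set file, and a JSON manifest with
#' seeds, parameters, effect vectors and the causal map.
#'
#' @param G `genotype_matrix` from [simulate_genotypes()].
#' @param trait `simulated_trait`.
#' @param spec `causal_spec`.
#' @param seg `segment_map`.
#' @param prefix Output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_simulation <- function(G, trait, spec, seg, prefix) {
  write_plink(G, prefix)
  utils::write.table(
    data.frame(id = names(trait$y), trait = unname(trait$y)),
    paste0(prefix, ".pheno"), quote = FALSE, row.names = FALSE, sep = "\t")
  write_snp_set(G$snps$id[spec$z1_snps], paste0(prefix, ".z1.snplist"))
  jsonlite::write_json(
    list(seed_trait = trait$seed, seed_causal = spec$seed,
         n = length(G$samples), m = nrow(G$snps),
         n_segments = seg$n_segments,
         causal_segments = spec$causal_segments,
         causal_snps = spec$causal_snps,
         z1_snps = spec$z1_snps,
         u_true = trait$u_true, u1_true = trait$u1_true,
         true_fe = trait$true_fe, true_h2 = trait$true_h2),
    paste0(prefix, ".truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}
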