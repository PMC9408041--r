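# Segment partitioning, causal selection, genotype and trait simulation

test_that("segment partition sizes and layout are deterministic", {
  seg <- partition_segments(42551, 1000)
  expect_identical(sum(seg$boundaries$size == 43L), 551L)
  expect_identical(sum(seg$boundaries$size == 42L), 449L)
  seg2 <- partition_segments(100, 10)
  expect_true(all(seg2$boundaries$size == 10L))
  # concatenated segments reproduce 1..m exactly
  idx <- unlist(mapply(seq.int, seg2$boundaries$start, seg2$boundaries$end,
                       SIMPLIFY = FALSE))
  expect_identical(idx, 1:100)
  expect_error(partition_segments(5, 10))
})

test_that("causal selection takes the 10 central SNPs of each chosen segment", {
  seg <- partition_segments(43 * 20, 20) # all segments length 43
  spec <- select_causal(seg, 3, seed = 81)
  expect_identical(spec$k, 30L)
  for (si in seq_along(spec$causal_segments)) {
    b <- seg$boundaries[spec$causal_segments[si], ]
    local_idx <- spec$causal_snps[(si - 1) * 10 + 1:10] - b$start + 1
    expect_identical(as.integer(local_idx), 17:26) # offset floor((43-10)/2)=16
  }
  expect_identical(select_causal(seg, 3, seed = 81)$causal_snps,
                   spec$causal_snps)
  expect_true(all(spec$causal_snps %in% spec$z1_snps))
  expect_error(select_causal(partition_segments(20, 4), 2, seed = 1),
               "at least")
})

test_that("s=10 segments yields k=100 causal SNPs", {
  seg <- partition_segments(2000, 100)
  spec <- select_causal(seg, 10, seed = 82)
  expect_identical(spec$k, 100L)
  expect_identical(length(spec$z1_snps), 200L) # 10 segments x 20 SNPs
})

test_that("simulated genotypes respect the MAF range and LD level", {
  # no LD: adjacent columns essentially uncorrelated
  G0 <- simulate_genotypes(800, 120, c(0.2, 0.4), 0, seed = 83)
  Z0 <- standardize(G0)$values
  ac0 <- sapply(2:120, function(j) cor(Z0[, j - 1], Z0[, j]))
  expect_lt(mean(abs(ac0)), 3 / sqrt(800))
  # strong LD with a narrow frequency band: correlation near the copy rate
  G9 <- simulate_genotypes(1000, 150, c(0.3, 0.35), 0.9, seed = 84)
  Z9 <- standardize(G9)$values
  ac9 <- sapply(2:150, function(j) cor(Z9[, j - 1], Z9[, j]))
  expect_gt(mean(ac9), 0.85)
  expect_lt(mean(ac9), 0.95)
  # empirical frequencies stay inside the target band up to noise
  f <- colMeans(G9$calls) / 2
  maf <- pmin(f, 1 - f)
  expect_gt(min(maf), 0.3 - 0.08)
  expect_lt(max(maf), 0.35 + 0.08)
})

test_that("trait simulation reconstructs exactly and records the true fe", {
  G <- simulate_genotypes(200, 1000, c(0.1, 0.45), 0.7, seed = 85)
  seg <- partition_segments(1000, 100)
  spec <- select_causal(seg, 10, seed = 86)
  Zs <- standardize(G)
  tr <- simulate_trait(Zs, spec, seed = 87)
  expect_lt(max(abs(tr$y - (tr$g_small + tr$g_large + tr$eps))), 1e-10)
  expect_equal(tr$true_fe, 0.5 / (100 / 1000) + 1) # = 6
  expect_equal(tr$true_fe,
               fold_of_enrichment(c(0.25, 0.25), length(spec$z1_snps), 1000)$fe)
  expect_equal(tr$true_h2, 0.5)
  # noiseless limit
  tr0 <- simulate_trait(Zs, spec, sigma2_e = 0, seed = 88)
  expect_equal(unname(tr0$y), unname(tr0$g_small + tr0$g_large),
               tolerance = 1e-12)
})

test_that("the genetic variance bookkeeping matches the target on average", {
  G <- simulate_genotypes(300, 2000, c(0.1, 0.45), 0.7, seed = 89)
  seg <- partition_segments(2000, 100)
  spec <- select_causal(seg, 10, seed = 90)
  Zs <- standardize(G)
  v_small <- sapply(1:30, function(r) {
    tr <- simulate_trait(Zs, spec, seed = 900 + r)
    var(tr$g_small)
  })
  expect_lt(abs(mean(v_small) - 0.25), 0.025)
})

test_that("mixed prior sets contain the requested causal/non-causal segments", {
  seg <- partition_segments(430 * 2, 20) # 20 segments of 43
  spec <- select_causal(seg, 10, seed = 91)
  z1_none <- make_z1(spec, seg, t_causal = 0, t_total = 10, seed = 92)
  expect_length(intersect(z1_none, spec$causal_snps), 0)
  expect_length(z1_none, 430)
  z1_all <- make_z1(spec, seg, t_causal = 10, t_total = 10, seed = 93)
  expect_identical(z1_all, sort(spec$z1_snps))
  z1_half <- make_z1(spec, seg, t_causal = 5, t_total = 10, seed = 94)
  expect_length(z1_half, 430)
  expect_error(make_z1(spec, seg, 11, 11, seed = 1), "exceeds")
  expect_error(make_z1(spec, seg, 0, 11, seed = 1), "non-causal")
})

test_that("simulation truth files round-trip through the writer", {
  G <- simulate_genotypes(30, 200, c(0.1, 0.45), 0.5, seed = 95)
  seg <- partition_segments(200, 20)
  spec <- select_causal(seg, 2, seed = 96)
  tr <- simulate_trait(standardize(G), spec, seed = 97)
  prefix <- file.path(tempdir(), "simout")
  write_simulation(G, tr, spec, seg, prefix)
  expect_identical(read_plink(prefix)$calls, G$calls)
  y <- read_phenotype(paste0(prefix, ".pheno"), ids = G$samples)
  expect_equal(as.numeric(y), as.numeric(tr$y), tolerance = 1e-12)
  z1 <- read_snp_set(paste0(prefix, ".z1.snplist"))
  expect_identical(z1, G$snps$id[spec$z1_snps])
  truth <- jsonlite::read_json(paste0(prefix, ".truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$true_fe, tr$true_fe)
  expect_equal(truth$causal_snps, spec$causal_snps)
})
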