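# BLUP, SNP-effect backsolving and GEBV prediction

make_instance <- function(n = 60, m = 90, p = 30, seed = 31) {
  G <- simulate_genotypes(n, m, c(0.15, 0.45), 0.5, seed = seed)
  Zs <- standardize(G)
  Z1s <- pgblup:::subset_std_geno(Zs, seq_len(p))
  set.seed(seed + 1)
  g <- drop(Zs$values %*% rnorm(m, 0, sqrt(0.25 / m))) +
    drop(Z1s$values %*% rnorm(p, 0, sqrt(0.25 / p)))
  y <- standardize_phenotype(g + rnorm(n, 0, sqrt(0.5)))
  list(y = y, Zs = Zs, Z1s = Z1s,
       A = compute_grm(Zs), A1 = compute_grm(Z1s))
}

test_that("BLUP matches explicit 3x3 matrix arithmetic", {
  A <- structure(list(matrix = diag(3) * 2, n_snps = 1L,
                      sample_ids = c("a", "b", "c")), class = "grm")
  y <- c(1, -0.5, 2)
  fit <- fixed_fit(c(g = 0.3, e = 0.4))
  gv <- blup_genetic_values(y, A, NULL, fit)
  V <- 2 * 0.3 * diag(3) + 0.4 * diag(3)
  Vi <- solve(V)
  mu <- sum(Vi %*% y) / sum(Vi)
  expect_equal(gv$g_small, drop(0.3 * (2 * diag(3)) %*% Vi %*% (y - mu)),
               tolerance = 1e-12)
  expect_equal(gv$g_large, rep(0, 3))
})

test_that("vanishing residual variance makes BLUP reproduce the centered data", {
  inst <- make_instance()
  fit <- fixed_fit(c(small = 0.5, large = 0.3, e = 1e-8))
  gv <- blup_genetic_values(inst$y, inst$A, inst$A1, fit)
  expect_lt(max(abs(gv$g_small + gv$g_large - (inst$y - gv$mu))), 1e-4)
})

test_that("training-set reconstruction identity holds through the backsolve", {
  for (seed in c(31, 77)) {
    inst <- make_instance(seed = seed)
    fit <- fit_reml(inst$y, list(small = inst$A, large = inst$A1))
    gv <- blup_genetic_values(inst$y, inst$A, inst$A1, fit)
    eff <- backsolve_snp_effects(inst$Zs, inst$Z1s, gv)
    expect_lt(max(abs(drop(inst$Zs$values %*% eff$u_small) - gv$g_small)), 1e-6)
    expect_lt(max(abs(drop(inst$Z1s$values %*% eff$u_large) - gv$g_large)), 1e-6)
    # predicting the training set itself returns g_small + g_large
    pred <- predict_gebv(inst$Zs, inst$Z1s, eff)
    expect_lt(max(abs(pred - (gv$g_small + gv$g_large))), 1e-6)
  }
})

test_that("zero genetic values backsolve to zero effects", {
  inst <- make_instance(n = 20, m = 30, p = 10)
  gv <- structure(list(g_small = rep(0, 20), g_large = rep(0, 20), mu = 0,
                       sample_ids = rownames(inst$Zs$values)),
                  class = "genetic_values")
  eff <- backsolve_snp_effects(inst$Zs, inst$Z1s, gv)
  expect_equal(max(abs(eff$u_small)), 0)
  expect_equal(max(abs(eff$u_large)), 0)
})

test_that("a single prior SNP reduces to the scalar least-squares coefficient", {
  inst <- make_instance(n = 25, m = 40, p = 1, seed = 41)
  fit <- fit_reml(inst$y, list(small = inst$A, large = inst$A1))
  gv <- blup_genetic_values(inst$y, inst$A, inst$A1, fit)
  eff <- backsolve_snp_effects(inst$Zs, inst$Z1s, gv)
  z1 <- inst$Z1s$values[, 1]
  expect_equal(unname(eff$u_large[1]), sum(z1 * gv$g_large) / sum(z1^2),
               tolerance = 1e-8)
})

test_that("prediction via effects equals kernel-form prediction", {
  n <- 70
  G <- simulate_genotypes(n, 100, c(0.15, 0.45), 0.5, seed = 51)
  train <- 1:50
  test <- 51:70
  Gt <- subset_genotypes(G, samples = train)
  Ztr <- standardize(Gt)
  Zte <- standardize(subset_genotypes(G, samples = test), ref_freqs = Ztr$freqs)
  Z1tr <- pgblup:::subset_std_geno(Ztr, 1:25)
  Z1te <- pgblup:::subset_std_geno(Zte, 1:25)
  set.seed(52)
  y <- standardize_phenotype(rnorm(50) + drop(Z1tr$values %*% rnorm(25, 0, 0.1)))
  res <- pgblup(y, Ztr, Z1tr, Zte, Z1te)
  s2 <- res$fit$sigma2
  V <- s2[[1]] * compute_grm(Ztr)$matrix + s2[[2]] * compute_grm(Z1tr)$matrix +
    diag(s2[[3]], 50)
  Vi <- solve(V)
  mu <- sum(Vi %*% y) / sum(Vi)
  Ctt <- s2[[1]] * tcrossprod(Zte$values, Ztr$values) / 100 +
    s2[[2]] * tcrossprod(Z1te$values, Z1tr$values) / 25
  kernel_pred <- drop(Ctt %*% Vi %*% (y - mu))
  expect_lt(max(abs(res$prediction - kernel_pred)), 1e-6)
})

test_that("pGBLUP with the prior set equal to all SNPs matches GBLUP predictions", {
  inst <- make_instance(n = 45, m = 60)
  Zall <- inst$Zs
  fit_p <- fixed_fit(c(small = 0.2, large = 0.3, e = 0.5))
  fit_g <- fixed_fit(c(g = 0.5, e = 0.5))
  res_p <- pgblup(inst$y, Zall, Zall, Zall, Zall, fit = fit_p)
  res_g <- gblup(inst$y, Zall, Zall, fit = fit_g)
  expect_lt(max(abs(res_p$prediction - res_g$prediction)), 1e-8)
})

test_that("gblup is continuous against pgblup with a floored large component", {
  inst <- make_instance(n = 40, m = 50)
  fit_p <- fixed_fit(c(small = 0.45, large = 1e-9, e = 0.55))
  fit_g <- fixed_fit(c(g = 0.45, e = 0.55))
  res_p <- pgblup(inst$y, inst$Zs, inst$Z1s, inst$Zs, inst$Z1s, fit = fit_p)
  res_g <- gblup(inst$y, inst$Zs, inst$Zs, fit = fit_g)
  expect_lt(max(abs(res_p$prediction - res_g$prediction)), 1e-4)
})

test_that("shrinkage strengthens as the noise-to-signal ratio grows", {
  A <- structure(list(matrix = diag(2), n_snps = 1L, sample_ids = c("a", "b")),
                 class = "grm")
  y <- c(1, -1)
  norms <- sapply(c(0.1, 1, 10), function(s2e) {
    gv <- blup_genetic_values(y, A, NULL, fixed_fit(c(g = 1, e = s2e)))
    sqrt(sum(gv$g_small^2))
  })
  expect_true(all(diff(norms) < 0))
})

test_that("SNP-ID mismatches are rejected at prediction time", {
  inst <- make_instance(n = 20, m = 30, p = 10)
  fit <- fixed_fit(c(small = 0.3, large = 0.2, e = 0.5))
  gv <- blup_genetic_values(inst$y, inst$A, inst$A1, fit)
  eff <- backsolve_snp_effects(inst$Zs, inst$Z1s, gv)
  Zbad <- pgblup:::subset_std_geno(inst$Zs, c(2:30, 1))
  expect_error(predict_gebv(Zbad, inst$Z1s, eff), "mismatch")
})
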