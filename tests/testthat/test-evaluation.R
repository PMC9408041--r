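# Cross-validation harness, accuracy summaries, enrichment reports

test_that("fold assignment is a balanced partition and seed-stable", {
  f412 <- make_folds(412, 5, seed = 1)
  expect_identical(as.integer(sort(table(f412), decreasing = TRUE)),
                   c(83L, 83L, 82L, 82L, 82L))
  f5024 <- make_folds(5024, 5, seed = 2)
  expect_identical(as.integer(sort(table(f5024), decreasing = TRUE)),
                   c(1005L, 1005L, 1005L, 1005L, 1004L))
  expect_identical(make_folds(412, 5, seed = 1), f412)
  expect_false(identical(make_folds(412, 5, seed = 99), f412))
  expect_identical(length(f412), 412L) # every sample in exactly one fold
  expect_error(make_folds(3, 5, seed = 1))
})

test_that("a noiseless genetic phenotype is predicted almost perfectly", {
  G <- simulate_genotypes(400, 120, c(0.15, 0.45), 0.5, seed = 111)
  Zs <- standardize(G)
  set.seed(112)
  y <- drop(Zs$values %*% rnorm(120, 0, sqrt(1 / 120)))
  cv <- run_cv("gblup", G, y, folds = make_folds(400, 5, seed = 113))
  expect_true(all(cv$fold_cor > 0.9))
})

test_that("a permuted-phenotype null centers the CV correlation on zero", {
  G <- simulate_genotypes(300, 400, c(0.1, 0.45), 0.6, seed = 114)
  seg <- partition_segments(400, 40)
  spec <- select_causal(seg, 4, seed = 115)
  tr <- simulate_trait(standardize(G), spec, seed = 116)
  set.seed(117)
  y_perm <- sample(unname(tr$y))
  names(y_perm) <- names(tr$y)
  cv <- run_cv("gblup", G, y_perm, folds = make_folds(300, 5, seed = 118))
  expect_lt(abs(cv$mean), 3 * cv$se + 0.05)
})

test_that("accuracy gain is the percent change of mean fold correlations", {
  mk <- function(m) structure(list(method = "x", fold_cor = rep(m, 5),
                                   mean = m, sd = 0, se = 0, n_folds = 5L),
                              class = "cv_result")
  expect_equal(accuracy_gain(mk(0.6), mk(0.5)), 20)
  expect_equal(accuracy_gain(mk(0.5), mk(0.6)), -16.6667, tolerance = 1e-4)
  expect_equal(accuracy_gain(mk(0.4), mk(0.4)), 0)
  expect_warning(g <- accuracy_gain(mk(0.4), mk(-0.1)), "not positive")
  expect_true(is.na(g))
})

test_that("cv summaries annotate the heritability-implied ceiling", {
  mk <- structure(list(method = "gblup", fold_cor = rep(0.4, 5), mean = 0.4,
                       sd = 0.02, se = 0.01, n_folds = 5L, fits = list()),
                  class = "cv_result")
  s <- summarize_cv(mk, h2 = 0.5)
  expect_equal(s$max_achievable, sqrt(0.5), tolerance = 1e-12)
  expect_equal(summarize_cv(mk, h2 = 0.793)$max_achievable, sqrt(0.793),
               tolerance = 1e-12)
})

test_that("enrichment reports run on all individuals and per training fold", {
  G <- simulate_genotypes(250, 500, c(0.1, 0.45), 0.6, seed = 119)
  seg <- partition_segments(500, 50)
  spec <- select_causal(seg, 5, seed = 120)
  tr <- simulate_trait(standardize(G), spec, seed = 121)
  z1 <- G$snps$id[spec$z1_snps]
  enr <- enrichment_report(G, tr$y, z1, mode = "all_individuals")
  expect_s3_class(enr, "enrichment_result")
  expect_gte(enr$fe, 1)
  folds <- make_folds(250, 5, seed = 122)
  per <- enrichment_report(G, tr$y, z1, mode = "per_training_fold",
                           folds = folds)
  expect_length(per, 5)
  expect_true(all(vapply(per, function(e) e$fe >= 1, logical(1))))
  expect_error(enrichment_report(G, tr$y, G$snps$id, mode = "all_individuals"),
               "proper subset")
})

test_that("a randomly chosen prior set shows little enrichment under a polygenic trait", {
  G <- simulate_genotypes(300, 600, c(0.1, 0.45), 0.5, seed = 123)
  Zs <- standardize(G)
  fes <- sapply(1:5, function(r) {
    set.seed(130 + r)
    u <- rnorm(600, 0, sqrt(0.5 / 600)) # purely polygenic trait
    y <- drop(Zs$values %*% u) + rnorm(300, 0, sqrt(0.5))
    names(y) <- G$samples
    z1 <- sample(G$snps$id, 60)
    suppressWarnings(enrichment_report(G, y, z1, mode = "all_individuals")$fe)
  })
  expect_gte(min(fes), 1)
  expect_lt(median(fes), 2.5)
})

test_that("the multi-trait report has one row per trait-method pair", {
  G <- simulate_genotypes(120, 200, c(0.1, 0.45), 0.5, seed = 124)
  seg <- partition_segments(200, 20)
  spec <- select_causal(seg, 2, seed = 125)
  Zs <- standardize(G)
  phenos <- as.data.frame(sapply(1:2, function(t) {
    unname(simulate_trait(Zs, spec, seed = 140 + t)$y)
  }))
  names(phenos) <- c("traitA", "traitB")
  folds <- make_folds(120, 5, seed = 126)
  rep <- cv_report(G, phenos, z1 = G$snps$id[spec$z1_snps],
                   methods = c("gblup", "pgblup"), folds = folds)
  expect_identical(nrow(rep), 4L)
  expect_setequal(names(rep), c("trait", "method", "mean", "sd", "se"))
  expect_true(all(is.finite(rep$mean)))
})

test_that("estimated enrichment grows as the prior set gains causal segments", {
  G <- simulate_genotypes(400, 1000, c(0.1, 0.45), 0.6, seed = 127)
  seg <- partition_segments(1000, 50)
  spec <- select_causal(seg, 10, seed = 128)
  tr <- simulate_trait(standardize(G), spec, seed = 129)
  fes <- sapply(c(0, 5, 10), function(t_causal) {
    z1 <- make_z1(spec, seg, t_causal, t_total = 10, seed = 150 + t_causal)
    suppressWarnings(
      enrichment_report(G, tr$y, G$snps$id[z1], mode = "all_individuals")$fe)
  })
  expect_true(all(diff(fes) > 0))
})
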