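test_that("conditioning on an uncorrelated variant leaves effects unchanged", {
  # two exactly orthogonal dosage columns
  x1 <- c(0, 0, 1, 1, 2, 2, 0, 0, 1, 1, 2, 2)
  x2 <- c(0, 2, 1, 1, 0, 2, 2, 0, 1, 1, 2, 0)
  stopifnot(abs(cov(x1, x2)) < 1e-12)
  g <- make_geno(cbind(t = x1, c = x2))
  cv <- snp_covariance(g, c("t", "c"))
  st <- make_stats(c("t", "c"), beta = c(0.12, 0.30), se = c(0.04, 0.05),
                   n = 5000L)
  adj <- conditional_sumstats(st, "c", cv, n = 5000)
  expect_equal(adj$beta[adj$variant_id == "t"], 0.12)
  # the conditioning variant itself is zeroed out
  expect_equal(adj$beta[adj$variant_id == "c"], 0)
  expect_equal(adj$p[adj$variant_id == "c"], 1)
})

test_that("conditional effects match the individual-level joint OLS oracle", {
  bc <- benchmark_conditional(n_samples = 2000, n_scenarios = 5, seed = 42)
  expect_lt(max(bc$rel_error), 0.02)
})

test_that("degenerate conditioning sets raise a pruning error", {
  set.seed(9)
  x <- rbinom(60, 2, 0.4)
  g <- make_geno(cbind(a = x, b = x, t = rbinom(60, 2, 0.3)))
  cv <- suppressWarnings(snp_covariance(g, c("a", "b", "t")))
  st <- make_stats(c("a", "b", "t"), beta = c(0.1, 0.1, 0.05),
                   se = c(0.03, 0.03, 0.03), n = 2000L)
  expect_error(conditional_sumstats(st, c("a", "b"), cv, n = 2000), "prune")
  expect_error(conditional_sumstats(st, "absent", cv, n = 2000), "absent")
})

test_that("conditional TWAS separates mediated from independent signals", {
  med <- benchmark_mediation("mediated", n_reps = 3, seed = 7)
  expect_true(all(abs(med$zscore) > 4))
  expect_true(all(abs(med$cond_zscore) < 1))
  ind <- benchmark_mediation("independent", n_reps = 3, seed = 7)
  expect_true(all(ind$cond_p < 1e-3))

  # no genome-wide lead in the window: flagged, Z unchanged
  cfg <- sim_config(n_ref_samples = 120, n_gwas_samples = 500,
                    n_variants = 40, chrom_length = 2e6, n_features = 1,
                    cis_h2 = 0.4, seed = 15)
  ref <- simulate_ld_genotypes(cfg, "reference")
  gw <- simulate_ld_genotypes(cfg, "gwas")
  ex <- simulate_molecular_phenotypes(ref, cfg, "expression")
  ss <- simulate_gwas_sumstats(gw, ex$truth, cfg, alpha = NULL)
  ph <- residualize(expression_filter_and_transform(ex$pheno), NULL)
  m <- train_cis_models(ref$geno, ph, cv = FALSE, seed = 4)[[1]]
  expect_gt(m$n_nonzero, 0)
  ct <- conditional_twas(m, ss, ref$geno)
  expect_false(ct$conditioned)
  expect_equal(ct$cond_zscore, ct$zscore)
})

test_that("permutation p follows the exceedance formula and is reproducible", {
  set.seed(21)
  dos <- sapply(runif(8, 0.2, 0.45), function(p) rbinom(300, 2, p))
  colnames(dos) <- paste0("v", 1:8)
  g <- make_geno(dos)
  cv <- snp_covariance(g, colnames(dos))
  w <- c(0.05, 0.1, 0.18, 0.25, 0.33, 0.42, 0.55, 0.7)
  # z strongly aligned with w: the observed pairing maximizes |Z|
  st <- make_stats(colnames(dos), beta = w * 10 + rnorm(8, sd = 0.01),
                   se = rep(1, 8))
  m <- make_model(colnames(dos), w)
  pt <- permutation_test(m, st, cv, seed = 5)
  expect_equal(pt$status, "ok")
  expect_equal(pt$perm_p, (1 + pt$n_exceed) / (1 + pt$n_perm))
  expect_equal(pt$n_exceed, 0L)
  expect_equal(pt$perm_p, 1 / 1001)
  # determinism under the same seed
  pt2 <- permutation_test(m, st, cv, seed = 5)
  expect_identical(pt, pt2)
  # a different seed may differ in stream but keeps the formula
  pt3 <- permutation_test(m, st, cv, seed = 6)
  expect_equal(pt3$perm_p, (1 + pt3$n_exceed) / (1 + pt3$n_perm))
})

test_that("permutation gate-keeps on marginal p and model size", {
  set.seed(22)
  dos <- sapply(runif(5, 0.2, 0.45), function(p) rbinom(200, 2, p))
  colnames(dos) <- paste0("v", 1:5)
  g <- make_geno(dos)
  cv <- snp_covariance(g, colnames(dos))
  null_st <- make_stats(colnames(dos), beta = rep(0.001, 5), se = rep(1, 5))
  m <- make_model(colnames(dos), runif(5, 0.1, 0.5))
  gate <- permutation_test(m, null_st, cv, seed = 1)
  expect_equal(gate$status, "not_entered")

  m2 <- make_model(colnames(dos)[1:2], c(0.5, 0.4))
  st2 <- make_stats(colnames(dos)[1:2], beta = c(5, 4), se = c(1, 1))
  cv2 <- snp_covariance(g, colnames(dos)[1:2])
  small <- permutation_test(m2, st2, cv2, seed = 1)
  expect_equal(small$status, "not_evaluable")

  # a null-ish entered feature stops early at the exceedance cap
  st3 <- make_stats(colnames(dos), beta = c(2.1, 0.1, -0.4, 0.3, -0.2),
                    se = rep(1, 5))
  m3 <- make_model(colnames(dos), c(0.9, 0.1, 0.12, 0.08, 0.11))
  pt3 <- permutation_test(m3, st3, cv, entry_threshold = 1, seed = 9)
  expect_equal(pt3$status, "ok")
  expect_lte(pt3$n_perm, 1000L)
  if (pt3$n_perm < 1000L) expect_equal(pt3$n_exceed, 20L)
})
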