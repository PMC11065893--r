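test_that("reference covariance is the sample covariance of dosages", {
  g <- make_geno(cbind(a = c(0, 1, 2, 1)))
  cv <- snp_covariance(g, "a")
  expect_equal(unname(cv$Gamma[1, 1]), 2 / 3)        # var of (0,1,2,1)
  expect_equal(unname(cv$sigma_l), sqrt(2 / 3))

  # duplicated column: rank-deficient but PSD, symmetric to 1e-12
  set.seed(1)
  x <- rbinom(40, 2, 0.4)
  g2 <- make_geno(cbind(a = x, b = x, c = rbinom(40, 2, 0.3)))
  cv2 <- snp_covariance(g2, c("a", "b", "c"))
  expect_lt(max(abs(cv2$Gamma - t(cv2$Gamma))), 1e-12)
  expect_equal(cov2cor(cv2$Gamma)["a", "b"], 1)
  w <- c(1, -1, 0.5)
  expect_gte(drop(w %*% cv2$Gamma %*% w), 0)

  # zero-variance variants are dropped with a warning
  g3 <- make_geno(cbind(a = x, flat = rep(1, 40)))
  expect_warning(cv3 <- snp_covariance(g3, c("a", "flat")), "zero-variance")
  expect_equal(cv3$variant_ids, "a")
  expect_error(snp_covariance(g3, "missing_id"), "absent")
})

test_that("the gene-level Z collapses correctly in analytic cases", {
  set.seed(2)
  x <- rbinom(200, 2, 0.35)
  # single-variant model with w = 1: Z equals the SNP's beta/se
  g <- make_geno(cbind(v1 = x))
  cv <- snp_covariance(g, "v1")
  st <- make_stats("v1", beta = 0.08, se = 0.02)
  m <- make_model("v1", 1)
  r <- twas_zscore(m, st, cv)
  expect_equal(r$zscore, 4)
  expect_equal(r$p, 2 * pnorm(-4))

  # two perfectly correlated variants, equal weights: Z equals the shared z
  g2 <- make_geno(cbind(v1 = x, v2 = x))
  cv2 <- suppressWarnings(snp_covariance(g2, c("v1", "v2")))
  st2 <- make_stats(c("v1", "v2"), beta = c(0.08, 0.08), se = c(0.02, 0.02))
  m2 <- make_model(c("v1", "v2"), c(0.5, 0.5))
  expect_equal(twas_zscore(m2, st2, cv2)$zscore, 4, tolerance = 1e-12)
})

test_that("Z is invariant to allele flips and weight rescaling", {
  set.seed(3)
  dos <- cbind(v1 = rbinom(150, 2, 0.3), v2 = rbinom(150, 2, 0.45),
               v3 = rbinom(150, 2, 0.2))
  g <- make_geno(dos)
  st <- make_stats(c("v1", "v2", "v3"), beta = c(0.05, -0.03, 0.02),
                   se = c(0.02, 0.015, 0.02))
  m <- make_model(c("v1", "v2", "v3"), c(0.4, -0.2, 0.1))
  cv <- snp_covariance(g, c("v1", "v2", "v3"))
  base <- twas_zscore(m, st, cv)

  # flip v2 everywhere: panel dosage 2-d, model alleles+weight, stats allele
  g_f <- make_geno(cbind(v1 = dos[, 1], v2 = 2 - dos[, 2], v3 = dos[, 3]),
                   ref = c("A", "G", "A"), alt = c("G", "A", "G"))
  m_f <- m
  m_f$variants$effect_allele[2] <- "A"
  m_f$variants$other_allele[2] <- "G"
  m_f$variants$weight[2] <- -m$variants$weight[2]
  st_f <- st
  st_f$effect_allele[2] <- "A"
  st_f$other_allele[2] <- "G"
  st_f$beta[2] <- -st$beta[2]
  st_f$eaf[2] <- 1 - st$eaf[2]
  cv_f <- snp_covariance(g_f, c("v1", "v2", "v3"))
  expect_equal(twas_zscore(m_f, st_f, cv_f)$zscore, base$zscore,
               tolerance = 1e-12)

  # rescaling all weights leaves |Z| unchanged
  m_s <- m
  m_s$variants$weight <- -3 * m$variants$weight
  expect_equal(abs(twas_zscore(m_s, st, cv)$zscore), abs(base$zscore),
               tolerance = 1e-12)
})

test_that("missing GWAS variants shrink the model and are accounted", {
  set.seed(4)
  g <- make_geno(cbind(v1 = rbinom(100, 2, 0.3), v2 = rbinom(100, 2, 0.4)))
  cv <- snp_covariance(g, c("v1", "v2"))
  st <- make_stats("v1", beta = 0.06, se = 0.02)      # v2 absent
  m <- make_model(c("v1", "v2"), c(0.3, 0.1))
  r <- twas_zscore(m, st, cv)
  expect_equal(r$n_used, 1L)
  expect_equal(r$n_dropped, 1L)
  expect_equal(r$weight_mass_dropped, 0.1 / 0.4)
  expect_equal(r$zscore, 3)                           # collapses to v1 alone

  empty <- make_stats("other", beta = 0.1, se = 0.05)
  r2 <- twas_zscore(m, empty, cv)
  expect_true(is.na(r2$zscore))
  expect_equal(r2$skip_reason, "no_gwas_overlap")
})

test_that("the scan applies per-layer Bonferroni bookkeeping", {
  cfg <- sim_config(n_ref_samples = 120, n_gwas_samples = 600,
                    n_variants = 100, chrom_length = 5e6, n_features = 5,
                    cis_h2 = 0.4, seed = 13)
  ref <- simulate_ld_genotypes(cfg, "reference")
  gw <- simulate_ld_genotypes(cfg, "gwas")
  ex <- simulate_molecular_phenotypes(ref, cfg, "expression")
  ss <- simulate_gwas_sumstats(gw, ex$truth, cfg, alpha = NULL)
  ph <- residualize(quantile_normalize(
    expression_filter_and_transform(ex$pheno)), NULL)
  db <- build_weight_db(train_cis_models(ref$geno, ph, cv = FALSE, seed = 3),
                        r_threshold = NA)
  res <- twas_scan(db, ss, ref$geno)
  tested <- !is.na(res$zscore)
  expect_equal(unique(res$m[tested]), sum(tested))
  expect_equal(res$threshold, 0.05 / res$m, tolerance = 1e-15)
  expect_equal(res$p[tested], 2 * pnorm(-abs(res$zscore[tested])))
  expect_equal(res$significant[tested],
               res$p[tested] < res$threshold[tested])
})

test_that("printed Bonferroni thresholds truncate at two significant digits", {
  expect_equal(bonferroni_threshold(9982, printed = TRUE), 5.0e-6)
  expect_equal(bonferroni_threshold(3309, printed = TRUE), 1.5e-5)
  expect_equal(bonferroni_threshold(11426, printed = TRUE), 4.3e-6)
  expect_equal(bonferroni_threshold(1000), 5e-5)
})

test_that("one-sided replication requires the prior direction", {
  r <- replication_test(c(2.4, -2.4, 0), c(1, 1, 1))
  expect_equal(r$one_sided_p[1], pnorm(-2.4))
  expect_lt(abs(r$one_sided_p[1] - 8.2e-3), 1e-4)
  expect_true(r$replicated[1])
  expect_gt(r$one_sided_p[2], 0.99)
  expect_false(r$replicated[2])
  expect_equal(r$one_sided_p[3], 0.5)
  # the same |Z| with a negative prior replicates the other way
  expect_true(replication_test(-2.4, -1)$replicated)
})
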