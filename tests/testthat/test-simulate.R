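test_that("identical configs give bit-identical cohorts", {
  cfg <- sim_config(n_ref_samples = 60, n_gwas_samples = 80, n_variants = 40,
                    chrom_length = 2e6, n_features = 2, seed = 9)
  a <- simulate_ld_genotypes(cfg, "reference")
  b <- simulate_ld_genotypes(cfg, "reference")
  expect_identical(a$geno$dosage, b$geno$dosage)
  expect_identical(a$geno$variants, b$geno$variants)

  pa <- simulate_molecular_phenotypes(a, cfg, "apa")
  pb <- simulate_molecular_phenotypes(b, cfg, "apa")
  expect_identical(pa$pheno$values, pb$pheno$values)

  sa <- simulate_gwas_sumstats(simulate_ld_genotypes(cfg, "gwas"), pa$truth,
                               cfg, alpha = setNames(0.1, pa$truth$features$feature_id[1]))
  sb <- simulate_gwas_sumstats(simulate_ld_genotypes(cfg, "gwas"), pb$truth,
                               cfg, alpha = setNames(0.1, pb$truth$features$feature_id[1]))
  expect_identical(as.data.frame(sa), as.data.frame(sb))

  # reference and GWAS cohorts share the variant map but not the draws
  gw <- simulate_ld_genotypes(cfg, "gwas")
  expect_identical(gw$geno$variants, a$geno$variants)
  expect_equal(nrow(gw$geno$dosage), 80)
})

test_that("ld_rho controls adjacent-variant correlation", {
  cfg0 <- sim_config(n_ref_samples = 2000, n_variants = 50, ld_rho = 0,
                     chrom_length = 1e6, n_features = 1, seed = 3)
  g0 <- simulate_ld_genotypes(cfg0, "reference")$geno
  r0 <- abs(diag(cor(g0$dosage[, -50], g0$dosage[, -1])))
  expect_lt(mean(r0), 0.05)

  cfg9 <- sim_config(n_ref_samples = 2000, n_variants = 50, ld_rho = 0.9,
                     chrom_length = 1e6, n_features = 1, seed = 3)
  g9 <- simulate_ld_genotypes(cfg9, "reference")$geno
  r9 <- abs(diag(cor(g9$dosage[, -50], g9$dosage[, -1])))
  expect_gt(mean(r9), 0.5)
})

test_that("empirical allele frequencies track their targets", {
  # binomial bound: 3 sqrt(p(1-p)/2n) ~ 0.014 at p = 0.3, n = 5000
  cfg <- sim_config(n_ref_samples = 5000, n_variants = 30,
                    maf_range = c(0.3, 0.3), ld_rho = 0.2,
                    chrom_length = 1e6, n_features = 1, seed = 17)
  g <- simulate_ld_genotypes(cfg, "reference")$geno
  emp <- colMeans(g$dosage) / 2
  expect_lt(max(abs(emp - 0.3)), 0.02)
})

test_that("ratio layers stay in [0,1] and record realized heritability", {
  cfg <- sim_config(n_ref_samples = 150, n_variants = 300,
                    chrom_length = 3e7, n_features = 30, cis_h2 = 0.3,
                    seed = 21)
  ref <- simulate_ld_genotypes(cfg, "reference")
  for (layer in c("apa", "junction")) {
    sim <- simulate_molecular_phenotypes(ref, cfg, layer)
    v <- sim$pheno$values
    expect_true(all(v >= 0 & v <= 1, na.rm = TRUE))
  }
  # mean realized genetic variance fraction near the cis_h2 target
  cfg2 <- sim_config(n_ref_samples = 150, n_variants = 1200,
                     chrom_length = 3e8, n_features = 300, cis_h2 = 0.3,
                     seed = 22)
  ref2 <- simulate_ld_genotypes(cfg2, "reference")
  ex <- simulate_molecular_phenotypes(ref2, cfg2, "expression")
  h2 <- ex$truth$features$realized_h2
  expect_gt(mean(h2), 0.25)
  expect_lt(mean(h2), 0.35)
})

test_that("summary statistics report the cohort allele frequency exactly", {
  cfg <- sim_config(n_ref_samples = 50, n_gwas_samples = 400,
                    n_variants = 60, chrom_length = 2e6, n_features = 2,
                    seed = 5)
  gw <- simulate_ld_genotypes(cfg, "gwas")
  ss <- simulate_gwas_sumstats(gw, NULL, cfg, alpha = NULL)
  expect_equal(ss$eaf, unname(colMeans(gw$geno$dosage) / 2),
               tolerance = 1e-12)
  expect_equal(ss$n, rep(400L, 60), ignore_attr = TRUE)
})

test_that("a fully null trait gives calibrated marginal p-values", {
  cfg <- sim_config(n_ref_samples = 50, n_gwas_samples = 1500,
                    n_variants = 5000, chrom_length = 2e8, ld_rho = 0.3,
                    n_features = 2, seed = 31)
  gw <- simulate_ld_genotypes(cfg, "gwas")
  ss <- simulate_gwas_sumstats(gw, NULL, cfg, alpha = NULL,
                               method = "linear")
  frac <- mean(ss$p < 0.05)
  expect_gt(frac, 0.04)
  expect_lt(frac, 0.06)
})

test_that("a causal variant is more associated than the genomic background", {
  meds <- t(vapply(1:20, function(r) {
    cfg <- sim_config(n_ref_samples = 100, n_gwas_samples = 1500,
                      n_variants = 60, chrom_length = 2e6, n_features = 1,
                      cis_h2 = 0.4, n_causal_per_feature = 1,
                      feature_effect_var = 0.02, seed = 400 + r)
    ref <- simulate_ld_genotypes(cfg, "reference")
    gw <- simulate_ld_genotypes(cfg, "gwas")
    ex <- simulate_molecular_phenotypes(ref, cfg, "expression")
    fid <- ex$truth$features$feature_id[1]
    ss <- simulate_gwas_sumstats(gw, ex$truth, cfg,
                                 alpha = setNames(sqrt(0.02), fid))
    causal <- ex$truth$causals$variant_id[1]
    z <- abs(ss$beta / ss$se)
    c(causal = z[ss$variant_id == causal], genome = median(z))
  }, numeric(2)))
  expect_gt(median(meds[, "causal"]), median(meds[, "genome"]))
})

test_that("invalid configurations and empty cis windows are handled", {
  expect_error(sim_config(n_variants = 0), "configuration error")
  expect_error(sim_config(maf_range = c(0, 0.6)), "configuration error")
  expect_error(sim_config(ld_rho = 1), "configuration error")
  expect_error(sim_config(cis_h2 = 0.95, covar_frac = 0.1),
               "configuration error")

  # sparse variants + many features: some windows are empty and skipped
  cfg <- sim_config(n_ref_samples = 40, n_variants = 5, chrom_length = 1e8,
                    n_features = 20, seed = 2)
  ref <- simulate_ld_genotypes(cfg, "reference")
  w <- capture_warnings(
    sim <- simulate_molecular_phenotypes(ref, cfg, "expression"))
  expect_match(w, "empty cis window", all = TRUE)
  expect_lt(nrow(sim$pheno$values), 20)
})
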