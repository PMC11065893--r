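# Self-contained calibration and validation studies. Each function builds a
# synthetic cohort, runs the relevant pipeline stages from scratch and
# returns the measured quantities; the test suite and the reproducibility
# script both call these. Problem sizes are the package's validation
# defaults (documented in the methods vignette).

#' Summary-based vs individual-level association equivalence study
#'
#' Simulates a quantitative-trait cohort in which the LD reference panel IS
#' the GWAS cohort, trains cis models, and compares each feature's
#' summary-statistics Z score against the z statistic of regressing the
#' individual-level trait on the model-predicted expression. The two are
#' mathematically equivalent up to finite-sample terms, so the maximum
#' absolute difference should be small.
#'
#' @param n_samples Cohort size (default 2000).
#' @param n_features Number of features (default 50).
#' @param seed Integer seed.
#' @return Data frame with `feature_id`, `z_summary`, `z_individual`,
#'   `delta` per trained feature.
#' @export
benchmark_equivalence <- function(n_samples = 2000L, n_features = 50L,
                                  seed = 1L) {
  cfg <- sim_config(n_ref_samples = n_samples, n_gwas_samples = n_samples,
                    n_variants = 20L * n_features,
                    chrom_length = 1e6 * n_features,
                    n_features = n_features, cis_h2 = 0.3, ld_rho = 0.6,
                    n_causal_per_feature = 2L, seed = seed)
  ref <- simulate_ld_genotypes(cfg, "reference")
  ex <- simulate_molecular_phenotypes(ref, cfg, "expression")
  fids <- ex$truth$features$feature_id
  causal <- fids[seq(2L, length(fids), by = 5L)]
  alpha <- setNames(rep(sqrt(0.004), length(causal)), causal)
  ss <- simulate_gwas_sumstats(ref, ex$truth, cfg, alpha = alpha,
                               method = "linear")
  y <- attr(ss, "phenotype")$liability
  ph <- residualize(quantile_normalize(
    expression_filter_and_transform(ex$pheno)), NULL)
  models <- train_cis_models(ref$geno, ph, cv = FALSE, seed = cfg$seed + 1L)
  rows <- lapply(models, function(m) {
    if (m$n_nonzero == 0L) return(NULL)
    cv <- snp_covariance(ref$geno, m$variants$id)
    z1 <- twas_zscore(m, ss, cv)$zscore
    pred <- predict(m, ref$geno)
    if (sd(pred) == 0) return(NULL)
    z2 <- summary(stats::lm(y ~ pred))$coefficients[2L, 3L]
    data.frame(feature_id = m$feature_id, z_summary = z1, z_individual = z2,
               delta = z1 - z2, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Conditional-adjustment accuracy study
#'
#' For each scenario, simulates a quantitative trait driven directly by a
#' target and a (weakly linked) conditioning variant, computes the
#' summary-level conditional effect of the target given the conditioning
#' variant, and compares it with the coefficient of the individual-level
#' joint ordinary-least-squares fit. The approximation replaces
#' `x_t' M_C x_t` by `n Gamma_tt`, so agreement is expected when the
#' target/conditioning LD is modest; scenarios place the two variants far
#' apart on the synthetic chromosome.
#'
#' @param n_samples Cohort size (default 2000).
#' @param n_scenarios Number of seeded scenarios (default 20).
#' @param seed Integer seed.
#' @return Data frame with per-scenario `beta_conditional`, `beta_joint_ols`
#'   and `rel_error`.
#' @export
benchmark_conditional <- function(n_samples = 2000L, n_scenarios = 20L,
                                  seed = 1L) {
  rows <- vector("list", n_scenarios)
  for (s in seq_len(n_scenarios)) {
    cfg <- sim_config(n_ref_samples = n_samples, n_gwas_samples = n_samples,
                      n_variants = 60L, chrom_length = 3e6, ld_rho = 0.5,
                      n_features = 1L, seed = seed + 97L * s)
    sim <- simulate_ld_genotypes(cfg, "reference")
    geno <- sim$geno
    t_id <- geno$variants$id[10L]
    c_id <- geno$variants$id[50L]          # ~2 Mb away: negligible LD
    xt <- geno$dosage[, t_id]
    xc <- geno$dosage[, c_id]
    y <- with_seed(cfg$seed + 7L,
                   0.15 * xt + 0.12 * xc + rnorm(n_samples))
    stats <- marginal_assoc(geno, y, logistic = FALSE)
    cov <- snp_covariance(geno, c(t_id, c_id))
    adj <- conditional_sumstats(stats[stats$variant_id %in% c(t_id, c_id), ],
                                c_id, cov, n = n_samples, var_y = var(y))
    beta_cond <- adj$beta[adj$variant_id == t_id]
    beta_joint <- stats::coef(stats::lm(y ~ xt + xc))[["xt"]]
    rows[[s]] <- data.frame(scenario = s, beta_conditional = beta_cond,
                            beta_joint_ols = beta_joint,
                            rel_error = abs(beta_cond - beta_joint) /
                              abs(beta_joint))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Mediation behavior of the conditional TWAS
#'
#' Two constructions, each replicated: `"mediated"` — the feature's only
#' causal cis variant is itself the trait's causal (lead) variant inside a
#' high-LD locus, so conditioning on the lead should suppress the gene-level
#' signal (|Z| below 1); `"independent"` — the trait is driven by both the
#' feature's causal variant and a distant, essentially uncorrelated lead
#' variant inside the window, so the conditional association should survive
#' (p below 1e-3).
#'
#' @param scenario `"mediated"` or `"independent"`.
#' @param n_reps Number of replicates (default 20).
#' @param seed Integer seed.
#' @return Data frame with per-replicate marginal and conditional `zscore`
#'   and `p`.
#' @export
benchmark_mediation <- function(scenario = c("mediated", "independent"),
                                n_reps = 20L, seed = 1L) {
  scenario <- match.arg(scenario)
  rows <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    if (scenario == "mediated") {
      # full mediation presumes the trained prediction tightly tags the
      # lead (conditional Z variance is 1 - r^2(prediction, lead)): a
      # compact high-LD locus with a strong single-eQTL architecture
      cfg <- sim_config(n_ref_samples = 150L, n_gwas_samples = 5000L,
                        n_variants = 30L, chrom_length = 5e5, ld_rho = 0.95,
                        n_features = 1L, cis_h2 = 0.6,
                        n_causal_per_feature = 1L,
                        feature_effect_var = 0.02, seed = seed + 131L * r)
    } else {
      cfg <- sim_config(n_ref_samples = 150L, n_gwas_samples = 5000L,
                        n_variants = 60L, chrom_length = 4e6, ld_rho = 0.5,
                        n_features = 2L, cis_h2 = 0.4,
                        n_causal_per_feature = 1L,
                        feature_effect_var = 0.01, seed = seed + 131L * r)
    }
    ref <- simulate_ld_genotypes(cfg, "reference")
    gw <- simulate_ld_genotypes(cfg, "gwas")
    ex <- simulate_molecular_phenotypes(ref, cfg, "expression")
    fid <- ex$truth$features$feature_id[1L]
    causal_id <- ex$truth$causals$variant_id[
      ex$truth$causals$feature_id == fid][1L]
    if (scenario == "mediated") {
      alpha <- setNames(sqrt(cfg$feature_effect_var), fid)
      ss <- simulate_gwas_sumstats(gw, ex$truth, cfg, alpha = alpha)
      lead <- causal_id
    } else {
      # second feature anchors the distant lead variant: its causal SNP is
      # >= 1 Mb from the first feature's, so target/lead LD is negligible
      fid2 <- ex$truth$features$feature_id[2L]
      alpha <- setNames(c(sqrt(cfg$feature_effect_var),
                          sqrt(cfg$feature_effect_var)), c(fid, fid2))
      ss <- simulate_gwas_sumstats(gw, ex$truth, cfg, alpha = alpha)
      lead <- ex$truth$causals$variant_id[
        ex$truth$causals$feature_id == fid2][1L]
    }
    # single-feature loci: quantile normalization is degenerate, residualize
    # the log scale directly
    ph <- residualize(expression_filter_and_transform(ex$pheno), NULL)
    models <- train_cis_models(ref$geno, ph, cv = FALSE, seed = cfg$seed + 3L)
    m <- models[[fid]]
    rows[[r]] <- if (is.null(m) || m$n_nonzero == 0L) NULL else {
      ct <- conditional_twas(m, ss, ref$geno, lead_variant = lead)
      cbind(rep = r, ct)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Null-calibration study for the association scan
#'
#' Trains cis models on a reference panel with real cis-genetic signal, then
#' scans them against summary statistics from a fully null case-control
#' GWAS (no causal features). Reports the per-feature TWAS p-values, which
#' should be uniform.
#'
#' @param n_features Number of features (default 1000).
#' @param n_gwas GWAS cohort size (default 2000).
#' @param variants_per_mb Variant density (default 8 per feature window).
#' @param seed Integer seed.
#' @return The `twas_result` data frame of the null scan.
#' @export
benchmark_null_scan <- function(n_features = 1000L, n_gwas = 2000L,
                                variants_per_mb = 8L, seed = 1L) {
  cfg <- sim_config(n_ref_samples = 150L, n_gwas_samples = n_gwas,
                    n_variants = variants_per_mb * n_features,
                    chrom_length = 1e6 * n_features,
                    n_features = n_features, cis_h2 = 0.3, ld_rho = 0.5,
                    n_causal_per_feature = 1L, seed = seed)
  ref <- simulate_ld_genotypes(cfg, "reference")
  gw <- simulate_ld_genotypes(cfg, "gwas")
  ex <- simulate_molecular_phenotypes(ref, cfg, "expression")
  ss <- simulate_gwas_sumstats(gw, ex$truth, cfg, alpha = NULL)
  ph <- residualize(quantile_normalize(
    expression_filter_and_transform(ex$pheno)), NULL)
  models <- train_cis_models(ref$geno, ph, cv = FALSE, seed = cfg$seed + 1L)
  db <- build_weight_db(models, r_threshold = NA)
  twas_scan(db, ss, ref$geno)
}

#' Null-calibration study for the permutation test
#'
#' Same construction as [benchmark_null_scan()] but with denser cis windows
#' (so models carry enough variants for a fine-grained permutation
#' distribution); every model is permuted regardless of its marginal p and
#' the full permutation budget is spent (calibration mode:
#' `entry_threshold = 1`, no adaptive stop — the early-stop estimator's
#' resolution floor would coarsen the p-values this study examines).
#'
#' @param n_features Number of features (default 200).
#' @param seed Integer seed.
#' @return Data frame of [permutation_test()] rows for evaluable models.
#' @export
benchmark_null_permutation <- function(n_features = 200L, seed = 1L) {
  cfg <- sim_config(n_ref_samples = 150L, n_gwas_samples = 2000L,
                    n_variants = 25L * n_features,
                    chrom_length = 1e6 * n_features,
                    n_features = n_features, cis_h2 = 0.4, ld_rho = 0.5,
                    n_causal_per_feature = 3L, seed = seed)
  ref <- simulate_ld_genotypes(cfg, "reference")
  gw <- simulate_ld_genotypes(cfg, "gwas")
  ex <- simulate_molecular_phenotypes(ref, cfg, "expression")
  ss <- simulate_gwas_sumstats(gw, ex$truth, cfg, alpha = NULL)
  ph <- residualize(quantile_normalize(
    expression_filter_and_transform(ex$pheno)), NULL)
  models <- train_cis_models(ref$geno, ph, cv = FALSE, seed = cfg$seed + 1L)
  rows <- lapply(models, function(m) {
    if (m$n_nonzero < 3L) return(NULL)
    harm <- harmonize_alleles(m$variants, ss)$stats
    cv <- snp_covariance(ref$geno, m$variants$id)
    pt <- permutation_test(m, harm, cv, entry_threshold = 1,
                           early_stop = Inf, seed = cfg$seed + 7L)
    if (pt$status == "ok") pt else NULL
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Causal-gene recovery study
#'
#' Each replicate simulates a locus of several genes with overlapping cis
#' windows, makes one gene mediate a GWAS risk effect, trains models for
#' all genes and checks whether the causal gene attains the largest |Z| at
#' the locus.
#'
#' @param n_reps Number of replicates (default 50).
#' @param n_genes Genes per locus (default 5).
#' @param seed Integer seed.
#' @return Data frame with per-replicate `causal_feature`, `best_feature`,
#'   `recovered`.
#' @export
benchmark_recovery <- function(n_reps = 50L, n_genes = 5L, seed = 1L) {
  rows <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    cfg <- sim_config(n_ref_samples = 150L, n_gwas_samples = 4000L,
                      n_variants = 30L * n_genes,
                      chrom_length = 8e5 * n_genes, ld_rho = 0.7,
                      n_features = n_genes, cis_h2 = 0.3,
                      n_causal_per_feature = 1L, feature_effect_var = 0.01,
                      seed = seed + 211L * r)
    ref <- simulate_ld_genotypes(cfg, "reference")
    gw <- simulate_ld_genotypes(cfg, "gwas")
    ex <- simulate_molecular_phenotypes(ref, cfg, "expression")
    causal_feature <- ex$truth$features$feature_id[ceiling(n_genes / 2)]
    alpha <- setNames(sqrt(cfg$feature_effect_var), causal_feature)
    ss <- simulate_gwas_sumstats(gw, ex$truth, cfg, alpha = alpha)
    ph <- residualize(quantile_normalize(
      expression_filter_and_transform(ex$pheno)), NULL)
    models <- train_cis_models(ref$geno, ph, cv = FALSE, seed = cfg$seed + 1L)
    db <- build_weight_db(models, r_threshold = NA)
    res <- twas_scan(db, ss, ref$geno)
    res <- res[!is.na(res$zscore), , drop = FALSE]
    best <- res$feature_id[which.max(abs(res$zscore))]
    rows[[r]] <- data.frame(rep = r, causal_feature = causal_feature,
                            best_feature = best,
                            recovered = identical(best, causal_feature),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
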