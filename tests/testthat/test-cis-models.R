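test_that("cis windows are inclusive, symmetric and left-truncated", {
  variants <- data.frame(id = c("a", "b", "c", "d"),
                         pos = c(500000L, 1500000L, 1500001L, 499999L))
  anchor <- data.frame(start = 1000000L, end = 1000000L)
  sel <- select_cis_variants(anchor, variants)
  expect_setequal(sel$id, c("a", "b"))

  # anchor near the chromosome start: window truncates at 1
  near <- select_cis_variants(data.frame(start = 200000L, end = 200000L),
                              data.frame(id = "x", pos = 1L))
  expect_equal(near$id, "x")
  far <- select_cis_variants(data.frame(start = 200000L, end = 200000L),
                             data.frame(id = "y", pos = 700001L))
  expect_equal(nrow(far), 0)
})

test_that("elastic net honors its penalized objective", {
  X <- orthonormal_design(400, 5, seed = 1)
  set.seed(2)
  y <- drop(X %*% c(0.5, -0.3, 0, 0.1, 0)) + rnorm(400)
  lam <- 0.2

  # lasso closed form on an orthonormal design
  fit1 <- fit_elastic_net(X, y, alpha = 1, lambda = lam, standardize = FALSE)
  ctr <- drop(crossprod(X, y - mean(y)) / 400)
  expect_equal(unname(fit1$weights),
               sign(ctr) * pmax(abs(ctr) - lam, 0), tolerance = 1e-8)

  # KKT stationarity for the elastic net at alpha = 0.5
  fit2 <- fit_elastic_net(X, y, alpha = 0.5, lambda = lam,
                          standardize = FALSE)
  act <- which(fit2$weights != 0)
  resid <- y - fit2$intercept - drop(X %*% fit2$weights)
  kkt <- drop(crossprod(X[, act, drop = FALSE], resid)) / 400 -
    lam * 0.5 * sign(fit2$weights[act]) - lam * 0.5 * fit2$weights[act]
  expect_lt(max(abs(kkt)), 1e-6)

  # overwhelming penalty: all weights zero, intercept = mean(y)
  fit3 <- fit_elastic_net(X, y, alpha = 0.5, lambda = 1e9)
  expect_true(all(fit3$weights == 0))
  expect_equal(fit3$intercept, mean(y), tolerance = 1e-8)

  expect_error(fit_elastic_net(X, rep(1, 400)), "zero-variance")
})

test_that("fixed-lambda fits are invariant to sample and variant order", {
  X <- orthonormal_design(200, 4, seed = 3)
  set.seed(5)
  y <- drop(X %*% c(0.4, 0, -0.2, 0.1)) + rnorm(200)
  base <- fit_elastic_net(X, y, alpha = 0.5, lambda = 0.05,
                          standardize = FALSE)
  perm_s <- sample(200)
  fit_s <- fit_elastic_net(X[perm_s, ], y[perm_s], alpha = 0.5,
                           lambda = 0.05, standardize = FALSE)
  expect_equal(fit_s$weights, base$weights, tolerance = 1e-10)

  perm_v <- c(3, 1, 4, 2)
  colnames(X) <- paste0("v", 1:4)
  base2 <- fit_elastic_net(X, y, alpha = 0.5, lambda = 0.05,
                           standardize = FALSE)
  fit_v <- fit_elastic_net(X[, perm_v], y, alpha = 0.5, lambda = 0.05,
                           standardize = FALSE)
  expect_equal(fit_v$weights[colnames(X)], base2$weights[colnames(X)],
               tolerance = 1e-10)
})

test_that("cross-validation partitions samples and detects signal", {
  set.seed(6)
  X <- matrix(rbinom(150 * 8, 2, 0.3), 150, 8)
  y <- 1.5 * X[, 3] + 0.2                              # noiseless signal
  out <- cross_validated_performance(X, y, k = 5, seed = 2)
  expect_gt(out$cv_R, 0.99)
  expect_setequal(unique(out$folds), 1:5)
  expect_equal(length(out$folds), 150)
  expect_error(cross_validated_performance(X[1:3, ], y[1:3], k = 5), "k-fold")
})

test_that("null phenotypes give cv_R centred at zero", {
  set.seed(7)
  r <- vapply(1:200, function(i) {
    X <- matrix(rbinom(80 * 6, 2, 0.3), 80, 6)
    y <- rnorm(80)
    cross_validated_performance(X, y, k = 5, seed = i)$cv_R
  }, numeric(1))
  expect_lt(abs(mean(r)), 0.03)
})

test_that("the causal cis variant usually carries the largest weight", {
  cfg <- sim_config(n_ref_samples = 150, n_variants = 500,
                    chrom_length = 5e7, n_features = 50, cis_h2 = 0.5,
                    n_causal_per_feature = 1, ld_rho = 0.4, seed = 77)
  ref <- simulate_ld_genotypes(cfg, "reference")
  ex <- simulate_molecular_phenotypes(ref, cfg, "expression")
  ph <- residualize(quantile_normalize(
    expression_filter_and_transform(ex$pheno)), NULL)
  models <- train_cis_models(ref$geno, ph, cv = FALSE, seed = 99)
  hits <- vapply(models, function(m) {
    if (m$n_nonzero == 0) return(FALSE)
    causal <- ex$truth$causals$variant_id[
      ex$truth$causals$feature_id == m$feature_id]
    m$variants$id[which.max(abs(m$variants$weight))] == causal
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("weight-database retention follows the strict R threshold", {
  anchor <- data.frame(chrom = "chr1", start = 1e5, end = 1e5)
  mk <- function(id, cv_R, w = 0.3) {
    weight_model(id, "expression", anchor,
                 data.frame(id = paste0(id, "_v"), pos = 1000L,
                            effect_allele = "G", other_allele = "A",
                            weight = w, stringsAsFactors = FALSE),
                 cv_R = cv_R)
  }
  zero <- weight_model("gz", "expression", anchor,
                       data.frame(id = character(0), pos = integer(0),
                                  effect_allele = character(0),
                                  other_allele = character(0),
                                  weight = numeric(0)), cv_R = 0.5)
  models <- list(mk("g1", 0.05), mk("g2", 0.10), mk("g3", 0.11), zero)
  db <- build_weight_db(models)
  expect_equal(names(db$models), "expression:g3")      # 0.10 excluded: strict
  expect_equal(unname(db$counts),
               c(4L, 3L, 1L))                          # attempted/predictable/retained
  expect_error(build_weight_db(list(mk("g1", 0.3), mk("g1", 0.4))),
               "duplicate")
})
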