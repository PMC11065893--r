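test_that("expression filter removes barely-expressed genes and logs values", {
  vals <- rbind(rare = c(rep(3, 4), rep(0, 146)),    # 2.7% expressed
                common = c(rep(1, 10), rep(0, 140)), # 6.7% expressed
                high = rep(2, 150))
  ph <- make_pheno(vals)
  out <- expression_filter_and_transform(ph)
  expect_setequal(rownames(out$values), c("common", "high"))
  expect_equal(unname(out$values["common", 1]), 1)   # log2(1+1)
  expect_equal(unname(out$values["common", 11]), 0)  # log2(0+1)
  expect_equal(unname(out$values["high", 1]), log2(3))
})

test_that("missingness filter removes leaky events and median-imputes the rest", {
  vals <- rbind(bad = c(rep(NA, 9), runif(141)),     # 6% missing
                ok = c(rep(NA, 7), rep(0.2, 100), rep(0.6, 43)),  # 4.7%
                full = runif(150))
  ph <- make_pheno(vals, layer = "apa")
  out <- event_missingness_filter(ph)
  expect_setequal(rownames(out$values), c("ok", "full"))
  expect_false(anyNA(out$values))
  expect_equal(unname(out$values["ok", 1]), 0.2)     # feature median
  expect_identical(out$values["full", ], ph$values["full", ])
})

test_that("quantile normalization maps samples onto the rank-mean distribution", {
  ph <- make_pheno(matrix(c(1, 2, 3, 4, 5, 6), nrow = 3,
                          dimnames = list(c("a", "b", "c"), NULL)))
  out <- quantile_normalize(ph)
  expect_equal(unname(out$values[, 1]), c(2.5, 3.5, 4.5))
  expect_equal(unname(out$values[, 2]), c(2.5, 3.5, 4.5))

  # identical value vectors are a fixed point
  same <- make_pheno(matrix(rep(c(2, 7, 1, 5), 3), ncol = 3))
  expect_equal(quantile_normalize(same)$values, same$values)

  # idempotence and the common sorted-column property
  set.seed(8)
  ph2 <- make_pheno(matrix(rnorm(200), nrow = 20))
  n1 <- quantile_normalize(ph2)
  n2 <- quantile_normalize(n1)
  expect_equal(n1$values, n2$values, tolerance = 1e-12)
  sorted <- apply(n1$values, 2, sort)
  expect_lt(max(abs(sorted - sorted[, 1])), 1e-12)

  # single sample: identity
  one <- make_pheno(matrix(c(3, 1, 2), ncol = 1))
  expect_equal(quantile_normalize(one)$values, one$values)
})

test_that("latent factors are orthogonal and recover an injected batch", {
  set.seed(12)
  n <- 60
  batch <- rep(c(0, 1), each = n / 2)
  vals <- matrix(rnorm(100 * n), nrow = 100) +
    outer(rnorm(100, sd = 0.3), rep(1, n)) +
    outer(rep(2, 100), batch)                 # strong 2-group shift
  ph <- make_pheno(vals)
  fac <- infer_latent_factors(ph, k = 3)
  gram <- crossprod(fac)
  expect_lt(max(abs(gram[upper.tri(gram)])), 1e-8)
  expect_gt(abs(cor(fac[, 1], batch)), 0.9)

  expect_equal(ncol(infer_latent_factors(ph, k = 0)), 0)
  expect_error(infer_latent_factors(ph, k = 60), "smaller")
})

test_that("residualization is an orthogonal projection", {
  set.seed(4)
  n <- 50
  age <- rnorm(n, 50, 8)
  vals <- rbind(lin = 2 * age + 3,                    # exactly linear in age
                noise = rnorm(n),
                mix = 0.5 * age + rnorm(n))
  ph <- make_pheno(vals)
  cov <- cbind(age = age, x = rnorm(n))

  ctr <- residualize(ph, NULL)                       # intercept only
  expect_equal(ctr$values, sweep(vals, 1, rowMeans(vals)), tolerance = 1e-12)

  out <- residualize(ph, cov)
  expect_lt(max(abs(out$values["lin", ])), 1e-10)
  expect_lt(max(abs(out$values %*% cbind(1, cov))), 1e-8)

  # projection: applying twice equals once
  out2 <- residualize(out, cov)
  expect_equal(out2$values, out$values, tolerance = 1e-10)

  # collinear covariates are named in the error
  expect_error(residualize(ph, cbind(age = age, age2 = 2 * age)), "age2")
})

test_that("PDUI and PSI ratios respect depth and bounds", {
  anch <- data.frame(feature_id = "e1", chrom = "chr1", start = 100L,
                     end = 200L, strand = "+", stringsAsFactors = FALSE)
  pd <- quantify_pdui(proximal = c(60, 0, 0, 8), distal = c(20, 0, 50, 1),
                      anchors = anch)
  expect_equal(unname(pd$values[1, ]), c(0.25, NA, 1.0, NA))
  expect_equal(pd$layer, "apa")

  ps <- quantify_psi(inclusion = c(30, 0, 3), exclusion = c(10, 40, 2),
                     anchors = anch)
  expect_equal(unname(ps$values[1, ]), c(0.75, 0.0, NA))
  expect_equal(ps$layer, "junction")

  expect_error(quantify_pdui(c(-1, 2), c(1, 2), anch), "non-negative")
})
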