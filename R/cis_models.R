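# Per-feature cis elastic-net prediction models and the weight database.

cis_window_bounds <- function(start, end, window) {
  c(max(1, start - window), end + window)
}

#' Select cis variants for a feature
#'
#' Variants whose position falls in `[start - window, end + window]`,
#' inclusive at both edges and truncated at position 1.
#'
#' @param anchor One-row data frame (or list) with `start`, `end`.
#' @param variants Variant table with a `pos` column.
#' @param cis_window Half-width in bp (default 500 kb).
#' @return The subset of `variants` inside the window (possibly empty).
#' @export
select_cis_variants <- function(anchor, variants, cis_window = 5e5) {
  b <- cis_window_bounds(anchor$start[1L], anchor$end[1L], cis_window)
  variants[variants$pos >= b[1L] & variants$pos <= b[2L], , drop = FALSE]
}

#' Fit a cis elastic-net model
#'
#' Minimizes `(1/(2n)) ||y - Xw - b||^2 + lambda (alpha |w|_1 +
#' ((1-alpha)/2) |w|_2^2)`. Columns are standardized internally and the
#' returned weights are mapped back to the raw dosage scale. When `lambda`
#' is `NULL` it is chosen by inner k-fold cross-validation over a 100-point
#' log grid spanning four orders of magnitude below the smallest
#' all-zero-weight lambda.
#'
#' @param X Dosage matrix for the cis variants (samples x variants).
#' @param y Complete phenotype vector (typically residualized).
#' @param alpha Elastic-net mixing parameter (default 0.5).
#' @param lambda Optional fixed penalty (skips the inner CV).
#' @param nfolds Inner CV folds (default 5).
#' @param seed Seed for the inner fold assignment.
#' @param standardize Standardize columns internally (default TRUE).
#' @param lambda_rule `"min"` (CV-MSE minimizer, default) or `"1se"`.
#' @return List with `weights` (named, original scale), `intercept`,
#'   `lambda`, `alpha`.
#' @export
fit_elastic_net <- function(X, y, alpha = 0.5, lambda = NULL, nfolds = 5L,
                            seed = 1L, standardize = TRUE,
                            lambda_rule = c("min", "1se")) {
  lambda_rule <- match.arg(lambda_rule)
  X <- as.matrix(X)
  if (anyNA(y)) stop("y must be complete")
  if (sd(y) == 0) stop("zero-variance phenotype")
  padded <- FALSE
  if (ncol(X) == 1L) {            # glmnet requires >= 2 columns
    X <- cbind(X, `..pad` = 0)
    padded <- TRUE
  }
  if (is.null(lambda)) {
    n <- nrow(X)
    foldid <- with_seed(seed, sample(rep(seq_len(nfolds), length.out = n)))
    cvfit <- glmnet::cv.glmnet(X, y, alpha = alpha, foldid = foldid,
                               nlambda = 100L, lambda.min.ratio = 1e-4,
                               standardize = standardize, family = "gaussian")
    lam <- if (lambda_rule == "min") cvfit$lambda.min else cvfit$lambda.1se
    fit <- cvfit$glmnet.fit
    cf <- as.matrix(stats::coef(fit, s = lam, exact = FALSE))
  } else {
    # glmnet standardizes y internally, which rescales the ridge part of a
    # user-supplied lambda; reparameterize on y/s so the stated objective
    # (1/(2n))RSS + lambda(alpha|w| + ((1-alpha)/2)w^2) holds exactly
    lam <- lambda[1L]
    n <- length(y)
    s <- sd(y) * sqrt((n - 1) / n)
    mu <- lam * alpha / s + lam * (1 - alpha)
    atil <- if (mu > 0) (lam * alpha / s) / mu else alpha
    fit <- glmnet::glmnet(X, y / s, alpha = atil, lambda = mu,
                          standardize = standardize, family = "gaussian",
                          thresh = 1e-14)
    cf <- s * as.matrix(stats::coef(fit, s = mu))
  }
  w <- cf[-1L, 1L]
  if (padded) w <- w[-length(w)]
  list(weights = w, intercept = cf[1L, 1L], lambda = lam, alpha = alpha)
}

#' Cross-validated prediction performance
#'
#' Splits samples into `k` disjoint folds by a seeded shuffle, refits the
#' elastic net on each training split (inner CV choosing its own lambda),
#' concatenates the held-out genetic scores `X w` (the training intercept,
#' a per-fold constant, is omitted so that weightless fits carry no signal)
#' and returns their Pearson correlation with the observed values.
#' Constant predictions give 0.
#'
#' @param X Dosage matrix (samples x variants).
#' @param y Complete phenotype vector.
#' @param k Number of folds (default 5).
#' @param seed Seed for the fold shuffle.
#' @param alpha Elastic-net mixing parameter.
#' @return List with `cv_R` and `folds` (the fold assignment used).
#' @export
cross_validated_performance <- function(X, y, k = 5L, seed = 1L,
                                        alpha = 0.5) {
  n <- length(y)
  if (n < k) stop("need at least k samples for k-fold cross-validation")
  folds <- with_seed(seed, sample(rep(seq_len(k), length.out = n)))
  pred <- rep(NA_real_, n)
  X <- as.matrix(X)
  for (fold in seq_len(k)) {
    test <- folds == fold
    fit <- tryCatch(
      fit_elastic_net(X[!test, , drop = FALSE], y[!test], alpha = alpha,
                      seed = seed + fold),
      error = function(e) NULL)
    # held-out prediction is the genetic score X w; the training intercept
    # is a per-fold constant that would only leak fold-mean noise into the
    # concatenated correlation
    pred[test] <- if (is.null(fit)) 0
      else drop(X[test, , drop = FALSE] %*% fit$weights)
  }
  cv_R <- if (sd(pred) == 0 || sd(y) == 0) 0 else cor(pred, y)
  list(cv_R = cv_R, folds = folds)
}

#' Train cis prediction models for every feature of a layer
#'
#' For each feature: select the +/-500 kb cis variants, mean-impute missing
#' dosages, optionally residualize the phenotype on covariates, fit the
#' elastic net on all samples (inner CV for lambda) and, when `cv = TRUE`,
#' measure five-fold cross-validated prediction R.
#'
#' @param geno A QC'd [genotype_matrix()] reference panel.
#' @param pheno A prepared [pheno_matrix()] (filtered, normalized).
#' @param covariates Optional covariate matrix to residualize out first.
#' @param alpha Elastic-net mixing parameter (default 0.5).
#' @param cv Measure cross-validated R (default TRUE; skipping it is much
#'   faster when retention by R is not needed).
#' @param nfolds Folds for the performance CV.
#' @param seed Base seed; each feature derives its own fold seeds.
#' @param cis_window Cis half-width in bp.
#' @return List of [weight_model()] objects (features with an empty cis
#'   window or constant phenotype are skipped with a warning), with
#'   attribute `n_attempted` = number of features presented.
#' @export
train_cis_models <- function(geno, pheno, covariates = NULL, alpha = 0.5,
                             cv = TRUE, nfolds = 5L, seed = 1L,
                             cis_window = 5e5) {
  stopifnot(inherits(geno, "genotype_matrix"), inherits(pheno, "pheno_matrix"))
  if (!is.null(covariates)) pheno <- residualize(pheno, covariates)
  models <- list()
  for (f in seq_len(nrow(pheno$anchors))) {
    anchor <- pheno$anchors[f, , drop = FALSE]
    cis <- select_cis_variants(anchor, geno$variants, cis_window)
    if (nrow(cis) == 0L) {
      warning("feature ", anchor$feature_id, " has no cis variants; skipped")
      next
    }
    y <- pheno$values[f, ]
    if (anyNA(y) || sd(y) == 0) {
      warning("feature ", anchor$feature_id,
              " has missing or constant phenotype; skipped")
      next
    }
    X <- impute_col_means(
      geno$dosage[, match(cis$id, geno$variants$id), drop = FALSE])
    fseed <- seed + f
    fit <- fit_elastic_net(X, y, alpha = alpha, nfolds = nfolds, seed = fseed)
    cv_R <- NA_real_
    if (cv)
      cv_R <- cross_validated_performance(X, y, k = nfolds, seed = fseed,
                                          alpha = alpha)$cv_R
    nz <- fit$weights != 0
    variants <- data.frame(id = cis$id[nz], pos = cis$pos[nz],
                           effect_allele = cis$alt[nz],
                           other_allele = cis$ref[nz],
                           weight = unname(fit$weights[nz]),
                           stringsAsFactors = FALSE)
    models[[anchor$feature_id]] <-
      weight_model(anchor$feature_id, pheno$layer, anchor, variants,
                   cv_R = cv_R, lambda = fit$lambda, alpha = alpha,
                   seed = fseed)
  }
  attr(models, "n_attempted") <- nrow(pheno$anchors)
  models
}

#' Build the weight database
#'
#' Retains models with cross-validated R strictly above `r_threshold` (when
#' `r_threshold` is not `NA`) and at least one nonzero weight, and records
#' the model-building summary counts: attempted, predictable (>= 1 nonzero
#' weight) and retained.
#'
#' @param models List of [weight_model()] (e.g. from [train_cis_models()]).
#' @param r_threshold Retention threshold on signed cv_R (strict; default
#'   0.1). `NA` retains every predictable model regardless of cv_R.
#' @return Object of class `weight_db`.
#' @export
build_weight_db <- function(models, r_threshold = 0.1) {
  keys <- vapply(models, function(m) paste0(m$layer, ":", m$feature_id),
                 character(1L))
  if (anyDuplicated(keys)) stop("duplicate feature keys in model list")
  n_attempted <- attr(models, "n_attempted")
  if (is.null(n_attempted)) n_attempted <- length(models)
  predictable <- vapply(models, function(m) m$n_nonzero >= 1L, logical(1L))
  retained <- predictable & if (is.na(r_threshold)) TRUE else
    vapply(models, function(m) !is.na(m$cv_R) && m$cv_R > r_threshold,
           logical(1L))
  db <- models[retained]
  names(db) <- keys[retained]
  structure(list(models = db,
                 counts = c(attempted = n_attempted,
                            predictable = sum(predictable),
                            retained = sum(retained)),
                 r_threshold = r_threshold),
            class = "weight_db")
}

#' @export
print.weight_db <- function(x, ...) {
  cat("weight_db\n")
  cat(sprintf("  features attempted:          %d\n", x$counts[["attempted"]]))
  cat(sprintf("  predictable (>=1 weight):    %d\n", x$counts[["predictable"]]))
  cat(sprintf("  retained (cv R > %s):        %d\n",
              format(x$r_threshold), x$counts[["retained"]]))
  invisible(x)
}

#' @export
summary.weight_db <- function(object, ...) {
  models <- object$models
  data.frame(layer = vapply(models, `[[`, character(1L), "layer"),
             feature_id = vapply(models, `[[`, character(1L), "feature_id"),
             n_variants = vapply(models, function(m) nrow(m$variants),
                                 integer(1L)),
             cv_R = vapply(models, `[[`, numeric(1L), "cv_R"),
             row.names = NULL, stringsAsFactors = FALSE)
}
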