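# Molecular phenotype quantification, filtering, normalization and
# covariate construction.

#' Quantify PDUI (distal polyA usage) from read counts
#'
#' PDUI = distal / (proximal + distal) per sample; samples whose total count
#' falls below `min_depth` are set missing.
#'
#' @param proximal,distal Count matrices, features in rows, samples in
#'   columns (or vectors for a single feature).
#' @param anchors Feature anchor data frame (see [pheno_matrix()]).
#' @param min_depth Minimum total count for a usable ratio.
#' @return A [pheno_matrix()] with layer `"apa"`.
#' @export
quantify_pdui <- function(proximal, distal, anchors, min_depth = 10) {
  quantify_ratio(distal, proximal, anchors, min_depth, "apa")
}

#' Quantify PSI (percent spliced isoform) from junction read counts
#'
#' PSI = inclusion / (inclusion + exclusion) per sample; totals below
#' `min_depth` are set missing.
#'
#' @param inclusion,exclusion Count matrices, features in rows, samples in
#'   columns.
#' @param anchors Feature anchor data frame.
#' @param min_depth Minimum total count for a usable ratio.
#' @return A [pheno_matrix()] with layer `"junction"`.
#' @export
quantify_psi <- function(inclusion, exclusion, anchors, min_depth = 10) {
  quantify_ratio(inclusion, exclusion, anchors, min_depth, "junction")
}

quantify_ratio <- function(num, other, anchors, min_depth, layer) {
  if (is.vector(num)) num <- matrix(num, nrow = 1L)
  if (is.vector(other)) other <- matrix(other, nrow = 1L)
  if (any(num < 0, na.rm = TRUE) || any(other < 0, na.rm = TRUE))
    stop("counts must be non-negative")
  total <- num + other
  values <- ifelse(total >= min_depth, num / total, NA_real_)
  pheno_matrix(values, anchors, layer)
}

#' Expression filter and log transform
#'
#' Removes genes expressed (TPM > 0) in no more than 5% of samples, then
#' replaces TPM by log2(TPM + 1).
#'
#' @param tpm A [pheno_matrix()] with layer `"expression"` on the TPM scale.
#' @param min_expressed_frac Minimum fraction of samples with TPM > 0 a gene
#'   must exceed to be kept (strict inequality; default 0.05).
#' @return The filtered, log-transformed `pheno_matrix` (bounds are relaxed
#'   to the log scale by tagging the matrix as log-transformed).
#' @export
expression_filter_and_transform <- function(tpm, min_expressed_frac = 0.05) {
  stopifnot(inherits(tpm, "pheno_matrix"), tpm$layer == "expression")
  frac <- rowMeans(tpm$values > 0, na.rm = TRUE)
  keep <- frac > min_expressed_frac
  out <- pheno_matrix(log2(tpm$values[keep, , drop = FALSE] + 1),
                      tpm$anchors[keep, , drop = FALSE], "expression")
  out$log_transformed <- TRUE
  out
}

#' Missingness filter for ratio phenotypes
#'
#' Removes APA/junction features with a missing fraction above 5% and
#' median-imputes the missing values of retained features (the downstream
#' elastic net needs complete response vectors).
#'
#' @param m A [pheno_matrix()] with layer `"apa"` or `"junction"`.
#' @param max_missing_frac Maximum tolerated missing fraction (strict;
#'   default 0.05).
#' @return The filtered, imputed `pheno_matrix`.
#' @export
event_missingness_filter <- function(m, max_missing_frac = 0.05) {
  stopifnot(inherits(m, "pheno_matrix"), m$layer %in% c("apa", "junction"))
  miss <- rowMeans(is.na(m$values))
  keep <- miss <= max_missing_frac
  vals <- m$values[keep, , drop = FALSE]
  if (anyNA(vals)) {
    med <- apply(vals, 1L, median, na.rm = TRUE)
    idx <- which(is.na(vals), arr.ind = TRUE)
    vals[idx] <- med[idx[, 1L]]
  }
  pheno_matrix(vals, m$anchors[keep, , drop = FALSE], m$layer)
}

#' Quantile normalization across samples
#'
#' Classic cross-sample rank-mean normalization: every sample's value vector
#' is mapped onto the per-rank mean of all samples, preserving within-sample
#' ranks (ties get the average of the tied rank means). Alternatively,
#' per-feature rank inverse-normal transformation (`method = "inverse_normal"`).
#'
#' @param m A [pheno_matrix()] without missing values.
#' @param method `"rank_mean"` (default) or `"inverse_normal"`.
#' @return The normalized `pheno_matrix` (value bounds no longer apply, so
#'   the result is tagged as normalized).
#' @export
quantile_normalize <- function(m, method = c("rank_mean", "inverse_normal")) {
  stopifnot(inherits(m, "pheno_matrix"))
  method <- match.arg(method)
  if (anyNA(m$values)) stop("quantile_normalize requires complete values")
  vals <- if (ncol(m$values) == 1L) {
    m$values
  } else if (method == "rank_mean") {
    out <- limma::normalizeQuantiles(m$values, ties = TRUE)
    dimnames(out) <- dimnames(m$values)
    out
  } else {
    t(apply(m$values, 1L, function(x) {
      qnorm((rank(x, ties.method = "average") - 0.5) / length(x))
    }))
  }
  out <- m
  out$values <- vals
  out$normalized <- TRUE
  out
}

#' Latent expression factors (PEER surrogate)
#'
#' Top-k principal-component scores of the feature-standardized phenotype
#' matrix, used in place of PEER factors as deterministic latent covariates
#' capturing batch effects and hidden confounders. Signs are fixed by making
#' each component's largest-magnitude loading positive. The default k
#' follows the sample-size rule used for PEER: 15 factors below 150 samples,
#' 30 at 150 or more.
#'
#' @param m A normalized [pheno_matrix()].
#' @param k Number of factors; `NULL` applies the sample-size default,
#'   capped at `n_samples - 1` and the number of usable features.
#' @return Matrix of factor scores, samples in rows, columns
#'   `factor1..factork` (zero columns when `k = 0`).
#' @export
infer_latent_factors <- function(m, k = NULL) {
  stopifnot(inherits(m, "pheno_matrix"))
  n <- ncol(m$values)
  if (is.null(k)) k <- if (n < 150L) 15L else 30L
  if (k >= n) stop("k must be smaller than the number of samples")
  if (k == 0L)
    return(matrix(numeric(0), nrow = n, ncol = 0L,
                  dimnames = list(colnames(m$values), NULL)))
  sds <- apply(m$values, 1L, sd)
  X <- m$values[sds > 0, , drop = FALSE]
  Xs <- t(scale(t(X)))             # standardize each feature
  k <- min(k, nrow(Xs) - 1L)
  pc <- prcomp(t(Xs), center = TRUE, scale. = FALSE, rank. = k)
  scores <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    lead <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[lead, j] < 0) scores[, j] <- -scores[, j]
  }
  colnames(scores) <- paste0("factor", seq_len(k))
  rownames(scores) <- colnames(m$values)
  scores
}

#' Top genetic principal components
#'
#' Principal components of the mean-imputed, column-standardized dosage
#' matrix — the usual ancestry/structure covariates.
#'
#' @param geno A [genotype_matrix()].
#' @param k Number of components (default 5).
#' @return Matrix of PC scores, samples in rows, columns `pc1..pck`.
#' @export
genotype_pcs <- function(geno, k = 5L) {
  stopifnot(inherits(geno, "genotype_matrix"))
  X <- impute_col_means(geno$dosage)
  sds <- apply(X, 2L, sd)
  X <- scale(X[, sds > 0, drop = FALSE])
  k <- min(k, nrow(X) - 1L, ncol(X))
  pc <- prcomp(X, center = FALSE, scale. = FALSE, rank. = k)
  scores <- pc$x[, seq_len(k), drop = FALSE]
  colnames(scores) <- paste0("pc", seq_len(k))
  rownames(scores) <- rownames(geno$dosage)
  scores
}

#' Residualize phenotypes on covariates
#'
#' Replaces every feature by its least-squares residuals on
#' `[intercept | covariates]`; residuals are orthogonal to every covariate
#' column. Rank-deficient covariate matrices raise an error naming the
#' collinear columns.
#'
#' @param m A [pheno_matrix()] with complete values.
#' @param covariates Numeric matrix or data frame, samples in rows
#'   (`NULL` or zero columns = intercept only, i.e. mean-centering).
#' @return The residualized `pheno_matrix`.
#' @export
residualize <- function(m, covariates = NULL) {
  stopifnot(inherits(m, "pheno_matrix"))
  if (anyNA(m$values)) stop("residualize requires complete values")
  n <- ncol(m$values)
  C <- if (is.null(covariates)) matrix(numeric(0), nrow = n, ncol = 0L)
       else as.matrix(covariates)
  if (nrow(C) != n) stop("covariates and phenotypes disagree on sample count")
  design <- cbind(`(Intercept)` = 1, C)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    bad <- colnames(design)[qrd$pivot[(qrd$rank + 1L):ncol(design)]]
    stop("collinear covariate column(s): ", paste(bad, collapse = ", "))
  }
  fit <- lm.fit(design, t(m$values))
  out <- m
  out$values <- t(as.matrix(fit$residuals))
  dimnames(out$values) <- dimnames(m$values)
  out$normalized <- TRUE
  out
}
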