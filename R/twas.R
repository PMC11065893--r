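# Gene-level association from GWAS summary statistics: the summary-based
# Z statistic, genome-wide scanning with Bonferroni control, and one-sided
# replication testing.

#' Reference-panel SNP covariance
#'
#' Sample covariance (denominator n-1) of the mean-centered dosages of the
#' requested variants; missing dosages are mean-imputed first. Zero-variance
#' variants are dropped with a warning.
#'
#' @param panel A [genotype_matrix()].
#' @param variant_ids Variants to include.
#' @return List of class `ref_covariance` with `Gamma` (covariance matrix),
#'   `variant_ids`, and `sigma_l` (per-variant SDs, `sqrt(diag(Gamma))`).
#' @export
snp_covariance <- function(panel, variant_ids) {
  stopifnot(inherits(panel, "genotype_matrix"))
  idx <- match(variant_ids, panel$variants$id)
  if (anyNA(idx))
    stop("variant id(s) absent from panel: ",
         paste(head(variant_ids[is.na(idx)], 5L), collapse = ", "))
  X <- impute_col_means(panel$dosage[, idx, drop = FALSE])
  keep <- apply(X, 2L, sd) > 0
  if (!any(keep)) stop("no variants with nonzero variance remain")
  if (!all(keep))
    warning("dropping zero-variance variant(s): ",
            paste(variant_ids[!keep], collapse = ", "))
  X <- X[, keep, drop = FALSE]
  Gamma <- cov(X)
  structure(list(Gamma = Gamma, variant_ids = variant_ids[keep],
                 sigma_l = sqrt(diag(Gamma)), n = nrow(X)),
            class = "ref_covariance")
}

#' Summary-statistics TWAS Z score for one feature
#'
#' The gene-level statistic `Z_g = sum_l w_lg (sigma_l / sigma_g)
#' (beta_l / se_l)` over the model's variants present in the GWAS summary
#' statistics, with `sigma_g = sqrt(w' Gamma w)` recomputed on that
#' intersection using the reference-panel covariance. Alleles must already
#' be harmonized ([harmonize_alleles()]). A two-sided p-value comes from
#' the standard normal.
#'
#' @param model A [weight_model()].
#' @param stats A `gwas_sumstats` data frame (harmonized).
#' @param cov A `ref_covariance` from [snp_covariance()] covering the model
#'   variants (extra variants are fine).
#' @param ridge Diagonal ridge added only if `w' Gamma w` is non-positive
#'   from floating-point noise (default 1e-8).
#' @return One-row data frame: `feature_id`, `layer`, `zscore`, `p`,
#'   `n_used`, `n_dropped`, `weight_mass_dropped`, `skip_reason` (`NA` when
#'   computed).
#' @export
twas_zscore <- function(model, stats, cov, ridge = 1e-8) {
  stopifnot(inherits(model, "weight_model"))
  skip <- function(reason)
    data.frame(feature_id = model$feature_id, layer = model$layer,
               zscore = NA_real_, p = NA_real_, n_used = 0L,
               n_dropped = nrow(model$variants),
               weight_mass_dropped = 1, skip_reason = reason,
               stringsAsFactors = FALSE)
  ids <- intersect(model$variants$id,
                   intersect(stats$variant_id, cov$variant_ids))
  if (length(ids) == 0L) return(skip("no_gwas_overlap"))
  w_all <- setNames(model$variants$weight, model$variants$id)
  w <- w_all[ids]
  mass_dropped <- 1 - sum(abs(w)) / sum(abs(w_all))
  G <- cov$Gamma[ids, ids, drop = FALSE]
  sig2_g <- drop(crossprod(w, G %*% w))
  if (sig2_g <= 0) sig2_g <- drop(crossprod(w, (G + diag(ridge, length(w))) %*% w))
  if (sig2_g <= 0) return(skip("zero_sigma_g"))
  st <- stats[match(ids, stats$variant_id), , drop = FALSE]
  sigma_l <- cov$sigma_l[match(ids, cov$variant_ids)]
  z <- sum(w * sigma_l / sqrt(sig2_g) * st$beta / st$se)
  data.frame(feature_id = model$feature_id, layer = model$layer,
             zscore = z, p = 2 * pnorm(-abs(z)),
             n_used = length(ids),
             n_dropped = nrow(model$variants) - length(ids),
             weight_mass_dropped = mass_dropped,
             skip_reason = NA_character_, stringsAsFactors = FALSE)
}

#' Genome-wide TWAS scan
#'
#' Harmonizes the GWAS statistics to every model, computes the gene-level Z
#' for each retained model and applies per-layer Bonferroni control:
#' `m` counts the models actually tested in a layer (features skipped for
#' zero GWAS overlap or degenerate variance are logged and excluded from
#' `m`), and the significance threshold is `0.05 / m`.
#'
#' @param db A [build_weight_db()] weight database.
#' @param stats A `gwas_sumstats` data frame.
#' @param panel Reference [genotype_matrix()] for the LD covariance.
#' @param alpha_fw Family-wise error budget per layer (default 0.05).
#' @return A `twas_result` data frame with one row per model: `zscore`, `p`,
#'   `n_used`, `n_dropped`, `weight_mass_dropped`, `m`, `threshold`,
#'   `significant`, `skip_reason`.
#' @export
twas_scan <- function(db, stats, panel, alpha_fw = 0.05) {
  stopifnot(inherits(db, "weight_db"))
  if (length(db$models) == 0L) stop("empty weight database")
  rows <- vector("list", length(db$models))
  for (i in seq_along(db$models)) {
    model <- db$models[[i]]
    harm <- harmonize_alleles(model$variants, stats)
    ids <- intersect(model$variants$id, harm$stats$variant_id)
    if (length(ids) == 0L) {
      rows[[i]] <- twas_zscore(model,
                               harm$stats[0L, , drop = FALSE],
                               structure(list(Gamma = matrix(0, 0, 0),
                                              variant_ids = character(0),
                                              sigma_l = numeric(0)),
                                         class = "ref_covariance"))
      next
    }
    cov <- tryCatch(snp_covariance(panel, ids), error = function(e) NULL)
    rows[[i]] <- if (is.null(cov)) {
      r <- twas_zscore(model, harm$stats[0L, , drop = FALSE],
                       structure(list(Gamma = matrix(0, 0, 0),
                                      variant_ids = character(0),
                                      sigma_l = numeric(0)),
                                 class = "ref_covariance"))
      r$skip_reason <- "zero_sigma_g"
      r
    } else suppressWarnings(twas_zscore(model, harm$stats, cov))
  }
  res <- do.call(rbind, rows)
  tested <- !is.na(res$zscore)
  m_layer <- tapply(tested, res$layer, sum)
  res$m <- as.integer(m_layer[res$layer])
  res$threshold <- alpha_fw / res$m
  res$significant <- tested & res$p < res$threshold
  class(res) <- c("twas_result", "data.frame")
  attr(res, "alpha_fw") <- alpha_fw
  res
}

#' @export
print.twas_result <- function(x, ...) {
  tested <- sum(!is.na(x$zscore))
  cat("twas_result: ", nrow(x), " models (", tested, " tested, ",
      sum(x$significant, na.rm = TRUE), " significant)\n", sep = "")
  for (ly in unique(x$layer)) {
    m <- x$m[x$layer == ly][1L]
    cat(sprintf("  layer %-10s m = %d, Bonferroni threshold = %s\n",
                ly, m, format(bonferroni_threshold(m, printed = TRUE))))
  }
  top <- x[order(x$p), , drop = FALSE]
  top <- top[!is.na(top$p), c("layer", "feature_id", "zscore", "p",
                              "significant"), drop = FALSE]
  print.data.frame(head(top, 5L), digits = 3L, row.names = FALSE)
  invisible(x)
}

#' @export
summary.twas_result <- function(object, ...) {
  df <- as.data.frame(object)
  df[order(df$p), , drop = FALSE]
}

#' Bonferroni significance threshold
#'
#' `alpha / m` for `m` tests. With `printed = TRUE` the value is truncated
#' toward zero at two significant digits — the conservative convention for
#' quoting a threshold (e.g. m = 11426 gives 4.3e-6, not 4.4e-6).
#'
#' @param m Number of tests.
#' @param alpha Family-wise error budget (default 0.05).
#' @param printed Truncate to 2 significant digits for display.
#' @return The threshold.
#' @export
bonferroni_threshold <- function(m, alpha = 0.05, printed = FALSE) {
  x <- alpha / m
  if (!printed) return(x)
  e <- floor(log10(x)) - 1L           # keep 2 significant digits
  trunc(x / 10^e) * 10^e
}

#' Z score implied by a printed p-value
#'
#' Inverts a two-sided (`|Z| = qnorm(p/2)` upper tail) or one-sided p-value
#' through the standard-normal quantile.
#'
#' @param p P-value(s).
#' @param sided 2 (default) or 1.
#' @return The implied (absolute) Z score(s).
#' @export
zscore_from_p <- function(p, sided = 2) {
  stopifnot(sided %in% c(1, 2))
  qnorm(p / sided, lower.tail = FALSE)
}

#' One-sided replication test
#'
#' Tests whether a feature's Z score replicates a previously reported
#' association direction: `p = pnorm(-Z * direction)`, replicated when
#' `p < level`.
#'
#' @param zscore TWAS Z score(s).
#' @param prior_direction +1 or -1 (the sign reported previously);
#'   vectorized.
#' @param level Significance level (default 0.05).
#' @return Data frame with `one_sided_p` and `replicated`.
#' @export
replication_test <- function(zscore, prior_direction, level = 0.05) {
  stopifnot(all(prior_direction %in% c(-1, 1)))
  p <- pnorm(-zscore * prior_direction)
  data.frame(one_sided_p = p, replicated = p < level)
}
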