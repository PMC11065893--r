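# Approximate conditional analysis on summary statistics (COJO-style) and
# the conditional TWAS rerun.

#' Adjust GWAS summary statistics for a conditioning variant set
#'
#' Approximate conditional analysis using reference LD in place of
#' individual-level genotypes: with `D_j = n Gamma_jj` and
#' `B_jk = n Gamma_jk`, the joint effect of the conditioning set `C` is
#' `b_C = B_CC^-1 (D_C * beta_C)` and the conditional effect of a target
#' variant `t` is `beta_t - D_t^-1 B_tC b_C`. Standard errors use the
#' residual-variance formula with the phenotypic variance treated as fixed
#' (`var_y`, default 1 for a standardized trait; for a logistic GWAS the
#' same LD algebra is applied on the log-odds scale as an approximation).
#' A target that is itself in `C` gets a conditional effect of exactly 0.
#'
#' @param stats A `gwas_sumstats` data frame (targets = all rows present in
#'   `cov`).
#' @param cond_ids Conditioning variant id(s), present in `stats` and `cov`.
#' @param cov A `ref_covariance` from [snp_covariance()] covering targets
#'   and conditioning variants.
#' @param n GWAS sample size (defaults to the median `n` in `stats`).
#' @param var_y Fixed phenotypic variance (default 1).
#' @return The adjusted `gwas_sumstats` (rows restricted to variants present
#'   in `cov`; `beta`, `se`, `p` replaced by conditional values).
#' @export
conditional_sumstats <- function(stats, cond_ids, cov,
                                 n = stats::median(stats$n), var_y = 1) {
  stopifnot(inherits(cov, "ref_covariance"))
  if (length(cond_ids) == 0L) stop("no conditioning variants given")
  if (!all(cond_ids %in% stats$variant_id))
    stop("conditioning variant(s) absent from stats: ",
         paste(setdiff(cond_ids, stats$variant_id), collapse = ", "))
  if (!all(cond_ids %in% cov$variant_ids))
    stop("conditioning variant(s) absent from covariance: ",
         paste(setdiff(cond_ids, cov$variant_ids), collapse = ", "))
  if (n <= length(cond_ids) + 1L)
    stop("sample size too small for the conditioning set")
  st <- stats[stats$variant_id %in% cov$variant_ids, , drop = FALSE]
  ids <- st$variant_id
  G <- cov$Gamma[ids, ids, drop = FALSE]
  D <- n * diag(G)
  beta <- st$beta
  ci <- match(cond_ids, ids)
  B_CC <- n * G[ci, ci, drop = FALSE]
  b_C <- tryCatch(solve(B_CC, D[ci] * beta[ci]),
                  error = function(e)
                    stop("singular conditioning-set LD matrix; ",
                         "prune correlated conditioning variants"))
  explained <- sum(b_C * D[ci] * beta[ci])
  sigma2 <- (n * var_y - explained) / (n - length(ci) - 1L)
  sigma2 <- max(sigma2, 1e-12)
  B_tC <- n * G[, ci, drop = FALSE]
  adj <- beta - drop(B_tC %*% b_C) / D
  adj[ci] <- 0
  se_adj <- sqrt(sigma2 / D)
  z <- adj / se_adj
  st$beta <- adj
  st$se <- se_adj
  st$p <- 2 * pnorm(-abs(z))
  rownames(st) <- NULL
  class(st) <- c("gwas_sumstats", "data.frame")
  st
}

#' Locate the lead GWAS variant near a feature
#'
#' The GWAS-significant variant (p below `p_threshold`) closest to the
#' feature's anchor interval within `+/- window`; distance ties are broken
#' by the smaller p-value.
#'
#' @param anchor One-row data frame with `chrom`, `start`, `end`.
#' @param stats A `gwas_sumstats` data frame.
#' @param window Search half-width in bp (default 500 kb).
#' @param p_threshold Genome-wide significance cutoff (default 5e-8).
#' @return The lead variant id, or `NA_character_` when none qualifies.
#' @export
find_lead_variant <- function(anchor, stats, window = 5e5,
                              p_threshold = 5e-8) {
  b <- cis_window_bounds(anchor$start[1L], anchor$end[1L], window)
  cand <- stats[stats$chrom == anchor$chrom[1L] &
                  stats$pos >= b[1L] & stats$pos <= b[2L] &
                  !is.na(stats$p) & stats$p < p_threshold, , drop = FALSE]
  if (nrow(cand) == 0L) return(NA_character_)
  dist <- pmax(0, pmax(anchor$start[1L] - cand$pos,
                       cand$pos - anchor$end[1L]))
  cand <- cand[order(dist, cand$p), , drop = FALSE]
  cand$variant_id[1L]
}

#' Conditional TWAS for one feature
#'
#' Adjusts every model variant for the nearest GWAS lead variant
#' ([find_lead_variant()] rule, configurable) and recomputes the gene-level
#' Z on the adjusted statistics with the same reference covariance. When no
#' lead variant lies within the window the marginal result is returned
#' flagged as not conditioned.
#'
#' @param model A [weight_model()].
#' @param stats A `gwas_sumstats` data frame (raw; harmonization to the
#'   model alleles is applied internally).
#' @param panel Reference [genotype_matrix()].
#' @param lead_variant Conditioning variant id; `NULL` applies the
#'   nearest-lead rule.
#' @param window,p_threshold Lead-variant search rule parameters.
#' @param var_y Passed to [conditional_sumstats()].
#' @return One-row data frame: marginal `zscore`/`p`, `cond_variant`,
#'   `cond_zscore`, `cond_p`, `conditioned` flag.
#' @export
conditional_twas <- function(model, stats, panel, lead_variant = NULL,
                             window = 5e5, p_threshold = 5e-8, var_y = 1) {
  stopifnot(inherits(model, "weight_model"))
  harm <- harmonize_alleles(model$variants, stats)$stats
  model_ids <- intersect(model$variants$id, harm$variant_id)
  if (length(model_ids) == 0L) stop("no model variants present in GWAS stats")
  if (is.null(lead_variant))
    lead_variant <- find_lead_variant(model$anchor, stats, window, p_threshold)
  marg_cov <- snp_covariance(panel, model_ids)
  marginal <- twas_zscore(model, harm, marg_cov)
  if (is.na(lead_variant)) {
    return(data.frame(feature_id = model$feature_id, layer = model$layer,
                      zscore = marginal$zscore, p = marginal$p,
                      cond_variant = NA_character_,
                      cond_zscore = marginal$zscore, cond_p = marginal$p,
                      conditioned = FALSE, stringsAsFactors = FALSE))
  }
  # the conditioning variant must share the panel's allele orientation or
  # the cross-covariance term B_tC flips sign against b_C
  li <- match(lead_variant, panel$variants$id)
  if (is.na(li)) stop("lead variant absent from the reference panel")
  lead_stats <- harmonize_alleles(
    data.frame(id = lead_variant,
               effect_allele = panel$variants$alt[li],
               other_allele = panel$variants$ref[li],
               stringsAsFactors = FALSE),
    stats)$stats
  if (nrow(lead_stats) == 0L)
    stop("lead variant absent from stats or not harmonizable")
  all_ids <- union(model_ids, lead_variant)
  cov <- snp_covariance(panel, all_ids)
  st <- rbind(harm[harm$variant_id %in% model_ids, , drop = FALSE],
              if (lead_variant %in% harm$variant_id) NULL else lead_stats)
  adj <- conditional_sumstats(st, lead_variant, cov, var_y = var_y)
  cond <- twas_zscore(model, adj, cov)
  data.frame(feature_id = model$feature_id, layer = model$layer,
             zscore = marginal$zscore, p = marginal$p,
             cond_variant = lead_variant,
             cond_zscore = cond$zscore, cond_p = cond$p,
             conditioned = TRUE, stringsAsFactors = FALSE)
}
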