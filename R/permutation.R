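# Weight-permutation test: does the variant-to-weight assignment add signal
# beyond the marginal SNP/trait associations at the locus?

#' Permutation test for a TWAS association
#'
#' Shuffles the weight-to-variant assignment within the model (default) or
#' flips weight signs, recomputes `|Z|` each time, and reports the empirical
#' p-value `(1 + #exceedances) / (1 + n_perm)`. Only features whose marginal
#' TWAS p is below `entry_threshold` are evaluated (others are recorded as
#' skipped); permutation stops early once `early_stop` exceedances have
#' accumulated, and never exceeds `max_perm` permutations.
#'
#' @param model A [weight_model()] with at least 3 variants usable in the
#'   GWAS statistics (fewer is reported as not evaluable).
#' @param stats A harmonized `gwas_sumstats` data frame.
#' @param cov A `ref_covariance` covering the model variants.
#' @param max_perm Permutation cap (default 1000).
#' @param entry_threshold Marginal p required to run the test (default 0.05).
#' @param seed Seed for the permutation stream.
#' @param early_stop Exceedance count triggering adaptive stop (default 20).
#' @param scheme `"shuffle"` (permute weights among the model's variants,
#'   default) or `"signflip"` (random sign flips).
#' @return One-row data frame: `feature_id`, `zscore`, `p` (marginal),
#'   `perm_p`, `n_perm`, `n_exceed`, `status` (`"ok"`, `"not_entered"`,
#'   `"not_evaluable"`), `seed`.
#' @export
permutation_test <- function(model, stats, cov, max_perm = 1000L,
                             entry_threshold = 0.05, seed = 1L,
                             early_stop = 20L,
                             scheme = c("shuffle", "signflip")) {
  scheme <- match.arg(scheme)
  obs <- twas_zscore(model, stats, cov)
  out <- data.frame(feature_id = model$feature_id, zscore = obs$zscore,
                    p = obs$p, perm_p = NA_real_, n_perm = 0L,
                    n_exceed = NA_integer_, status = "not_evaluable",
                    seed = seed, stringsAsFactors = FALSE)
  if (is.na(obs$zscore)) return(out)
  ids <- intersect(model$variants$id,
                   intersect(stats$variant_id, cov$variant_ids))
  if (length(ids) < 3L) return(out)
  if (obs$p >= entry_threshold) {
    out$status <- "not_entered"
    return(out)
  }
  w <- setNames(model$variants$weight, model$variants$id)[ids]
  G <- cov$Gamma[ids, ids, drop = FALSE]
  sigma_l <- cov$sigma_l[match(ids, cov$variant_ids)]
  st <- stats[match(ids, stats$variant_id), , drop = FALSE]
  zl <- st$beta / st$se
  score <- sigma_l * zl
  zfun <- function(wp) {
    s2 <- drop(crossprod(wp, G %*% wp))
    if (s2 <= 0) return(0)
    sum(wp * score) / sqrt(s2)
  }
  z_obs <- abs(zfun(w))
  res <- with_seed(seed, {
    exceed <- 0L
    nperm <- 0L
    for (i in seq_len(max_perm)) {
      wp <- if (scheme == "shuffle") sample(w) else
        w * sample(c(-1, 1), length(w), replace = TRUE)
      nperm <- i
      if (abs(zfun(wp)) >= z_obs) exceed <- exceed + 1L
      if (exceed >= early_stop) break
    }
    c(exceed = exceed, nperm = nperm)
  })
  out$perm_p <- (1 + res[["exceed"]]) / (1 + res[["nperm"]])
  out$n_perm <- res[["nperm"]]
  out$n_exceed <- res[["exceed"]]
  out$status <- "ok"
  out
}
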