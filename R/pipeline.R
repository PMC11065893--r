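# End-to-end driver: QC -> phenotype preparation -> model training ->
# summary-statistics association, per molecular layer.

#' Run the full TWAS pipeline on in-memory objects
#'
#' Chains the standard stages for each supplied layer: variant QC on the
#' reference panel; layer-appropriate phenotype preparation (expression
#' filter + log transform, or missingness filter for APA/junction, then
#' quantile normalization, latent factors and residualization on
#' covariates + factors); cis elastic-net training with five-fold CV;
#' weight-database retention; and the summary-statistics association scan
#' with per-layer Bonferroni control.
#'
#' @param panel A [genotype_matrix()] reference panel.
#' @param phenotypes Named list of raw [pheno_matrix()] objects keyed by
#'   layer (`expression` on the TPM scale; `apa`/`junction` as ratios).
#' @param stats A `gwas_sumstats` data frame.
#' @param covariates Optional data frame / matrix of measured covariates
#'   (e.g. age); genetic PCs and latent factors are added internally.
#' @param config A [pipeline_config()] supplying thresholds and the seed.
#' @param n_genetic_pcs Genetic principal components to adjust (default 5).
#' @param n_factors Latent phenotype factors; `NULL` applies the
#'   sample-size rule of [infer_latent_factors()].
#' @return List with `results` (a `twas_result`), `db` (per-layer
#'   [build_weight_db()] databases), and `qc` (the panel `qc_report`).
#' @export
twas_pipeline <- function(panel, phenotypes, stats, covariates = NULL,
                          config = pipeline_config(), n_genetic_pcs = 5L,
                          n_factors = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  qc <- qc_filter(panel, maf = config$maf, hwe_p = config$hwe_p,
                  missing = config$missing, impute_r2 = config$impute_r2)
  panel <- qc$geno
  pcs <- genotype_pcs(panel, k = n_genetic_pcs)
  dbs <- list()
  results <- list()
  for (layer in intersect(config$layers, names(phenotypes))) {
    ph <- phenotypes[[layer]]
    ph <- if (layer == "expression") expression_filter_and_transform(ph)
          else event_missingness_filter(ph)
    if (nrow(ph$values) == 0L) next
    ph <- quantile_normalize(ph)
    factors <- infer_latent_factors(ph, k = n_factors)
    covs <- cbind(if (!is.null(covariates)) as.matrix(covariates), pcs,
                  factors)
    models <- train_cis_models(panel, ph, covariates = covs,
                               alpha = config$alpha, nfolds = config$folds,
                               seed = config$seed,
                               cis_window = config$cis_window)
    db <- build_weight_db(models, r_threshold = config$r_threshold)
    if (length(db$models) == 0L) {
      warning("no models retained for layer ", layer)
      next
    }
    dbs[[layer]] <- db
    results[[layer]] <- twas_scan(db, stats, panel)
  }
  res <- do.call(rbind, results)
  if (!is.null(res)) {
    rownames(res) <- NULL
    class(res) <- c("twas_result", "data.frame")
  }
  list(results = res, db = dbs, qc = qc$report)
}
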