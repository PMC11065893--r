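# Core containers shared across the pipeline. All are light S3 wrappers over
# base matrices / data frames so that every stage can be inspected directly.

#' Construct a genotype matrix
#'
#' Bundles a samples-by-variants dosage matrix with per-variant metadata.
#' Dosages count copies of the alternate allele and lie in `[0, 2]`;
#' missing genotypes are `NA`.
#'
#' @param dosage Numeric matrix, samples in rows, variants in columns.
#'   Column names must match `variants$id`.
#' @param variants Data frame with columns `id`, `chrom`, `pos` (1-based),
#'   `ref`, `alt`, and optionally `r2` (imputation quality, `NA` when
#'   genotyped directly) and `multiallelic` (logical).
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, variants) {
  stopifnot(is.matrix(dosage), is.data.frame(variants))
  req <- c("id", "chrom", "pos", "ref", "alt")
  missing_cols <- setdiff(req, names(variants))
  if (length(missing_cols) > 0L)
    stop("variants table lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (ncol(dosage) != nrow(variants))
    stop("dosage has ", ncol(dosage), " columns but variants has ",
         nrow(variants), " rows")
  if (anyDuplicated(variants$id))
    stop("duplicate variant ids in genotype matrix")
  if (is.null(colnames(dosage))) colnames(dosage) <- variants$id
  if (!identical(colnames(dosage), as.character(variants$id)))
    stop("dosage column names do not match variants$id")
  if (is.null(variants$r2)) variants$r2 <- NA_real_
  if (is.null(variants$multiallelic)) variants$multiallelic <- FALSE
  bad <- dosage < 0 | dosage > 2
  if (any(bad, na.rm = TRUE)) stop("dosages must lie in [0, 2]")
  structure(list(dosage = dosage, variants = variants),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix: ", nrow(x$dosage), " samples x ",
      nrow(x$variants), " variants\n", sep = "")
  cat("  chrom(s): ", paste(unique(x$variants$chrom), collapse = ", "), "\n",
      sep = "")
  miss <- mean(is.na(x$dosage))
  cat(sprintf("  missing dosage fraction: %.4f\n", miss))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Subset a genotype matrix by variant id
#'
#' @param geno A [genotype_matrix()].
#' @param ids Variant ids to keep (order preserved).
#' @return A `genotype_matrix` restricted to `ids`.
#' @export
subset_variants <- function(geno, ids) {
  stopifnot(inherits(geno, "genotype_matrix"))
  idx <- match(ids, geno$variants$id)
  if (anyNA(idx))
    stop("variant id(s) not present: ",
         paste(head(ids[is.na(idx)], 5L), collapse = ", "))
  genotype_matrix(geno$dosage[, idx, drop = FALSE],
                  geno$variants[idx, , drop = FALSE])
}

#' Construct a molecular phenotype matrix
#'
#' Holds quantified molecular levels for one layer: `expression` (TPM-scale,
#' non-negative), `apa` (PDUI in `[0, 1]`) or `junction` (PSI in `[0, 1]`).
#' Features are rows, samples are columns; each feature carries a genomic
#' anchor used to define its cis window.
#'
#' @param values Numeric matrix, features in rows, samples in columns.
#' @param anchors Data frame with columns `feature_id`, `chrom`, `start`,
#'   `end`, `strand` (1-based inclusive coordinates, `start <= end`).
#' @param layer One of `"expression"`, `"apa"`, `"junction"`.
#' @return An object of class `pheno_matrix`.
#' @export
pheno_matrix <- function(values, anchors, layer) {
  layer <- match.arg(layer, c("expression", "apa", "junction"))
  stopifnot(is.matrix(values), is.data.frame(anchors))
  req <- c("feature_id", "chrom", "start", "end", "strand")
  missing_cols <- setdiff(req, names(anchors))
  if (length(missing_cols) > 0L)
    stop("anchors table lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(values) != nrow(anchors))
    stop("values and anchors disagree on feature count")
  if (any(anchors$start > anchors$end)) stop("anchor start > end")
  if (is.null(rownames(values))) rownames(values) <- anchors$feature_id
  rng <- range(values, na.rm = TRUE)
  if (layer == "expression" && rng[1L] < 0)
    stop("expression values must be non-negative")
  if (layer %in% c("apa", "junction") && (rng[1L] < 0 || rng[2L] > 1))
    stop(layer, " values must lie in [0, 1]")
  structure(list(values = values, anchors = anchors, layer = layer),
            class = "pheno_matrix")
}

#' @export
print.pheno_matrix <- function(x, ...) {
  cat("pheno_matrix [", x$layer, "]: ", nrow(x$values), " features x ",
      ncol(x$values), " samples\n", sep = "")
  cat(sprintf("  missing fraction: %.4f\n", mean(is.na(x$values))))
  invisible(x)
}

#' Construct a per-feature weight model
#'
#' A trained cis prediction model: variant weights on the raw 0-2 dosage
#' scale together with cross-validated performance.
#'
#' @param feature_id Feature identifier.
#' @param layer Molecular layer (`expression`, `apa`, `junction`).
#' @param anchor One-row data frame with `chrom`, `start`, `end`.
#' @param variants Data frame with `id`, `pos`, `effect_allele`,
#'   `other_allele`, `weight` (only variants with nonzero weight need be
#'   retained, but zeros are tolerated).
#' @param cv_R Cross-validated prediction correlation in `[-1, 1]` (`NA`
#'   when not assessed).
#' @param lambda,alpha Elastic-net hyperparameters used.
#' @param seed Seed used for the fold assignment.
#' @return Object of class `weight_model`.
#' @export
weight_model <- function(feature_id, layer, anchor, variants,
                         cv_R = NA_real_, lambda = NA_real_,
                         alpha = NA_real_, seed = NA_integer_) {
  layer <- match.arg(layer, c("expression", "apa", "junction"))
  req <- c("id", "pos", "effect_allele", "other_allele", "weight")
  missing_cols <- setdiff(req, names(variants))
  if (length(missing_cols) > 0L)
    stop("weight model variants lack column(s): ",
         paste(missing_cols, collapse = ", "))
  if (anyDuplicated(variants$id)) stop("duplicate variant ids in weight model")
  if (!is.na(cv_R) && abs(cv_R) > 1) stop("cv_R must lie in [-1, 1]")
  structure(list(feature_id = feature_id, layer = layer,
                 anchor = anchor, variants = variants,
                 cv_R = cv_R, n_nonzero = sum(variants$weight != 0),
                 lambda = lambda, alpha = alpha, seed = seed),
            class = "weight_model")
}

#' @export
print.weight_model <- function(x, ...) {
  cat("weight_model: ", x$feature_id, " [", x$layer, "]\n", sep = "")
  cat(sprintf("  %d variants (%d nonzero), cv_R = %s\n",
              nrow(x$variants), x$n_nonzero,
              ifelse(is.na(x$cv_R), "NA", sprintf("%.3f", x$cv_R))))
  invisible(x)
}

#' @export
coef.weight_model <- function(object, ...) {
  setNames(object$variants$weight, object$variants$id)
}

#' Predict genetically regulated levels from a weight model
#'
#' Computes the model's linear score `X w` on raw dosages. Variants absent
#' from the genotype matrix are dropped; missing dosages are imputed to the
#' per-variant mean.
#'
#' @param object A [weight_model()].
#' @param geno A [genotype_matrix()].
#' @param ... Unused.
#' @return Numeric vector of predicted levels, one per sample.
#' @export
predict.weight_model <- function(object, geno, ...) {
  stopifnot(inherits(geno, "genotype_matrix"))
  ids <- intersect(object$variants$id, geno$variants$id)
  if (length(ids) == 0L)
    stop("no model variants present in the genotype matrix")
  X <- geno$dosage[, ids, drop = FALSE]
  X <- impute_col_means(X)
  w <- setNames(object$variants$weight, object$variants$id)[ids]
  drop(X %*% w)
}

# mean-impute missing entries column-wise (all-NA columns become 0)
impute_col_means <- function(X) {
  if (!anyNA(X)) return(X)
  mu <- colMeans(X, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  idx <- which(is.na(X), arr.ind = TRUE)
  X[idx] <- mu[idx[, 2L]]
  X
}
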