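# Readers and writers for the formats the pipeline touches: VCF genotypes,
# GWAS summary-statistics TSV, phenotype TSV, the weight-database TSV and
# the YAML pipeline configuration. Coordinates are 1-based inclusive
# everywhere (VCF convention).

#' Write genotypes as VCF
#'
#' Plain-text VCF v4.2 with `GT:DS` per sample and the imputation quality in
#' `INFO/R2`. Hard-call genotypes are rounded from dosage; missing dosages
#' become `./.:.`.
#'
#' @param geno A [genotype_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotypes_vcf <- function(geno, path) {
  stopifnot(inherits(geno, "genotype_matrix"))
  v <- geno$variants
  ord <- order(v$chrom, v$pos)
  v <- v[ord, , drop = FALSE]
  dos <- geno$dosage[, ord, drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=R2,Number=1,Type=Float,Description=\"Imputation quality\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Alt allele dosage\">",
    paste0("##contig=<ID=", unique(v$chrom), ">"),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(dos)), collapse = "\t")), con)
  gt_codes <- c("0/0", "0/1", "1/1")
  for (j in seq_len(nrow(v))) {
    d <- dos[, j]
    hard <- pmin(pmax(round(d), 0), 2)
    cells <- ifelse(is.na(d), "./.:.",
                    paste0(gt_codes[hard + 1L], ":",
                           formatC(d, format = "g", digits = 8)))
    info <- if (is.na(v$r2[j])) "." else paste0("R2=", formatC(v$r2[j], format = "g"))
    writeLines(paste(c(v$chrom[j], v$pos[j], v$id[j], v$ref[j], v$alt[j],
                       ".", "PASS", info, "GT:DS", cells), collapse = "\t"),
               con)
  }
  invisible(path)
}

#' Read genotypes from VCF
#'
#' Parses a VCF v4.x via `vcfR`. Dosage is taken from `DS` when the field is
#' present, otherwise from the `GT` alternate-allele count. Multi-allelic
#' records are kept but flagged for [qc_filter()]; `INFO/R2` is read as the
#' imputation quality when present.
#'
#' @param path VCF file (plain or gzipped).
#' @return A [genotype_matrix()].
#' @export
read_genotypes_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (nrow(fix) == 0L) stop("no variant records in ", path)
  fmt <- unique(unlist(strsplit(unname(fix_format(vcf)), ":", fixed = TRUE)))
  has_gt <- "GT" %in% fmt
  has_ds <- "DS" %in% fmt
  if (!has_gt && !has_ds) stop("VCF carries neither GT nor DS")
  r2 <- suppressWarnings(vcfR::extract.info(vcf, "R2", as.numeric = TRUE))
  if (is.null(r2)) r2 <- rep(NA_real_, nrow(fix))
  dos <- NULL
  if (has_ds)
    dos <- t(vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE))
  if (has_gt) {
    gt <- vcfR::extract.gt(vcf, element = "GT")
    counts <- t(apply(gt, c(1L, 2L), gt_alt_count))
    if (is.null(dos)) dos <- counts else {
      na_ds <- is.na(dos)
      dos[na_ds] <- counts[na_ds]
    }
  }
  ids <- fix[, "ID"]
  blank <- is.na(ids) | ids == "."
  ids[blank] <- paste0(fix[blank, "CHROM"], ":", fix[blank, "POS"])
  variants <- data.frame(id = ids, chrom = fix[, "CHROM"],
                         pos = as.integer(fix[, "POS"]),
                         ref = fix[, "REF"], alt = fix[, "ALT"],
                         r2 = r2,
                         multiallelic = grepl(",", fix[, "ALT"], fixed = TRUE),
                         stringsAsFactors = FALSE)
  colnames(dos) <- variants$id
  genotype_matrix(dos, variants)
}

fix_format <- function(vcf) {
  if ("FORMAT" %in% colnames(vcf@gt)) vcf@gt[, "FORMAT"] else character(0)
}

gt_alt_count <- function(g) {
  if (is.na(g) || g %in% c(".", "./.", ".|.")) return(NA_real_)
  alleles <- strsplit(g, "[/|]")[[1L]]
  if (any(alleles == ".")) return(NA_real_)
  sum(alleles != "0")
}

#' Read GWAS summary statistics
#'
#' Tab-separated file with header columns `variant_id`, `chrom`, `pos`,
#' `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `p`, `n`. Rows with
#' non-positive `se` or `eaf` outside (0, 1) are rejected; their count is
#' attached as attribute `n_rejected`.
#'
#' @param path TSV path.
#' @return A `gwas_sumstats` data frame.
#' @export
read_gwas_sumstats <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  req <- c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
           "eaf", "beta", "se", "p", "n")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0L)
    stop("summary-statistics file lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  df <- df[, req]
  bad <- is.na(df$se) | df$se <= 0 | is.na(df$eaf) | df$eaf <= 0 | df$eaf >= 1
  out <- df[!bad, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("gwas_sumstats", "data.frame")
  attr(out, "n_rejected") <- sum(bad)
  out
}

#' Write GWAS summary statistics
#'
#' @param stats A `gwas_sumstats` data frame.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_gwas_sumstats <- function(stats, path) {
  ord <- order(stats$chrom, stats$pos, stats$variant_id)
  cols <- c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
            "eaf", "beta", "se", "p", "n")
  write.table(as.data.frame(stats)[ord, cols], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a weight database as TSV
#'
#' One row per (feature, variant), sorted by layer, feature and position;
#' the model-building counts are preserved in a `#counts` comment line.
#'
#' @param db A [build_weight_db()] database.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_weight_db <- function(db, path) {
  stopifnot(inherits(db, "weight_db"))
  rows <- lapply(db$models, function(m) {
    if (nrow(m$variants) == 0L) return(NULL)
    data.frame(layer = m$layer, feature_id = m$feature_id,
               chrom = m$anchor$chrom[1L], start = m$anchor$start[1L],
               end = m$anchor$end[1L], variant_id = m$variants$id,
               pos = m$variants$pos,
               effect_allele = m$variants$effect_allele,
               other_allele = m$variants$other_allele,
               weight = m$variants$weight, cv_R = m$cv_R,
               n_nonzero = m$n_nonzero, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#counts\tattempted=%d\tpredictable=%d\tretained=%d\tr_threshold=%s",
                     db$counts[["attempted"]], db$counts[["predictable"]],
                     db$counts[["retained"]], format(db$r_threshold)), con)
  if (is.null(tab)) {
    writeLines(paste(c("layer", "feature_id", "chrom", "start", "end",
                       "variant_id", "pos", "effect_allele", "other_allele",
                       "weight", "cv_R", "n_nonzero"), collapse = "\t"), con)
  } else {
    tab <- tab[order(tab$layer, tab$feature_id, tab$chrom, tab$pos), ]
    writeLines(paste(colnames(tab), collapse = "\t"), con)
    writeLines(do.call(paste, c(lapply(tab, function(x)
      if (is.numeric(x)) formatC(x, format = "g", digits = 15) else x),
      sep = "\t")), con)
  }
  invisible(path)
}

#' Read a weight database from TSV
#'
#' Inverse of [write_weight_db()]; duplicated (feature, variant) rows raise
#' an error.
#'
#' @param path TSV path.
#' @return A `weight_db`.
#' @export
read_weight_db <- function(path) {
  first <- readLines(path, n = 1L)
  counts <- c(attempted = NA_integer_, predictable = NA_integer_,
              retained = NA_integer_)
  r_threshold <- 0.1
  has_header_comment <- startsWith(first, "#counts")
  if (has_header_comment) {
    kv <- strsplit(strsplit(first, "\t")[[1L]][-1L], "=", fixed = TRUE)
    for (pair in kv) {
      if (pair[1L] == "r_threshold") r_threshold <- as.numeric(pair[2L])
      else counts[pair[1L]] <- as.integer(pair[2L])
    }
  }
  tab <- read.delim(path, skip = if (has_header_comment) 1L else 0L,
                    stringsAsFactors = FALSE)
  if (nrow(tab) > 0L &&
      anyDuplicated(tab[, c("feature_id", "variant_id")]) > 0L)
    stop("duplicated (feature, variant) rows in weight database")
  models <- list()
  keys <- if (nrow(tab) == 0L) character(0) else
    unique(paste0(tab$layer, ":", tab$feature_id))
  for (key in keys) {
    sub <- tab[paste0(tab$layer, ":", tab$feature_id) == key, , drop = FALSE]
    anchor <- data.frame(chrom = sub$chrom[1L], start = sub$start[1L],
                         end = sub$end[1L], stringsAsFactors = FALSE)
    models[[key]] <- weight_model(
      sub$feature_id[1L], sub$layer[1L], anchor,
      data.frame(id = sub$variant_id, pos = sub$pos,
                 effect_allele = sub$effect_allele,
                 other_allele = sub$other_allele, weight = sub$weight,
                 stringsAsFactors = FALSE),
      cv_R = sub$cv_R[1L])
  }
  if (is.na(counts[["attempted"]])) counts[["attempted"]] <- length(models)
  if (is.na(counts[["predictable"]])) counts[["predictable"]] <- length(models)
  if (is.na(counts[["retained"]])) counts[["retained"]] <- length(models)
  structure(list(models = models, counts = counts,
                 r_threshold = r_threshold),
            class = "weight_db")
}

#' Write a phenotype matrix as TSV
#'
#' Feature rows with anchor columns `feature_id`, `chrom`, `start`, `end`,
#' `strand` followed by one column per sample.
#'
#' @param m A [pheno_matrix()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_pheno_tsv <- function(m, path) {
  stopifnot(inherits(m, "pheno_matrix"))
  tab <- cbind(m$anchors, as.data.frame(m$values))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phenotype matrix from TSV
#'
#' @param path TSV from [write_pheno_tsv()].
#' @param layer Molecular layer of the stored values.
#' @return A [pheno_matrix()].
#' @export
read_pheno_tsv <- function(path, layer) {
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  anchor_cols <- c("feature_id", "chrom", "start", "end", "strand")
  missing_cols <- setdiff(anchor_cols, names(tab))
  if (length(missing_cols) > 0L)
    stop("phenotype file lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  vals <- as.matrix(tab[, setdiff(names(tab), anchor_cols), drop = FALSE])
  rownames(vals) <- tab$feature_id
  pheno_matrix(vals, tab[, anchor_cols], layer)
}

#' Pipeline configuration
#'
#' Validated bundle of file paths and thresholds driving
#' [twas_pipeline()]; round-trips through YAML unchanged.
#'
#' @param panel_vcf,phenotype_tsv,covariates_tsv,gwas_tsv Input paths
#'   (`phenotype_tsv` a named list per layer); `NULL` entries allowed for
#'   in-memory use.
#' @param maf,hwe_p,missing,impute_r2 QC thresholds.
#' @param cis_window Cis half-width in bp.
#' @param alpha Elastic-net mixing parameter.
#' @param folds CV folds.
#' @param r_threshold Weight-database retention threshold.
#' @param max_perm Permutation cap.
#' @param seed Integer seed.
#' @param layers Layers to run.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(panel_vcf = NULL, phenotype_tsv = NULL,
                            covariates_tsv = NULL, gwas_tsv = NULL,
                            maf = 0.05, hwe_p = 1e-4, missing = 0.05,
                            impute_r2 = 0.8, cis_window = 5e5, alpha = 0.5,
                            folds = 5L, r_threshold = 0.1, max_perm = 1000L,
                            seed = 1L,
                            layers = c("expression", "apa", "junction")) {
  stopifnot(maf >= 0, maf <= 0.5, hwe_p >= 0, hwe_p <= 1,
            missing >= 0, missing <= 1, impute_r2 >= 0, impute_r2 <= 1,
            cis_window > 0, alpha >= 0, alpha <= 1, folds >= 2,
            max_perm >= 1)
  layers <- match.arg(layers, several.ok = TRUE)
  structure(list(panel_vcf = panel_vcf, phenotype_tsv = phenotype_tsv,
                 covariates_tsv = covariates_tsv, gwas_tsv = gwas_tsv,
                 maf = maf, hwe_p = hwe_p, missing = missing,
                 impute_r2 = impute_r2, cis_window = cis_window,
                 alpha = alpha, folds = as.integer(folds),
                 r_threshold = r_threshold, max_perm = as.integer(max_perm),
                 seed = as.integer(seed), layers = layers),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path YAML path.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}
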