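# Synthetic cohort generator: LD-structured genotypes, cis-regulated
# molecular phenotypes (expression / APA / junction) and case-control GWAS
# summary statistics with known ground truth.

#' Simulation configuration
#'
#' Collects every knob of the synthetic cohort in one validated list. The
#' defaults mirror the study design the pipeline targets: a reference panel
#' of 150 individuals with RNA-derived molecular phenotypes, a much larger
#' case-control GWAS cohort (case fraction 0.449, the cases/(cases+controls)
#' ratio of the target consortium), and moderate cis heritability.
#'
#' @param n_ref_samples Reference-panel sample size (phenotyped + genotyped).
#' @param n_gwas_samples GWAS cohort sample size.
#' @param n_variants Number of biallelic variants on the synthetic chromosome.
#' @param chrom_length Chromosome length in bp; feature anchors are spaced
#'   uniformly along it (default 1 feature per Mb when
#'   `n_features = chrom_length / 1e6`).
#' @param maf_range Range the per-variant minor allele frequency is drawn
#'   from, within (0, 0.5].
#' @param ld_rho AR(1) correlation of adjacent latent haplotype scores in
#'   `[0, 1)`; genotype LD decays as `ld_rho^k` with variant distance `k`.
#' @param n_features Number of molecular features per layer.
#' @param cis_h2 Target cis heritability of each feature's latent level,
#'   in `[0, 1)`.
#' @param n_causal_per_feature Causal cis variants per feature.
#' @param feature_effect_var Liability-variance fraction contributed by one
#'   causal feature in the GWAS trait model.
#' @param case_fraction Fraction of GWAS samples that are cases, in (0, 1).
#' @param covar_frac Variance fraction of the latent feature level explained
#'   by shared covariates (age + batch), in `[0, 1)`.
#' @param missing_rate Genotype missingness injected uniformly at random.
#' @param read_depth Mean per-sample read depth for APA/junction counts.
#' @param cis_window Cis window half-width in bp around a feature anchor.
#' @param seed Integer seed; identical configs give bit-identical cohorts.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_ref_samples = 150L,
                       n_gwas_samples = 5000L,
                       n_variants = 500L,
                       chrom_length = 5e6,
                       maf_range = c(0.05, 0.5),
                       ld_rho = 0.6,
                       n_features = 5L,
                       cis_h2 = 0.3,
                       n_causal_per_feature = 1L,
                       feature_effect_var = 0.01,
                       case_fraction = 0.449,
                       covar_frac = 0.1,
                       missing_rate = 0,
                       read_depth = 60,
                       cis_window = 5e5,
                       seed = 1L) {
  cfg <- list(n_ref_samples = as.integer(n_ref_samples),
              n_gwas_samples = as.integer(n_gwas_samples),
              n_variants = as.integer(n_variants),
              chrom_length = chrom_length,
              maf_range = maf_range, ld_rho = ld_rho,
              n_features = as.integer(n_features),
              cis_h2 = cis_h2,
              n_causal_per_feature = as.integer(n_causal_per_feature),
              feature_effect_var = feature_effect_var,
              case_fraction = case_fraction,
              covar_frac = covar_frac,
              missing_rate = missing_rate,
              read_depth = read_depth,
              cis_window = cis_window,
              seed = as.integer(seed))
  if (cfg$n_variants <= 0L) stop("configuration error: n_variants must be positive")
  if (length(maf_range) != 2L || maf_range[1L] <= 0 || maf_range[2L] > 0.5 ||
      maf_range[1L] > maf_range[2L])
    stop("configuration error: maf_range must lie within (0, 0.5]")
  if (ld_rho < 0 || ld_rho >= 1) stop("configuration error: ld_rho must lie in [0, 1)")
  if (cis_h2 < 0 || cis_h2 >= 1) stop("configuration error: cis_h2 must lie in [0, 1)")
  if (covar_frac < 0 || cis_h2 + covar_frac >= 1)
    stop("configuration error: cis_h2 + covar_frac must stay below 1")
  if (case_fraction <= 0 || case_fraction >= 1)
    stop("configuration error: case_fraction must lie in (0, 1)")
  if (feature_effect_var < 0 || feature_effect_var >= 1)
    stop("configuration error: feature_effect_var must lie in [0, 1)")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("configuration error: missing_rate must lie in [0, 1)")
  if (cfg$n_ref_samples < 2L || cfg$n_gwas_samples < 2L)
    stop("configuration error: sample sizes must be at least 2")
  class(cfg) <- "sim_config"
  cfg
}

# Variant map shared by the reference and GWAS cohorts: positions, allele
# frequencies and non-ambiguous allele pairs, all derived from config$seed.
variant_map <- function(config) {
  with_seed(config$seed, {
    pos <- sort(sample.int(config$chrom_length, config$n_variants))
    eaf <- runif(config$n_variants, config$maf_range[1L], config$maf_range[2L])
    ref <- sample(c("A", "C", "G", "T"), config$n_variants, replace = TRUE)
    # partner alleles chosen so no pair is strand-ambiguous (A/T or C/G)
    partner <- list(A = c("C", "G"), C = c("A", "T"),
                    G = c("A", "T"), T = c("C", "G"))
    alt <- vapply(ref, function(r) sample(partner[[r]], 1L), character(1L))
    data.frame(id = sprintf("rs%06d", seq_len(config$n_variants)),
               chrom = "chr1", pos = pos, ref = ref, alt = unname(alt),
               r2 = 1, multiallelic = FALSE, eaf = eaf,
               stringsAsFactors = FALSE)
  })
}

# run expr with a temporary RNG state seeded at `seed`
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate LD-structured diploid genotypes
#'
#' Draws two haplotypes per sample from a Gaussian-copula AR(1) latent
#' process and thresholds each latent score at the allele-frequency quantile,
#' so genotypes are in Hardy-Weinberg proportions at the drawn frequency and
#' adjacent-variant correlation decays geometrically with `ld_rho`.
#' The variant map (positions, frequencies, alleles) depends only on the
#' config seed, so the `reference` and `gwas` cohorts share their variants.
#'
#' @param config A [sim_config()].
#' @param cohort `"reference"` (size `n_ref_samples`) or `"gwas"`
#'   (size `n_gwas_samples`).
#' @return A list with elements `geno` (a [genotype_matrix()]) and `truth`
#'   (data frame of per-variant true effect-allele frequencies).
#' @export
simulate_ld_genotypes <- function(config, cohort = c("reference", "gwas")) {
  stopifnot(inherits(config, "sim_config"))
  cohort <- match.arg(cohort)
  vm <- variant_map(config)
  n <- if (cohort == "reference") config$n_ref_samples else config$n_gwas_samples
  seed <- config$seed + if (cohort == "reference") 11L else 12L
  m <- config$n_variants
  dosage <- with_seed(seed, {
    rho <- config$ld_rho
    z <- matrix(0, nrow = 2L * n, ncol = m)
    z[, 1L] <- rnorm(2L * n)
    if (m > 1L) {
      innov_sd <- sqrt(1 - rho^2)
      for (j in 2:m) z[, j] <- rho * z[, j - 1L] + innov_sd * rnorm(2L * n)
    }
    thr <- qnorm(vm$eaf)
    hap <- sweep(z, 2L, thr, `<`) * 1
    d <- hap[seq_len(n), , drop = FALSE] + hap[n + seq_len(n), , drop = FALSE]
    if (config$missing_rate > 0) {
      drop_idx <- which(runif(length(d)) < config$missing_rate)
      d[drop_idx] <- NA_real_
    }
    d
  })
  rownames(dosage) <- sprintf("%s_%04d", substr(cohort, 1L, 3L), seq_len(n))
  colnames(dosage) <- vm$id
  list(geno = genotype_matrix(dosage, vm[, c("id", "chrom", "pos", "ref",
                                             "alt", "r2", "multiallelic")]),
       truth = vm[, c("id", "eaf")])
}

#' Simulate shared sample covariates
#'
#' Age (years) and a two-level batch label, reproducible from the config
#' seed. The same covariates feed every phenotype layer of a cohort.
#'
#' @param config A [sim_config()].
#' @param n_samples Number of samples (defaults to the reference panel size).
#' @return Data frame with columns `age` and `batch` (0/1).
#' @export
simulate_covariates <- function(config, n_samples = config$n_ref_samples) {
  with_seed(config$seed + 31L, {
    data.frame(age = round(rnorm(n_samples, mean = 50, sd = 10), 1L),
               batch = rbinom(n_samples, 1L, 0.5))
  })
}

#' Simulate cis-regulated molecular phenotypes
#'
#' Each feature's latent level is `sqrt(cis_h2) * g + sqrt(covar_frac) * c +
#' noise`, with `g` the standardized genetic value of its causal cis variants
#' and `c` a standardized covariate score; the noise variance completes the
#' unit total so the genetic fraction equals `cis_h2` in expectation.
#' Expression is reported on a TPM-like positive scale (`2^(latent + 5)`);
#' APA and junction layers convert the latent level to a distal/inclusion
#' fraction through a logistic link and draw proximal/distal
#' (exclusion/inclusion) read counts, reporting PDUI respectively PSI;
#' samples whose total count falls below `min_depth` are set missing.
#'
#' @param geno_sim Output of [simulate_ld_genotypes()] (list with `geno`).
#' @param config A [sim_config()].
#' @param layer `"expression"`, `"apa"` or `"junction"`.
#' @param covariates Data frame from [simulate_covariates()]; generated from
#'   the config when `NULL`.
#' @param min_depth Minimum total read count for a ratio value (APA and
#'   junction layers).
#' @return List with `pheno` (a [pheno_matrix()]), `truth` (per-feature
#'   causal variants, effects and realized cis heritability, plus the
#'   centering used for genetic values) and `covariates`.
#' @export
simulate_molecular_phenotypes <- function(geno_sim, config,
                                          layer = c("expression", "apa",
                                                    "junction"),
                                          covariates = NULL,
                                          min_depth = 10) {
  stopifnot(inherits(config, "sim_config"))
  layer <- match.arg(layer)
  geno <- if (inherits(geno_sim, "genotype_matrix")) geno_sim else geno_sim$geno
  n <- nrow(geno$dosage)
  if (is.null(covariates)) covariates <- simulate_covariates(config, n)
  spacing <- config$chrom_length / config$n_features
  anchor_pos <- pmax(1L, round((seq_len(config$n_features) - 0.5) * spacing))
  prefix <- switch(layer, expression = "gene", apa = "apa", junction = "jx")
  anchors <- data.frame(feature_id = sprintf("%s_%03d", prefix,
                                             seq_len(config$n_features)),
                        chrom = "chr1", start = anchor_pos, end = anchor_pos,
                        strand = "+", stringsAsFactors = FALSE)
  layer_seed <- config$seed + switch(layer, expression = 41L, apa = 42L,
                                     junction = 43L)
  cov_score <- scale_vec(scale_vec(covariates$age) + covariates$batch)
  dos <- impute_col_means(geno$dosage)

  out <- with_seed(layer_seed, {
    values <- matrix(NA_real_, nrow = config$n_features, ncol = n)
    causal_list <- vector("list", config$n_features)
    truth_feat <- cbind(anchors, layer = layer, realized_h2 = NA_real_,
                        g_center = 0, g_scale = 1)
    keep <- rep(TRUE, config$n_features)
    for (f in seq_len(config$n_features)) {
      win <- cis_window_bounds(anchors$start[f], anchors$end[f],
                               config$cis_window)
      cis <- which(geno$variants$pos >= win[1L] & geno$variants$pos <= win[2L])
      if (length(cis) == 0L) {
        warning("feature ", anchors$feature_id[f],
                " has an empty cis window; skipped")
        keep[f] <- FALSE
        next
      }
      ncausal <- min(config$n_causal_per_feature, length(cis))
      causal <- sort(sample(cis, ncausal))
      b <- rnorm(ncausal)
      g <- drop(dos[, causal, drop = FALSE] %*% b)
      g_center <- mean(g); g_scale <- sd(g)
      g_std <- if (config$cis_h2 > 0 && g_scale > 0)
        (g - g_center) / g_scale else rep(0, n)
      if (g_scale == 0) { g_center <- 0; g_scale <- 1 }
      gen_part <- sqrt(config$cis_h2) * g_std
      noise_sd <- sqrt(1 - config$cis_h2 - config$covar_frac)
      y <- gen_part + sqrt(config$covar_frac) * cov_score +
        rnorm(n, sd = noise_sd)
      truth_feat$realized_h2[f] <- var(gen_part) / var(y)
      truth_feat$g_center[f] <- g_center
      truth_feat$g_scale[f] <- g_scale
      causal_list[[f]] <- data.frame(feature_id = anchors$feature_id[f],
                                     variant_id = geno$variants$id[causal],
                                     effect = b, stringsAsFactors = FALSE)
      values[f, ] <- if (layer == "expression") {
        2^(y + 5)
      } else {
        frac <- plogis(1.5 * y)
        total <- rpois(n, config$read_depth)
        num <- rbinom(n, total, frac)
        v <- ifelse(total >= min_depth, num / total, NA_real_)
        v
      }
    }
    list(values = values[keep, , drop = FALSE],
         anchors = anchors[keep, , drop = FALSE],
         truth_feat = truth_feat[keep, , drop = FALSE],
         causals = do.call(rbind, causal_list[keep]))
  })
  colnames(out$values) <- rownames(geno$dosage)
  list(pheno = pheno_matrix(out$values, out$anchors, layer),
       truth = list(features = out$truth_feat, causals = out$causals),
       covariates = covariates)
}

scale_vec <- function(x) {
  s <- sd(x)
  if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
}

#' Standardized genetic value of a feature in any cohort
#'
#' Applies the truth's causal effects to a genotype matrix and standardizes
#' with the centering recorded at phenotype simulation time, so the value is
#' on the same scale in the reference and GWAS cohorts.
#'
#' @param truth Truth list from [simulate_molecular_phenotypes()].
#' @param feature_id Feature to score.
#' @param geno A [genotype_matrix()].
#' @return Numeric vector, one genetic value per sample.
#' @export
true_genetic_value <- function(truth, feature_id, geno) {
  ft <- truth$features[truth$features$feature_id == feature_id, , drop = FALSE]
  if (nrow(ft) != 1L) stop("unknown feature: ", feature_id)
  ca <- truth$causals[truth$causals$feature_id == feature_id, , drop = FALSE]
  X <- impute_col_means(
    geno$dosage[, match(ca$variant_id, geno$variants$id), drop = FALSE])
  (drop(X %*% ca$effect) - ft$g_center) / ft$g_scale
}

#' Simulate GWAS summary statistics with mediated risk
#'
#' Builds a liability as the sum of chosen features' standardized genetic
#' values times their liability effects plus Gaussian environment noise,
#' dichotomizes at the case-fraction threshold, and computes per-variant
#' marginal association statistics: logistic regression of case status on
#' dosage (default) or linear regression on the continuous liability
#' (`method = "linear"`, exact at any sample size, used for oracle
#' comparisons).
#'
#' @param geno_sim Output of [simulate_ld_genotypes()] for the GWAS cohort
#'   (or a bare [genotype_matrix()]).
#' @param truth Truth list from [simulate_molecular_phenotypes()] (may be
#'   `NULL` when `alpha` is `NULL`).
#' @param config A [sim_config()].
#' @param alpha Named vector of per-feature liability effects (per standard
#'   deviation of genetic value); `NULL` or empty means a fully null trait.
#' @param method `"logistic"` or `"linear"`.
#' @return A `gwas_sumstats` data frame (one row per variant: `variant_id`,
#'   `chrom`, `pos`, `effect_allele`, `other_allele`, `eaf`, `beta`, `se`,
#'   `p`, `n`) with the individual-level phenotype attached as attribute
#'   `"phenotype"` (list with `liability` and `case`).
#' @export
simulate_gwas_sumstats <- function(geno_sim, truth = NULL, config,
                                   alpha = NULL,
                                   method = c("logistic", "linear")) {
  stopifnot(inherits(config, "sim_config"))
  method <- match.arg(method)
  geno <- if (inherits(geno_sim, "genotype_matrix")) geno_sim else geno_sim$geno
  n <- nrow(geno$dosage)
  if (!is.null(alpha) && length(alpha) > 0L && is.null(names(alpha)))
    stop("alpha must be a named vector of feature liability effects")
  with_seed(config$seed + 51L, {
    gsum <- rep(0, n)
    tot_var <- 0
    if (!is.null(alpha)) {
      alpha <- alpha[alpha != 0]
      for (f in names(alpha)) {
        gsum <- gsum + alpha[[f]] * true_genetic_value(truth, f, geno)
        tot_var <- tot_var + alpha[[f]]^2
      }
    }
    env_sd <- sqrt(max(1 - tot_var, 0.05))
    liability <- gsum + rnorm(n, sd = env_sd)
    case <- as.integer(liability > quantile(liability, 1 - config$case_fraction))
    if (all(case == 1L) || all(case == 0L))
      stop("degenerate phenotype: all cases or all controls")
    y <- if (method == "linear") liability else case
    stats <- marginal_assoc(geno, y, logistic = (method == "logistic"))
    attr(stats, "phenotype") <- list(liability = liability, case = case)
    stats
  })
}

# per-variant marginal regression of y on dosage (with intercept)
marginal_assoc <- function(geno, y, logistic) {
  dos <- geno$dosage
  m <- ncol(dos)
  n_obs <- colSums(!is.na(dos))
  eaf <- colMeans(dos, na.rm = TRUE) / 2
  beta <- se <- rep(NA_real_, m)
  if (logistic) {
    for (j in seq_len(m)) {
      x <- dos[, j]
      ok <- !is.na(x)
      xj <- x[ok]; yj <- y[ok]
      if (var(xj) == 0) { beta[j] <- 0; next }
      fit <- suppressWarnings(
        glm.fit(cbind(1, xj), yj, family = binomial()))
      r <- fit$rank
      cov_unscaled <- chol2inv(fit$qr$qr[seq_len(r), seq_len(r), drop = FALSE])
      beta[j] <- fit$coefficients[2L]
      se[j] <- sqrt(cov_unscaled[2L, 2L])
    }
  } else {
    # closed-form simple linear regression, vectorized over variants
    for (j in seq_len(m)) {
      x <- dos[, j]
      ok <- !is.na(x)
      xj <- x[ok] - mean(x[ok]); yj <- y[ok] - mean(y[ok])
      sxx <- sum(xj^2)
      if (sxx == 0) { beta[j] <- 0; next }
      b <- sum(xj * yj) / sxx
      s2 <- (sum(yj^2) - b * sum(xj * yj)) / (length(xj) - 2L)
      beta[j] <- b
      se[j] <- sqrt(s2 / sxx)
    }
  }
  z <- beta / se
  out <- data.frame(variant_id = geno$variants$id,
                    chrom = geno$variants$chrom,
                    pos = geno$variants$pos,
                    effect_allele = geno$variants$alt,
                    other_allele = geno$variants$ref,
                    eaf = eaf, beta = beta, se = se,
                    p = 2 * pnorm(-abs(z)), n = n_obs,
                    stringsAsFactors = FALSE)
  class(out) <- c("gwas_sumstats", "data.frame")
  rownames(out) <- NULL
  out
}
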