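# Variant-level quality control and allele harmonization.

#' Per-variant allele statistics
#'
#' @param dosages Numeric vector of per-sample dosages in `[0, 2]`
#'   (`NA` = missing).
#' @return List with `alt_freq` (mean dosage / 2 over non-missing samples),
#'   `maf`, `missing_rate`, and `genotype_counts` (`n_AA`, `n_Aa`, `n_aa`
#'   hard-call counts, counting only dosages within 0.1 of an integer).
#' @export
allele_stats <- function(dosages) {
  ok <- !is.na(dosages)
  if (!any(ok)) stop("all genotypes missing")
  d <- dosages[ok]
  alt_freq <- sum(d) / (2 * length(d))
  hard <- round(d)
  callable <- abs(d - hard) <= 0.1
  counts <- c(n_AA = sum(hard[callable] == 0),
              n_Aa = sum(hard[callable] == 1),
              n_aa = sum(hard[callable] == 2))
  list(alt_freq = alt_freq,
       maf = min(alt_freq, 1 - alt_freq),
       missing_rate = mean(!ok),
       genotype_counts = counts)
}

#' Hardy-Weinberg equilibrium test
#'
#' Exact test by full enumeration over heterozygote counts conditional on
#' the allele counts (two-sided: sums the probabilities of all tables no
#' more probable than the observed one), or the 1-df chi-square
#' goodness-of-fit test. Monomorphic variants return p = 1.
#'
#' @param genotype_counts Vector `(n_AA, n_Aa, n_aa)` of genotype counts.
#' @param method `"exact"` (default) or `"chisq"`.
#' @return The HWE p-value.
#' @export
hwe_test <- function(genotype_counts, method = c("exact", "chisq")) {
  method <- match.arg(method)
  cts <- as.numeric(genotype_counts)
  if (length(cts) != 3L || any(cts < 0)) stop("counts must be 3 non-negative values")
  n_aa <- cts[1L]; n_ab <- cts[2L]; n_bb <- cts[3L]
  n <- n_aa + n_ab + n_bb
  if (n == 0) stop("counts must be 3 non-negative values with positive total")
  n_a <- 2 * n_aa + n_ab
  n_b <- 2 * n_bb + n_ab
  if (n_a == 0 || n_b == 0) return(1)
  if (method == "chisq") {
    p <- n_a / (2 * n)
    e <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
    x2 <- sum((cts - e)^2 / e)
    return(pchisq(x2, df = 1L, lower.tail = FALSE))
  }
  # exact: enumerate heterozygote counts with the parity of the rare-allele
  # count; probabilities built by the standard ratio recurrence, then
  # normalized
  rare <- min(n_a, n_b)
  hets <- seq(rare %% 2, rare, by = 2)
  probs <- numeric(length(hets))
  mid_idx <- which.min(abs(hets - rare * (n_a + n_b - rare) / (n_a + n_b)))
  probs[mid_idx] <- 1
  if (mid_idx < length(hets)) {
    for (k in mid_idx:(length(hets) - 1L)) {
      h <- hets[k]
      hom_r <- (rare - h) / 2
      hom_c <- n - h - hom_r
      # P(h + 2) / P(h)
      probs[k + 1L] <- probs[k] * 4 * hom_r * hom_c / ((h + 2) * (h + 1))
    }
  }
  if (mid_idx > 1L) {
    for (k in mid_idx:2L) {
      h <- hets[k]
      hom_r <- (rare - h) / 2
      hom_c <- n - h - hom_r
      # P(h - 2) / P(h)
      probs[k - 1L] <- probs[k] * h * (h - 1) / (4 * (hom_r + 1) * (hom_c + 1))
    }
  }
  probs <- probs / sum(probs)
  p_obs <- probs[match(n_ab, hets)]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-9)]))
}

#' Variant quality-control filter
#'
#' Applies the standard model-building exclusions: minor allele frequency
#' below 5%, Hardy-Weinberg exact p below 1e-4, missing genotyping rate
#' above 5%, imputation quality r2 below 0.8 (when recorded), multi-allelic
#' records, and strand-ambiguous allele pairs (A/T or C/G). All printed
#' inequalities are strict, so a variant sitting exactly on a threshold
#' passes. Non-integral dosages more than 0.1 from a hard call are ignored
#' for the HWE test only.
#'
#' @param panel A [genotype_matrix()].
#' @param maf,hwe_p,missing,impute_r2 Thresholds (defaults 0.05, 1e-4,
#'   0.05, 0.8).
#' @param hwe_method Passed to [hwe_test()].
#' @return List with `geno` (retained variants) and `report` (a `qc_report`:
#'   one row per excluded variant with comma-joined reasons, plus per-reason
#'   counts).
#' @export
qc_filter <- function(panel, maf = 0.05, hwe_p = 1e-4, missing = 0.05,
                      impute_r2 = 0.8, hwe_method = "exact") {
  stopifnot(inherits(panel, "genotype_matrix"))
  if (nrow(panel$variants) == 0L) stop("empty genotype panel")
  v <- panel$variants
  m <- nrow(v)
  reasons <- vector("list", m)
  ambiguous_pair <- function(a, b) {
    (a == "A" & b == "T") | (a == "T" & b == "A") |
      (a == "C" & b == "G") | (a == "G" & b == "C")
  }
  for (j in seq_len(m)) {
    r <- character(0)
    if (isTRUE(v$multiallelic[j]) || grepl(",", v$alt[j], fixed = TRUE))
      r <- c(r, "multiallelic")
    if (ambiguous_pair(v$ref[j], v$alt[j])) r <- c(r, "ambiguous")
    st <- allele_stats(panel$dosage[, j])
    if (st$maf < maf) r <- c(r, "maf")
    if (st$missing_rate > missing) r <- c(r, "missing")
    if (!("multiallelic" %in% r) && sum(st$genotype_counts) > 0 &&
        hwe_test(st$genotype_counts, method = hwe_method) < hwe_p)
      r <- c(r, "hwe")
    if (!is.na(v$r2[j]) && v$r2[j] < impute_r2) r <- c(r, "imputation")
    reasons[[j]] <- r
  }
  failed <- lengths(reasons) > 0L
  report <- structure(
    list(excluded = data.frame(
           variant_id = v$id[failed],
           reasons = vapply(reasons[failed], paste, character(1L),
                            collapse = ","),
           stringsAsFactors = FALSE),
         counts = table(factor(unlist(reasons),
                               levels = c("maf", "hwe", "missing",
                                          "imputation", "multiallelic",
                                          "ambiguous"))),
         n_input = m, n_retained = sum(!failed)),
    class = "qc_report")
  if (all(failed)) warning("no variants retained by QC")
  list(geno = genotype_matrix(panel$dosage[, !failed, drop = FALSE],
                              v[!failed, , drop = FALSE]),
       report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("qc_report: ", x$n_retained, " of ", x$n_input,
      " variants retained\n", sep = "")
  cts <- x$counts[x$counts > 0]
  if (length(cts) > 0)
    cat("  exclusions: ",
        paste(sprintf("%s=%d", names(cts), as.integer(cts)), collapse = ", "),
        "\n", sep = "")
  invisible(x)
}

#' Harmonize GWAS summary statistics to model effect alleles
#'
#' Aligns each GWAS record to the prediction model's effect allele: matching
#' alleles pass unchanged; swapped effect/other alleles get their beta
#' negated and EAF complemented; strand-ambiguous (A/T, C/G) or incompatible
#' allele pairs are dropped and reported.
#'
#' @param model_variants Data frame with columns `id` (or `variant_id`),
#'   `effect_allele`, `other_allele` — the weight-model side.
#' @param stats A `gwas_sumstats` data frame.
#' @return List with `stats` (harmonized rows for matched variants, effect
#'   allele set to the model's) and `dropped` (data frame of
#'   `variant_id` + `reason`: `ambiguous`, `mismatch` or `absent`).
#' @export
harmonize_alleles <- function(model_variants, stats) {
  mv <- model_variants
  if (is.null(mv$id) && !is.null(mv$variant_id)) mv$id <- mv$variant_id
  if (anyDuplicated(mv$id)) stop("duplicate variant ids in model variants")
  if (anyDuplicated(stats$variant_id)) stop("duplicate variant ids in GWAS stats")
  idx <- match(mv$id, stats$variant_id)
  dropped <- data.frame(variant_id = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  add_drop <- function(ids, why) {
    rbind(dropped, data.frame(variant_id = ids, reason = why,
                              stringsAsFactors = FALSE))
  }
  absent <- is.na(idx)
  if (any(absent)) dropped <- add_drop(mv$id[absent], "absent")
  mv2 <- mv[!absent, , drop = FALSE]
  st <- stats[idx[!absent], , drop = FALSE]
  ambig <- paste0(mv2$effect_allele, mv2$other_allele) %in%
    c("AT", "TA", "CG", "GC")
  same <- st$effect_allele == mv2$effect_allele &
    st$other_allele == mv2$other_allele
  swapped <- st$effect_allele == mv2$other_allele &
    st$other_allele == mv2$effect_allele
  mismatch <- !ambig & !same & !swapped
  if (any(ambig)) dropped <- add_drop(mv2$id[ambig], "ambiguous")
  if (any(mismatch)) dropped <- add_drop(mv2$id[mismatch], "mismatch")
  keep_swap <- swapped & !ambig
  st$beta[keep_swap] <- -st$beta[keep_swap]
  st$eaf[keep_swap] <- 1 - st$eaf[keep_swap]
  st$effect_allele[keep_swap] <- mv2$effect_allele[keep_swap]
  st$other_allele[keep_swap] <- mv2$other_allele[keep_swap]
  keep <- (same | swapped) & !ambig
  out <- st[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("gwas_sumstats", "data.frame")
  list(stats = out, dropped = dropped)
}
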