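# Shared fixture builders for the test suite. Everything is generated in
# code; no stored binary data.

# small genotype matrix from an explicit dosage matrix
make_geno <- function(dosage, pos = NULL, ref = NULL, alt = NULL, r2 = NA) {
  m <- ncol(dosage)
  if (is.null(colnames(dosage))) colnames(dosage) <- sprintf("v%02d", 1:m)
  if (is.null(rownames(dosage))) rownames(dosage) <- sprintf("s%03d", seq_len(nrow(dosage)))
  genotype_matrix(dosage, data.frame(
    id = colnames(dosage), chrom = "chr1",
    pos = if (is.null(pos)) seq(1000L, by = 1000L, length.out = m) else pos,
    ref = if (is.null(ref)) rep("A", m) else ref,
    alt = if (is.null(alt)) rep("G", m) else alt,
    r2 = r2, multiallelic = FALSE, stringsAsFactors = FALSE))
}

# phenotype matrix from an explicit value matrix; values may already be on
# a normalized (real-valued) scale, so bounds checks are bypassed
make_pheno <- function(values, layer = "expression", start = NULL) {
  k <- nrow(values)
  if (is.null(rownames(values))) rownames(values) <- sprintf("f%02d", 1:k)
  ph <- pheno_matrix(matrix(0, k, ncol(values),
                            dimnames = dimnames(values)),
                     data.frame(
    feature_id = rownames(values), chrom = "chr1",
    start = if (is.null(start)) seq(1e5L, by = 1e5L, length.out = k) else start,
    end = if (is.null(start)) seq(1e5L, by = 1e5L, length.out = k) else start,
    strand = "+", stringsAsFactors = FALSE), layer)
  ph$values <- values
  ph
}

# independent HWE oracle: direct conditional probability of each
# heterozygote count given the allele counts, via log-gamma arithmetic
# (separate code path from the package's ratio recurrence)
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  n_a <- 2 * n_AA + n_Aa
  n_b <- 2 * n_aa + n_Aa
  rare <- min(n_a, n_b)
  hets <- seq(rare %% 2, rare, by = 2)
  logp <- vapply(hets, function(h) {
    hom_r <- (rare - h) / 2
    hom_c <- n - h - hom_r
    lgamma(n + 1) - lgamma(hom_r + 1) - lgamma(h + 1) - lgamma(hom_c + 1) +
      h * log(2) + lgamma(n_a + 1) + lgamma(n_b + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[match(n_Aa, hets)]
  min(1, sum(p[p <= obs * (1 + 1e-9)]))
}

# zero-mean orthonormal design with X'X / n = I, for closed-form checks
orthonormal_design <- function(n, p, seed = 1) {
  set.seed(seed)
  M <- scale(matrix(rnorm(n * p), n, p), center = TRUE, scale = FALSE)
  qr.Q(qr(M)) * sqrt(n)
}

# minimal harmonized sumstats table
make_stats <- function(ids, beta, se, eaf = 0.3, pos = NULL,
                       effect = "G", other = "A", n = 1000L) {
  k <- length(ids)
  out <- data.frame(variant_id = ids, chrom = "chr1",
                    pos = if (is.null(pos)) seq(1000L, by = 1000L, length.out = k) else pos,
                    effect_allele = rep_len(effect, k),
                    other_allele = rep_len(other, k),
                    eaf = rep_len(eaf, k), beta = beta, se = se,
                    p = 2 * pnorm(-abs(beta / se)), n = n,
                    stringsAsFactors = FALSE)
  class(out) <- c("gwas_sumstats", "data.frame")
  out
}

# weight model over the given variant ids
make_model <- function(ids, weights, pos = NULL, feature = "gene_x",
                       anchor_pos = 1e5L, effect = "G", other = "A") {
  weight_model(feature, "expression",
               data.frame(chrom = "chr1", start = anchor_pos,
                          end = anchor_pos, stringsAsFactors = FALSE),
               data.frame(id = ids,
                          pos = if (is.null(pos)) seq(1000L, by = 1000L, length.out = length(ids)) else pos,
                          effect_allele = rep_len(effect, length(ids)),
                          other_allele = rep_len(other, length(ids)),
                          weight = weights, stringsAsFactors = FALSE),
               cv_R = 0.5)
}
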