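#!/usr/bin/env Rscript
# Regenerates inst/extdata/toy_panel_synthetic.vcf: a deterministic
# 100-sample, 12-variant panel in which six variants each trip exactly one
# QC filter (low MAF, HWE departure, missingness, low imputation r2,
# multi-allelic record, strand-ambiguous alleles) and six are clean.
library(sumtwas)

hwe_dosages <- function(n_AA, n_Aa, n_aa) {
  rep(c(0, 1, 2), times = c(n_AA, n_Aa, n_aa))
}
set.seed(20240501)
n <- 100L
clean <- function(maf) {
  q <- 1 - maf
  d <- hwe_dosages(round(n * q^2), n - round(n * q^2) - round(n * maf^2),
                   round(n * maf^2))
  sample(d)
}
dos <- cbind(
  v01 = clean(0.30), v02 = clean(0.25), v03 = clean(0.40),
  v04 = clean(0.20), v05 = clean(0.35), v06 = clean(0.45),
  v07_lowmaf  = sample(hwe_dosages(94, 6, 0)),          # MAF 3%
  v08_hwe     = sample(hwe_dosages(60, 20, 20)),        # het deficit
  v09_missing = clean(0.30),                            # 10% missing below
  v10_lowr2   = clean(0.25),                            # r2 = 0.7
  v11_multi   = clean(0.30),                            # ALT = G,T
  v12_ambig   = clean(0.25))                            # A/T alleles
dos[sample(n, 10L), "v09_missing"] <- NA
rownames(dos) <- sprintf("ind_%03d", seq_len(n))

variants <- data.frame(
  id = colnames(dos), chrom = "chr1",
  pos = seq(10000L, by = 5000L, length.out = 12L),
  ref = c("A", "C", "G", "T", "A", "C", "A", "G", "T", "C", "A", "A"),
  alt = c("G", "T", "A", "C", "C", "A", "G", "A", "G", "A", "G,T", "T"),
  r2 = c(rep(0.95, 9L), 0.7, 0.95, 0.95),
  multiallelic = FALSE, stringsAsFactors = FALSE)
geno <- genotype_matrix(dos, variants)
out <- file.path("inst", "extdata", "toy_panel_synthetic.vcf")
dir.create(dirname(out), recursive = TRUE, showWarnings = FALSE)
write_genotypes_vcf(geno, out)
cat("wrote", out, "\n")
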