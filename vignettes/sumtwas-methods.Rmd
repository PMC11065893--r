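---
title: "Methods: summary-statistics TWAS across three molecular layers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: summary-statistics TWAS across three molecular layers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

A transcriptome-wide association study (TWAS) asks whether the genetically
regulated component of a molecular phenotype is associated with a trait. The
workflow has two halves. On a reference panel with both genotypes and
molecular measurements, each feature $g$ gets a sparse linear cis prediction
model: weights $w_{lg}$ over the variants within $\pm 500$ kb of the
feature's anchor, fit by the elastic net. Against a trait GWAS known only
through per-variant summary statistics
$\hat\beta_l, \mathrm{se}(\hat\beta_l)$, the gene-level association is the
summary-based score

$$
Z_g \;=\; \sum_{l \in \mathrm{Model}_g}
w_{lg}\,\frac{\hat\sigma_l}{\hat\sigma_g}\,
\frac{\hat\beta_l}{\mathrm{se}(\hat\beta_l)},
\qquad
\hat\sigma_g^2 = w^\top \Gamma w,
$$

where $\Gamma$ is the reference-panel covariance of the model's dosages and
$\hat\sigma_l = \sqrt{\Gamma_{ll}}$. $Z_g$ approximates the z statistic of
regressing the trait on the predicted (genetically regulated) feature level
without ever touching individual-level GWAS data. Its assumptions: the
GWAS marginal effects are well calibrated, the panel LD matches the GWAS
cohort's, and alleles are coherently oriented between the weight models and
the summary statistics (the package enforces the last one mechanically via
`harmonize_alleles()`).

Three molecular layers run through identical machinery: gene expression
(TPM), 3' UTR alternative polyadenylation quantified as the distal polyA
usage index PDUI $= d/(p+d) \in [0,1]$, and exon-junction splicing
quantified as percent-spliced-in PSI $= i/(i+e) \in [0,1]$.

# Pipeline stages and their parameters

**Variant QC** (`qc_filter()`). Exclusions: minor allele frequency $<$ 5%,
Hardy–Weinberg exact-test p $< 10^{-4}$, missing rate $>$ 5%, imputation
$r^2 < 0.8$ when recorded, multi-allelic records, strand-ambiguous pairs
(A/T, C/G). All the printed inequalities are strict, so a variant exactly on
a boundary passes. The HWE test is the exact conditional enumeration over
heterozygote counts (two-sided, summing tables no more probable than the
observed one); a 1-df chi-square alternative is available. Dosages further
than 0.1 from an integer are ignored for the HWE count only.

**Phenotype preparation.** Expression: genes with TPM $> 0$ in at most 5% of
samples are dropped, then values become $\log_2(\mathrm{TPM}+1)$ — the
pseudocount of 1 keeps zeros at zero. Ratio layers: events missing in more
than 5% of samples are dropped; surviving missing values are median-imputed
per feature because the elastic net needs complete response vectors.
Quantile normalization uses the classic cross-sample rank-mean map (every
sample gets the identical sorted vector; ties get the average of tied rank
means), with a per-feature rank inverse-normal dialect behind a flag since
published processing pipelines differ on this point. Hidden structure is
captured by the top principal components of the feature-standardized matrix
— a deterministic surrogate for PEER factors, with the same sample-size
rule for the default count (15 below 150 samples, 30 at 150 or more) and
signs fixed by making each component's largest-magnitude loading positive.
Covariates (age, genetic PCs from `genotype_pcs()`, latent factors) are
removed by least-squares residualization *before* model fitting rather than
entering the penalized design; this keeps the weights purely genotypic,
which is what the association statistic assumes.

**Cis model training** (`train_cis_models()`). Elastic net with mixing
$\alpha = 0.5$, penalty chosen by inner 5-fold cross-validation over a
100-point log grid spanning four decades below the smallest all-zero
$\lambda$, taking the CV-MSE minimizer (a `lambda.1se` flag exists; the
minimizer is the default because the retention step below already guards
against overfit models). Dosage columns are standardized inside the solver
and weights are returned on the raw 0–2 dosage scale, so they apply
directly to any cohort's dosages. Performance is the Pearson correlation
between observed values and five-fold held-out *genetic scores* $Xw$; the
per-fold training intercept is deliberately omitted from the concatenated
predictions because it is constant within a fold and its between-fold
variation injects fold-mean noise that biases the null correlation
negative. Constant predictions score 0. Retention into the weight database
requires signed cross-validated $R > 0.1$ (strict) and at least one nonzero
weight; the database records the attempted / predictable / retained counts.

**Association scan** (`twas_scan()`). $\sigma_g$ is recomputed on the
intersection of model variants with the GWAS file; dropped variants are
counted and models losing more than half their absolute weight mass are
flagged rather than silently reported. Per layer, $m$ counts the models
actually tested (features skipped for zero overlap or zero variance are
excluded from $m$), and significance uses the exact threshold $0.05/m$.
Printed thresholds are truncated toward zero at two significant digits —
the conservative convention for quoting a cutoff (so $0.05/11426$ prints as
$4.3\times 10^{-6}$). No ridge is added to $\Gamma$ unless
$w^\top\Gamma w \le 0$ from floating-point noise, in which case $10^{-8}$
is added to the diagonal. Replication against a previously reported
direction uses the one-sided $p = \Phi(-Z_g \cdot \mathrm{dir})$ at the 5%
level.

**Conditional analysis** (`conditional_sumstats()`, `conditional_twas()`).
Using reference LD in place of genotypes, with $D_j = n\Gamma_{jj}$ and
$B = n\Gamma$: the conditioning set's joint effect is
$b_C = B_{CC}^{-1}(D_C \circ \hat\beta_C)$ and the target's conditional
effect is $\tilde\beta_t = \hat\beta_t - D_t^{-1} B_{tC}\, b_C$, with the
standard error from the residual-variance formula treating the phenotypic
variance as fixed (1 for a standardized trait; for a case-control GWAS the
same algebra runs on the log-odds scale, a documented approximation). Note
the $D_t$ denominator: the estimator equals the joint-OLS coefficient times
$1 - R^2_{t,C}$, so it matches individual-level joint regression when
target/conditioning LD is modest and shrinks toward zero — conservatively —
when the target is strongly tagged by the conditioning variant. Multi-variant
conditioning uses the joint formula, never sequential adjustment; a singular
conditioning block raises an error suggesting pruning. The default lead
variant is the GWAS-significant variant ($p < 5\times10^{-8}$) nearest the
feature within $\pm 500$ kb, ties broken by smaller p; when none qualifies
the feature is flagged "not conditioned" with its marginal result.

**Permutation test** (`permutation_test()`). Shuffles the weight-to-variant
assignment within a model (sign-flipping available behind a flag),
recomputes $|Z|$, and reports $(1 + \#\mathrm{exceedances})/(1 + n)$ with a
cap of 1000 permutations. Screening runs stop adaptively at 20 exceedances
— beyond that the p-value is already resolved well above any interesting
threshold — while calibration studies spend the full budget, because the
early-stop estimator has a resolution floor near 0.02 that coarsens exactly
the region a uniformity check examines. Models contributing fewer than 3
usable variants are reported "not evaluable"; features whose marginal
p is above 0.05 are recorded as skipped, mirroring the screening use of the
test.

# The synthetic cohort

`sim_config()` fixes the study conditions; the defaults mirror the design
this pipeline targets: a reference panel of 150 phenotyped individuals, a
case-control GWAS with case fraction 0.449, moderate cis heritability
(0.3), covariates explaining 10% of phenotype variance, and one causal cis
variant per feature. Genotypes come from a Gaussian-copula latent AR(1)
process per haplotype, thresholded at the allele-frequency quantile: this
yields Hardy–Weinberg genotypes at the drawn frequency with adjacent-variant
LD decaying geometrically in `ld_rho`, is reproducible bit-for-bit from the
seed, and is far simpler than haplotype resampling while giving the one LD
property the methods actually consume (a tunable decay). Molecular levels
are built on a latent unit-variance scale with the genetic fraction equal
to `cis_h2`, then mapped to each layer's observation scale: expression as
$2^{y+5}$ (TPM-like), APA and junction layers through a logistic link to a
distal/inclusion fraction with Poisson read totals (mean `read_depth`, 60)
and binomial counts, totals under `min_depth` (10 reads) set missing. The
GWAS trait is a liability: chosen features' standardized genetic values
times their effects plus Gaussian environment, dichotomized at the
case-fraction quantile; marginal statistics come from per-variant logistic
regression, or linear regression on the continuous liability when an exact
small-error oracle is wanted.

What the generator does **not** emulate: realistic human LD blocks and
recombination hotspots, admixture and population structure, imputation
error correlated with frequency, polygenic background beyond the chosen
causal features, and shared causal architecture between layers. Passing
calibration and recovery studies on this cohort therefore demonstrates the
statistical machinery is correct and calibrated under its own assumptions —
not that real-data results are reproduced.

# Validation studies and their problem sizes

The package ships its validation as callable studies (`benchmark_*`), run
by both the test suite and `scripts/acceptance.R`:

- *Equivalence*: 2000 samples, 50 features, panel = cohort, linear trait;
  summary-based $Z_g$ agrees with individual-level predicted-expression
  regression z to within 0.1 (observed: well below 0.01).
- *Conditional accuracy*: 20 scenarios at n = 2000 with the target and
  conditioning variants placed ~2 Mb apart (the low-LD regime where the
  $D_t$-denominator estimator is exact up to sampling noise); relative
  error under 2%.
- *Mediation*: 20 replicates each of a fully mediated gene (compact 500 kb
  locus, `ld_rho` 0.95 — full mediation presumes the model variants tightly
  tag the lead) and of a gene with an independent causal variant ~2 Mb from
  the lead.
- *Null calibration*: 1000 features, null case-control GWAS of 2000
  samples; fraction of TWAS p below 0.05 and a Kolmogorov–Smirnov
  uniformity check. With a 150-sample LD panel the Z variance carries a
  small finite-panel inflation of order $n_{\mathrm{ref}}/(n_{\mathrm{ref}}-2)$;
  at these sizes the p-value fraction stays inside [0.04, 0.06].
- *Permutation calibration*: 200 features with dense (25 variants/Mb) cis
  windows, full 1000 permutations per feature.
- *Recovery*: 50 replicate loci of 5 genes, the middle gene mediating a
  1%-of-liability effect; the causal gene should attain the locus-best
  $|Z|$ in at least 80% of replicates.

# Known limitations

The conditional standard error treats the phenotypic variance as fixed,
which understates uncertainty on the log-odds scale for strongly associated
conditioning variants; conditional z scores for case-control traits are
therefore approximate (their p-values remain useful for the
mediated-vs-independent distinction they serve). The latent-factor
surrogate removes linear hidden structure only, and with very few features
it can absorb genuine cis signal — it is intended for feature counts in the
hundreds or more. The weight database stores only nonzero weights, so a
model refit from file is equivalent for association but not for resuming
training. Finally, the AR(1) LD model makes long-range tagging decay
geometrically; methods sensitive to realistic LD block structure should be
evaluated on real panels.
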