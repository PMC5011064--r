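---
title: "Mapping adiposity-dependent regulatory variation in twin cohorts"
author: "twinGxE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping adiposity-dependent regulatory variation in twin cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinGxE)
```

# The scientific problem

Adiposity, usually measured as body mass index (BMI, kg/m²), reshapes
gene expression in peripheral tissues, and some regulatory variants act
differently depending on how much adipose tissue a person carries. A
genotype-by-BMI (G × BMI) interaction on expression shows up as a change
in the slope of the expression–BMI relationship across genotype classes
— in the clearest cases the two homozygote classes have slopes of
opposite sign. twinGxE implements the full analysis path for mapping
such context-specific eQTLs in a twin-structured RNA-seq cohort: exon
quantification and normalization, twin-aware phenotype association,
latent-factor confounder correction, cis and trans interaction scans
with an empirical FDR, and the downstream statistics used to interpret
hits (π1 sharing, Sobel mediation, colocalization with GWAS signals).

Because the motivating data (adipose biopsies from an adult female twin
registry) are access-controlled, the package ships a synthetic
twin-cohort generator with planted effects. Every claim the test suite
makes is a claim about what the methods recover from data whose truth
is known by construction.

# Models

## Quantification

All overlapping annotated exons of a gene are merged into *meta-exons*
(`mergeMetaExons()`, interval union via `GenomicRanges::reduce`); the
meta-exon is the quantification unit throughout. Counts are scaled to
the cohort's median well-mapped read count (`normalizeDepth()`), rows
quantified in at most 90% of individuals are dropped
(`filterExpressed()`; the "more than 90%" rule is a strict inequality),
and each meta-exon is rank-based inverse-normal transformed
(`inverseNormalTransform()`): values map to `qnorm((rank - 0.5)/n)`
with average ranks for ties (rankit offset; Blom available via
`offset = "blom"`). Internal coordinates are 1-based inclusive (GTF
convention); BED I/O converts to 0-based half-open at the boundary.

## Twin-aware phenotype association (the direct effect of adiposity)

`fitLmmLrt()` fits, per meta-exon,

$$y \sim X\beta + Zu + \varepsilon$$

with fixed effects phenotype, centered age, age², and technical
covariates (mean GC content, insert-size mode), and random intercepts
for *family* and *zygosity* (plus, optionally, primer index and batch).
Family codes are shared by co-twins; zygosity codes are shared only
within monozygotic pairs, so the zygosity variance component captures
the excess resemblance of MZ over DZ co-twins. The phenotype effect is
tested by a one-degree-of-freedom likelihood-ratio test against
χ²₁, with both models fitted by maximum likelihood (REML likelihoods
are not comparable across fixed-effect specifications). Grouping
factors in which every level is a singleton are dropped — they carry no
shared variance and are unidentifiable as random intercepts; with no
groupings left, the fit reduces exactly to the nested OLS LRT.

`transcriptomeScan()` reuses the fitted model structure and refits per
exon (`lme4::refit`), which makes transcriptome scale practical. Warm
starting occasionally strands one of the two models on a poor optimum;
the scan guards against this by comparing the LRT with the Wald
chi-square of the phenotype coefficient and refitting both models from
scratch when they disagree grossly, keeping the higher likelihood.
Q-values are computed per scan and a gene is called associated when at
least one of its meta-exons has q ≤ 0.05.

## Latent-factor correction

`estimateLatentFactors()` extracts k factors (default 50) from the
truncated SVD of the feature-standardized residual matrix, after family
structure and known technical covariates have been removed. This is a
deliberate design choice: the pipeline contract is "k latent factors
capturing broad expression variance", for which the truncated SVD is
the transparent, deterministic estimator; Bayesian latent-factor
machinery would add posterior inference the downstream steps never
consume. Factor scores are orthogonal, ordered by variance explained,
and sign-fixed (largest-magnitude loading positive). Per-factor
correlations with the phenotype are reported because adiposity itself
is a broad driver of expression: in practice several leading factors
correlate with BMI, and `residualize()` can either keep them in the
design or exclude factors whose |r| with the phenotype exceeds a
threshold (`excludeCorrThreshold`) to limit collinearity with the
interaction term being tested. Both modes are exposed; neither is
asserted to be the uniquely correct choice.

Family structure is removed by `familyResiduals()`: per feature, the
one-way ANOVA moment estimator of the family (then zygosity) variance
yields best-linear-unbiased-predicted group means, which are
subtracted. Unlike fixed-effect family regression, the shrinkage keeps
most of the between-family genotype contrast — essential in a twin
cohort where MZ co-twins carry identical genotypes and a fixed family
effect would absorb the entire cis signal. The price is a known, mild
attenuation of coefficients and slight conservatism of nominal p-values
(the global-null scan runs at ~4.4–4.9% positives at α = 0.05 rather
than 5%); the permutation FDR below recalibrates the decision rule
empirically, and parameter-recovery tests therefore scan data that are
residualized for technical covariates only.

## Cis interaction scan

`cisInteractionScan()` tests, for every meta-exon and every SNP within
1 Mb of its transcription start site,

$$y \sim I + \beta_A A + \beta_{A^2} A^2 + \beta_P P + \beta_{SNP} G +
\beta_{P \times SNP}\, G P + \varepsilon$$

by OLS, with a Wald t test on the interaction coefficient (equivalent
to the 1-df F test). The same pair refitted without the interaction
term gives the main-effect eQTL p-value. Internally the scan uses the
Frisch–Waugh–Lovell decomposition against the shared covariate block,
which reproduces full-design OLS coefficients, standard errors and
p-values to machine precision (the test suite holds it to an
independent normal-equations oracle at 10⁻⁸ relative error) at a
fraction of the cost.

## Permutation FDR with exon-count strata

Genes with many exons get more chances to show a small interaction p by
luck. `permutationFdr()` therefore bins genes into quartile strata of
expressed-exon count and estimates, within each stratum,

$$\widehat{FDR}(t) = \frac{\#\{p_{perm} \le t\}/n_{perm}}
{\#\{p_{obs} \le t\}}$$

from n = 100 permutations (at least 20 required), monotonized to be
non-decreasing in p. Before permuting, all main effects (phenotype,
SNP, age) are regressed out per exon–SNP pair — per pair rather than
per exon, because the SNP main effect differs across the SNPs of an
exon and leaving it in would corrupt the interaction null. Expression
residuals are permuted across samples while the genotypes stay fixed.
Pairs with FDR < 0.05 (strict) are flagged significant.

## Two-step trans discovery

A genome-wide all-pairs trans interaction scan is hopeless at cohort
scale, so trans discovery is seeded: the cis scan is repeated on
residuals *not* corrected for latent factors (factor correction removes
broadly acting variance — exactly what a multi-gene trans regulator
produces), and the significant cis variants are then tested against
every expressed meta-exon more than 5 Mb away or on another chromosome
(`transInteractionScan()`). Significance uses the strict Bonferroni
threshold α/(variants × exons) (`bonferroniThreshold()`); with four
variants against 116,643 exons this is 1.1 × 10⁻⁷ to two significant
figures.

## Mediation of trans networks

For a trans target y, mediator expression E, cis dosage G and phenotype
P, `mediationTest()` fits

$$M5: y \sim \beta_1 A + \beta_2 A^2 + \beta_3 P + \beta_4 G +
\beta_5 P \times G + \varepsilon$$
$$M6: y \sim \beta_1 E + \beta_2 A + \beta_3 A^2 + \beta_4 P +
\beta_5 G + \beta_6 P \times G + \varepsilon$$

and reports the mediation score
$(\beta_{M5_5} - \beta_{M6_6})/\beta_{M5_5}$, the fraction of the
interaction absorbed by conditioning on the mediator. Significance uses
Sobel's product-of-paths statistic on the indirect path — a, the
interaction coefficient of the mediator's own cis model, and b, the
mediator coefficient in M6:

$$Z = \frac{a\,b}{\sqrt{b^2 S_a^2 + a^2 S_b^2}}$$

Note that plugging the M5/M6 interaction coefficients themselves into
the product formula would behave pathologically (it tends to 0 under
full mediation, because the conditional coefficient vanishes); the
product of path coefficients is the statistic Sobel's method defines
and the one whose p-value is small exactly when the signal reaches the
mediator and the mediator transmits it. The default calling threshold
(Sobel p ≤ 0.001) is configurable. The p-value is two-sided; sidedness
is a package choice.

## π0/π1 and replication sharing

`estimatePi0Qvalues()` implements the Storey estimator: π̂0(λ) =
#{p > λ}/(m(1−λ)) over λ = 0.05, …, 0.95, smoothed with a cubic
smoothing spline (df = 3) and read off at λ = 0.95, clipped to [0, 1];
q-values follow. π1 = 1 − π0 measures the fraction of true signals in a
p-value set, and `pi1Replication()` applies it to discovery pairs
matched by identifier into another tissue or cohort — fewer than 100
matched pairs flags the estimate unstable. A bootstrap π0 alternative
was considered and not implemented; the spline variant is the standard
choice and the only one the pipeline consumes.

## Regulatory trait concordance (RTC)

To ask whether a GWAS variant and a regulatory interaction tag the same
underlying signal, `rtcScore()` conditions the interaction on every SNP
in a window (e.g. 250 kb) in turn — mode `"interaction"` fits
$y \sim P \times SNP_N + P \times SNP_{eQTL}$, mode `"main"` fits
$y \sim SNP_N + P \times SNP_{eQTL}$ — and records the conditional
p-value of the eQTL term. SNPs are ranked so that rank 1 is the SNP
whose conditioning most abrogates the signal (largest residual p); then

$$RTC = (N_{SNPs} - Rank_{GWAS})/N_{SNPs},$$

approaching 1 when the GWAS SNP explains the regulatory signal and
centring near 0.5 for an unrelated SNP. The rank direction is a package
reading of the construction (it is the direction under which
colocalized signals score near 1); ties are broken by genomic position
for determinism.

## Replication across annotations

`matchMetaExons()` maps meta-exons between two annotation sets of the
same genome build by reciprocal overlap: a pair is *matched* when the
overlap exceeds 90% of both meta-exon lengths, *partial* when they
overlap but fail the reciprocal rule, *unmatched* otherwise. The
partial class deliberately includes one-sided containment (a 33%
fragment fully inside a larger meta-exon is partial, not matched).

# The synthetic cohort generator

`simulateCohort()` emulates the study conditions end to end:

* **Twin structure.** MZ pairs share genotypes, family and zygosity
  codes and age; DZ pairs are formed by Mendelian sampling from four
  simulated parental haplotypes (expected within-pair dosage
  correlation 1/2); unrelated singletons fill the rest. The default
  cohort is 120 MZ pairs + 120 DZ pairs + 220 singletons = 700
  samples, ages uniform on 38–84.
* **Genotypes.** Biallelic dosages at MAF ∈ [0.05, 0.5]; optional
  AR(1) haplotype blocks by allele copying (adjacent-locus correlation
  ρ, so proxies at r² > 0.9 exist as in real blocks — needed by the
  colocalization tests). The copying chain lets realized MAF drift
  toward the block average; containers record empirical frequencies.
* **Phenotype.** BMI-like scale (mean 25, SD 4), with an additive
  genetic component (default heritability 0.4) shared fully within MZ
  and half within DZ pairs.
* **Expression.** Generated directly on the scale of the
  inverse-normal transformed data the models consume: gene-level age
  effects, family and zygosity random intercepts (default variance
  0.05 each), per-exon technical effects (GC, insert size, primer,
  batch; SD 0.05), per-exon latent-factor loadings (default five
  factors, the leading three correlated with the phenotype at r = 0.5,
  0.3, 0.2 — echoing how strongly adiposity drives broad expression
  variance in real tissue), planted effects, and Gaussian noise
  (SD 0.3, chosen so that planted interaction coefficients of
  0.02–0.06 reach the significance range reported for real cohorts at
  n ≈ 700). An optional negative-binomial count layer maps the signal
  onto raw read counts for exercising the quantification steps.
* **Planted truth.** Main eQTLs, G × phenotype interactions
  (including Figure-style sign flips via `beta_pheno = -beta_int`
  configurations), and cis-mediated trans networks
  (`plantTransNetwork()`): a fraction of each target's interaction is
  routed through the mediator's realized expression, the rest wired
  directly. Every realized effect is recorded in the `TruthTable`.

What the generator does **not** emulate: read-level sequencing noise,
LD from real population history, sex chromosomes, population
stratification, or cell-type composition shifts. Passing tests
therefore demonstrate statistical correctness of the machinery on data
satisfying the model's assumptions, not robustness to everything real
tissue does.

# Numerical and design choices

* Variance fractions of the synthetic expression (genetic / family /
  noise) are free parameters with the defaults above; they are not
  claims about any real cohort.
* Null-calibration experiments use cohorts without latent confounders
  and without technical effects. With dense *shared* factor
  realizations the per-cohort type-I error of the phenotype LRT swings
  widely (all exons ride the same realized factor–phenotype sample
  correlation) — that is precisely the failure mode factor correction
  exists for, and it is exercised by the power-gain comparison
  instead.
* The mediation-recovery experiments likewise run without shared
  latent confounders: a confounder loading on both mediator and target
  violates the mediation null by construction (the classic caveat of
  mediation analysis), which is worth demonstrating but not a test of
  estimator correctness.
* Degenerate inputs: monomorphic SNPs are skipped and logged;
  collinear designs error with the offending columns named; all-tied
  expression vectors are a degenerate-input error for the INT;
  non-convergent mixed models fall back to a family-only random
  effect, flagged, never silently NA.
* Problem sizes in the acceptance checks — 20 null cohorts of 700
  samples and 1,000 genes for calibration, 200 planted interactions
  for recovery, 50 replicates per colocalization arm — were chosen as
  the smallest designs whose binomial/Monte-Carlo error is comfortably
  inside the tolerances being asserted.
* Two runs with the same configuration and seeds are bit-identical;
  all randomness flows from explicit seeds.

# Known limitations

* The family correction is moment-based BLUP shrinkage, not a full
  mixed-model residualization; it is slightly conservative and mildly
  attenuating (see above). The mixed model itself is used wherever a
  calibrated per-test p-value matters (phenotype association).
* The LRT for a family-structured phenotype is asymptotic in the
  number of family units; at 470 units it runs at ≈ 0.05 with
  cohort-to-cohort variation of about ±0.01.
* π1 on fewer than 100 matched pairs is flagged unstable rather than
  refused; treat such estimates as qualitative.
* The RTC rank convention is documented, not asserted to be the
  original authors'; both conventions differ only by RTC ↔ 1 − RTC −
  1/N.
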