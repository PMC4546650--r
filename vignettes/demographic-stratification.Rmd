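---
title: "Demographic stratification of SNP-lipid associations: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Demographic stratification of SNP-lipid associations: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(demostrat)
```

## The scientific problem

Genome-wide association studies usually treat a risk allele as an
unconditional property of a variant: one effect size, estimated in the
largest sample obtainable. For complex, environmentally entangled traits
such as total cholesterol (TC) that assumption is questionable. If the
effect of a variant differs between men and women, between birth cohorts
that grew up under different diets and treatments, or between age strata,
then pooling everyone averages antagonistic signals, deflates effect
sizes, and inflates the sample sizes needed for discovery.

demostrat implements the re-analysis workflow that makes this argument
quantitative for a three-generation family study: additive-genotype mixed
models fitted inside demographic cells (sex x generation x age stratum),
heterogeneity statistics over the resulting cell-level effects, a
partition of cells into a homogeneous strongly supporting subsample (S)
and its weak complement (W), analytic sample-size projections, and an
enrichment test of significant cell-level associations against chance.
Because the original cohort data are access-restricted, the package ships
a synthetic cohort generator that emulates the study design; every
downstream stage is exercised and tested against it.

## The association models

TC is analysed on the scale `y = 100 * log10(TC mg/dL)`, which corrects
the right skew of raw TC; effects in mg/dL are obtained by fitting the
untransformed value instead (`scale = "raw"`). The effect allele is
always the minor allele, and genotype enters as dosage 0/1/2
(`transform_tc()`, `fit_additive_baseline()`).

Two estimation levels mirror the repeated-measurement design:

* **Baseline (two-level).** Each individual's first exam, with a random
  intercept per family:
  `y ~ dosage + covariates + (1 | family)`.
* **Cumulative (three-level).** All exams of all individuals, with
  nested random intercepts for family and subject:
  `y ~ dosage + covariates + (1 | family / subject)`.
  The dosage coefficient is then the genetic effect pooled over the
  individuals' follow-up ("cumulative effect"); repeated measurements
  typically shrink its standard error relative to the baseline fit.

Estimation is restricted maximum likelihood via lme4; p-values are
two-sided Wald tails under the standard normal reference, the common
large-sample convention in mixed-model association work. Covariates
follow the study's adjustment set — cross-sectional age (the per-exam age
in the cumulative model, the only choice that uses the repeated
measurements coherently), sex, whole-genome-amplification status of the
DNA sample, and cohort (generation) indicators; covariates that are
constant within a cell (sex inside a single-sex cell, generation inside
one cohort) are dropped automatically. Missing dosages drop an individual
for that SNP only (complete case). Two documented degenerate paths keep
the models well-defined at the boundary: when every family contributes a
single analysed unit the family intercept is unidentifiable and the fit
collapses to ordinary least squares on the same fixed effects, and when
no individual has repeated records the subject level is dropped, making
the cumulative fit equal the baseline fit.

Binary-covariate sensitivity screens (fasting, lipid-lowering treatment)
reuse the two-level model with the flag as the effect of interest
(`covariate_effect_test()`). Fasting is dichotomized as 12+ hours or
unknown status versus a recorded shorter fast.

## Demographic cells, age strata, and exam matching

`build_cells()` partitions genotyped individuals along sex and
generation (six cells for three generations); empty cells are retained
with `n = 0` so scans can report them as skipped rather than silently
renumbering. `split_by_median_age()` splits a cell at a cutoff on age at
biospecimen collection — the variable that controls survival selection
across birth cohorts — with the younger stratum strictly below the
cutoff; the defaults are the study medians, 40 years for generation 3 and
60 for generation 2, supplied per generation through configuration.
Individuals with unknown collection age are excluded from strata and
counted in a message.

Cross-generation comparisons additionally require comparable ages at
measurement. `match_age_cohorts()` ranks the exams of one cohort by the
absolute difference between their mean age at examination and the target
cohort's mean age at measurement, breaking ties toward the lower exam
index. The top-ranked exam is the default selection, but the full ranking
is returned and any candidate may be chosen by configuration: an exam
marginally further in mean age can be preferable on substantive grounds
(for example because its associations resemble the cumulative estimates),
so the closest-mean rule is deliberately not hard-coded.

`scan_cells()` runs one fit per SNP per cell, labels each entry
significant (p <= 0.05), suggestive (0.05 < p <= 0.1) or null — pure
threshold functions of the p-value — and records per-entry fit failures
without aborting the scan.

## Heterogeneity and the S/W partition

Cell-level effects `b_i` with standard errors `se_i` are pooled by
inverse variance (`pool_fixed()`); Cochran's
`Q = sum(w_i (b_i - b_hat)^2)` with `w_i = 1/se_i^2` and
`I2 = 100 * max(0, (Q - df)/Q)` quantify between-cell heterogeneity
(`cochran_q()`, `i_squared()`).

`partition_sw()` formalises the S/W construction: the S-subsample is a
group of cells with homogeneous effects whose pooled estimate carries the
sign of the reference meta-analytic effect; the W-subsample is the
complement. Because sampling noise rarely yields exactly `Q <= df`, the
"I2 = 0" requirement is implemented as *minimal within-group I2, and 0
whenever attainable*. Among feasible candidates the partition maximising
the between-group I2 (computed on the two pooled estimates, df = 1) is
selected; ties break toward the larger |pooled z| of S and then toward
the lexicographically first cell set, making the result deterministic.
All `2^k - 2` ordered bipartitions are enumerated — exact for the at most
6-12 cells a demographic scan produces — and all feasible candidates are
returned for audit, since the selection could defensibly have been made
by hand. Two flagged edge cases: fully homogeneous cells (no bipartition
has positive between-group I2) return `"degenerate"`, and the absence of
any sign-concordant group returns `"no-support"` with the
least-contradicting singleton as S. The partition operates on cell-level
summaries; a pooled-individual mixed-model fit of the S or W union is
available through the association module, and reports state which of the
two produced each number.

## Power and sample-size projection

Under Hardy-Weinberg equilibrium an additive effect `beta` at minor
allele frequency `p` explains `v = 2 p (1 - p) beta^2` of the trait
variance, so the minimal unrelated-sample size for a two-sided level
`alpha` and target power is

```
N = ceil( (z_{1-alpha/2} + z_{power})^2 * sigma^2 / v )
```

(`required_n()`, inverse `power_at_n()`). Defaults: trait SD 38 mg/dL
(the study's population TC SD around a mean of 194 mg/dL), `alpha` 0.05
nominal or 5e-8 genome-wide. The residual variance `sigma^2` defaults to
the *total* trait variance, which reproduces the study's published
projections most closely; subtracting the explained variance is available
behind a flag. The target power is not printed in the study; 0.80
two-sided reproduces every published projection within 0.1% and is
adopted as a derived constant, overridable in configuration. These are
deliberately the most optimistic numbers: family clustering would inflate
them.

## Enrichment over chance

A scan of `n` cells x SNPs at level `alpha` expects `n * alpha`
significant results under the global null; `fold_excess()` reports the
observed/expected ratio and `enrichment_test()` attaches two one-sided
p-values: the exact binomial tail `P(X >= observed)` and a normal
approximation on the observed proportion (variance taken from the
observed proportion; defined as 1 at zero observed, where that estimate
degenerates). The tests of a scan are treated as independent for the
chance expectation — the demographic cells are disjoint, though the ten
SNPs share individuals — and both p-values are reported rather than
privileging either approximation. The exact tail is proven super-uniform
under simulated null scans in the test suite.

## The synthetic cohort generator

`simulate_pedigree()` builds extended families: a founder couple
(generation 1), their children plus unrelated married-in spouses
(generation 2, sharing the family id of the lineage — a stated
convention, since the original study does not describe how spouses were
grouped in the random-effect structure), and grandchildren
(generation 3). Birth years are drawn per generation and sex around the
published means (1911/1937/1963, SD 6/10/9 for men). Biospecimen
collection years are fixed at 1995/1997/2002, matching collection late in
follow-up for the first two generations and at the single baseline exam
of the third; the implied age-at-collection medians straddle the 60- and
40-year stratification cutoffs, as in the study. An optional
age-dependent thinning of generation-1 members emulates survival
selection and is off by default, the study describing no explicit model.

`simulate_genotypes()` draws founders in Hardy-Weinberg equilibrium at
each SNP's minor allele frequency and transmits alleles Mendelianly, so
parent-offspring consistency holds exactly. SNPs are simulated
independently (the study treats them marginally; no linkage
disequilibrium) and without genotyping error.

`simulate_phenotypes()` generates the analysis-scale value additively —
cell intercept, age slope centred at the structural mean age at baseline,
optional secular birth-year trend, per-SNP genetic effects, family and
subject random effects, residual — and back-transforms to mg/dL, so the
fitted mixed models are exactly correctly specified and
parameter-recovery tests are meaningful. Exam schedules default to the
study design: 16 biennial exams (generation 1, from 1948), 7 quadrennial
(generation 2, from 1971), one baseline exam (generation 3, 2002).
Per-exam missingness is completely at random at a configurable rate,
default 0 (the study gives no missingness model).

Key numeric defaults, chosen once against the published cohort table:

* Variance components 11 / 32 / 59-sum on the transformed scale
  (family 11, subject 32, residual 29; total SD 8.49, matching the
  study's coefficient of variation 38/194), i.e. familial ICC 0.15.
* Age slope 0.25 transformed units per year (~1.1 mg/dL/yr at the
  population mean), a typical mid-life TC trajectory.
* Cell intercepts calibrated by exact lognormal moment matching so the
  back-transformed mean equals the published per-cell TC mean; the
  variance contributed by the age slope enters the correction.
* Genetic contributions are centred on the cohort mean dosage, so
  planted effects do not drift the calibrated cell means while leaving
  the dosage coefficient recovered by the models unchanged.
* Fasting prevalence 0.10/0.85/0.90 across generations (early random
  draws versus later fasting draws), unknown status 5%; lifetime
  treatment probabilities 0.02/0.08/0.10; whole-genome amplification
  10%.

`scenario_library()` encodes the qualitative effect structures the
re-analysis found: `homogeneous` (one effect everywhere; with
`beta = 0`, the global null), `generation_clustered` (effects confined to
the youngest generation), `antagonistic` (positive everywhere except the
younger generation-3 stratum, which is negative — the sign-reversing
profile that cancels in pooled analysis), and `age_stratum` (effects in
younger strata only).

What the generator does **not** emulate: linkage disequilibrium,
genotyping error, realistic mortality and ascertainment, non-lognormal
tails of TC, informative missingness, assortative mating, and birth-year
dependence within couples (spouse and sibling birth years are drawn
independently). Tests passing on this generator therefore validate the
statistical machinery — calibration, recovery, partition optimality,
power arithmetic — not the substantive effect sizes of any real cohort.

## Verification design and problem sizes

The test suite validates each stage against an independent oracle:
ordinary least squares via explicit normal equations for the
variance-collapse limit, metafor's fixed-effect model for Q/I2,
brute-force enumeration for the S/W partition, a hand-summed binomial
tail for the enrichment p-value, and Monte-Carlo simulation for type-I
error (2000 null replicates of ~1000 individuals per model level, with
one design shared across replicates and phenotypes redrawn — a valid
conditional null Monte Carlo), parameter recovery (200 seeds, planted
effect 0.4, ~1500 individuals with 7 exams), empirical power at the
projected sample size (2000 unrelated-sample replicates), and scan
behaviour under the scenario library (null scan-count calibration and
enrichment super-uniformity over 2000 replicate 60-test scans of
unrelated adults, 150 per cell, where the family level is deliberately
absent because those properties concern the scan and enrichment
machinery, not the clustering already validated elsewhere). The
`analysis/` scripts run the same pipeline at a 400-family scale chosen so
the full workflow completes in minutes on one core.

## Known limitations

* Random-intercept models only: no kinship-matrix (GRM) relatedness, no
  random slopes, matching the study's intercept-nesting structure.
* Fixed-effect pooling stands behind the S/W summaries; no
  random-effects (tau^2) meta-analysis beyond I2.
* Power calculations assume unrelated individuals and a Gaussian trait.
* The Wald-normal reference is slightly anti-conservative in small
  cells; cells of a few dozen individuals should be read accordingly.
* The pipeline treats the 10 SNPs marginally; no multiple-testing
  correction is applied beyond the enrichment argument itself.
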