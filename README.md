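# demostrat

Demographic stratification of SNP associations with blood lipids in
multi-generation family cohorts.

## The problem

GWAS meta-analyses report one effect size per variant, implicitly
treating risk alleles as unconditional. For environmentally entangled
quantitative traits such as total cholesterol (TC), the effect of a
variant can differ by sex, by birth cohort (a proxy of environmental
exposures), and by age (a proxy of biological aging) — and opposite-sign
("antagonistic") effects in different strata cancel in pooled analysis,
making a strong variant look null. `demostrat` implements the re-analysis
workflow that quantifies this for a three-generation family study design,
for statistical geneticists and genetic epidemiologists who want to test
demographic effect modulation rather than assume it away.

## The models

* **Association.** TC is analysed as `y = 100·log10(TC mg/dL)` (or raw
  mg/dL for comparability with meta-analytic effects), regressed on
  minor-allele dosage (0/1/2) under an additive model. Baseline
  associations use a two-level mixed model, `y ~ dosage + covariates +
  (1 | family)`; cumulative associations over all repeated exams use the
  three-level model `y ~ dosage + covariates + (1 | family/subject)`
  (REML via lme4; two-sided Wald p-values, normal reference).
* **Stratification.** Associations are scanned over demographic cells —
  sex × generation, and younger/older strata split at the per-cohort
  median age at biospecimen collection (40 y for the youngest
  generation, 60 y for the middle one) — with entries classed
  significant (p ≤ 0.05) or suggestive (0.05 < p ≤ 0.1).
* **Heterogeneity.** Cell effects are pooled by inverse variance;
  Cochran's Q and `I² = 100·max(0, (Q − df)/Q)` quantify between-cell
  heterogeneity, and `partition_sw()` splits the cells into a
  homogeneous subsample supporting the reference meta-analytic effect
  (S) and its weak complement (W), maximizing between-group I².
* **Power.** With variance explained `v = 2·MAF·(1 − MAF)·β²`, the
  minimal unrelated-sample size at two-sided level α and power 1 − γ is
  `N = ⌈(z₁₋α/₂ + z₁₋γ)² σ² / v⌉` (σ = 38 mg/dL by default).
* **Enrichment.** An observed count of significant tests in a scan is
  compared with the chance expectation `n·α` (fold excess, exact
  binomial and normal tail p-values).

A seeded synthetic cohort generator (pedigrees with Mendelian genotype
transmission, repeated TC exams calibrated to the published cohort
means, and scenario libraries including antagonistic profiles) makes the
whole pipeline runnable and testable without access to the restricted
cohort data. See the methods vignette
(`vignettes/demographic-stratification.Rmd`) for model details, defaults
and limitations.

## Worked example

Simulate 200 families under the "generation-clustered" scenario (effects
confined to the youngest generation), scan sex × generation cells, and
partition the cells for the PCSK9 SNP:

```r
library(demostrat)
snps <- lipid_snps()[c(1, 3), ]          # rs2479409 (PCSK9), rs1800562 (HFE)
coh <- simulate_cohort(200, model = "generation_clustered", snps = snps,
                       beta = 3, seed = 7)
scan <- scan_cells(coh$phenotypes, coh$genotypes,
                   cells = build_cells(coh$phenotypes))
scan[scan$snp_id == "rs2479409",
     c("cell", "n_individuals", "beta", "se", "p_value", "class")]
#>    cell n_individuals   beta    se  p_value       class
#>  gen1/M           200  0.801 0.881 3.63e-01        null
#>  gen1/W           200  0.303 0.863 7.26e-01        null
#>  gen2/M           401 -0.261 0.615 6.72e-01        null
#>  gen2/W           401  0.524 0.617 3.95e-01        null
#>  gen3/M           429  3.301 0.634 1.91e-07 significant
#>  gen3/W           385  2.635 0.635 3.29e-05 significant
```

The planted effect (3 transformed units ≈ 14 mg/dL per minor allele at
the population mean) is recovered only in the generation-3 cells. The
scan-level enrichment and the S/W partition make the clustering
quantitative:

```r
enrichment_summary(scan)
#>   n_tests alpha observed expected fold p_exact p_normal
#> 1      12  0.05        3      0.6    5  0.0196   0.0548

cr <- scan[scan$snp_id == "rs2479409" & is.finite(scan$beta),
           c("cell", "beta", "se")]
partition_sw(cr, reference_beta = 1.96)
#> <sw_partition> ok
#>   S: gen3/M, gen3/W (pooled beta 2.968, se 0.448, I2 0.0%)
#>   W: gen1/M, gen1/W, gen2/M, gen2/W (pooled beta 0.269, se 0.356, I2 0.0%)
#>   between-group I2: 95.5%
```

Five significant results against 0.6 expected by chance (5-fold,
exact p = 0.02), and a partition whose S-subsample isolates the two
generation-3 cells with between-group I² of 95.5% while both subsamples
are internally homogeneous. Sample-size projections for the reference
meta-analytic effect of rs2479409 (β = 1.96 mg/dL, MAF 0.34, SD 38):

```r
required_n(1.96, 0.34)                 # nominal p = 0.05
#> [1] 6574
required_n(1.96, 0.34, alpha = 5e-8)   # genome-wide significance
#> [1] 33168
```

## The analysis workflow

The numbered scripts under `analysis/` run the full study sequence on a
400-family synthetic cohort and write their tables under `results/`:

1. `01_simulate_cohort.R` — generate and write the cohort (pedigree FAM,
   genotype TSV, phenotype TSV).
2. `02_pooled_associations.R` — pooled baseline (raw + transformed) and
   cumulative associations per SNP; nominal sample-size projections for
   the meta-analytic effects.
3. `03_sex_generation_scan.R` — 6-cell scan under both model levels,
   significance classes, enrichment over chance.
4. `04_heterogeneity_sw.R` — per-SNP S/W partitions with I², and
   genome-wide sample-size projections for S, W and the entire sample.
5. `05_age_stratified.R` — younger/older scans at the 40/60-year median
   cutoffs, exam-level age matching across generations, and the
   antagonism analysis of rs2479409.

Run them in order from the repository root after installing the package:
`Rscript analysis/01_simulate_cohort.R` etc. `run_pipeline()` performs
the same sequence programmatically from a single (YAML-able)
configuration.

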