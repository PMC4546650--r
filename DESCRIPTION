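Package: demostrat
Title: Demographic Stratification of SNP Associations with Blood Lipids in
    Multi-Generation Family Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Re-analysis toolkit for genome-wide association signals of a
    quantitative lipid trait (total cholesterol) across demographic strata of
    a three-generation family study. Fits additive-genotype mixed-effects
    models with family-level (two-level) and family-plus-subject (three-level,
    repeated measurements) random intercepts; scans sex-by-generation and
    median-age demographic cells with significance classes; quantifies
    between-cell heterogeneity by Cochran's Q and I-squared and constructs the
    strong-support/weak-support (S/W) subsample partition; projects
    additive-model sample sizes at nominal and genome-wide significance; and
    tests enrichment of observed significant associations over chance.
    Includes a seeded synthetic three-generation cohort generator (pedigrees
    with Mendelian genotype transmission, calibrated repeated cholesterol
    measurements, secular trends, and scenario libraries with antagonistic
    sign-reversing genetic effects) so the whole pipeline runs without access
    to restricted cohort data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    lme4,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    metafor,
    vcfR,
    withr,
    knitr
Config/testthat/edition: 3
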