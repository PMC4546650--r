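#' Baseline characteristics of the three study generations
#'
#' Published per-sex summaries of the three generations of the family study
#' the synthetic cohort emulates: genotyped sample size, birth-year mean (SD),
#' age at baseline examination, and total cholesterol (TC) in mg/dL. These
#' numbers calibrate the default simulation scenarios.
#'
#' @return A data frame with one row per generation x sex: `generation`
#'   (1 = original cohort, 2 = offspring, 3 = third generation), `sex`
#'   (`"M"`/`"W"`), `n`, `birth_mean`, `birth_sd` (calendar years),
#'   `age_mean`, `age_sd` (years at baseline), `tc_mean`, `tc_sd` (mg/dL).
#' @export
#' @examples
#' cohort_reference()
cohort_reference <- function() {
  data.frame(
    generation = rep(1:3, each = 2),
    sex        = rep(c("M", "W"), 3),
    n          = c(613, 916, 1781, 1969, 1819, 2069),
    birth_mean = c(1911, 1910, 1937, 1938, 1963, 1963),
    birth_sd   = c(6, 7, 10, 10, 9, 9),
    age_mean   = c(38.7, 39.3, 36.0, 35.2, 40.3, 40.0),
    age_sd     = c(6.5, 7.0, 10.4, 9.9, 8.9, 8.8),
    tc_mean    = c(214.7, 210.7, 198.5, 190.5, 192.8, 185.3),
    tc_sd      = c(38.8, 42.4, 38.4, 37.7, 37.0, 33.7),
    stringsAsFactors = FALSE
  )
}

#' The ten directly genotyped lipid SNPs and their meta-analytic effects
#'
#' The ten GWAS SNPs associated with total cholesterol that were directly
#' genotyped on the study array, with the minor allele frequency (MAF) in the
#' study sample and the effect size per minor allele (mg/dL of TC) with its
#' standard error as reported by the large GWAS meta-analysis the re-analysis
#' takes as reference. These effect sizes are the inputs of the sample-size
#' projections and the reference signs for the S/W subsample partition.
#'
#' @return A data frame: `snp_id`, `chr`, `gene`, `maf`, `beta_meta` (mg/dL
#'   per minor allele), `se_meta` (mg/dL).
#' @export
#' @examples
#' lipid_snps()
lipid_snps <- function() {
  data.frame(
    snp_id = c("rs2479409", "rs3177928", "rs1800562", "rs9488822",
               "rs1564348", "rs10128711", "rs11220462", "rs3764261",
               "rs7206971", "rs1800961"),
    chr  = c(1, 6, 6, 6, 6, 11, 11, 16, 17, 20),
    gene = c("PCSK9", "HLA-DRA", "HFE", "FRK", "SLC22A1", "SPTY2D1",
             "ST3GAL4", "CETP", "EFCAB13", "HNF4A"),
    maf  = c(0.34, 0.14, 0.06, 0.37, 0.16, 0.23, 0.13, 0.30, 0.49, 0.03),
    beta_meta = c(1.96, 2.31, -2.16, -1.18, 2.18, -1.06, 2.01, 1.67,
                  1.01, -4.73),
    se_meta   = c(0.24, 0.27, 0.43, 0.20, 0.27, 0.22, 0.33, 0.23,
                  0.20, 0.66),
    stringsAsFactors = FALSE
  )
}

#' Default examination schedule per generation
#'
#' The original cohort was examined roughly biennially over sixteen captured
#' exams, the offspring cohort roughly every four years over seven exams, and
#' the third generation has a single baseline exam. `baseline_year` anchors
#' each generation's first exam in calendar time, which determines age at
#' each exam from birth year.
#'
#' @return A data frame with columns `generation`, `n_exams`,
#'   `spacing_years`, `baseline_year`.
#' @export
default_exam_schedule <- function() {
  data.frame(
    generation    = 1:3,
    n_exams       = c(16L, 7L, 1L),
    spacing_years = c(2, 4, 0),
    baseline_year = c(1948, 1971, 2002)
  )
}

#' Validate an exam schedule table
#' @noRd
check_schedule <- function(schedule) {
  stopifnot(is.data.frame(schedule),
            all(c("generation", "n_exams", "spacing_years",
                  "baseline_year") %in% names(schedule)))
  if (any(schedule$n_exams < 1))
    stop("exam schedule: number_of_exams must be >= 1", call. = FALSE)
  invisible(schedule)
}
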