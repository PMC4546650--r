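# Additive-genotype association models. Two estimation levels mirror the
# study design: a two-level model (random intercept per family) for
# single-exam (baseline) analyses, and a three-level model (subject nested
# in family) for cumulative analyses over repeated exams. Estimation is by
# REML via lme4; inference is Wald with the large-sample normal reference.

#' Transform total cholesterol to the analysis scale
#'
#' The analysis scale is `100 * log10(TC)`: the log corrects the right skew
#' of raw TC and the factor 100 gives convenient resolution of effect sizes.
#'
#' @param tc_mgdl total cholesterol in mg/dL, strictly positive.
#' @return `100 * log10(tc_mgdl)`.
#' @export
#' @examples
#' transform_tc(100)  # 200
#' transform_tc(194)  # 228.78
transform_tc <- function(tc_mgdl) {
  if (any(!is.finite(tc_mgdl)) || any(tc_mgdl <= 0))
    stop("tc_mgdl must be finite and > 0", call. = FALSE)
  100 * log10(tc_mgdl)
}

#' Dichotomize fasting status
#'
#' A draw counts as fasting when the recorded fast lasted 12 or more hours
#' or when fasting status is unknown (`NA`); shorter recorded fasts count
#' as non-fasting.
#'
#' @param fasting_hours hours fasted, `NA` for unknown.
#' @return Logical vector, `TRUE` = fasting.
#' @export
#' @examples
#' dichotomize_fasting(c(12, 11.5, NA))  # TRUE FALSE TRUE
dichotomize_fasting <- function(fasting_hours) {
  if (any(fasting_hours < 0, na.rm = TRUE))
    stop("fasting_hours must be non-negative", call. = FALSE)
  is.na(fasting_hours) | fasting_hours >= 12
}

# Restrict a phenotype table to each individual's first available exam.
baseline_records <- function(pheno) {
  if (!anyDuplicated(pheno$individual_id)) return(pheno)
  first <- ave(pheno$exam_index, pheno$individual_id, FUN = min)
  pheno[pheno$exam_index == first, , drop = FALSE]
}

# Attach the dosage of one SNP, complete-case on dosage and the response.
assoc_frame <- function(pheno, geno, snp_id) {
  if (!snp_id %in% colnames(geno))
    stop("unknown SNP: ", snp_id, call. = FALSE)
  d <- pheno
  d$dosage <- geno[match(d$individual_id, rownames(geno)), snp_id]
  drop <- is.na(d$dosage) | is.na(d$tc_mgdl)
  if (any(drop)) d <- d[!drop, , drop = FALSE]
  d
}

# Map requested covariate names to model columns, dropping covariates that
# are constant in the analysis sample (e.g. sex within a single-sex cell,
# generation within one cohort).
covariate_terms <- function(data, covariates) {
  map <- c(age = "age_at_exam", sex = "sex", wga = "wga",
           generation = "generation", fasting = "fasting",
           treatment = "lipid_treatment")
  unknown <- setdiff(covariates, names(map))
  if (length(unknown))
    stop("unknown covariate(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  keep <- character(0)
  for (cv in covariates) {
    col <- map[[cv]]
    vals <- data[[col]]
    if (length(unique(vals[!is.na(vals)])) > 1)
      keep <- c(keep, if (cv == "generation") "factor(generation)" else col)
  }
  keep
}

# Shared fitting core. `level` picks the random-effect structure; when every
# family has a single analysed unit the family intercept is unidentifiable
# and the model collapses to ordinary least squares on the same fixed
# effects (the documented degenerate path); likewise the subject level is
# dropped when no individual has repeated records.
fit_additive <- function(data, term, covariates, scale, level, cell,
                         snp_id) {
  scale <- match.arg(scale, c("transformed", "raw"))
  data$y <- if (scale == "transformed") transform_tc(data$tc_mgdl) else
    data$tc_mgdl
  if (nrow(data) < 3)
    stop("too few records to fit (", nrow(data), ")", call. = FALSE)
  if (length(unique(data[[term]])) < 2)
    stop("degenerate predictor: '", term,
         "' is constant in the analysis sample", call. = FALSE)
  fixed <- c(term, covariate_terms(data, covariates))
  rhs <- paste(fixed, collapse = " + ")

  ind_first <- !duplicated(data$individual_id)
  n_ind <- sum(ind_first)
  repeated <- nrow(data) > n_ind
  clustered <- anyDuplicated(data$family_id[ind_first]) > 0
  use_subject <- level == "three_level" && repeated

  if (!clustered && !use_subject) {
    if (identical(fixed, term)) {
      # closed-form simple OLS; avoids formula overhead in large scans
      x <- as.numeric(data[[term]]); y <- data$y
      n <- length(y)
      xc <- x - mean(x); yc <- y - mean(y)
      est <- sum(xc * yc) / sum(xc^2)
      rss <- sum((yc - est * xc)^2)
      se <- sqrt(rss / (n - 2) / sum(xc^2))
    } else {
      fit <- stats::lm(as.formula(paste("y ~", rhs)), data = data)
      cf <- summary(fit)$coefficients
      est <- cf[term, 1]; se <- cf[term, 2]
    }
  } else {
    re <- if (use_subject && clustered) "(1 | family_id/individual_id)"
          else if (use_subject) "(1 | individual_id)"
          else "(1 | family_id)"
    form <- as.formula(paste("y ~", rhs, "+", re))
    fit <- tryCatch(
      lme4::lmer(form, data = data, REML = TRUE,
                 control = lme4::lmerControl(calc.derivs = FALSE,
                                             check.conv.singular = "ignore")),
      error = function(e) stop("mixed-model fit failed for ", snp_id,
                               " [", cell, "]: ", conditionMessage(e),
                               call. = FALSE))
    cf <- lme4::fixef(fit)
    se_all <- sqrt(diag(as.matrix(stats::vcov(fit))))
    est <- cf[[term]]; se <- se_all[[match(term, names(cf))]]
  }
  p <- 2 * pnorm(-abs(est / se))
  structure(list(snp_id = snp_id, cell = cell, n_individuals = n_ind,
                 n_records = nrow(data), beta = unname(est),
                 se = unname(se), p_value = unname(p), model_level = level,
                 scale = scale),
            class = "data.frame", row.names = 1L)
}

#' Baseline (two-level) additive association of a SNP with TC
#'
#' Regresses the baseline TC value on minor-allele dosage (0/1/2) with a
#' random intercept per family, adjusting for the requested covariates.
#' Individuals with missing dosage are dropped for that SNP. Covariates that
#' are constant in the analysis sample (e.g. generation within a single
#' cohort) are dropped automatically. The p-value is the two-sided tail of
#' the Wald statistic `beta/se` under the standard normal reference.
#'
#' @param pheno long-format phenotype table (see [simulate_phenotypes()] for
#'   the column contract); only each individual's first exam is used.
#' @param geno dosage matrix, rows named by individual id.
#' @param snp_id column of `geno` to test.
#' @param covariates any of `"age"`, `"sex"`, `"wga"`, `"generation"`,
#'   `"fasting"`, `"treatment"`.
#' @param scale `"transformed"` (100*log10 TC, default) or `"raw"` (mg/dL).
#' @param cell label describing the analysis sample (default `"pooled"`).
#' @return One-row data frame: `snp_id`, `cell`, `n_individuals`,
#'   `n_records`, `beta`, `se`, `p_value`, `model_level`, `scale`.
#' @export
fit_additive_baseline <- function(pheno, geno, snp_id,
                                  covariates = c("age", "sex", "wga",
                                                 "generation"),
                                  scale = "transformed", cell = "pooled") {
  data <- assoc_frame(baseline_records(pheno), geno, snp_id)
  fit_additive(data, "dosage", covariates, scale, "two_level", cell, snp_id)
}

#' Cumulative (three-level) additive association over repeated exams
#'
#' Uses every available exam record, with nested random intercepts for
#' family and for subject within family, so the estimate pools the genetic
#' effect over the individuals' follow-up ("cumulative" effect). Age enters
#' as the per-exam age. When no individual has more than one record the
#' subject level is unidentifiable and the fit collapses to the two-level
#' baseline model.
#'
#' @inheritParams fit_additive_baseline
#' @return One-row data frame as in [fit_additive_baseline()], with
#'   `model_level = "three_level"`.
#' @export
fit_additive_cumulative <- function(pheno, geno, snp_id,
                                    covariates = c("age", "sex", "wga",
                                                   "generation"),
                                    scale = "transformed",
                                    cell = "pooled") {
  data <- assoc_frame(pheno, geno, snp_id)
  fit_additive(data, "dosage", covariates, scale, "three_level", cell,
               snp_id)
}

#' Association of TC with a binary covariate at one exam
#'
#' Sensitivity screen used for fasting status and lipid-lowering treatment:
#' a two-level (family-clustered) model of TC at a single exam with the
#' binary flag as the effect of interest.
#'
#' @param pheno phenotype records of a single exam (one row per individual).
#' @param covariate `"fasting"` (dichotomized via [dichotomize_fasting()])
#'   or `"treatment"`, or the name of a logical column of `pheno`.
#' @param covariates additional adjustment covariates.
#' @inheritParams fit_additive_baseline
#' @return One-row data frame as in [fit_additive_baseline()], with
#'   `snp_id` set to the covariate name.
#' @export
covariate_effect_test <- function(pheno, covariate,
                                  covariates = c("age", "sex"),
                                  scale = "transformed", cell = "pooled") {
  data <- pheno
  flag_col <- switch(covariate,
                     fasting = {
                       data$flag <- dichotomize_fasting(data$fasting_hours)
                       "flag"
                     },
                     treatment = {
                       data$flag <- as.logical(data$lipid_treatment)
                       "flag"
                     },
                     {
                       if (!covariate %in% names(data))
                         stop("unknown covariate: ", covariate,
                              call. = FALSE)
                       data$flag <- as.logical(data[[covariate]])
                       "flag"
                     })
  if (length(unique(data$flag[!is.na(data$flag)])) < 2)
    stop("degenerate predictor: covariate '", covariate,
         "' has a single level", call. = FALSE)
  data <- data[!is.na(data$flag), , drop = FALSE]
  data$flag <- as.numeric(data$flag)
  fit_additive(data, flag_col, setdiff(covariates, covariate), scale,
               "two_level", cell, covariate)
}
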