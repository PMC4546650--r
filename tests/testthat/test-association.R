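# Additive-genotype mixed-model association fits.

test_that("transform_tc is 100*log10 and rejects non-positive input", {
  expect_equal(transform_tc(100), 200)
  expect_equal(transform_tc(1000), 300)
  expect_equal(transform_tc(194), 228.78, tolerance = 0.01 / 228.78)
  expect_error(transform_tc(0), "> 0")
  expect_error(transform_tc(-5), "> 0")
})

test_that("fasting dichotomization follows the 12-hour/unknown rule", {
  expect_true(dichotomize_fasting(12))
  expect_true(dichotomize_fasting(NA))
  expect_false(dichotomize_fasting(11.5))
  expect_equal(dichotomize_fasting(c(0, 12, 16, NA, 11.99)),
               c(FALSE, TRUE, TRUE, TRUE, FALSE))
  expect_error(dichotomize_fasting(-1), "non-negative")
})

test_that("noise-free baseline fit recovers the planted effect exactly", {
  ped <- unrelated_pedigree(200)
  snps <- data.frame(snp_id = "snp1", maf = 0.3)
  geno <- simulate_genotypes(ped, snps, seed = 3)
  model <- flat_model(snps, beta = 0.5)
  pheno <- simulate_phenotypes(ped, geno, model,
                               schedule = one_exam_schedule(), seed = 4)
  r <- suppressWarnings(  # zero-residual fit is intentionally exact
    fit_additive_baseline(pheno, geno, "snp1", covariates = character(0)))
  expect_equal(r$beta, 0.5, tolerance = 1e-6 / 0.5)
  expect_equal(r$model_level, "two_level")
})

test_that("singleton-family fit matches the normal-equation OLS oracle", {
  ped <- unrelated_pedigree(300)
  snps <- data.frame(snp_id = "snp1", maf = 0.3)
  geno <- simulate_genotypes(ped, snps, seed = 2)
  model <- scenario_library("homogeneous", snps = snps, beta = 1)
  pheno <- simulate_phenotypes(ped, geno, model,
                               schedule = one_exam_schedule(), seed = 5)
  r <- fit_additive_baseline(pheno, geno, "snp1",
                             covariates = c("age", "sex", "wga"))
  d <- pheno
  d$dosage <- geno[match(d$individual_id, rownames(geno)), "snp1"]
  X <- cbind(dosage = d$dosage, age = d$age_at_exam,
             sexW = as.numeric(d$sex == "W"), wga = as.numeric(d$wga))
  # age and wga vary; sex varies; all covariates retained
  o <- ols_oracle(X, transform_tc(d$tc_mgdl))
  expect_equal(r$beta, unname(o$beta["dosage"]), tolerance = 1e-6)
  expect_equal(r$se, unname(o$se["dosage"]), tolerance = 1e-6)
})

test_that("cumulative fit collapses to the baseline fit with one exam", {
  ped <- simulate_pedigree(80, seed = 4)
  snps <- data.frame(snp_id = "snp1", maf = 0.3)
  geno <- simulate_genotypes(ped, snps, seed = 5)
  model <- scenario_library("homogeneous", snps = snps, beta = 1,
                            varcomp = c(family = 11, subject = 0,
                                        residual = 61))
  pheno <- simulate_phenotypes(ped, geno, model,
                               schedule = data.frame(
                                 generation = 1:3, n_exams = 1L,
                                 spacing_years = 0,
                                 baseline_year = c(1948, 1971, 2002)),
                               seed = 6)
  rb <- fit_additive_baseline(pheno, geno, "snp1")
  rc <- fit_additive_cumulative(pheno, geno, "snp1")
  expect_equal(rc$beta, rb$beta, tolerance = 1e-6)
  expect_equal(rc$se, rb$se, tolerance = 1e-6)
  expect_equal(rc$p_value, rb$p_value, tolerance = 1e-6)
})

test_that("reported p-values are the two-sided normal Wald tail", {
  coh <- planted_cohort(50, beta = 0.5, seed = 9)
  r <- rbind(
    fit_additive_baseline(coh$phenotypes, coh$genotypes, "snp1"),
    fit_additive_cumulative(coh$phenotypes, coh$genotypes, "snp1"))
  expect_equal(r$p_value, 2 * pnorm(-abs(r$beta / r$se)), tolerance = 1e-12)
  expect_true(all(r$se > 0))
})

test_that("outputs are invariant to record order and scale-equivariant", {
  coh <- planted_cohort(60, beta = 0.8, seed = 12)
  ph <- coh$phenotypes
  r1 <- fit_additive_cumulative(ph, coh$genotypes, "snp1")
  set.seed(1)
  r2 <- fit_additive_cumulative(ph[sample(nrow(ph)), ], coh$genotypes,
                                "snp1")
  expect_equal(r1$beta, r2$beta, tolerance = 1e-8)
  expect_equal(r1$se, r2$se, tolerance = 1e-8)

  # TC -> TC^k multiplies the transformed response by k
  k <- 2.5
  ph_k <- ph
  ph_k$tc_mgdl <- ph$tc_mgdl^k
  rk <- fit_additive_cumulative(ph_k, coh$genotypes, "snp1")
  expect_equal(rk$beta / r1$beta, k, tolerance = 1e-8)
  expect_equal(rk$se / r1$se, k, tolerance = 1e-8)
  expect_equal(rk$p_value, r1$p_value, tolerance = 1e-8)
})

test_that("degenerate predictors raise errors", {
  coh <- planted_cohort(20, beta = 0, seed = 21)
  geno_const <- coh$genotypes
  geno_const[] <- 1L
  expect_error(fit_additive_baseline(coh$phenotypes, geno_const, "snp1"),
               "degenerate predictor")
  ph <- coh$phenotypes
  ph$lipid_treatment <- TRUE
  expect_error(covariate_effect_test(ph[ph$exam_index == 1, ], "treatment"),
               "single level")
})

test_that("a planted treatment shift is recovered by the covariate test", {
  snps <- data.frame(snp_id = "snp1", maf = 0.3)
  shift <- 2.2  # transformed units, ~ +10 mg/dL at the population mean
  hits <- 0
  betas <- ses <- numeric(0)
  for (s in 1:30) {
    model <- scenario_library("homogeneous", snps = snps, beta = 0,
                              treatment_effect = shift,
                              treatment_prob = c(0.3, 0.3, 0.3))
    coh <- simulate_cohort(100, model = model, snps = snps, seed = 100 + s,
                           schedule = one_exam_schedule(1:3))
    r <- covariate_effect_test(coh$phenotypes, "treatment",
                               covariates = c("age", "sex", "generation"))
    if (abs(r$beta - shift) <= 2 * r$se) hits <- hits + 1
    betas <- c(betas, r$beta); ses <- c(ses, r$se)
  }
  expect_gte(hits, 25)
  # unbiasedness of the recovered shift
  expect_lt(abs(mean(betas) - shift), 3 * mean(ses) / sqrt(30))
})

test_that("fasting status acts through the dichotomized flag", {
  snps <- data.frame(snp_id = "snp1", maf = 0.3)
  model <- scenario_library("homogeneous", snps = snps, beta = 0)
  coh <- simulate_cohort(80, model = model, snps = snps, seed = 31,
                         schedule = one_exam_schedule(1:3))
  r <- covariate_effect_test(coh$phenotypes, "fasting")
  expect_equal(r$snp_id, "fasting")
  expect_true(is.finite(r$p_value))
  ph2 <- coh$phenotypes
  ph2$fasting_hours <- 14
  expect_error(covariate_effect_test(ph2, "fasting"), "single level")
})
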