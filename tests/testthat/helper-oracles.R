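# Independent oracles and fixture builders shared across test files.

# Ordinary least squares via explicit normal equations (independent of the
# package's fitting path and of lm()).
ols_oracle <- function(X, y) {
  X <- cbind(`(Intercept)` = 1, X)
  xtx <- crossprod(X)
  beta <- solve(xtx, crossprod(X, y))
  res <- y - X %*% beta
  s2 <- sum(res^2) / (nrow(X) - ncol(X))
  se <- sqrt(diag(solve(xtx)) * s2)
  list(beta = drop(beta), se = se)
}

# Brute-force S/W partition oracle: enumerate S candidates with utils::combn,
# recomputing pooling/Q/I2 with formulas written out independently.
brute_partition_sw <- function(cell_results, reference_beta, tol = 1e-8) {
  cr <- cell_results[is.finite(cell_results$beta) &
                       is.finite(cell_results$se), , drop = FALSE]
  k <- nrow(cr)
  pool <- function(b, s) {
    w <- s^-2
    list(beta = sum(b * w) / sum(w), se = sum(w)^-0.5)
  }
  i2_of <- function(b, s) {
    if (length(b) < 2) return(0)
    w <- s^-2
    mu <- sum(b * w) / sum(w)
    q <- sum(w * (b - mu)^2)
    if (q <= 0) 0 else 100 * max(0, (q - (length(b) - 1)) / q)
  }
  cand <- NULL
  for (size in 1:(k - 1)) {
    for (j in seq_len(ncol(combn(k, size)))) {
      idx <- combn(k, size)[, j]
      ps <- pool(cr$beta[idx], cr$se[idx])
      if (sign(ps$beta) != sign(reference_beta)) next
      comp <- setdiff(seq_len(k), idx)
      pw <- pool(cr$beta[comp], cr$se[comp])
      cand <- rbind(cand, data.frame(
        key = paste(sort(cr$cell[idx]), collapse = "|"),
        i2_s = i2_of(cr$beta[idx], cr$se[idx]),
        i2_between = i2_of(c(ps$beta, pw$beta), c(ps$se, pw$se)),
        z_s = abs(ps$beta / ps$se),
        s_cells = paste(cr$cell[idx], collapse = ","),
        stringsAsFactors = FALSE))
    }
  }
  if (is.null(cand)) return(NULL)
  feas <- cand[cand$i2_s <= min(cand$i2_s) + tol, , drop = FALSE]
  feas <- feas[order(-feas$i2_between, -feas$z_s, feas$s_cells), ]
  feas[1, ]
}

# A cohort of unrelated adults (singleton families, one generation-1 exam
# row each) for fast null scans and power simulations. Built as a valid
# pedigree and run through the package generator.
unrelated_pedigree <- function(n, generation = 1L) {
  ped <- data.frame(
    id = sprintf("U%05d", seq_len(n)),
    family_id = sprintf("UF%05d", seq_len(n)),
    father_id = NA_character_, mother_id = NA_character_,
    sex = rep(c("M", "W"), length.out = n),
    generation = generation,
    birth_year = 1930L + seq_len(n) %% 40L,  # ages vary across members
    stringsAsFactors = FALSE)
  ped$age_at_biospecimen <- 1995L - ped$birth_year
  class(ped) <- c("pedigree", "data.frame")
  ped
}

# Effect model with one flat intercept in every cell (no age slope), so the
# unadjusted regression function is exactly intercept + beta * dosage.
flat_model <- function(snps, beta,
                       varcomp = c(family = 0, subject = 0, residual = 0),
                       intercept = 228) {
  scenario_library("homogeneous", snps = snps, beta = beta,
                   varcomp = varcomp, age_slope = 0,
                   intercepts = data.frame(
                     generation = rep(1:3, each = 2),
                     sex = rep(c("M", "W"), 3),
                     intercept = intercept, age_ref = 40))
}

# A demographic cell built directly (same shape as build_cells() output).
new_cell_for_test <- function(members, sex = "M", generation = 3,
                              stratum = "all") {
  list(sex = sex, generation = generation, age_stratum = stratum,
       label = paste0("gen", generation, "/", sex), members = members,
       n = length(members))
}

one_exam_schedule <- function(generation = 1L) {
  data.frame(generation = generation, n_exams = 1L, spacing_years = 0,
             baseline_year = 1995)
}

# Cohort with planted effect for recovery tests: n_families extended
# families, single focal SNP.
planted_cohort <- function(n_families, beta, seed, scenario = "homogeneous",
                           schedule = default_exam_schedule(),
                           varcomp = c(family = 11, subject = 32,
                                       residual = 29)) {
  snps <- data.frame(snp_id = "snp1", maf = 0.3)
  model <- scenario_library(scenario, snps = snps, beta = beta,
                            varcomp = varcomp)
  simulate_cohort(n_families, model = model, snps = snps, seed = seed,
                  schedule = schedule)
}
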