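# Synthetic three-generation cohort generator. All randomness is funnelled
# through local_seed() so identical (inputs, seed) give identical output
# without disturbing the caller's RNG state.

local_seed <- function(seed, env = parent.frame()) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv(), inherits = FALSE) else NULL
  restore <- if (is.null(old)) {
    quote(if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()))
  } else {
    bquote(assign(".Random.seed", .(old), envir = globalenv()))
  }
  do.call(on.exit, list(restore, add = TRUE), envir = env)
  set.seed(as.integer(seed))
  invisible(seed)
}

# Calendar year of DNA collection per generation. Collection happened late in
# follow-up for the first two generations and at the single baseline exam of
# the third, which places the age-at-biospecimen medians near the 60- and
# 40-year stratification cutoffs.
biospecimen_year <- c(`1` = 1995, `2` = 1997, `3` = 2002)

#' Simulate a three-generation pedigree
#'
#' Builds `n_families` independent extended families: a founder couple
#' (generation 1), their children plus married-in spouses (generation 2), and
#' the grandchildren (generation 3). Spouses are unrelated founders who share
#' the family id of the lineage they married into. Birth years are drawn per
#' generation and sex around the published cohort means (1911/1937/1963,
#' SDs 6/10/9 for men). Age at biospecimen collection is derived from fixed
#' per-generation collection years; with `survival_thinning = TRUE`,
#' generation-1 members may instead be recorded as deceased before collection
#' (missing age) with probability increasing in attained age.
#'
#' @param n_families number of families (>= 1).
#' @param offspring number of children per couple: a fixed non-negative
#'   integer, or a function `f(n)` returning `n` integer counts (default
#'   one plus a Poisson(1) draw).
#' @param seed integer seed; identical inputs and seed give identical output.
#' @param reference per-generation calibration table, see [cohort_reference()].
#' @param survival_thinning if `TRUE`, thin generation-1 members from
#'   biospecimen collection with age-dependent probability.
#' @return A data frame of class `pedigree`: `id`, `family_id`, `father_id`,
#'   `mother_id` (`NA` when absent), `sex` (`"M"`/`"W"`), `generation`,
#'   `birth_year`, `age_at_biospecimen` (`NA` if deceased before collection).
#' @export
#' @examples
#' ped <- simulate_pedigree(5, seed = 1)
#' table(ped$generation)
simulate_pedigree <- function(n_families, offspring = function(n) 1L + rpois(n, 1),
                              seed = 1L, reference = cohort_reference(),
                              survival_thinning = FALSE) {
  if (!is.numeric(n_families) || length(n_families) != 1 || n_families < 1)
    stop("n_families must be a positive integer", call. = FALSE)
  n_families <- as.integer(n_families)
  draw_k <- if (is.function(offspring)) {
    offspring
  } else if (is.numeric(offspring) && length(offspring) == 1 && offspring >= 0) {
    function(n) rep(as.integer(offspring), n)
  } else stop("offspring must be a count or a function(n)", call. = FALSE)

  local_seed(seed)
  birth_year <- function(gen, sex) {
    ref <- reference[reference$generation == gen & reference$sex == sex, ]
    round(rnorm(length(sex), ref$birth_mean[match(sex, ref$sex)][1],
                ref$birth_sd[1]))
  }
  rows <- vector("list", n_families)
  for (f in seq_len(n_families)) {
    fid <- sprintf("F%04d", f)
    nid <- 0L
    new_id <- function() {
      nid <<- nid + 1L
      sprintf("%s_I%03d", fid, nid)
    }
    fa1 <- new_id(); mo1 <- new_id()
    recs <- list(
      data.frame(id = fa1, family_id = fid, father_id = NA_character_,
                 mother_id = NA_character_, sex = "M", generation = 1L,
                 birth_year = birth_year(1, "M"), stringsAsFactors = FALSE),
      data.frame(id = mo1, family_id = fid, father_id = NA_character_,
                 mother_id = NA_character_, sex = "W", generation = 1L,
                 birth_year = birth_year(1, "W"), stringsAsFactors = FALSE)
    )
    k1 <- draw_k(1)
    for (c1 in seq_len(k1)) {
      child <- new_id()
      csex <- sample(c("M", "W"), 1)
      recs[[length(recs) + 1L]] <- data.frame(
        id = child, family_id = fid, father_id = fa1, mother_id = mo1,
        sex = csex, generation = 2L, birth_year = birth_year(2, csex),
        stringsAsFactors = FALSE)
      spouse <- new_id()
      ssex <- if (csex == "M") "W" else "M"
      recs[[length(recs) + 1L]] <- data.frame(
        id = spouse, family_id = fid, father_id = NA_character_,
        mother_id = NA_character_, sex = ssex, generation = 2L,
        birth_year = birth_year(2, ssex), stringsAsFactors = FALSE)
      fa2 <- if (csex == "M") child else spouse
      mo2 <- if (csex == "M") spouse else child
      k2 <- draw_k(1)
      for (c2 in seq_len(k2)) {
        gsex <- sample(c("M", "W"), 1)
        recs[[length(recs) + 1L]] <- data.frame(
          id = new_id(), family_id = fid, father_id = fa2, mother_id = mo2,
          sex = gsex, generation = 3L, birth_year = birth_year(3, gsex),
          stringsAsFactors = FALSE)
      }
    }
    rows[[f]] <- do.call(rbind, recs)
  }
  ped <- do.call(rbind, rows)
  rownames(ped) <- NULL
  ped$age_at_biospecimen <-
    unname(biospecimen_year[as.character(ped$generation)]) - ped$birth_year
  if (survival_thinning) {
    g1 <- ped$generation == 1L
    p_dead <- pmin(1, pmax(0, (ped$age_at_biospecimen[g1] - 70) / 40))
    dead <- runif(sum(g1)) < p_dead
    ped$age_at_biospecimen[g1][dead] <- NA_real_
  }
  class(ped) <- c("pedigree", "data.frame")
  ped
}

#' Validate pedigree structure
#'
#' Checks id uniqueness, parent references, generation ordering of parents,
#' and that founders carry no parent ids.
#'
#' @param ped a pedigree data frame.
#' @return `ped`, invisibly; stops on violation.
#' @export
validate_pedigree <- function(ped) {
  req <- c("id", "family_id", "father_id", "mother_id", "sex", "generation")
  if (!all(req %in% names(ped)))
    stop("pedigree is missing columns: ",
         paste(setdiff(req, names(ped)), collapse = ", "), call. = FALSE)
  if (anyDuplicated(ped$id))
    stop("duplicate individual ids in pedigree", call. = FALSE)
  for (col in c("father_id", "mother_id")) {
    known <- is.na(ped[[col]]) | ped[[col]] %in% ped$id
    if (!all(known))
      stop("unknown ", col, " reference: ",
           ped[[col]][!known][1], call. = FALSE)
    has <- !is.na(ped[[col]])
    pg <- ped$generation[match(ped[[col]][has], ped$id)]
    if (any(pg != ped$generation[has] - 1L))
      stop("parent generation must be child generation - 1", call. = FALSE)
  }
  invisible(ped)
}

#' Simulate minor-allele dosages over a pedigree
#'
#' Founders (individuals without recorded parents) are drawn in
#' Hardy-Weinberg equilibrium at each SNP's minor allele frequency; all
#' other individuals receive one allele from each parent by Mendelian
#' transmission, so parent-offspring consistency holds exactly.
#'
#' @param ped pedigree from [simulate_pedigree()] (or equivalent).
#' @param snps data frame with columns `snp_id` and `maf` (each MAF in
#'   (0, 0.5]), e.g. [lipid_snps()].
#' @param seed integer seed.
#' @param missing_rate proportion of entries set missing completely at
#'   random (default 0).
#' @return Integer matrix of dosages (0/1/2, `NA` = missing) with rows named
#'   by individual id and columns by `snp_id`.
#' @export
simulate_genotypes <- function(ped, snps, seed = 1L, missing_rate = 0) {
  validate_pedigree(ped)
  stopifnot(is.data.frame(snps), all(c("snp_id", "maf") %in% names(snps)))
  if (any(snps$maf <= 0 | snps$maf > 0.5))
    stop("maf must lie in (0, 0.5]", call. = FALSE)
  local_seed(seed)
  n <- nrow(ped)
  founder <- is.na(ped$father_id) & is.na(ped$mother_id)
  ord <- order(ped$generation)      # parents resolved before children
  geno <- matrix(NA_integer_, n, nrow(snps),
                 dimnames = list(ped$id, snps$snp_id))
  fa_idx <- match(ped$father_id, ped$id)
  mo_idx <- match(ped$mother_id, ped$id)
  for (s in seq_len(nrow(snps))) {
    maf <- snps$maf[s]
    dos <- integer(n)
    dos[founder] <- rbinom(sum(founder), 2L, maf)
    for (i in ord[!founder[ord]]) {
      dos[i] <- rbinom(1L, 1L, dos[fa_idx[i]] / 2) +
                rbinom(1L, 1L, dos[mo_idx[i]] / 2)
    }
    geno[, s] <- dos
  }
  if (missing_rate > 0) {
    drop <- runif(length(geno)) < missing_rate
    geno[drop] <- NA_integer_
  }
  geno
}

c_log10 <- log(10) / 100  # d ln(TC) per unit of 100*log10(TC)

#' Calibrate cell intercepts to target raw-scale TC moments
#'
#' Matches the mean of back-transformed TC exactly under the lognormal model
#' used by the generator: if `100*log10(TC)` is normal with total variance
#' `v_total`, the intercept `100*log10(m) - v_total * log(10)/200` gives
#' raw-scale mean `m`.
#'
#' @param tc_mean target raw-scale mean (mg/dL).
#' @param v_total total variance of the transformed value (includes variance
#'   contributed by the age slope across individuals).
#' @return Intercept on the 100*log10 scale.
#' @export
calibrate_intercept <- function(tc_mean, v_total) {
  stopifnot(tc_mean > 0, v_total >= 0)
  100 * log10(tc_mean) - v_total * c_log10 / 2
}

#' Construct an effect model for the phenotype generator
#'
#' The generator works on the analysis scale, `y = 100*log10(TC)`:
#' \deqn{y = intercept(sex, gen) + slope (age - age_{ref}) + \beta(snp, sex,
#'   gen, stratum) dosage + u_{family} + u_{subject} + e}
#' so fitted mixed models are exactly correctly specified. Intercepts are
#' calibrated to the published per-cell TC means by lognormal moment
#' matching unless supplied.
#'
#' @param effects data frame of genetic effects with columns `snp_id`, `sex`
#'   (`"M"`, `"W"`, or `"both"`), `generation` (1/2/3, or 0 for any),
#'   `age_stratum` (`"younger"`, `"older"`, or `"all"`), `beta` (units of
#'   100*log10(mg/dL) per minor allele). The most specific matching row wins;
#'   SNPs with no matching row contribute nothing.
#' @param varcomp named numeric: variances `family`, `subject`, `residual`
#'   on the transformed scale (all >= 0).
#' @param age_slope slope per year of age on the transformed scale.
#' @param age_cutoffs named numeric, per-generation age-at-biospecimen
#'   cutoffs defining `younger` (< cutoff) vs `older` (>= cutoff) strata.
#' @param intercepts optional data frame `generation`, `sex`, `intercept`,
#'   `age_ref`; defaults to calibration against [cohort_reference()].
#' @param fasting_prob,fasting_unknown_rate per-generation probability that
#'   a record is a fasting draw, and rate of unknown fasting status.
#' @param treatment_prob per-generation lifetime probability of starting
#'   lipid-lowering treatment during follow-up.
#' @param treatment_effect additive shift (transformed scale) applied to
#'   records under treatment (default 0).
#' @param wga_prob probability a subject's DNA sample was whole-genome
#'   amplified.
#' @param secular_slope additional trend per birth year (transformed scale),
#'   on top of the generation-specific intercepts (default 0).
#' @param reference calibration table, see [cohort_reference()].
#' @return An object of class `effect_model`.
#' @export
effect_model <- function(effects,
                         varcomp = c(family = 11, subject = 32, residual = 29),
                         age_slope = 0.25,
                         age_cutoffs = c(`2` = 60, `3` = 40),
                         intercepts = NULL,
                         fasting_prob = c(0.10, 0.85, 0.90),
                         fasting_unknown_rate = 0.05,
                         treatment_prob = c(0.02, 0.08, 0.10),
                         treatment_effect = 0,
                         wga_prob = 0.10,
                         secular_slope = 0,
                         reference = cohort_reference()) {
  stopifnot(is.data.frame(effects),
            all(c("snp_id", "sex", "generation", "age_stratum", "beta")
                %in% names(effects)))
  varcomp <- varcomp[c("family", "subject", "residual")]
  if (any(is.na(varcomp)) || any(varcomp < 0))
    stop("varcomp must supply non-negative family/subject/residual variances",
         call. = FALSE)
  if (is.null(intercepts)) {
    # centre the age slope at the structural mean age at baseline
    # (baseline year minus mean birth year) so the slope contributes no
    # mean shift; its variance across individuals (age SD at a fixed exam
    # year = birth-year SD) enters the lognormal mean correction
    sched <- default_exam_schedule()
    base_year <- sched$baseline_year[match(reference$generation,
                                           sched$generation)]
    v_tot <- sum(varcomp) + age_slope^2 * reference$birth_sd^2
    intercepts <- data.frame(
      generation = reference$generation, sex = reference$sex,
      intercept = mapply(calibrate_intercept, reference$tc_mean, v_tot),
      age_ref = base_year - reference$birth_mean, stringsAsFactors = FALSE)
  }
  structure(list(effects = effects, varcomp = varcomp,
                 age_slope = age_slope, age_cutoffs = age_cutoffs,
                 intercepts = intercepts,
                 fasting_prob = fasting_prob,
                 fasting_unknown_rate = fasting_unknown_rate,
                 treatment_prob = treatment_prob,
                 treatment_effect = treatment_effect,
                 wga_prob = wga_prob, secular_slope = secular_slope),
            class = "effect_model")
}

#' @exportS3Method base::print
print.effect_model <- function(x, ...) {
  cat("<effect_model>\n")
  cat("  variance components (100*log10 scale):",
      paste(names(x$varcomp), round(x$varcomp, 2), sep = "=",
            collapse = ", "), "\n")
  cat("  age slope:", x$age_slope, "per year;  secular slope:",
      x$secular_slope, "per birth year\n")
  cat("  genetic effects:", nrow(x$effects), "rows over",
      length(unique(x$effects$snp_id)), "SNPs\n")
  invisible(x)
}

# Age stratum of each individual given per-generation cutoffs.
age_stratum_of <- function(generation, age_at_biospecimen, age_cutoffs) {
  out <- rep("all", length(generation))
  cut <- age_cutoffs[as.character(generation)]
  known <- !is.na(cut) & !is.na(age_at_biospecimen)
  out[known] <- ifelse(age_at_biospecimen[known] < cut[known],
                       "younger", "older")
  out
}

# Per-individual beta for one SNP: the most specific matching effects row.
beta_lookup <- function(eff, snp, sex, generation, stratum) {
  rows <- eff[eff$snp_id == snp, , drop = FALSE]
  beta <- numeric(length(sex))
  if (nrow(rows) == 0) return(beta)
  best <- rep(-1L, length(sex))
  for (r in seq_len(nrow(rows))) {
    ok <- (rows$sex[r] == "both" | rows$sex[r] == sex) &
          (rows$generation[r] == 0 | rows$generation[r] == generation) &
          (rows$age_stratum[r] == "all" | rows$age_stratum[r] == stratum)
    spec <- (rows$sex[r] != "both") + (rows$generation[r] != 0) +
            (rows$age_stratum[r] != "all")
    take <- ok & spec > best
    beta[take] <- rows$beta[r]
    best[take] <- spec
  }
  beta
}

#' Simulate repeated total-cholesterol phenotypes
#'
#' Generates the long-format phenotype table: one row per individual x exam
#' following the per-generation exam schedule. The transformed value is built
#' additively from the effect-model components (cell intercept, centred age
#' slope, secular birth-year trend, per-SNP genetic effects, family and
#' subject random effects, residual, treatment shift) and back-transformed to
#' mg/dL. Repeated records of one individual share the subject and family
#' effects.
#'
#' @param ped pedigree.
#' @param geno dosage matrix from [simulate_genotypes()].
#' @param model an [effect_model()].
#' @param schedule exam schedule table, see [default_exam_schedule()].
#' @param seed integer seed.
#' @param missing_rate per-record probability of a missing exam (MCAR,
#'   default 0).
#' @return Data frame with columns `individual_id`, `family_id`, `sex`,
#'   `generation`, `birth_year`, `age_at_biospecimen`, `age_stratum`,
#'   `exam_index`, `age_at_exam` (years), `tc_mgdl`, `fasting_hours`
#'   (`NA` = unknown), `lipid_treatment`, `wga`.
#' @export
simulate_phenotypes <- function(ped, geno, model,
                                schedule = default_exam_schedule(),
                                seed = 1L, missing_rate = 0) {
  validate_pedigree(ped)
  stopifnot(inherits(model, "effect_model"))
  check_schedule(schedule)
  cells <- unique(ped[, c("sex", "generation")])
  key <- paste(model$intercepts$generation, model$intercepts$sex)
  miss <- !(paste(cells$generation, cells$sex) %in% key)
  if (any(miss))
    stop("effect model lacks intercepts for cell(s): ",
         paste(paste0("generation ", cells$generation[miss], "/",
                      cells$sex[miss]), collapse = ", "), call. = FALSE)

  local_seed(seed)
  n <- nrow(ped)
  fam <- factor(ped$family_id)
  u_fam <- rnorm(nlevels(fam), 0, sqrt(model$varcomp[["family"]]))[
    as.integer(fam)]
  u_sub <- rnorm(n, 0, sqrt(model$varcomp[["subject"]]))
  stratum <- age_stratum_of(ped$generation, ped$age_at_biospecimen,
                            model$age_cutoffs)
  # Genetic contribution: beta * dosage, centred on the cohort mean dosage
  # so nonzero effects do not drift the calibrated cell means (the dosage
  # coefficient recovered by the association models is unaffected).
  gshift <- numeric(n)
  snps <- intersect(unique(model$effects$snp_id), colnames(geno))
  for (s in snps) {
    b <- beta_lookup(model$effects, s, ped$sex, ped$generation, stratum)
    dos <- geno[ped$id, s]
    dos[is.na(dos)] <- 0L
    centre <- if (any(b != 0)) mean(dos) else 0
    gshift <- gshift + b * (dos - centre)
  }
  im <- match(paste(ped$generation, ped$sex), key)
  base <- model$intercepts$intercept[im] + gshift + u_fam + u_sub +
    model$secular_slope * (ped$birth_year -
                           mean(cohort_reference()$birth_mean))
  age_ref <- model$intercepts$age_ref[im]

  wga <- runif(n) < model$wga_prob
  treated_ever <- runif(n) < model$treatment_prob[ped$generation]

  si <- match(ped$generation, schedule$generation)
  n_ex <- schedule$n_exams[si]
  rows <- rep(seq_len(n), n_ex)
  exam <- sequence(n_ex)
  exam_year <- schedule$baseline_year[si][rows] +
    (exam - 1) * schedule$spacing_years[si][rows]
  age_at_exam <- exam_year - ped$birth_year[rows]
  onset <- ifelse(treated_ever, ceiling(runif(n) * n_ex), Inf)
  treated <- exam >= onset[rows]
  y <- base[rows] + model$age_slope * (age_at_exam - age_ref[rows]) +
    treated * model$treatment_effect +
    rnorm(length(rows), 0, sqrt(model$varcomp[["residual"]]))

  unknown <- runif(length(rows)) < model$fasting_unknown_rate
  fast <- runif(length(rows)) < model$fasting_prob[ped$generation[rows]]
  fasting_hours <- ifelse(fast, runif(length(rows), 12, 16),
                          runif(length(rows), 0, 10))
  fasting_hours[unknown] <- NA_real_

  pheno <- data.frame(
    individual_id = ped$id[rows],
    family_id = ped$family_id[rows],
    sex = ped$sex[rows],
    generation = ped$generation[rows],
    birth_year = ped$birth_year[rows],
    age_at_biospecimen = ped$age_at_biospecimen[rows],
    age_stratum = stratum[rows],
    exam_index = exam,
    age_at_exam = age_at_exam,
    tc_mgdl = 10^(y / 100),
    fasting_hours = round(fasting_hours, 1),
    lipid_treatment = treated,
    wga = wga[rows],
    stringsAsFactors = FALSE)
  if (missing_rate > 0)
    pheno <- pheno[runif(nrow(pheno)) >= missing_rate, , drop = FALSE]
  pheno <- pheno[order(pheno$individual_id, pheno$exam_index), ]
  rownames(pheno) <- NULL
  pheno
}

#' Library of genetic-effect scenarios
#'
#' Named effect structures covering the qualitative patterns seen in the
#' stratified re-analysis:
#' \describe{
#'   \item{homogeneous}{one effect `beta` in every sex x generation cell
#'     (set `beta = 0` for a global null).}
#'   \item{generation_clustered}{effect only in generation 3, mirroring the
#'     clustering of the strongest associations in the youngest cohort.}
#'   \item{antagonistic}{effect `+beta` everywhere except the younger
#'     generation-3 stratum, which gets `-beta` — the sign-reversing
#'     (protective vs detrimental) profile that cancels in pooled analysis.}
#'   \item{age_stratum}{effect confined to the younger age strata of
#'     generations 2 and 3.}
#' }
#'
#' @param name scenario name (see above).
#' @param snps SNP table (`snp_id`, `maf`); defaults to [lipid_snps()].
#' @param beta effect magnitude on the transformed scale (recycled over
#'   SNPs).
#' @param ... passed to [effect_model()] (variance components, prevalences,
#'   ...).
#' @return An [effect_model()].
#' @export
#' @examples
#' m <- scenario_library("antagonistic", beta = 2)
#' subset(m$effects, snp_id == "rs2479409")
scenario_library <- function(name, snps = lipid_snps(), beta = 2, ...) {
  stopifnot(is.character(name), length(name) == 1)
  beta <- rep_len(beta, nrow(snps))
  row <- function(sex, generation, age_stratum, b)
    data.frame(snp_id = snps$snp_id, sex = sex, generation = generation,
               age_stratum = age_stratum, beta = b,
               stringsAsFactors = FALSE)
  effects <- switch(
    name,
    homogeneous = row("both", 0, "all", beta),
    generation_clustered = rbind(row("both", 0, "all", 0),
                                 row("both", 3, "all", beta)),
    antagonistic = rbind(row("both", 0, "all", beta),
                         row("both", 3, "younger", -beta)),
    age_stratum = rbind(row("both", 0, "all", 0),
                        row("both", 2, "younger", beta),
                        row("both", 3, "younger", beta)),
    stop("unknown scenario: ", name, call. = FALSE))
  effect_model(effects, ...)
}

#' Simulate a complete cohort in one call
#'
#' Convenience wrapper chaining [simulate_pedigree()],
#' [simulate_genotypes()] and [simulate_phenotypes()] with sub-seeds derived
#' from `seed`.
#'
#' @inheritParams simulate_pedigree
#' @inheritParams simulate_genotypes
#' @param model an [effect_model()] or scenario name for
#'   [scenario_library()].
#' @param schedule exam schedule.
#' @param beta passed to [scenario_library()] when `model` is a name.
#' @return List with elements `pedigree`, `genotypes`, `phenotypes`,
#'   `model`, `seed`.
#' @export
simulate_cohort <- function(n_families, model = "homogeneous",
                            snps = lipid_snps(), seed = 1L, beta = 2,
                            schedule = default_exam_schedule(),
                            offspring = function(n) 1L + rpois(n, 1)) {
  if (is.character(model))
    model <- scenario_library(model, snps = snps, beta = beta)
  # decorrelated sub-seeds: consecutive master seeds must not share the
  # RNG streams of any stage
  sub <- (as.numeric(seed) * 48271 + c(11, 23, 37)) %% 2147483647
  ped <- simulate_pedigree(n_families, offspring = offspring, seed = sub[1])
  geno <- simulate_genotypes(ped, snps, seed = sub[2])
  pheno <- simulate_phenotypes(ped, geno, model, schedule = schedule,
                               seed = sub[3])
  list(pedigree = ped, genotypes = geno, phenotypes = pheno, model = model,
       seed = seed)
}
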