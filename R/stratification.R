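# Demographic cells and the SNP x cell association scan.

#' Build demographic cells
#'
#' Partitions the genotype-bearing individuals of a cohort into demographic
#' cells along the requested axes. With `axes = c("sex", "generation")` the
#' full grid of 2 sexes x 3 generations (6 cells) is returned; cells with no
#' members are retained with `n = 0` so a scan can report them as skipped.
#'
#' @param pheno long-format phenotype table (individual-level columns `sex`,
#'   `generation` are taken from it).
#' @param axes non-empty subset of `c("sex", "generation")`.
#' @return List of cells; each cell is a list with `sex` (`"M"`, `"W"` or
#'   `"both"`), `generation` (1/2/3 or `"pooled"`), `age_stratum`
#'   (`"all"`), `label`, `members` (individual ids) and `n`.
#' @export
#' @examples
#' coh <- simulate_cohort(5, seed = 1)
#' length(build_cells(coh$phenotypes))  # 6
build_cells <- function(pheno, axes = c("sex", "generation")) {
  if (length(axes) == 0)
    stop("axes must be non-empty", call. = FALSE)
  if (!all(axes %in% c("sex", "generation")))
    stop("unknown stratification axis: ",
         paste(setdiff(axes, c("sex", "generation")), collapse = ", "),
         call. = FALSE)
  ind <- pheno[!duplicated(pheno$individual_id),
               c("individual_id", "sex", "generation")]
  sexes <- if ("sex" %in% axes) c("M", "W") else "both"
  gens <- if ("generation" %in% axes) 1:3 else "pooled"
  cells <- list()
  for (g in gens) for (s in sexes) {
    keep <- rep(TRUE, nrow(ind))
    if (s != "both") keep <- keep & ind$sex == s
    if (!identical(g, "pooled")) keep <- keep & ind$generation == g
    cells[[length(cells) + 1L]] <- new_cell(s, g, "all",
                                            ind$individual_id[keep])
  }
  cells
}

new_cell <- function(sex, generation, age_stratum, members) {
  label <- paste0("gen", generation, "/", sex,
                  if (age_stratum != "all") paste0("/", age_stratum) else "")
  list(sex = sex, generation = generation, age_stratum = age_stratum,
       label = label, members = members, n = length(members))
}

#' Split a demographic cell at an age-at-biospecimen cutoff
#'
#' Members with known age at biospecimen collection are partitioned into a
#' `younger` stratum (age strictly below the cutoff) and an `older` stratum
#' (age at or above it). Members with unknown age are excluded, with a
#' message giving the count.
#'
#' @param cell a cell from [build_cells()].
#' @param pheno phenotype table carrying `age_at_biospecimen` per
#'   individual.
#' @param cutoff_years cutoff in years (the study medians are 40 for
#'   generation 3 and 60 for generation 2).
#' @return List with elements `younger` and `older`, each a cell.
#' @export
split_by_median_age <- function(cell, pheno, cutoff_years) {
  ind <- pheno[!duplicated(pheno$individual_id),
               c("individual_id", "age_at_biospecimen")]
  age <- ind$age_at_biospecimen[match(cell$members, ind$individual_id)]
  if (all(is.na(age)))
    stop("no member of cell ", cell$label,
         " has a known age at biospecimen collection", call. = FALSE)
  n_unknown <- sum(is.na(age))
  if (n_unknown > 0)
    message(n_unknown, " member(s) of ", cell$label,
            " excluded from age strata (unknown age at biospecimen)")
  known <- !is.na(age)
  list(
    younger = new_cell(cell$sex, cell$generation, "younger",
                       cell$members[known & age < cutoff_years]),
    older = new_cell(cell$sex, cell$generation, "older",
                     cell$members[known & age >= cutoff_years]))
}

#' Rank the exams of one cohort by age match to another
#'
#' Cross-generation comparisons must hold age at measurement comparable:
#' this ranks the exams of cohort B by the absolute difference between their
#' mean age at examination and the mean age at TC measurement in cohort A.
#' Ties break toward the lower exam index. The top-ranked exam is the
#' default selection, but all candidates are returned so a substantive
#' override (e.g. preferring the exam whose associations resemble the
#' cumulative estimates) stays possible.
#'
#' @param pheno_a phenotype records of the target cohort (its mean
#'   `age_at_exam` is the matching target).
#' @param pheno_b phenotype records of the cohort whose exams are ranked.
#' @param window_years candidates within this distance of the target are
#'   flagged (`within_window`), default 2.
#' @return List: `target_mean_age`, `ranking` (data frame `exam_index`,
#'   `mean_age`, `abs_diff`, `within_window`, ordered best first),
#'   `selected` (top-ranked exam index, `NA` if no candidate).
#' @export
match_age_cohorts <- function(pheno_a, pheno_b, window_years = 2) {
  if (nrow(pheno_b) == 0 || all(is.na(pheno_b$age_at_exam)))
    stop("cohort B has no exams with recorded ages", call. = FALSE)
  target <- mean(pheno_a$age_at_exam, na.rm = TRUE)
  means <- aggregate(age_at_exam ~ exam_index, data = pheno_b, FUN = mean)
  names(means) <- c("exam_index", "mean_age")
  means$abs_diff <- abs(means$mean_age - target)
  means <- means[order(means$abs_diff, means$exam_index), ]
  rownames(means) <- NULL
  means$within_window <- means$abs_diff <= window_years
  if (!any(means$within_window))
    warning("no exam of cohort B lies within ", window_years,
            " years of the target mean age (", round(target, 1), ")")
  list(target_mean_age = target, ranking = means,
       selected = means$exam_index[1])
}

#' Classify association p-values
#'
#' Pure function of the p-value and the two thresholds: `significant`
#' (p <= 0.05), `suggestive` (0.05 < p <= 0.1), otherwise `null`.
#'
#' @param p p-values.
#' @param thresholds named numeric with `significant < suggestive`.
#' @return Character vector of classes (`NA` input gives `NA`).
#' @export
classify_significance <- function(p, thresholds = c(significant = 0.05,
                                                    suggestive = 0.1)) {
  if (thresholds[["significant"]] >= thresholds[["suggestive"]])
    stop("significant threshold must be below suggestive threshold",
         call. = FALSE)
  ifelse(is.na(p), NA_character_,
         ifelse(p <= thresholds[["significant"]], "significant",
                ifelse(p <= thresholds[["suggestive"]], "suggestive",
                       "null")))
}

#' Scan SNPs across demographic cells
#'
#' Fits the additive association of every SNP in every cell and attaches the
#' significance class of each entry. Fit failures (e.g. a monomorphic SNP
#' within a small cell) are recorded per entry and the scan continues;
#' empty cells are skipped with a warning.
#'
#' @param pheno,geno cohort tables as in [fit_additive_baseline()].
#' @param snps character vector of SNP ids (default: all columns of
#'   `geno`).
#' @param cells list of cells from [build_cells()] /
#'   [split_by_median_age()].
#' @param model `"baseline"` (two-level) or `"cumulative"` (three-level).
#' @param covariates adjustment covariates passed to the fit (constant ones
#'   are dropped per cell).
#' @param thresholds significance thresholds, see
#'   [classify_significance()].
#' @param scale analysis scale.
#' @return Data frame of class `cell_scan`: one row per SNP x cell with
#'   `snp_id`, `sex`, `generation`, `age_stratum`, `cell`,
#'   `n_individuals`, `n_records`, `beta`, `se`, `p_value`, `class`,
#'   `model_level`, `scale`, `error` (`NA` if the fit succeeded).
#' @export
scan_cells <- function(pheno, geno, snps = colnames(geno), cells,
                       model = c("baseline", "cumulative"),
                       covariates = c("age", "wga"),
                       thresholds = c(significant = 0.05, suggestive = 0.1),
                       scale = "transformed") {
  model <- match.arg(model)
  fitter <- if (model == "baseline") fit_additive_baseline else
    fit_additive_cumulative
  level <- if (model == "baseline") "two_level" else "three_level"
  n_out <- length(cells) * length(snps)
  snp_v <- cell_v <- sex_v <- gen_v <- strat_v <- err_v <-
    character(n_out)
  n_ind <- n_rec <- integer(n_out)
  beta_v <- se_v <- p_v <- rep(NA_real_, n_out)
  i <- 0L
  for (cell in cells) {
    sub <- pheno[pheno$individual_id %in% cell$members, , drop = FALSE]
    for (snp in snps) {
      i <- i + 1L
      snp_v[i] <- snp; cell_v[i] <- cell$label; sex_v[i] <- cell$sex
      gen_v[i] <- as.character(cell$generation)
      strat_v[i] <- cell$age_stratum
      n_ind[i] <- cell$n
      err_v[i] <- NA_character_
      if (cell$n == 0) {
        warning("skipping empty cell ", cell$label, call. = FALSE)
        err_v[i] <- "empty cell"
        next
      }
      fit <- tryCatch(
        fitter(sub, geno, snp, covariates = covariates, scale = scale,
               cell = cell$label),
        error = function(e) conditionMessage(e))
      if (is.character(fit)) {
        err_v[i] <- fit
      } else {
        n_ind[i] <- fit$n_individuals; n_rec[i] <- fit$n_records
        beta_v[i] <- fit$beta; se_v[i] <- fit$se; p_v[i] <- fit$p_value
      }
    }
  }
  scan <- data.frame(
    snp_id = snp_v, sex = sex_v, generation = gen_v,
    age_stratum = strat_v, cell = cell_v, n_individuals = n_ind,
    n_records = n_rec, beta = beta_v, se = se_v, p_value = p_v,
    model_level = level, scale = scale, error = err_v,
    stringsAsFactors = FALSE)
  scan$class <- classify_significance(scan$p_value, thresholds)
  attr(scan, "thresholds") <- thresholds
  class(scan) <- c("cell_scan", "data.frame")
  scan
}

#' Summarize a cell scan
#'
#' @param scan a `cell_scan` from [scan_cells()].
#' @return List with `n_tests` (entries with a fitted p-value),
#'   `n_significant`, `n_suggestive`, and the per-class counts by
#'   generation.
#' @export
summarize_scan <- function(scan) {
  ok <- !is.na(scan$p_value)
  list(n_tests = sum(ok),
       n_significant = sum(scan$class[ok] == "significant"),
       n_suggestive = sum(scan$class[ok] == "suggestive"),
       by_generation = table(generation = scan$generation[ok],
                             class = scan$class[ok]))
}
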