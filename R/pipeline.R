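# End-to-end pipeline: simulation -> association -> scan -> heterogeneity
# -> power -> enrichment, with a machine-readable manifest. Outputs are a
# pure function of (config, seed): no timestamps, so repeated runs are
# byte-identical.

#' Default pipeline configuration
#'
#' @param seed master seed; every stage derives its randomness from it.
#' @param scenario scenario name for [scenario_library()].
#' @param n_families number of simulated families.
#' @param scenario_beta planted effect magnitude (transformed scale).
#' @param out_dir output directory.
#' @return Named list understood by [run_pipeline()]; thresholds,
#'   age cutoffs and power defaults can be edited before the run.
#' @export
default_config <- function(seed = 1L, scenario = "antagonistic",
                           n_families = 300L, scenario_beta = 2,
                           out_dir = "demostrat-run") {
  list(seed = as.integer(seed), scenario = scenario,
       scenario_beta = scenario_beta, n_families = as.integer(n_families),
       thresholds = c(significant = 0.05, suggestive = 0.1),
       age_cutoffs = c(`2` = 60, `3` = 40),
       power = list(alpha = 0.05, gw_alpha = 5e-8, power = 0.80,
                    trait_sd = 38),
       out_dir = out_dir)
}

#' Read a pipeline configuration from YAML
#'
#' Unspecified fields fall back to [default_config()] values.
#'
#' @param path YAML file.
#' @return Configuration list.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_config()
  for (nm in names(cfg)) base[[nm]] <- cfg[[nm]]
  if (!is.null(cfg$thresholds))
    base$thresholds <- unlist(cfg$thresholds)
  if (!is.null(cfg$age_cutoffs))
    base$age_cutoffs <- unlist(cfg$age_cutoffs)
  if (base$thresholds[["significant"]] >= base$thresholds[["suggestive"]])
    stop("config: significant threshold must be below suggestive",
         call. = FALSE)
  base
}

# Tiny stable FNV-1a hash of the deparsed configuration, for the manifest.
config_hash <- function(config) {
  txt <- paste(deparse(config[sort(names(config))]), collapse = "")
  h <- 2166136261
  for (b in utf8ToInt(txt)) {
    h <- bitwXor(h, b)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%08x", h)
}

#' Run the full demographic-stratification pipeline
#'
#' Simulates a cohort under the configured scenario, then reproduces the
#' analysis sequence of the study design: pooled baseline (raw and
#' transformed scale) and cumulative associations per SNP; the
#' sex-by-generation scan under both model levels with significance
#' classes; per-SNP S/W subsample partitions with within- and
#' between-group I-squared; additive-model sample-size projections at
#' nominal and genome-wide significance; and the enrichment-over-chance
#' summary of the scan. All tables are written as seed-stamped TSVs plus a
#' JSON manifest, and returned invisibly.
#'
#' Counts and the enrichment summary are based on the baseline-model scan
#' (one test per individual per cell, the standard design for counting
#' independent tests); the cumulative scan is written alongside and the
#' manifest records which scan fed the enrichment.
#'
#' @param config configuration list from [default_config()] /
#'   [read_config()].
#' @return Invisible list with every table plus the manifest.
#' @export
run_pipeline <- function(config = default_config()) {
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  snps <- lipid_snps()
  coh <- stage("simulate", {
    model <- scenario_library(config$scenario, snps = snps,
                              beta = config$scenario_beta,
                              age_cutoffs = config$age_cutoffs)
    simulate_cohort(config$n_families, model = model, snps = snps,
                    seed = seed)
  })
  write_pedigree(coh$pedigree, file.path(out, "pedigree.fam"), seed)
  write_genotypes(coh$genotypes, file.path(out, "genotypes.tsv"), seed)
  write_phenotypes(coh$phenotypes, file.path(out, "phenotypes.tsv"), seed)

  pooled <- stage("association", {
    do.call(rbind, lapply(snps$snp_id, function(s) rbind(
      fit_additive_baseline(coh$phenotypes, coh$genotypes, s,
                            scale = "raw"),
      fit_additive_baseline(coh$phenotypes, coh$genotypes, s,
                            scale = "transformed"),
      fit_additive_cumulative(coh$phenotypes, coh$genotypes, s,
                              scale = "transformed"))))
  })
  write.table(pooled, file.path(out, "pooled_associations.tsv"),
              quote = FALSE, sep = "\t", row.names = FALSE)

  cells <- build_cells(coh$phenotypes)
  scan_base <- stage("scan", {
    scan_cells(coh$phenotypes, coh$genotypes, cells = cells,
               model = "baseline", thresholds = config$thresholds)
  })
  scan_cum <- stage("scan", {
    scan_cells(coh$phenotypes, coh$genotypes, cells = cells,
               model = "cumulative", thresholds = config$thresholds)
  })
  write_scan(scan_base, file.path(out, "scan_sex_generation_baseline.tsv"),
             seed)
  write_scan(scan_cum, file.path(out, "scan_sex_generation_cumulative.tsv"),
             seed)

  partitions <- stage("heterogeneity", {
    lapply(setNames(nm = snps$snp_id), function(s) {
      sub <- scan_cum[scan_cum$snp_id == s & !is.na(scan_cum$beta), ]
      if (nrow(sub) < 3) return(NULL)
      partition_sw(sub[, c("cell", "beta", "se")],
                   reference_beta = snps$beta_meta[snps$snp_id == s])
    })
  })
  part_tab <- do.call(rbind, lapply(names(partitions), function(s) {
    p <- partitions[[s]]
    if (is.null(p)) return(NULL)
    data.frame(snp_id = s, flag = p$flag,
               s_cells = paste(p$s_cells, collapse = ","),
               w_cells = paste(p$w_cells, collapse = ","),
               i2_s_pct = p$i2_s, i2_w_pct = p$i2_w,
               i2_between_pct = p$i2_between,
               s_beta = p$s_pooled$beta, s_se = p$s_pooled$se,
               s_p = p$s_pooled$p_value,
               w_beta = p$w_pooled$beta, w_se = p$w_pooled$se,
               w_p = p$w_pooled$p_value, stringsAsFactors = FALSE)
  }))
  write.table(part_tab, file.path(out, "sw_partitions.tsv"), quote = FALSE,
              sep = "\t", row.names = FALSE)

  power_tab <- stage("power", {
    obs <- pooled[pooled$scale == "raw" & pooled$model_level == "two_level",
                  c("snp_id", "beta")]
    obs$maf <- snps$maf[match(obs$snp_id, snps$snp_id)]
    obs <- obs[obs$beta != 0, ]
    cbind(source = "pooled_baseline_raw",
          project_sample_sizes(obs, trait_sd = config$power$trait_sd,
                               alpha = config$power$alpha,
                               power = config$power$power,
                               gw_alpha = config$power$gw_alpha))
  })
  meta_tab <- cbind(source = "meta_analysis",
                    project_sample_sizes(
                      data.frame(snp_id = snps$snp_id,
                                 beta = snps$beta_meta, maf = snps$maf),
                      trait_sd = config$power$trait_sd,
                      alpha = config$power$alpha,
                      power = config$power$power,
                      gw_alpha = config$power$gw_alpha))
  power_all <- rbind(meta_tab, power_tab)
  write.table(power_all, file.path(out, "power_projections.tsv"),
              quote = FALSE, sep = "\t", row.names = FALSE)

  enrich <- stage("enrichment", {
    enrichment_summary(scan_base,
                       alpha = config$thresholds[["significant"]])
  })
  write.table(enrich, file.path(out, "enrichment.tsv"), quote = FALSE,
              sep = "\t", row.names = FALSE)

  manifest <- list(
    seed = seed, scenario = config$scenario,
    n_families = config$n_families,
    package_version = as.character(utils::packageVersion("demostrat")),
    config_hash = config_hash(config),
    enrichment_scan = "baseline",
    outputs = c("pedigree.fam", "genotypes.tsv", "phenotypes.tsv",
                "pooled_associations.tsv",
                "scan_sex_generation_baseline.tsv",
                "scan_sex_generation_cumulative.tsv", "sw_partitions.tsv",
                "power_projections.tsv", "enrichment.tsv"))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(cohort = coh, pooled = pooled, scan_baseline = scan_base,
                 scan_cumulative = scan_cum, partitions = partitions,
                 partition_table = part_tab, power = power_all,
                 enrichment = enrich, manifest = manifest))
}
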