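# Analytic power and sample-size projection for a quantitative trait under
# the additive genetic model with unrelated individuals.

#' Phenotypic variance explained by an additive SNP effect
#'
#' Under Hardy-Weinberg equilibrium the dosage variance is
#' `2 * maf * (1 - maf)`, so an additive effect `beta` per minor allele
#' explains `v = 2 * maf * (1 - maf) * beta^2` of the trait variance.
#'
#' @param beta effect per minor allele (trait units).
#' @param maf minor allele frequency in (0, 0.5].
#' @return Variance explained, in squared trait units.
#' @export
#' @examples
#' variance_explained(1.96, 0.34)  # 1.724
variance_explained <- function(beta, maf) {
  stopifnot(is.finite(beta), is.finite(maf))
  if (maf <= 0 || maf > 0.5)
    stop("maf must lie in (0, 0.5]", call. = FALSE)
  2 * maf * (1 - maf) * beta^2
}

#' Sample size required to detect an additive SNP effect
#'
#' Normal-approximation sample size for a two-sided Wald test of an
#' additive genetic effect on a quantitative trait in unrelated
#' individuals:
#' \deqn{N = \lceil (z_{1-\alpha/2} + z_{power})^2 \sigma^2 / v \rceil}
#' with `v` the variance explained ([variance_explained()]) and
#' `sigma^2` the residual trait variance — by default the total trait
#' variance `trait_sd^2` (the most conservative choice for small `v`);
#' set `subtract_explained = TRUE` to use `trait_sd^2 - v`.
#'
#' Family clustering would inflate these numbers; they are the most
#' optimistic (minimal) sizes.
#'
#' @param beta effect per minor allele; the sign is irrelevant.
#' @param maf minor allele frequency in (0, 0.5].
#' @param trait_sd phenotype standard deviation in the same units as
#'   `beta` (default 38 mg/dL, the study's population TC SD around a mean
#'   of 194 mg/dL).
#' @param alpha two-sided significance level (0.05 nominal, 5e-8
#'   genome-wide).
#' @param power target power in (0, 1), default 0.80.
#' @param subtract_explained subtract the explained variance from the
#'   residual variance (default `FALSE`).
#' @return Required sample size (integer).
#' @export
#' @examples
#' required_n(1.96, 0.34)              # ~6.6k at nominal significance
#' required_n(1.96, 0.34, alpha = 5e-8)  # genome-wide projection
required_n <- function(beta, maf, trait_sd = 38, alpha = 0.05,
                       power = 0.80, subtract_explained = FALSE) {
  stopifnot(trait_sd > 0, alpha > 0, alpha < 1, power > 0, power < 1)
  v <- variance_explained(beta, maf)
  if (v <= 0)
    stop("infeasible: the SNP explains no variance (beta = 0)",
         call. = FALSE)
  sigma2 <- trait_sd^2 - if (subtract_explained) v else 0
  if (sigma2 <= 0)
    stop("infeasible: explained variance exceeds trait variance",
         call. = FALSE)
  as.integer(ceiling((qnorm(1 - alpha / 2) + qnorm(power))^2 * sigma2 / v))
}

#' Power achieved at a given sample size
#'
#' Inverse of [required_n()]:
#' `power = Phi(sqrt(n v / sigma^2) - z_{1-alpha/2})`.
#'
#' @inheritParams required_n
#' @param n sample size (>= 2).
#' @return Achieved power in (0, 1).
#' @export
#' @examples
#' power_at_n(required_n(1.96, 0.34), 1.96, 0.34)  # >= 0.80
power_at_n <- function(n, beta, maf, trait_sd = 38, alpha = 0.05,
                       subtract_explained = FALSE) {
  stopifnot(n >= 2, trait_sd > 0, alpha > 0, alpha < 1)
  v <- variance_explained(beta, maf)
  sigma2 <- trait_sd^2 - if (subtract_explained) v else 0
  pnorm(sqrt(n * v / sigma2) - qnorm(1 - alpha / 2))
}

#' Sample-size projections for a table of SNP effects
#'
#' Batch interface over [required_n()]: one projection per SNP at the
#' nominal and (optionally) genome-wide significance levels.
#'
#' @param snp_effects data frame with columns `snp_id`, `beta`, `maf`.
#' @param trait_sd,power as in [required_n()].
#' @param alpha nominal level (default 0.05).
#' @param gw_alpha genome-wide level (default 5e-8); set `NULL` to skip.
#' @return Data frame: `snp_id`, `beta`, `maf`, `variance_explained`,
#'   `n_nominal`, and `n_genome_wide` when requested.
#' @export
project_sample_sizes <- function(snp_effects, trait_sd = 38, alpha = 0.05,
                                 power = 0.80, gw_alpha = 5e-8) {
  stopifnot(all(c("snp_id", "beta", "maf") %in% names(snp_effects)))
  out <- data.frame(
    snp_id = snp_effects$snp_id, beta = snp_effects$beta,
    maf = snp_effects$maf,
    variance_explained = mapply(variance_explained, snp_effects$beta,
                                snp_effects$maf),
    n_nominal = mapply(required_n, snp_effects$beta, snp_effects$maf,
                       MoreArgs = list(trait_sd = trait_sd, alpha = alpha,
                                       power = power)),
    stringsAsFactors = FALSE)
  if (!is.null(gw_alpha))
    out$n_genome_wide <- mapply(required_n, snp_effects$beta,
                                snp_effects$maf,
                                MoreArgs = list(trait_sd = trait_sd,
                                                alpha = gw_alpha,
                                                power = power))
  out
}
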