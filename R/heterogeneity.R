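# Between-cell heterogeneity statistics and the strong/weak-support (S/W)
# subsample partition of demographic cells.

#' Cochran's Q for a set of effect estimates
#'
#' `Q = sum(w_i (b_i - b_hat)^2)` with inverse-variance weights
#' `w_i = 1/se_i^2` and `b_hat` the fixed-effect pooled estimate;
#' `df = k - 1`.
#'
#' @param betas effect estimates (length >= 2).
#' @param ses their standard errors (> 0).
#' @return List with `q` and `df`.
#' @export
#' @examples
#' cochran_q(c(1, 2), c(0.2, 0.2))  # q = 12.5, df = 1
cochran_q <- function(betas, ses) {
  if (length(betas) < 2)
    stop("need at least 2 effects for Cochran's Q", call. = FALSE)
  if (length(ses) != length(betas) || any(!is.finite(ses)) || any(ses <= 0))
    stop("ses must be positive and match betas in length", call. = FALSE)
  w <- 1 / ses^2
  bhat <- sum(w * betas) / sum(w)
  list(q = sum(w * (betas - bhat)^2), df = length(betas) - 1L)
}

#' Heterogeneity coefficient I-squared
#'
#' The percentage of total variability in a set of effect sizes that is due
#' to true between-sample heterogeneity rather than sampling error:
#' `I2 = 100 * max(0, (Q - df) / Q)`, and 0 when `Q = 0`.
#'
#' @param q Cochran's Q (>= 0).
#' @param df its degrees of freedom (>= 1).
#' @return I-squared in percent, in \[0, 100\].
#' @export
#' @examples
#' i_squared(12.5, 1)  # 92
i_squared <- function(q, df) {
  stopifnot(is.finite(q), q >= 0, df >= 1)
  if (q <= 0) return(0)
  100 * max(0, (q - df) / q)
}

#' Inverse-variance fixed-effect pooling
#'
#' @param betas effect estimates (length >= 1).
#' @param ses their standard errors (> 0).
#' @return List with `beta` (weighted mean) and `se`
#'   (`1/sqrt(sum(w_i))`).
#' @export
#' @examples
#' pool_fixed(c(1, 2), c(0.2, 0.2))  # beta 1.5, se 0.1414
pool_fixed <- function(betas, ses) {
  if (length(betas) < 1)
    stop("pool_fixed needs at least one effect", call. = FALSE)
  if (length(ses) != length(betas) || any(!is.finite(ses)) || any(ses <= 0))
    stop("ses must be positive and match betas in length", call. = FALSE)
  w <- 1 / ses^2
  list(beta = sum(w * betas) / sum(w), se = 1 / sqrt(sum(w)))
}

# I-squared between two pooled group estimates (df = 1).
i2_between_groups <- function(pool_s, pool_w) {
  q <- cochran_q(c(pool_s$beta, pool_w$beta), c(pool_s$se, pool_w$se))
  i_squared(q$q, q$df)
}

#' Partition demographic cells into S- and W-subsamples
#'
#' The S-subsample is the group of demographic cells whose effects are
#' homogeneous (within-group I-squared zero, or minimal when zero is not
#' attainable) and whose pooled effect carries the sign of the reference
#' (meta-analytic) effect — the cells giving the strongest support to the
#' reference association. The W-subsample is the complement, giving the
#' weakest support. Among feasible S candidates the partition maximizing
#' the between-group I-squared (computed on the two pooled estimates,
#' df = 1) is chosen; ties break toward the larger |pooled z| of S, then
#' toward the lexicographically first cell set.
#'
#' All `2^k - 2` ordered bipartitions are enumerated, which is exact for
#' the at most 6-12 cells a demographic scan produces.
#'
#' @param cell_results data frame with columns `cell`, `beta`, `se` (one
#'   row per demographic cell; rows with missing estimates are dropped).
#' @param reference_beta signed reference effect (non-zero), e.g. the
#'   meta-analytic beta of the SNP.
#' @param i2_tol within-group I-squared within `i2_tol` of the minimum
#'   counts as minimal (default 1e-8).
#' @return Object of class `sw_partition`: `s_cells`, `w_cells`,
#'   `i2_s`, `i2_w`, `i2_between`, `s_pooled` / `w_pooled` (lists with
#'   `beta`, `se`, `z`, `p_value`), `flag` (`"ok"`, `"degenerate"` when
#'   no between-group heterogeneity exists, `"no-support"` when no
#'   sign-concordant group exists), and `candidates` (data frame of all
#'   feasible S candidates for audit).
#' @export
partition_sw <- function(cell_results, reference_beta, i2_tol = 1e-8) {
  stopifnot(is.data.frame(cell_results),
            all(c("cell", "beta", "se") %in% names(cell_results)))
  if (!is.finite(reference_beta) || reference_beta == 0)
    stop("reference_beta must be non-zero", call. = FALSE)
  cr <- cell_results[is.finite(cell_results$beta) &
                       is.finite(cell_results$se), , drop = FALSE]
  k <- nrow(cr)
  if (k < 3)
    stop("partition_sw needs at least 3 cells with estimates", call. = FALSE)
  ref_sign <- sign(reference_beta)

  subset_stats <- function(idx) {
    pool <- pool_fixed(cr$beta[idx], cr$se[idx])
    i2 <- if (length(idx) < 2) 0 else {
      q <- cochran_q(cr$beta[idx], cr$se[idx])
      i_squared(q$q, q$df)
    }
    list(pool = pool, i2 = i2)
  }

  cand <- list()
  for (m in seq_len(2^k - 2)) {
    s_idx <- which(bitwAnd(m, bitwShiftL(1L, seq_len(k) - 1L)) != 0L)
    s <- subset_stats(s_idx)
    if (sign(s$pool$beta) != ref_sign) next
    w_idx <- setdiff(seq_len(k), s_idx)
    w <- subset_stats(w_idx)
    cand[[length(cand) + 1L]] <- data.frame(
      mask = m, size = length(s_idx), i2_s = s$i2, i2_w = w$i2,
      i2_between = i2_between_groups(s$pool, w$pool),
      s_beta = s$pool$beta, s_se = s$pool$se,
      w_beta = w$pool$beta, w_se = w$pool$se,
      s_cells = paste(cr$cell[s_idx], collapse = ","),
      stringsAsFactors = FALSE)
  }

  if (length(cand) == 0) {
    # no sign-concordant group at all: best singleton by signed z
    z <- ref_sign * cr$beta / cr$se
    i <- which.max(z)
    s_idx <- i; w_idx <- setdiff(seq_len(k), i)
    s <- subset_stats(s_idx); w <- subset_stats(w_idx)
    return(sw_result(cr, s_idx, w_idx, s, w, "no-support",
                     data.frame()))
  }

  cand <- do.call(rbind, cand)
  feasible <- cand[cand$i2_s <= min(cand$i2_s) + i2_tol, , drop = FALSE]
  zs <- abs(feasible$s_beta / feasible$s_se)
  ord <- order(-feasible$i2_between, -zs, feasible$s_cells)
  best <- feasible[ord[1], ]
  s_idx <- which(bitwAnd(best$mask, bitwShiftL(1L, seq_len(k) - 1L)) != 0L)
  w_idx <- setdiff(seq_len(k), s_idx)
  s <- subset_stats(s_idx); w <- subset_stats(w_idx)
  flag <- if (best$i2_between <= 0) "degenerate" else "ok"
  sw_result(cr, s_idx, w_idx, s, w, flag, feasible)
}

sw_result <- function(cr, s_idx, w_idx, s, w, flag, candidates) {
  as_pool <- function(p) {
    z <- p$pool$beta / p$pool$se
    list(beta = p$pool$beta, se = p$pool$se, z = z,
         p_value = 2 * pnorm(-abs(z)))
  }
  structure(list(
    s_cells = cr$cell[s_idx], w_cells = cr$cell[w_idx],
    i2_s = s$i2, i2_w = w$i2,
    i2_between = i2_between_groups(s$pool, w$pool),
    s_pooled = as_pool(s), w_pooled = as_pool(w),
    flag = flag, candidates = candidates), class = "sw_partition")
}

#' @exportS3Method base::print
print.sw_partition <- function(x, ...) {
  cat("<sw_partition>", x$flag, "\n")
  cat("  S:", paste(x$s_cells, collapse = ", "),
      sprintf("(pooled beta %.3f, se %.3f, I2 %.1f%%)\n",
              x$s_pooled$beta, x$s_pooled$se, x$i2_s))
  cat("  W:", paste(x$w_cells, collapse = ", "),
      sprintf("(pooled beta %.3f, se %.3f, I2 %.1f%%)\n",
              x$w_pooled$beta, x$w_pooled$se, x$i2_w))
  cat(sprintf("  between-group I2: %.1f%%\n", x$i2_between))
  invisible(x)
}
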