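# Enrichment of observed significant associations over chance expectation.

#' Expected number of significant tests by chance
#'
#' @param n_tests number of independent tests (>= 1).
#' @param alpha per-test significance level in (0, 1).
#' @return `n_tests * alpha`.
#' @export
#' @examples
#' expected_by_chance(60, 0.05)  # 3
expected_by_chance <- function(n_tests, alpha) {
  stopifnot(n_tests >= 1, alpha > 0, alpha < 1)
  n_tests * alpha
}

#' Fold excess of observed over expected significant tests
#'
#' @param observed observed count of significant tests (>= 0).
#' @param n_tests,alpha as in [expected_by_chance()].
#' @return `observed / (n_tests * alpha)`.
#' @export
#' @examples
#' fold_excess(16, 60, 0.05)  # 5.33 (prints as 5.3 to 1 d.p.)
fold_excess <- function(observed, n_tests, alpha) {
  stopifnot(observed >= 0)
  observed / expected_by_chance(n_tests, alpha)
}

#' Test enrichment of significant associations over chance
#'
#' Treats the tests of a scan as independent Bernoulli(alpha) trials under
#' the global null and asks whether the observed count of significant
#' results is excessive. Two one-sided upper-tail p-values are returned:
#' the exact binomial tail `P(X >= observed)` and the normal approximation
#' on the observed proportion with variance estimated from the observed
#' proportion itself (`p_normal = 1` when `observed = 0`, where that
#' variance estimate degenerates).
#'
#' @inheritParams fold_excess
#' @return List with `p_exact` and `p_normal`.
#' @export
#' @examples
#' enrichment_test(16, 60, 0.05)
enrichment_test <- function(observed, n_tests, alpha) {
  stopifnot(observed >= 0, observed <= n_tests)
  p_exact <- pbinom(observed - 1, n_tests, alpha, lower.tail = FALSE)
  phat <- observed / n_tests
  p_normal <- if (observed == 0) 1 else {
    z <- (phat - alpha) / sqrt(phat * (1 - phat) / n_tests)
    pnorm(z, lower.tail = FALSE)
  }
  list(p_exact = p_exact, p_normal = p_normal)
}

#' Enrichment summary for a scan
#'
#' Convenience wrapper computing the full enrichment record, either from an
#' observed count or directly from a [scan_cells()] result.
#'
#' @param x a `cell_scan`, or an observed count of significant tests.
#' @param n_tests number of tests (ignored when `x` is a scan).
#' @param alpha per-test level, default 0.05.
#' @return One-row data frame: `n_tests`, `alpha`, `observed`, `expected`,
#'   `fold`, `p_exact`, `p_normal`.
#' @export
enrichment_summary <- function(x, n_tests = NULL, alpha = 0.05) {
  if (inherits(x, "cell_scan")) {
    s <- summarize_scan(x)
    observed <- s$n_significant
    n_tests <- s$n_tests
  } else {
    observed <- x
    if (is.null(n_tests))
      stop("n_tests is required when x is a count", call. = FALSE)
  }
  p <- enrichment_test(observed, n_tests, alpha)
  data.frame(n_tests = n_tests, alpha = alpha, observed = observed,
             expected = expected_by_chance(n_tests, alpha),
             fold = fold_excess(observed, n_tests, alpha),
             p_exact = p$p_exact, p_normal = p$p_normal)
}
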