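#' Permutation p-value from a pooled null
#'
#' The permutation p-value of a score `t` is the fraction of pooled permuted
#' scores greater than or equal to `t` (ties counted inclusively). At the
#' i-th order statistic of an all-distinct pool of size `r` this is the
#' rank-based quantile estimate `(r - i + 1) / r`.
#'
#' @param t numeric vector of thresholds (finite).
#' @param pool a [build_null_pool()] result, or a numeric vector of pooled
#'   null scores.
#' @return List with vectors `k` (exceedance counts), scalar `denom` (`r`)
#'   and vector `estimate = k / denom`.
#' @examples
#' empirical_pvalue(0.5, c(0.1, 0.5, 0.5, 2.0)) # k = 3, estimate = 0.75
#' @export
empirical_pvalue <- function(t, pool) {
  scores <- if (inherits(pool, "null_pool")) pool$null_scores else sort(pool)
  if (length(scores) == 0L) stop("empty null pool", call. = FALSE)
  .exceedance(t, scores)
}

#' Empirical exceedance fraction of the observed scores
#'
#' Estimates the marginal exceedance probability `Pr(T >= t)` over the gene
#' population by the fraction of observed scores at or above `t`; at the
#' i-th smallest of `m` distinct observed scores this is `(m - i + 1) / m`.
#'
#' @param t numeric vector of thresholds (finite).
#' @param scores observed per-gene scores (any order).
#' @return As [empirical_pvalue()], with `denom = m`.
#' @examples
#' empirical_gamma(2, c(1, 2, 3, 4)) # 3/4
#' @export
empirical_gamma <- function(t, scores) {
  if (length(scores) == 0L) stop("no observed scores", call. = FALSE)
  .exceedance(t, sort(scores))
}

# inclusive exceedance counts against a sorted reference set
.exceedance <- function(t, sorted_ref) {
  if (anyNA(t) || any(!is.finite(t))) {
    stop("thresholds must be finite", call. = FALSE)
  }
  n <- length(sorted_ref)
  below <- findInterval(t, sorted_ref, left.open = TRUE) # strictly < t
  k <- n - below
  list(k = k, denom = n, estimate = k / n)
}

#' One-sided conservative bounds for an exceedance probability
#'
#' Given an exceedance count `k` out of `denom` trials, `conservative_upper()`
#' returns the smallest `u` with `P(Binomial(denom, u) <= k) <= level` — the
#' `(1 - level)` quantile of the Beta distribution with shapes
#' `(k + 1, denom - k)` — so that `P(bound >= truth) >= 1 - level` whenever
#' `k` is a binomial draw at the true probability. `conservative_lower()` is
#' the mirror image: the largest `l` with `P(Binomial(denom, l) >= j) <=
#' level`, the `level` quantile of Beta`(j, denom - j + 1)`, guaranteeing
#' `P(bound <= truth) >= 1 - level`. These are the classical one-sided
#' Clopper-Pearson limits, expressible through the regularized incomplete
#' beta function, and carry exact (conservative) coverage with no assumption
#' on the score distribution.
#'
#' Degenerate cases: `conservative_upper` returns 1 when `k = denom` or
#' `level = 0`; `conservative_lower` returns 0 when `j = 0` or `level = 0`.
#' A `level` of 0 therefore yields a vacuous bound — callers wanting
#' "no adjustment" must pass the point estimate through explicitly (as the
#' q-value layer does).
#'
#' The binomial model treats pool entries as independent draws; a null pool
#' shared across genes violates independence, a caveat inherited from the
#' pooled-permutation design itself.
#'
#' @param k,j exceedance counts in `0..denom` (vectorised).
#' @param denom number of trials (pool size `r` or gene count `m`).
#' @param level one-sided mis-coverage in `[0, 1)`.
#' @return Numeric vector of bounds in `[0, 1]`.
#' @examples
#' conservative_upper(0, 10, 0.05) # 1 - 0.05^(1/10)
#' conservative_lower(10, 10, 0.05) # 0.05^(1/10)
#' @export
conservative_upper <- function(k, denom, level) {
  .check_bound_args(k, denom, level)
  bound <- ifelse(k >= denom | level == 0, 1,
                  stats::qbeta(1 - level, k + 1, denom - k))
  pmin(pmax(bound, 0), 1)
}

#' @rdname conservative_upper
#' @export
conservative_lower <- function(j, denom, level) {
  .check_bound_args(j, denom, level)
  bound <- ifelse(j <= 0 | level == 0, 0,
                  stats::qbeta(level, j, denom - j + 1))
  pmin(pmax(bound, 0), 1)
}

.check_bound_args <- function(k, denom, level) {
  if (length(level) != 1L || is.na(level) || level < 0 || level >= 1) {
    stop("level must be a single value in [0, 1)", call. = FALSE)
  }
  if (any(denom < 1)) stop("denom must be positive", call. = FALSE)
  if (any(k < 0 | k > denom)) {
    stop("counts must lie in 0..denom", call. = FALSE)
  }
  invisible(TRUE)
}
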