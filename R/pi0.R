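#' Conservative estimation of the true-null proportion
#'
#' The proportion pi0 of non-differentially-expressed genes enters the
#' q-value multiplicatively, so an underestimate deflates every q-value.
#' Identifiability forces conservative estimation in practice. Three
#' policies are provided:
#'
#' * `"fixed"` — return a supplied constant, default 1.0: the maximally
#'   conservative choice, satisfying `P(estimate >= pi0) = 1` exactly.
#' * `"storey"` — `min(1, #\{p > lambda\} / ((1 - lambda) * m))`, the
#'   standard tail-uniformity estimator. Approximately conservative in
#'   expectation, but for small `m` (or unlucky draws) it can fall below the
#'   true pi0; the coverage of the adjusted q-value then degrades
#'   accordingly.
#' * `"external"` — record a value produced elsewhere (e.g. by a convex
#'   decreasing-density estimator such as convest, which is not
#'   re-implemented here), trusting the caller that it is conservative.
#'
#' Because conservative pi0 estimates already over-cover, no mis-coverage
#' budget is spent on this component: the q-value layer fixes `a0 = 0`.
#'
#' @param pvalues per-gene p-values in `[0, 1]` (required for `"storey"`).
#' @param method `"fixed"`, `"storey"` or `"external"`.
#' @param value the constant for `"fixed"`/`"external"` (default 1.0).
#' @param lambda tuning threshold in `(0, 1)` for `"storey"` (default 0.5).
#' @return Object of class `"pi0_estimate"`: list with `value`, `method`,
#'   `params`.
#' @examples
#' estimate_pi0(method = "fixed")
#' estimate_pi0(c(0.1, 0.2, 0.3, 0.8), method = "storey", lambda = 0.5)
#' @export
estimate_pi0 <- function(pvalues = NULL,
                         method = c("fixed", "storey", "external"),
                         value = 1.0, lambda = 0.5) {
  method <- match.arg(method)
  if (!is.null(pvalues)) {
    if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1)) {
      stop("p-values must lie in [0, 1]", call. = FALSE)
    }
  }
  out <- switch(method,
    fixed = {
      if (is.na(value) || value < 0 || value > 1) {
        stop("fixed pi0 must lie in [0, 1]", call. = FALSE)
      }
      list(value = value, params = list(value = value))
    },
    storey = {
      if (is.null(pvalues)) {
        stop("storey estimation needs p-values", call. = FALSE)
      }
      if (is.na(lambda) || lambda <= 0 || lambda >= 1) {
        stop("lambda must lie strictly in (0, 1)", call. = FALSE)
      }
      m <- length(pvalues)
      est <- min(1, sum(pvalues > lambda) / ((1 - lambda) * m))
      list(value = est, params = list(lambda = lambda))
    },
    external = {
      if (is.na(value) || value < 0 || value > 1) {
        stop("external pi0 must lie in [0, 1]", call. = FALSE)
      }
      list(value = value, params = list(value = value, source = "external"))
    })
  structure(list(value = out$value, method = method, params = out$params),
            class = "pi0_estimate")
}

#' @export
print.pi0_estimate <- function(x, ...) {
  cat(sprintf("pi0 estimate: %.4f (%s)\n", x$value, x$method))
  invisible(x)
}

.pi0_value <- function(pi0) {
  if (inherits(pi0, "pi0_estimate")) pi0$value else as.numeric(pi0)
}
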