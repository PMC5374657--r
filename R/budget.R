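#' Multiplicative mis-coverage budget
#'
#' The conservatively adjusted q-value is a product/ratio of three one-sided
#' confidence limits — for pi0, for the null exceedance probability alpha(t)
#' (the p-value), and for the marginal exceedance fraction gamma(t). If the
#' components carry mis-coverages `a0`, `a1`, `a2` with
#' `(1 - a0)(1 - a1)(1 - a2) >= 1 - a`, the composite exceeds the theoretical
#' q-value with probability at least `1 - a`.
#'
#' `make_budget()` splits an overall level `a` evenly, on the multiplicative
#' scale, across the active components: each of the `c` active components
#' receives `1 - (1 - a)^(1/c)` and inactive components receive 0, so the
#' constraint holds with equality. The shipped presets never spend budget on
#' pi0 (`a0 = 0`), matching conservative pi0 estimation; and with theoretical
#' p-values only `gamma` is active, giving `a2 = a`.
#'
#' @param a overall mis-coverage in `[0, 1)`.
#' @param active character subset of `c("pi0", "alpha", "gamma")` naming the
#'   components that consume budget.
#' @return Object of class `"confidence_budget"`: list with `a`, `a0`, `a1`,
#'   `a2`, `active`.
#' @examples
#' make_budget(0.05) # a1 = a2 = 1 - sqrt(0.95)
#' make_budget(0.05, active = "gamma") # a2 = 0.05
#' @export
make_budget <- function(a, active = c("alpha", "gamma")) {
  if (length(a) != 1L || is.na(a) || a < 0 || a >= 1) {
    stop("overall level a must lie in [0, 1)", call. = FALSE)
  }
  all_comp <- c("pi0", "alpha", "gamma")
  active <- unique(as.character(active))
  if (length(active) && !all(active %in% all_comp)) {
    stop("active components must be among: ",
         paste(all_comp, collapse = ", "), call. = FALSE)
  }
  comp <- stats::setNames(numeric(3), all_comp)
  cn <- length(active)
  if (cn > 0L && a > 0) comp[active] <- 1 - (1 - a)^(1 / cn)
  structure(list(a = a,
                 a0 = unname(comp["pi0"]),
                 a1 = unname(comp["alpha"]),
                 a2 = unname(comp["gamma"]),
                 active = active),
            class = "confidence_budget")
}

#' @export
print.confidence_budget <- function(x, ...) {
  cat(sprintf(
    "confidence budget: a = %g (a0 = %g, a1 = %g, a2 = %g)\n",
    x$a, x$a0, x$a1, x$a2))
  invisible(x)
}

.check_budget <- function(budget) {
  if (!inherits(budget, "confidence_budget")) {
    stop("budget must come from make_budget()", call. = FALSE)
  }
  with(budget, {
    if (any(c(a0, a1, a2) < 0) || any(c(a0, a1, a2) >= 1)) {
      stop("budget components must lie in [0, 1)", call. = FALSE)
    }
    if ((1 - a0) * (1 - a1) * (1 - a2) < 1 - a - 1e-12) {
      stop("budget violates (1-a0)(1-a1)(1-a2) >= 1-a", call. = FALSE)
    }
  })
  invisible(TRUE)
}
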