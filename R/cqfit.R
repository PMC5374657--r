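#' Fit conservative q-values to expression data or p-values
#'
#' The single front end of the package. Two analysis paths are supported:
#'
#' * **Permutation path** (`x` + group labels): per-gene |t| scores, a pooled
#'   permutation null across all genes, permutation p-values `k/r`, q-values
#'   `pi0 * (k/r)/(j/m)`, and conservatively adjusted q-values in which the
#'   p-value and exceedance components are replaced by one-sided confidence
#'   limits under a multiplicative budget (`a` split over alpha and gamma,
#'   `a0 = 0`).
#' * **Theoretical-p path** (`pvalues`): exact p-values need no adjustment
#'   (`a1 = 0`); the whole budget goes to the exceedance component
#'   (`a2 = a`).
#'
#' @param x an [expression_matrix()] or numeric matrix (permutation path).
#' @param labels group labels when `x` is a bare matrix.
#' @param pvalues numeric vector of exact per-gene p-values
#'   (theoretical-p path); mutually exclusive with `x`.
#' @param a overall mis-coverage of the adjustment (default 0.05).
#' @param pi0 pi0 policy: `"fixed"`, `"storey"` or `"external"`
#'   (see [estimate_pi0()]), or a [estimate_pi0()] object, or a bare number
#'   (treated as a fixed value).
#' @param pi0_value,lambda parameters passed to [estimate_pi0()].
#' @param permutations `"exhaustive"` (all balanced relabelings) or
#'   `"sampled"`.
#' @param n_random,seed,include_observed,cap passed to [build_null_pool()].
#' @return Object of class `"cqfit"`: list with `table` (the per-gene result
#'   data.frame: `gene_id`, `score`, `k`, `r`, `j`, `m`, `p`, `q`, `p_c`,
#'   `q_c`), `pi0`, `budget`, `pool` (provenance: `r`, `B`, `scheme`,
#'   `seed`), `mode`, `call`.
#' @examples
#' sc <- generate_scenario(m = 50, pi0 = 0.8, delta = 2, seed = 7)
#' fit <- cqfit(sc$x, a = 0.05, pi0 = "fixed")
#' fit
#' head(as.data.frame(fit))
#' @seealso [run_analyze()] for the file-in/file-out wrapper.
#' @export
cqfit <- function(x = NULL, labels = NULL, pvalues = NULL, a = 0.05,
                  pi0 = c("fixed", "storey", "external"), pi0_value = 1,
                  lambda = 0.5, permutations = c("exhaustive", "sampled"),
                  n_random = 1000L, seed = NULL, include_observed = TRUE,
                  cap = 20000L) {
  cl <- match.call()
  if (is.null(x) == is.null(pvalues)) {
    stop("supply exactly one of x (expression data) or pvalues",
         call. = FALSE)
  }

  if (!is.null(pvalues)) {
    budget <- make_budget(a, active = "gamma")
    pi0_est <- .resolve_pi0(pi0, pvalues, pi0_value, lambda)
    tab <- theoretical_path_qvalues(pvalues, pi0c = pi0_est, budget = budget,
                                    gene_ids = names(pvalues))
    return(structure(list(table = tab, pi0 = pi0_est, budget = budget,
                          pool = NULL, mode = "theoretical-p", call = cl),
                     class = "cqfit"))
  }

  permutations <- match.arg(permutations)
  x <- .as_expression_matrix(x, labels)
  pool <- build_null_pool(x, mode = permutations, n_random = n_random,
                          seed = seed, include_observed = include_observed,
                          cap = cap)
  scores <- two_sample_t_scores(x)
  pvals <- empirical_pvalue(scores, pool)$estimate
  pi0_est <- .resolve_pi0(pi0, pvals, pi0_value, lambda)
  budget <- make_budget(a, active = c("alpha", "gamma"))
  tab <- compute_qvalues(scores, pool, pi0_est)
  tab <- conservative_qvalues(tab, pi0c = pi0_est, budget = budget)
  structure(list(table = tab, pi0 = pi0_est, budget = budget,
                 pool = pool[c("r", "B", "scheme", "includes_observed",
                               "seed")],
                 mode = "permutation", call = cl),
            class = "cqfit")
}

.resolve_pi0 <- function(pi0, pvalues, pi0_value, lambda) {
  if (inherits(pi0, "pi0_estimate")) return(pi0)
  if (is.numeric(pi0)) {
    return(estimate_pi0(method = "external", value = pi0))
  }
  method <- match.arg(pi0, c("fixed", "storey", "external"))
  estimate_pi0(pvalues, method = method, value = pi0_value, lambda = lambda)
}

#' @export
print.cqfit <- function(x, ...) {
  cat("Conservative q-value fit (", x$mode, " path)\n", sep = "")
  cat(sprintf("  genes: %d\n", nrow(x$table)))
  if (!is.null(x$pool)) {
    cat(sprintf("  null pool: r = %d (%s, B = %d relabelings)\n",
                x$pool$r, x$pool$scheme, x$pool$B))
  }
  cat(sprintf("  pi0: %.4f (%s); budget a = %g (a1 = %g, a2 = %g)\n",
              x$pi0$value, x$pi0$method, x$budget$a, x$budget$a1,
              x$budget$a2))
  ng <- function(th, col) sum(x$table[[col]] <= th)
  cat(sprintf("  genes at q <= 0.05: %d unadjusted, %d adjusted\n",
              ng(0.05, "q"), ng(0.05, "q_c")))
  invisible(x)
}

#' @export
summary.cqfit <- function(object, thresholds = c(0.01, 0.05, 0.1, 0.2), ...) {
  tab <- object$table
  counts <- data.frame(
    threshold = thresholds,
    n_q = vapply(thresholds, function(th) sum(tab$q <= th), integer(1)),
    n_q_conservative = vapply(thresholds, function(th) sum(tab$q_c <= th),
                              integer(1)))
  out <- list(mode = object$mode, m = nrow(tab), pi0 = object$pi0,
              budget = object$budget, pool = object$pool, counts = counts)
  class(out) <- "summary.cqfit"
  out
}

#' @export
print.summary.cqfit <- function(x, ...) {
  cat("Conservative q-value fit (", x$mode, " path), m = ", x$m,
      " genes\n", sep = "")
  print(x$pi0)
  print(x$budget)
  if (!is.null(x$pool)) {
    cat(sprintf("null pool: r = %d (%s)\n", x$pool$r, x$pool$scheme))
  }
  cat("\ngenes identified (q-value at or below threshold):\n")
  print(x$counts, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.cqfit <- function(x, ...) x$table

#' Plot estimated FDR against the number of identified genes
#'
#' Draws the standard summary curve of a differential expression analysis:
#' for each gene count `x`, the smallest q-value threshold admitting `x`
#' genes. The unadjusted q-values are a solid curve, the conservatively
#' adjusted q-values a dashed curve; a wide gap between them flags rankings
#' whose low q-values are statistically fragile.
#'
#' @param x a [cqfit()] object.
#' @param ... passed to [plot()].
#' @export
plot.cqfit <- function(x, ...) {
  q <- sort(x$table$q)
  qc <- sort(x$table$q_c)
  n <- seq_along(q)
  args <- list(...)
  defaults <- list(x = n, y = q, type = "s", ylim = c(0, 1),
                   xlab = "number of identified genes",
                   ylab = "estimated FDR (q-value)", lty = 1)
  do.call(graphics::plot, utils::modifyList(defaults, args))
  graphics::lines(n, qc, type = "s", lty = 2)
  graphics::legend("bottomright", lty = c(1, 2),
                   legend = c("q-value", "conservatively adjusted"),
                   bty = "n")
  invisible(x)
}
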