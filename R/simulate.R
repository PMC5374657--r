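#' Simulate a two-group differential expression scenario
#'
#' Generates an `m`-gene, two-group Gaussian expression matrix of the kind
#' used to study q-value behaviour: true-null genes are N(0, 1) in both
#' groups; differentially expressed genes are N(0, 1) in group 1 and
#' N(delta, 1) in group 2. The number of DE genes is `round(m * (1 - pi0))`
#' (round half to even). Deterministic given `seed`.
#'
#' @param m number of genes.
#' @param pi0 true-null proportion in `[0, 1]`.
#' @param delta mean shift of DE genes in group 2 (units of the unit
#'   within-group standard deviation).
#' @param n1,n2 group sizes (each at least 2).
#' @param seed optional integer seed; the session RNG state is restored.
#' @return List with `x` (an [expression_matrix()]; DE genes come first) and
#'   `true_null` (logical vector, `TRUE` for null genes).
#' @examples
#' sc <- generate_scenario(m = 100, pi0 = 0.9, delta = 2, seed = 1)
#' table(sc$true_null)
#' @export
generate_scenario <- function(m, pi0, delta, n1 = 5, n2 = 5, seed = NULL) {
  m <- as.integer(m)
  if (m < 1L) stop("m must be at least 1", call. = FALSE)
  if (pi0 < 0 || pi0 > 1) stop("pi0 must lie in [0, 1]", call. = FALSE)
  if (n1 < 2L || n2 < 2L) stop("group sizes must be at least 2", call. = FALSE)
  m_de <- as.integer(round(m * (1 - pi0)))
  gen <- function() {
    vals <- matrix(stats::rnorm(m * (n1 + n2)), nrow = m)
    if (m_de > 0L) {
      vals[seq_len(m_de), n1 + seq_len(n2)] <-
        vals[seq_len(m_de), n1 + seq_len(n2)] + delta
    }
    vals
  }
  vals <- if (is.null(seed)) gen() else .with_seed(seed, gen())
  x <- expression_matrix(vals,
                         gene_ids = paste0("gene_", seq_len(m)),
                         group_labels = rep(c("g1", "g2"), c(n1, n2)))
  list(x = x, true_null = c(rep(FALSE, m_de), rep(TRUE, m - m_de)))
}

#' Theoretically exact FDR for the Gaussian two-group scenario
#'
#' Under the simulation model the |t| score of a null gene follows a central
#' t distribution with `n1 + n2 - 2` degrees of freedom, and of a DE gene a
#' noncentral t with noncentrality `delta * sqrt(n1 * n2 / (n1 + n2))`. The
#' theoretical q-value at threshold `t` is therefore available in closed
#' form:
#' `q~(t) = pi0 * S0(t) / (pi0 * S0(t) + (1 - pi0) * S1(t))`
#' with `S0(t) = P(|T_nu| >= t)` and `S1(t) = P(|T'_nu,ncp| >= t)`. This is
#' the oracle against which estimated q-values are judged: `q~(0) = pi0`,
#' and for `delta > 0` the curve is nonincreasing in `t`.
#'
#' @param t nonnegative threshold(s) on the |t| score (vectorised).
#' @param pi0 true-null proportion.
#' @param delta DE mean shift.
#' @param n1,n2 group sizes.
#' @return Theoretical FDR values in `[0, 1]`.
#' @examples
#' theoretical_fdr(c(0, 2, 4), pi0 = 0.9, delta = 2)
#' @export
theoretical_fdr <- function(t, pi0, delta, n1 = 5, n2 = 5) {
  if (any(t < 0)) stop("thresholds must be nonnegative", call. = FALSE)
  nu <- n1 + n2 - 2
  ncp <- delta * sqrt(n1 * n2 / (n1 + n2))
  s0 <- 2 * stats::pt(t, df = nu, lower.tail = FALSE)
  s1 <- stats::pt(-t, df = nu, ncp = ncp) +
    stats::pt(t, df = nu, ncp = ncp, lower.tail = FALSE)
  denom <- pi0 * s0 + (1 - pi0) * s1
  out <- pi0 * s0 / denom
  # denom > 0 for all finite t; guard only against numeric underflow
  out[denom == 0] <- pi0
  pmin(pmax(out, 0), 1)
}

#' Realized false discovery proportion
#'
#' `V / R`: the number of true-null genes among those selected, divided by
#' the number selected, with the convention `0 / 0 = 0`.
#'
#' @param true_null logical vector over genes (`TRUE` = null).
#' @param selected logical vector over genes, or integer indices of the
#'   selected genes.
#' @return A single number in `[0, 1]`.
#' @examples
#' empirical_fdp(c(TRUE, TRUE, FALSE, FALSE), c(1, 3))
#' @export
empirical_fdp <- function(true_null, selected) {
  if (is.logical(selected)) {
    if (length(selected) != length(true_null)) {
      stop("logical selection must match the gene count", call. = FALSE)
    }
    sel <- which(selected)
  } else {
    sel <- as.integer(selected)
    if (length(sel) && (min(sel) < 1L || max(sel) > length(true_null))) {
      stop("selected indices out of range", call. = FALSE)
    }
  }
  R <- length(sel)
  if (R == 0L) return(0)
  sum(true_null[sel]) / R
}

#' Replicate harness: underestimation frequency and coverage
#'
#' Repeats the full permutation analysis on freshly simulated scenarios and
#' compares the estimated curves to the theoretical FDR oracle at every
#' observed threshold. Two summaries are reported: the fraction of
#' replicates in which the plain q-value falls below the theoretical FDR
#' somewhere in the region where the theoretical FDR is below `fdr_region`
#' (the underestimation phenomenon), and the fraction of replicates in which
#' the conservatively adjusted q-value dominates the theoretical FDR at
#' every observed threshold (the coverage the adjustment guarantees at level
#' `1 - a`).
#'
#' Following the adjustment's design, the plain q-values use a practical pi0
#' estimate (`pi0_method`, default Storey) while the adjusted q-values use a
#' strictly conservative pi0 (`pi0c_value`, default 1) so the coverage claim
#' is isolated from pi0 estimation error.
#'
#' @param m,pi0,delta,n1,n2 scenario parameters (see [generate_scenario()]).
#' @param reps number of replicates; 0 returns an empty summary.
#' @param a overall adjustment level (budget split over alpha and gamma).
#' @param seed integer seed driving all replicates.
#' @param pi0_method pi0 estimator for the plain q-values (`"storey"` or
#'   `"fixed"`).
#' @param lambda Storey tuning parameter.
#' @param pi0c_value conservative pi0 used for the adjusted q-values.
#' @param fdr_region underestimation is assessed where the theoretical FDR
#'   is below this value (default 0.05).
#' @param keep_curves return the per-replicate curves (default TRUE).
#' @return List with `summary` (data.frame: `rep`, `underestimated`,
#'   `covered`), `underestimation_frequency`, `coverage`, and (optionally)
#'   `curves`, a list of per-replicate data.frames with columns `score`,
#'   `q`, `q_c`, `q_tilde`, `fdp`.
#' @export
run_coverage_experiment <- function(m = 2000, pi0 = 0.85, delta = 1.5,
                                    n1 = 5, n2 = 5, reps = 20, a = 0.05,
                                    seed = 1, pi0_method = "storey",
                                    lambda = 0.5, pi0c_value = 1,
                                    fdr_region = 0.05, keep_curves = TRUE) {
  reps <- as.integer(reps)
  empty <- data.frame(rep = integer(), underestimated = logical(),
                      covered = logical())
  if (reps == 0L) {
    return(list(summary = empty, underestimation_frequency = NA_real_,
                coverage = NA_real_, curves = list()))
  }
  budget <- make_budget(a, active = c("alpha", "gamma"))
  rep_seeds <- .with_seed(seed, sample.int(2^31 - 2, reps))
  curves <- vector("list", reps)
  under <- covered <- logical(reps)
  for (b in seq_len(reps)) {
    sc <- generate_scenario(m, pi0, delta, n1, n2, seed = rep_seeds[b])
    pool <- build_null_pool(sc$x, mode = "exhaustive")
    scores <- two_sample_t_scores(sc$x)
    pvals <- empirical_pvalue(scores, pool)$estimate
    pi0_hat <- if (identical(pi0_method, "fixed")) {
      estimate_pi0(method = "fixed", value = 1)
    } else {
      estimate_pi0(pvals, method = "storey", lambda = lambda)
    }
    tab <- compute_qvalues(scores, pool, pi0_hat)
    tab <- conservative_qvalues(tab, pi0c = pi0c_value, budget = budget)
    q_tilde <- theoretical_fdr(tab$score, pi0, delta, n1, n2)
    in_region <- q_tilde < fdr_region
    under[b] <- any(tab$q[in_region] < q_tilde[in_region])
    covered[b] <- all(tab$q_c >= q_tilde - 1e-12)
    if (keep_curves) {
      fdp <- vapply(tab$score, function(t)
        empirical_fdp(sc$true_null, tab$score >= t), numeric(1))
      ord <- order(tab$score, decreasing = TRUE)
      curves[[b]] <- data.frame(score = tab$score[ord], q = tab$q[ord],
                                q_c = tab$q_c[ord], q_tilde = q_tilde[ord],
                                fdp = fdp[ord])
    }
  }
  list(summary = data.frame(rep = seq_len(reps), underestimated = under,
                            covered = covered),
       underestimation_frequency = mean(under),
       coverage = mean(covered),
       curves = if (keep_curves) curves else list())
}
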