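#' Permutation q-values over a pooled null
#'
#' For each observed score threshold `t = T_i` the q-value estimates the
#' false discovery rate among genes called at that threshold:
#' `q_raw(t) = pi0 * (k/r) / (j/m)` where `k/r` is the permutation p-value
#' from the pooled null and `j/m` the fraction of observed scores at or
#' above `t`. Raw values are made monotone by a running minimum taken from
#' the least significant gene downward in score order — the usual q-value
#' convention that q(t) is the smallest estimated FDR over thresholds at
#' least as permissive as t — then clipped to `[0, 1]`. Tied scores receive
#' identical q-values.
#'
#' @param scores per-gene |t| scores (named vector as from
#'   [two_sample_t_scores()]).
#' @param pool a [build_null_pool()] result (or numeric pool).
#' @param pi0 a [estimate_pi0()] result or a number in `[0, 1]`.
#' @return A `data.frame` (one row per gene, input order) with columns
#'   `gene_id`, `score`, `k`, `r`, `j`, `m`, `p`, `q`.
#' @examples
#' s <- c(a = 2, b = 1, c = 0.5)
#' compute_qvalues(s, pool = c(s, 0.1, 0.4, 0.9, 1.5, 2.5, 3), pi0 = 1)
#' @export
compute_qvalues <- function(scores, pool, pi0 = 1) {
  pi0v <- .pi0_value(pi0)
  if (is.na(pi0v) || pi0v < 0 || pi0v > 1) {
    stop("pi0 must lie in [0, 1]", call. = FALSE)
  }
  m <- length(scores)
  if (m < 1L) stop("no scores", call. = FALSE)
  alpha <- empirical_pvalue(scores, pool)
  gamma <- empirical_gamma(scores, scores)
  if (any(gamma$k == 0L)) {
    stop("internal error: zero observed exceedance at an observed threshold",
         call. = FALSE)
  }
  q_raw <- pi0v * alpha$estimate / gamma$estimate
  data.frame(
    gene_id = if (is.null(names(scores))) paste0("gene_", seq_len(m))
              else names(scores),
    score = as.numeric(scores),
    k = alpha$k, r = alpha$denom,
    j = gamma$k, m = m,
    p = alpha$estimate,
    q = .monotonize_q(q_raw, scores),
    stringsAsFactors = FALSE, row.names = NULL)
}

# running minimum from the least significant threshold (smallest score)
# toward larger scores, then clipped to [0, 1]
.monotonize_q <- function(q_raw, scores) {
  ord <- order(scores)
  out <- numeric(length(q_raw))
  out[ord] <- cummin(q_raw[ord])
  pmin(pmax(out, 0), 1)
}

#' Conservatively adjusted q-values
#'
#' Replaces each component of the q-value by a one-sided confidence limit:
#' the permutation p-value `k/r` by its upper limit
#' [conservative_upper()]`(k, r, a1)`, the exceedance fraction `j/m` by its
#' lower limit [conservative_lower()]`(j, m, a2)`, and pi0 by a conservative
#' estimate (no budget spent: `a0 = 0` policy). A component with zero budget
#' passes through unadjusted, so a zero budget reproduces the plain q-values
#' exactly. The adjusted ratio is monotonized and clipped like the q-value
#' itself. Under the budget constraint the adjusted value exceeds the
#' theoretical q-value `pi0 * alpha(t) / gamma(t)` with probability at least
#' `(1 - a0)(1 - a1)(1 - a2) >= 1 - a` at each threshold.
#'
#' A lower confidence limit is not attempted: pi0 estimation is itself only
#' conservative, which breaks the symmetric argument.
#'
#' @param table result of [compute_qvalues()] (columns `k`, `r`, `j`, `m`
#'   required).
#' @param pi0c conservative pi0: an [estimate_pi0()] result or a number.
#' @param budget a [make_budget()] result.
#' @return `table` with columns `p_c` (adjusted p-value) and `q_c` (adjusted
#'   q-value) added, plus attributes `pi0_used` and `budget_used`.
#' @export
conservative_qvalues <- function(table, pi0c = 1, budget = make_budget(0.05)) {
  .check_budget(budget)
  need <- c("score", "k", "r", "j", "m")
  if (!all(need %in% names(table))) {
    stop("table must carry columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  pi0v <- .pi0_value(pi0c)
  r <- table$r[1]; m <- table$m[1]
  alpha_c <- if (budget$a1 > 0) {
    conservative_upper(table$k, r, budget$a1)
  } else table$k / r
  gamma_c <- if (budget$a2 > 0) {
    conservative_lower(table$j, m, budget$a2)
  } else table$j / m
  qc_raw <- ifelse(gamma_c == 0, 1, pi0v * alpha_c / gamma_c)
  table$p_c <- alpha_c
  table$q_c <- .monotonize_q(qc_raw, table$score)
  attr(table, "pi0_used") <- pi0v
  attr(table, "budget_used") <- budget
  table
}

#' q-values from theoretical p-values
#'
#' When exact p-values are available (e.g. from a Wilcoxon rank-sum test at
#' large sample size) the p-value component needs no adjustment (`a1 = 0`);
#' only the empirical exceedance fraction — here the fraction of genes with
#' p-values at or below each observed p-value, mirroring the count of scores
#' at or above a threshold — is replaced by its lower confidence limit.
#'
#' @param pvalues per-gene p-values in `[0, 1]`.
#' @param pi0c conservative pi0 (estimate or number).
#' @param budget a [make_budget()] result with `a1 = 0`; a positive `a1` is
#'   allowed but flagged with a warning (there is no permutation count to
#'   bound, so the p-values are used as-is).
#' @param gene_ids optional identifiers.
#' @return A `data.frame` as [conservative_qvalues()], with `score = -p`
#'   ranks expressed through `p` itself (columns `p`, `j`, `m`, `q`, `p_c`,
#'   `q_c`).
#' @examples
#' theoretical_path_qvalues(c(0.01, 0.2, 0.5, 0.9), pi0c = 1,
#'                          budget = make_budget(0, active = character()))
#' @export
theoretical_path_qvalues <- function(pvalues, pi0c = 1,
                                     budget = make_budget(0.05,
                                                          active = "gamma"),
                                     gene_ids = NULL) {
  .check_budget(budget)
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  if (budget$a1 > 0) {
    warning("a1 > 0 has no effect with theoretical p-values; ",
            "the p-value component is used unadjusted", call. = FALSE)
  }
  m <- length(pvalues)
  pi0v <- .pi0_value(pi0c)
  # significance increases as p decreases; use -p as the score
  score <- -pvalues
  j <- .exceedance(score, sort(score))$k # = #\{p <= p_i\}, ties inclusive
  q_raw <- pi0v * pvalues / (j / m)
  gamma_c <- if (budget$a2 > 0) conservative_lower(j, m, budget$a2) else j / m
  qc_raw <- ifelse(gamma_c == 0, 1, pi0v * pvalues / gamma_c)
  out <- data.frame(
    gene_id = if (is.null(gene_ids)) paste0("gene_", seq_len(m))
              else as.character(gene_ids),
    score = score,
    k = NA_integer_, r = NA_integer_,
    j = j, m = m,
    p = pvalues,
    q = .monotonize_q(q_raw, score),
    p_c = pvalues,
    q_c = .monotonize_q(qc_raw, score),
    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "pi0_used") <- pi0v
  attr(out, "budget_used") <- budget
  out
}
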