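#' Absolute two-sample t scores
#'
#' Computes, per gene, the absolute value of the two-sample pooled-variance
#' (Student) t statistic between the two groups. Testing is two-sided:
#' exceedance sets used downstream are one-sided in |t|, so differential
#' expression in either direction counts.
#'
#' Degenerate genes are handled deterministically: if the pooled variance is
#' zero and the group means are equal the score is 0; if the pooled variance
#' is zero but the means differ the score would be infinite and is replaced
#' by the maximum finite score in the matrix plus 1, with a warning. This
#' keeps every score finite and ranks meaningful.
#'
#' @param x an [expression_matrix()], or a plain numeric matrix if `labels`
#'   is supplied.
#' @param labels optional group labels, required when `x` is a bare matrix;
#'   ignored (must be `NULL`) when `x` is an `expression_matrix`.
#' @return Named numeric vector of nonnegative finite scores, one per gene,
#'   in input row order.
#' @examples
#' em <- expression_matrix(rbind(g1 = c(0, 1, 0, 1), g2 = c(0, 0, 5, 5)),
#'                         group_labels = c("A", "A", "B", "B"))
#' two_sample_t_scores(em)
#' @export
two_sample_t_scores <- function(x, labels = NULL) {
  x <- .as_expression_matrix(x, labels)
  n <- .group_sizes(x$groups)
  if (any(n < 2L)) {
    stop("each group needs at least 2 samples for a t statistic (got ",
         n[1], " and ", n[2], ")", call. = FALSE)
  }
  idx1 <- which(x$groups == levels(x$groups)[1])
  scores <- .abs_t(x$values, idx1, warn = TRUE)
  names(scores) <- rownames(x$values)
  scores
}

.as_expression_matrix <- function(x, labels = NULL) {
  if (inherits(x, "expression_matrix")) {
    if (!is.null(labels)) {
      stop("labels are taken from the expression_matrix; do not supply both",
           call. = FALSE)
    }
    return(x)
  }
  expression_matrix(x, group_labels = labels)
}

# |t| for all genes given the column indices of group 1; vectorised over rows.
.abs_t <- function(values, idx1, warn = FALSE) {
  idx2 <- setdiff(seq_len(ncol(values)), idx1)
  n1 <- length(idx1); n2 <- length(idx2)
  x1 <- values[, idx1, drop = FALSE]
  x2 <- values[, idx2, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  ss1 <- rowSums((x1 - m1)^2)
  ss2 <- rowSums((x2 - m2)^2)
  sp2 <- (ss1 + ss2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tt <- abs(m1 - m2) / se
  zero_var <- se == 0
  if (any(zero_var)) {
    tt[zero_var & (m1 == m2)] <- 0
    blown <- zero_var & (m1 != m2)
    if (any(blown)) {
      if (warn) {
        warning(sum(blown), " gene(s) with zero pooled variance but unequal ",
                "means; score set to the maximum finite score plus 1",
                call. = FALSE)
      }
      mx <- suppressWarnings(max(tt[is.finite(tt)], 0))
      tt[blown] <- mx + 1
    }
  }
  tt
}

#' Enumerate all balanced two-group relabelings
#'
#' Lists every distinct assignment of `n1 + n2` samples into groups of sizes
#' `n1` and `n2`. When `n1 == n2`, assignments differing only by swapping the
#' two (interchangeable) group names are identified and counted once, giving
#' `choose(n1 + n2, n1) / 2` assignments — e.g. 126 for two groups of 5.
#' When `n1 != n2` all `choose(n1 + n2, n1)` splits are returned. The
#' identity assignment (first `n1` samples in group 1) is always included,
#' as the first column.
#'
#' @param n1,n2 group sizes (each at least 1).
#' @return Integer matrix with `n1` rows; each column holds the sample
#'   indices assigned to group 1 under one relabeling.
#' @examples
#' ncol(enumerate_balanced_relabelings(5, 5)) # 126
#' enumerate_balanced_relabelings(2, 2)
#' @export
enumerate_balanced_relabelings <- function(n1, n2) {
  n1 <- as.integer(n1); n2 <- as.integer(n2)
  if (n1 < 1L || n2 < 1L) stop("group sizes must be at least 1", call. = FALSE)
  n <- n1 + n2
  combos <- utils::combn(n, n1)
  if (n1 == n2) {
    # keep one representative per swap pair: those containing sample 1
    combos <- combos[, combos[1L, ] == 1L, drop = FALSE]
  }
  # put the identity split (1..n1) first
  id <- which(colSums(combos == seq_len(n1)) == n1)
  if (length(id) == 1L && id != 1L) {
    combos <- combos[, c(id, setdiff(seq_len(ncol(combos)), id)), drop = FALSE]
  }
  combos
}

#' Pooled permutation null distribution of |t| scores
#'
#' Recomputes the absolute t score of every gene under relabelings of the
#' samples and pools all permuted scores across genes into one sorted
#' empirical null distribution of size `r = m * B`, where `B` is the number
#' of relabelings. With `mode = "exhaustive"` all distinct balanced
#' relabelings are used (refusing above `cap`); with `mode = "sampled"`,
#' `n_random` relabelings are drawn uniformly with replacement (the identity
#' split may recur).
#'
#' Because the observed scores arise from the identity relabeling, they are
#' conventionally part of the null pool; with `include_observed = TRUE`
#' (the default) the observed scores are appended when sampling happened not
#' to draw the identity split, so that every observed threshold has pool
#' exceedance count at least 1.
#'
#' @inheritParams two_sample_t_scores
#' @param mode `"exhaustive"` or `"sampled"`.
#' @param n_random number of sampled relabelings (sampled mode).
#' @param seed integer seed for sampled mode (required there); the RNG state
#'   of the session is restored afterwards.
#' @param include_observed ensure the observed scores are in the pool.
#' @param cap refuse exhaustive enumeration above this many relabelings.
#' @return Object of class `"null_pool"`: list with `null_scores` (sorted
#'   increasing), `r`, `B`, `scheme`, `includes_observed`, `seed`.
#' @examples
#' em <- expression_matrix(matrix(rnorm(40), 10),
#'                         group_labels = rep(c("A", "B"), each = 2))
#' build_null_pool(em) # 3 relabelings for 2+2, r = 30
#' @export
build_null_pool <- function(x, labels = NULL,
                            mode = c("exhaustive", "sampled"),
                            n_random = 1000L, seed = NULL,
                            include_observed = TRUE, cap = 20000L) {
  x <- .as_expression_matrix(x, labels)
  mode <- match.arg(mode)
  n <- .group_sizes(x$groups)
  if (any(n < 2L)) {
    stop("each group needs at least 2 samples", call. = FALSE)
  }
  idx1_obs <- which(x$groups == levels(x$groups)[1])
  n1 <- n[1]; n2 <- n[2]
  ntot <- n1 + n2

  if (mode == "exhaustive") {
    total <- if (n1 == n2) choose(ntot, n1) / 2 else choose(ntot, n1)
    if (total > cap) {
      stop("exhaustive enumeration would need ", format(total, big.mark = ","),
           " relabelings (cap ", cap, "); use mode = \"sampled\"",
           call. = FALSE)
    }
    combos <- enumerate_balanced_relabelings(n1, n2)
    # relabelings permute sample positions, not labels: map to the observed
    # layout so the identity column reproduces the observed scores exactly
    sample_order <- c(idx1_obs, setdiff(seq_len(ntot), idx1_obs))
    cols <- lapply(seq_len(ncol(combos)),
                   function(b) sample_order[combos[, b]])
    has_identity <- TRUE
  } else {
    if (is.null(seed)) stop("sampled mode requires a seed", call. = FALSE)
    n_random <- as.integer(n_random)
    if (n_random < 1L) stop("n_random must be at least 1", call. = FALSE)
    cols <- .with_seed(seed, {
      lapply(seq_len(n_random), function(b) sample(ntot, n1))
    })
    has_identity <- any(vapply(cols, function(ix) {
      setequal(ix, idx1_obs) ||
        (n1 == n2 && setequal(ix, setdiff(seq_len(ntot), idx1_obs)))
    }, logical(1)))
    if (include_observed && !has_identity) {
      cols <- c(cols, list(idx1_obs))
      has_identity <- TRUE
    }
  }

  pool <- unlist(lapply(cols, function(ix) .abs_t(x$values, ix)),
                 use.names = FALSE)
  structure(list(null_scores = sort(pool),
                 r = length(pool),
                 B = length(cols),
                 scheme = mode,
                 includes_observed = include_observed && has_identity,
                 seed = seed),
            class = "null_pool")
}

#' @export
print.null_pool <- function(x, ...) {
  cat(sprintf("null_pool: r = %d pooled |t| scores (%s, B = %d relabelings%s)\n",
              x$r, x$scheme, x$B,
              if (isTRUE(x$includes_observed)) ", observed included" else ""))
  invisible(x)
}

# evaluate expr under a temporary seed, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}
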