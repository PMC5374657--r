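#' Read an expression matrix and group labels from TSV files
#'
#' The expression file is tab-separated with a header row of sample names;
#' the first column holds gene identifiers, the remaining cells are numeric.
#' The labels file is either two tab-separated columns (sample name, group)
#' or a single line of labels matching the expression header order. Exactly
#' two distinct groups are required.
#'
#' @param path expression TSV path.
#' @param labels_path labels file path.
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(path, labels_path) {
  if (!file.exists(path)) stop("expression file not found: ", path,
                               call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "#")
  if (ncol(df) < 2L) stop("expression file needs gene IDs plus samples",
                          call. = FALSE)
  gene_ids <- as.character(df[[1]])
  vals <- df[, -1, drop = FALSE]
  bad <- !vapply(vals, is.numeric, logical(1))
  if (any(bad)) {
    stop("non-numeric expression values in column(s): ",
         paste(names(vals)[bad], collapse = ", "), call. = FALSE)
  }
  vals <- as.matrix(vals)
  labels <- read_group_labels(labels_path, colnames(vals))
  expression_matrix(vals, gene_ids = gene_ids, group_labels = labels)
}

#' @rdname read_expression_matrix
#' @param sample_names expected sample order (the expression header).
#' @export
read_group_labels <- function(labels_path, sample_names) {
  if (!file.exists(labels_path)) stop("labels file not found: ", labels_path,
                                      call. = FALSE)
  lines <- readLines(labels_path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (length(lines) == 1L && length(fields[[1]]) == length(sample_names)) {
    labels <- fields[[1]]
  } else {
    if (any(lengths(fields) < 2L)) {
      stop("labels file must have two tab-separated columns ",
           "(sample, group) or one header-matching line", call. = FALSE)
    }
    map <- stats::setNames(vapply(fields, `[`, "", 2),
                           vapply(fields, `[`, "", 1))
    missing <- setdiff(sample_names, names(map))
    if (length(missing)) {
      stop("labels missing for sample(s): ",
           paste(utils::head(missing, 3), collapse = ", "), call. = FALSE)
    }
    labels <- unname(map[sample_names])
  }
  if (length(unique(labels)) != 2L) {
    stop("exactly two sample groups are required, got ",
         length(unique(labels)), call. = FALSE)
  }
  labels
}

#' Read per-gene p-values, one per line
#'
#' Blank lines and `#` comments are skipped; an optional second tab field is
#' treated as `gene_id<TAB>p`. Values outside `[0, 1]` are rejected.
#'
#' @param path p-value file.
#' @return Named numeric vector of p-values.
#' @export
read_pvalues <- function(path) {
  if (!file.exists(path)) stop("p-value file not found: ", path,
                               call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  two_col <- all(lengths(fields) >= 2L) && length(fields) > 0L
  raw <- if (two_col) vapply(fields, `[`, "", 2) else trimws(lines)
  p <- suppressWarnings(as.numeric(raw))
  if (anyNA(p)) stop("non-numeric p-value at line ",
                     which(is.na(p))[1], call. = FALSE)
  if (any(p < 0 | p > 1)) {
    stop("p-value outside [0, 1] at line ", which(p < 0 | p > 1)[1],
         call. = FALSE)
  }
  if (two_col) names(p) <- vapply(fields, `[`, "", 1)
  p
}

#' Write a per-gene result table as annotated TSV
#'
#' Columns `gene_id, score, p, p_conservative, q, q_conservative`; header
#' comment lines (starting with `#`) record pi0, the budget, the pool size
#' and seed so a result file is self-describing.
#'
#' @param fit a [cqfit()] object (or a bare result data.frame).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_results <- function(fit, path) {
  if (inherits(fit, "cqfit")) {
    tab <- fit$table
    hdr <- c(
      sprintf("# cqvalue %s | mode=%s",
              as.character(utils::packageVersion("cqvalue")), fit$mode),
      sprintf("# pi0=%.6g method=%s", fit$pi0$value, fit$pi0$method),
      sprintf("# budget a=%g a0=%g a1=%g a2=%g", fit$budget$a, fit$budget$a0,
              fit$budget$a1, fit$budget$a2),
      if (!is.null(fit$pool)) {
        sprintf("# pool r=%d B=%d scheme=%s seed=%s", fit$pool$r, fit$pool$B,
                fit$pool$scheme,
                if (is.null(fit$pool$seed)) "NA" else fit$pool$seed)
      })
  } else {
    tab <- fit
    hdr <- character()
  }
  out <- data.frame(gene_id = tab$gene_id, score = tab$score, p = tab$p,
                    p_conservative = tab$p_c, q = tab$q,
                    q_conservative = tab$q_c, stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis workflow on files
#'
#' Orchestrates reading, scoring, permutation, pi0 estimation, q-value
#' computation and conservative adjustment, writing a result TSV. Supply an
#' expression matrix plus labels (permutation path) or a p-value file
#' (theoretical-p path, `a1 = 0`).
#'
#' @param matrix,labels,pvalues input file paths (see
#'   [read_expression_matrix()], [read_pvalues()]).
#' @param a overall adjustment level.
#' @param pi0 pi0 policy string: `"fixed"`, `"fixed:<value>"`,
#'   `"storey"`, `"storey:<lambda>"` or `"external:<value>"`.
#' @param permutations `"exhaustive"` or `"sampled:<N>"`.
#' @param seed integer seed (required for sampled permutations).
#' @param out output TSV path (omit to skip writing).
#' @return The [cqfit()] object, invisibly.
#' @export
run_analyze <- function(matrix = NULL, labels = NULL, pvalues = NULL,
                        a = 0.05, pi0 = "fixed:1.0",
                        permutations = "exhaustive", seed = NULL,
                        out = NULL) {
  p0 <- .parse_pi0_spec(pi0)
  if (!is.null(pvalues)) {
    pv <- read_pvalues(pvalues)
    fit <- cqfit(pvalues = pv, a = a, pi0 = p0$method,
                 pi0_value = p0$value, lambda = p0$lambda)
  } else {
    if (is.null(matrix) || is.null(labels)) {
      stop("permutation mode needs --matrix and --labels", call. = FALSE)
    }
    em <- read_expression_matrix(matrix, labels)
    pm <- .parse_perm_spec(permutations)
    fit <- cqfit(em, a = a, pi0 = p0$method, pi0_value = p0$value,
                 lambda = p0$lambda, permutations = pm$mode,
                 n_random = pm$n, seed = seed)
  }
  if (!is.null(out)) write_gene_results(fit, out)
  invisible(fit)
}

.parse_pi0_spec <- function(spec) {
  parts <- strsplit(as.character(spec), ":", fixed = TRUE)[[1]]
  method <- parts[1]
  if (!method %in% c("fixed", "storey", "external")) {
    stop("unknown pi0 method: ", method, call. = FALSE)
  }
  num <- if (length(parts) > 1L) as.numeric(parts[2]) else NA_real_
  list(method = method,
       value = if (method != "storey" && !is.na(num)) num else 1,
       lambda = if (method == "storey" && !is.na(num)) num else 0.5)
}

.parse_perm_spec <- function(spec) {
  parts <- strsplit(as.character(spec), ":", fixed = TRUE)[[1]]
  if (parts[1] == "exhaustive") return(list(mode = "exhaustive", n = 0L))
  if (parts[1] == "sampled") {
    n <- if (length(parts) > 1L) as.integer(parts[2]) else 1000L
    return(list(mode = "sampled", n = n))
  }
  stop("permutations must be 'exhaustive' or 'sampled:<N>'", call. = FALSE)
}

#' Run the simulation harness and write replicate summaries
#'
#' Wraps [run_coverage_experiment()]: writes one TSV per replicate curve
#' (`rep_<i>.tsv`: score, q, q_c, q_tilde, fdp) and a `summary.tsv` with the
#' per-replicate underestimation/coverage flags plus the two aggregate
#' frequencies.
#'
#' @inheritParams run_coverage_experiment
#' @param out_dir output directory (created if needed).
#' @return The [run_coverage_experiment()] result, invisibly.
#' @export
run_simulate <- function(m = 2000, pi0 = 0.85, delta = 1.5, n1 = 5, n2 = 5,
                         reps = 20, a = 0.05, seed = 1,
                         pi0_method = "storey", lambda = 0.5,
                         pi0c_value = 1, out_dir = NULL) {
  res <- run_coverage_experiment(m = m, pi0 = pi0, delta = delta, n1 = n1,
                                 n2 = n2, reps = reps, a = a, seed = seed,
                                 pi0_method = pi0_method, lambda = lambda,
                                 pi0c_value = pi0c_value)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (b in seq_along(res$curves)) {
      utils::write.table(res$curves[[b]],
                         file.path(out_dir, sprintf("rep_%03d.tsv", b)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    smry <- res$summary
    smry$underestimation_frequency <- res$underestimation_frequency
    smry$coverage <- res$coverage
    utils::write.table(smry, file.path(out_dir, "summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(res)
}

#' Conservatively adjust an existing table of permutation p-values
#'
#' For workflows that already produced permutation p-values (each of the
#' form `k/r` from `r` pooled permuted scores), reconstructs the exceedance
#' counts, computes q-values under a conservative pi0, and adds the adjusted
#' columns. This is the post-hoc entry point: only the p-values, the pool
#' size `r` and a conservative pi0 estimate are needed.
#'
#' @param pvalues permutation p-values (multiples of `1/r`).
#' @param r permutation pool size used to compute them.
#' @param pi0 conservative pi0 estimate (number, default 1).
#' @param a overall adjustment level; split over alpha and gamma.
#' @param gene_ids optional identifiers.
#' @return A result data.frame as from [conservative_qvalues()].
#' @export
adjust_qvalues <- function(pvalues, r, pi0 = 1, a = 0.05, gene_ids = NULL) {
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  r <- as.integer(r)
  if (r < 1L) stop("pool size r must be positive", call. = FALSE)
  m <- length(pvalues)
  k <- as.integer(round(pvalues * r))
  if (any(abs(k - pvalues * r) > 1e-6)) {
    warning("p-values are not exact multiples of 1/r; ",
            "exceedance counts were rounded", call. = FALSE)
  }
  # smaller p = more significant; -p is a valid score for ranking
  score <- -pvalues
  j <- .exceedance(score, sort(score))$k
  budget <- make_budget(a, active = c("alpha", "gamma"))
  tab <- data.frame(
    gene_id = if (is.null(gene_ids)) paste0("gene_", seq_len(m))
              else as.character(gene_ids),
    score = score, k = k, r = r, j = j, m = m, p = k / r,
    q = .monotonize_q(.pi0_value(pi0) * (k / r) / (j / m), score),
    stringsAsFactors = FALSE, row.names = NULL)
  conservative_qvalues(tab, pi0c = pi0, budget = budget)
}

#' @rdname adjust_qvalues
#' @param table TSV path with a `gene_id` column and a `p` column (or two
#'   unnamed columns: id, p).
#' @param out output TSV path.
#' @export
run_adjust <- function(table, r, pi0 = 1, a = 0.05, out = NULL) {
  df <- utils::read.delim(table, header = TRUE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE)
  pcol <- if ("p" %in% names(df)) "p" else names(df)[min(2L, ncol(df))]
  idcol <- if ("gene_id" %in% names(df)) "gene_id" else names(df)[1]
  res <- adjust_qvalues(df[[pcol]], r = r, pi0 = pi0, a = a,
                        gene_ids = if (ncol(df) > 1L) df[[idcol]] else NULL)
  if (!is.null(out)) write_gene_results(res, out)
  invisible(res)
}
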