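#' Two-group expression matrix
#'
#' Bundles a genes x samples numeric matrix with a two-level group factor.
#' This is the raw input of the permutation analysis path: `m` genes measured
#' on `n1 + n2` samples split into exactly two groups.
#'
#' @param values numeric matrix, genes in rows, samples in columns. No
#'   missing values are allowed; rows with `NA` are rejected, not imputed.
#' @param gene_ids character vector of unique gene identifiers, one per row.
#'   Defaults to `rownames(values)` (or `gene_1 ... gene_m` if absent).
#' @param group_labels vector of length `ncol(values)` with exactly two
#'   distinct values, assigning each sample to a group.
#' @return An object of class `"expression_matrix"`: a list with elements
#'   `values` (the matrix, rownames set to `gene_ids`) and `groups`
#'   (a two-level factor).
#' @examples
#' x <- matrix(rnorm(40), nrow = 10)
#' em <- expression_matrix(x, group_labels = rep(c("A", "B"), each = 2))
#' em
#' @export
expression_matrix <- function(values, gene_ids = NULL, group_labels) {
  values <- as.matrix(values)
  if (!is.numeric(values)) {
    stop("expression values must be numeric", call. = FALSE)
  }
  if (nrow(values) < 1L) stop("need at least one gene", call. = FALSE)
  if (anyNA(values) || any(!is.finite(values))) {
    stop("expression matrix contains missing or non-finite values; ",
         "filter the input rather than imputing", call. = FALSE)
  }
  if (is.null(gene_ids)) {
    gene_ids <- rownames(values)
    if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(nrow(values)))
  }
  gene_ids <- as.character(gene_ids)
  if (length(gene_ids) != nrow(values)) {
    stop("gene_ids length must match the number of rows", call. = FALSE)
  }
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene identifiers: ",
         paste(utils::head(unique(gene_ids[duplicated(gene_ids)]), 3),
               collapse = ", "), call. = FALSE)
  }
  if (length(group_labels) != ncol(values)) {
    stop("one group label per sample is required", call. = FALSE)
  }
  if (anyNA(group_labels)) stop("group labels contain NA", call. = FALSE)
  groups <- factor(group_labels)
  if (nlevels(groups) != 2L) {
    stop("exactly two sample groups are required, got ", nlevels(groups),
         call. = FALSE)
  }
  rownames(values) <- gene_ids
  structure(list(values = values, groups = groups),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  n <- table(x$groups)
  cat(sprintf("expression_matrix: %d genes x %d samples (%s: %d, %s: %d)\n",
              nrow(x$values), ncol(x$values),
              names(n)[1], n[1], names(n)[2], n[2]))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

# group sizes (n1, n2) in level order
.group_sizes <- function(groups) as.integer(table(groups))
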