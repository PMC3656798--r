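#' Construct an expression matrix
#'
#' A validated genes-by-experiments matrix of real-valued expression
#' measurements. Rows are genes (with unique identifiers), columns are
#' experiments (arrays, time points, conditions or cells). This is the input
#' container for [hdp_cluster()] and the synthetic generators' output.
#'
#' Internally the sampler indexes an observation as \eqn{g_{ji}}: the value of
#' gene \eqn{i} in experiment \eqn{j}. On disk and in this container genes are
#' rows, which is the usual orientation for expression data.
#'
#' @param x numeric matrix (or object coercible to one), genes as rows.
#' @param gene_ids character vector of unique gene identifiers; defaults to
#'   `rownames(x)` or `gene1..geneN`.
#' @param experiment_ids character vector of experiment identifiers; defaults
#'   to `colnames(x)` or `exp1..expM`.
#' @return an `expression_matrix`: a numeric matrix with dimnames set and
#'   class `c("expression_matrix", "matrix", "array")`.
#' @examples
#' m <- expression_matrix(matrix(rnorm(6), 3, 2))
#' dim(m)
#' @export
expression_matrix <- function(x, gene_ids = NULL, experiment_ids = NULL) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("expression values must be numeric")
  if (nrow(x) < 1L || ncol(x) < 1L) stop("need at least one gene and one experiment")
  if (any(!is.finite(x)))
    stop("expression matrix contains non-finite values (NA/NaN/Inf); preprocess first")
  if (is.null(gene_ids)) gene_ids <- rownames(x)
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(nrow(x)))
  if (is.null(experiment_ids)) experiment_ids <- colnames(x)
  if (is.null(experiment_ids)) experiment_ids <- paste0("exp", seq_len(ncol(x)))
  gene_ids <- as.character(gene_ids)
  experiment_ids <- as.character(experiment_ids)
  if (length(gene_ids) != nrow(x)) stop("gene_ids length must equal nrow(x)")
  if (length(experiment_ids) != ncol(x)) stop("experiment_ids length must equal ncol(x)")
  if (anyDuplicated(gene_ids))
    stop("duplicate gene ids: ", paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  dimnames(x) <- list(gene_ids, experiment_ids)
  class(x) <- c("expression_matrix", "matrix", "array")
  x
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d experiments\n", nrow(x), ncol(x)))
  y <- unclass(x)
  print(head(y[, seq_len(min(6L, ncol(y))), drop = FALSE], 6L))
  if (nrow(x) > 6L || ncol(x) > 6L) cat("...\n")
  invisible(x)
}

#' @export
`[.expression_matrix` <- function(x, i, j, ..., drop = FALSE) {
  y <- NextMethod(drop = drop)
  if (is.matrix(y)) class(y) <- c("expression_matrix", "matrix", "array")
  y
}

is_expression_matrix <- function(x) inherits(x, "expression_matrix")

as_expression_matrix <- function(x) {
  if (is_expression_matrix(x)) x else expression_matrix(x)
}
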