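# Plain-text I/O: expression matrices (TSV/CSV, genes as rows), cluster
# tables, preprocessing, and optional JSON-lines trace serialization.

#' Read an expression matrix from TSV/CSV
#'
#' Expects a header row of experiment identifiers and a first column of
#' unique gene identifiers; all remaining cells numeric. Non-numeric cells
#' are reported with their gene and experiment location.
#'
#' @param path file path.
#' @param dialect `"tsv"` or `"csv"`; default guessed from the file
#'   extension (`.csv` means comma, anything else tab).
#' @return an [expression_matrix()].
#' @export
read_expression_matrix <- function(path, dialect = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(dialect))
    dialect <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "tsv"
  dialect <- match.arg(dialect, c("tsv", "csv"))
  sep <- if (dialect == "csv") "," else "\t"
  raw <- read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                    colClasses = "character", row.names = NULL,
                    stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("expected a gene-id column plus at least one experiment column")
  ids <- raw[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate gene ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  vals <- suppressWarnings(vapply(raw[-1L], as.numeric, numeric(nrow(raw))))
  vals <- matrix(vals, nrow = nrow(raw))
  bad <- which(is.na(vals), arr.ind = TRUE)
  if (nrow(bad)) {
    b <- bad[1L, ]
    stop(sprintf("non-numeric value '%s' at gene '%s', experiment '%s'",
                 raw[b[1L], b[2L] + 1L], ids[b[1L]], colnames(raw)[b[2L] + 1L]))
  }
  expression_matrix(vals, gene_ids = ids, experiment_ids = colnames(raw)[-1L])
}

#' Write an expression matrix to TSV/CSV
#'
#' @param x an [expression_matrix()] (or matrix with dimnames).
#' @param path output file path.
#' @param dialect `"tsv"` or `"csv"`; default guessed from the extension.
#' @export
write_expression_matrix <- function(x, path, dialect = NULL) {
  x <- as_expression_matrix(x)
  if (is.null(dialect))
    dialect <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "tsv"
  sep <- if (dialect == "csv") "," else "\t"
  df <- data.frame(gene_id = rownames(x), unclass(x), check.names = FALSE)
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter and transform an expression matrix
#'
#' Optionally applies a log2 transform (all values must be positive), then
#' drops genes whose mean falls below `min_mean` or whose variance falls
#' below `min_var` (both computed after any transform). Removal reasons are
#' reported per gene.
#'
#' @param x an [expression_matrix()].
#' @param log2 apply `log2` elementwise before filtering.
#' @param min_mean,min_var non-negative thresholds; 0 disables a filter.
#' @return list with `data` (the filtered [expression_matrix()]) and
#'   `removed` (data frame with columns `gene_id`, `reason`).
#' @export
preprocess <- function(x, log2 = FALSE, min_mean = 0, min_var = 0) {
  x <- as_expression_matrix(x)
  stopifnot(min_mean >= 0, min_var >= 0)
  if (log2) {
    if (any(x <= 0)) stop("log transform requires strictly positive values")
    x <- expression_matrix(log2(unclass(x)), rownames(x), colnames(x))
  }
  mu <- rowMeans(x)
  v <- apply(unclass(x), 1L, var)
  # a zero threshold disables its filter (log-scale data can have any sign)
  low_mean <- if (min_mean > 0) mu < min_mean else rep(FALSE, nrow(x))
  low_var <- if (min_var > 0) v < min_var else rep(FALSE, nrow(x))
  drop <- low_mean | low_var
  reason <- ifelse(low_mean & low_var, "mean+variance",
                   ifelse(low_mean, "mean", "variance"))
  removed <- data.frame(gene_id = rownames(x)[drop], reason = reason[drop],
                        stringsAsFactors = FALSE)
  if (all(drop)) stop("all genes removed by the filters")
  list(data = x[!drop, , drop = FALSE], removed = removed)
}

#' Write a cluster table
#'
#' Writes a TSV with columns `gene_id`, `cluster` and (when a
#' `membership_posterior` is supplied) `max_posterior_probability`, the
#' gene's aggregated membership probability of its assigned cluster.
#' With `long = TRUE` a second data frame of per-experiment memberships
#' (`gene_id`, `experiment_id`, `cluster`, `probability`) is also written to
#' `<path>.long.tsv`.
#'
#' @param partition named integer vector of cluster labels (e.g.
#'   [map_assignment()] output or `fit$cluster`).
#' @param path output file path.
#' @param posterior optional `membership_posterior`.
#' @param long also write the per-experiment membership table.
#' @return the main output path, invisibly.
#' @export
write_clusters <- function(partition, path, posterior = NULL, long = FALSE) {
  df <- data.frame(gene_id = names(partition), cluster = as.integer(partition),
                   stringsAsFactors = FALSE)
  if (!is.null(posterior)) {
    stopifnot(inherits(posterior, "membership_posterior"))
    gp <- posterior$gene
    # probability of the gene's modal canonical label
    df$max_posterior_probability <- apply(gp, 1L, max)
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (long && !is.null(posterior)) {
    P <- posterior$P
    M <- dim(P)[1L]; N <- dim(P)[2L]
    zhat <- apply(P, c(1L, 2L), which.max)
    phat <- apply(P, c(1L, 2L), max)
    longdf <- data.frame(
      gene_id = rep(posterior$gene_ids, each = M),
      experiment_id = rep(seq_len(M), times = N),
      cluster = as.vector(zhat),
      probability = as.vector(phat))
    write.table(longdf, paste0(path, ".long.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(path)
}

#' Read a cluster table written by [write_clusters()]
#'
#' @param path file path.
#' @return named integer vector of cluster labels.
#' @export
read_clusters <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "cluster") %in% names(df)))
    stop("cluster table needs gene_id and cluster columns")
  out <- as.integer(df$cluster)
  names(out) <- df$gene_id
  out
}

#' Serialize a chain trace as JSON lines
#'
#' One JSON object per snapshot: canonical table labels `phi` and dish
#' labels `z` (row-major lists over experiments), concentration values and
#' the snapshot index.
#'
#' @param trace an `hdp_trace`.
#' @param path output path.
#' @export
write_trace_jsonl <- function(trace, path) {
  stopifnot(inherits(trace, "hdp_trace"))
  L <- dim(trace$z)[3L]
  con <- file(path, "w")
  on.exit(close(con))
  M <- dim(trace$z)[1L]
  for (l in seq_len(L)) {
    rec <- list(iteration = l,
                phi = lapply(seq_len(M), function(j) trace$tab[j, , l]),
                z = lapply(seq_len(M), function(j) trace$z[j, , l]),
                alpha0 = trace$alpha0[l], alpha1 = trace$alpha1[l])
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}
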