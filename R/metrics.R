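#' Pair agreement counts between two partitions
#'
#' Counts the \eqn{n(n-1)/2} unordered item pairs into the four classes used
#' by the Rand index: `Z1` pairs together in both partitions, `Z2` pairs
#' apart in both, `Z3` together in `x` only, `Z4` together in `y` only.
#'
#' @param x,y cluster label vectors over the same items (any label type).
#' @return named integer vector `c(Z1, Z2, Z3, Z4)`.
#' @export
pair_counts <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("partitions must label the same items")
  if (n < 2L) stop("need at least 2 items")
  if (!is.null(names(x)) && !is.null(names(y))) {
    if (!setequal(names(x), names(y))) stop("partitions must label the same items")
    y <- y[names(x)]
  }
  tab <- table(x, y)
  total <- choose(n, 2)
  same_both <- sum(choose(tab, 2))
  same_x <- sum(choose(rowSums(tab), 2))
  same_y <- sum(choose(colSums(tab), 2))
  z <- c(Z1 = same_both,
         Z2 = total - same_x - same_y + same_both,
         Z3 = same_x - same_both,
         Z4 = same_y - same_both)
  storage.mode(z) <- "integer"
  z
}

#' Rand index between two partitions
#'
#' Fraction of unordered item pairs on which two clusterings agree (both
#' together or both apart): \eqn{RI = (Z_1 + Z_2) / (Z_1+Z_2+Z_3+Z_4)}.
#' Symmetric in its arguments, invariant to relabeling, in `[0, 1]` with 1
#' for identical partitions.
#'
#' @inheritParams pair_counts
#' @return scalar in `[0, 1]`.
#' @examples
#' rand_index(c(1, 1, 2), c(1, 2, 3))  # 2/3
#' @export
rand_index <- function(x, y) {
  z <- pair_counts(x, y)
  (z[["Z1"]] + z[["Z2"]]) / sum(z)
}

#' Silhouette index of a clustering
#'
#' Mean silhouette width over all points. For point `p` with within-cluster
#' mean distance `x` and minimum mean distance `y` to any other cluster,
#' \eqn{s(p) = (y - x) / \max(x, y)}; a point alone in its cluster
#' contributes 0. Values lie in `[-1, 1]`; higher means more compact,
#' better-separated clusters.
#'
#' @param data an [expression_matrix()] / numeric matrix whose rows are the
#'   clustered points (genes), or a [stats::dist] object / square distance
#'   matrix.
#' @param labels cluster label vector, one per point; at least two distinct
#'   clusters are required.
#' @param metric distance metric passed to [stats::dist()] when `data` is a
#'   matrix of coordinates (default `"euclidean"`).
#' @return scalar in `[-1, 1]`.
#' @export
silhouette_index <- function(data, labels, metric = "euclidean") {
  if (inherits(data, "dist")) {
    D <- as.matrix(data)
  } else if (is.matrix(data) && nrow(data) == ncol(data) &&
             !is_expression_matrix(data) && isTRUE(all.equal(unname(data), unname(t(data))))) {
    D <- data
  } else {
    D <- as.matrix(dist(unclass(data), method = metric))
  }
  n <- nrow(D)
  labels <- as.vector(labels)
  if (length(labels) != n) stop("one label per point required")
  labs <- unique(labels)
  if (length(labs) < 2L) stop("silhouette undefined for a single cluster")
  s <- numeric(n)
  for (p in seq_len(n)) {
    own <- labels == labels[p]
    if (sum(own) == 1L) { s[p] <- 0; next }
    x <- mean(D[p, own & seq_len(n) != p])
    y <- min(vapply(labs[labs != labels[p]],
                    function(l) mean(D[p, labels == l]), 0))
    s[p] <- if (max(x, y) == 0) 0 else (y - x) / max(x, y)
  }
  mean(s)
}
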