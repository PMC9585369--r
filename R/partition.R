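#' Cluster partitions
#'
#' A partition assigns each specimen a cluster label `1..K` or the noise
#' label `0`. All clustering backends in the package return partitions in a
#' canonical labelling: clusters are numbered by ascending cluster mean of
#' the first canonical feature (head capsule length), so cluster 1 is always
#' the smallest (earliest) instar.
#'
#' @param labels integer vector of labels, `0` for noise.
#' @return A `partition` object.
#' @export
partition <- function(labels) {
  labels <- as.integer(labels)
  if (any(is.na(labels)) || any(labels < 0)) {
    stop("labels must be nonnegative integers (0 = noise)")
  }
  k <- length(setdiff(unique(labels), 0L))
  structure(list(labels = labels, K = k), class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  sizes <- cluster_sizes(x)
  cat("partition: n =", length(x$labels), " K =", x$K,
      " noise =", sum(x$labels == 0L), "\n")
  if (x$K > 0) cat("cluster sizes:", paste(sizes, collapse = ", "), "\n")
  invisible(x)
}

#' @rdname partition
#' @param x a `partition`.
#' @export
partition_labels <- function(x) {
  if (inherits(x, "partition")) x$labels else as.integer(x)
}

#' Non-noise cluster sizes of a partition, in label order
#' @param x a `partition`.
#' @return Named integer vector of cluster sizes (labels `1..K`).
#' @export
cluster_sizes <- function(x) {
  labels <- partition_labels(x)
  labels <- labels[labels != 0L]
  if (length(labels) == 0) return(integer(0))
  tab <- table(factor(labels, levels = sort(unique(labels))))
  stats::setNames(as.integer(tab), names(tab))
}

#' Canonicalize cluster labels by instar size order
#'
#' Renumbers non-noise clusters `1..K` by ascending cluster mean of the first
#' canonical feature, making instar numbering deterministic and biologically
#' ordered regardless of the order in which a backend discovered clusters.
#'
#' @param labels raw integer labels (`0` = noise), any numbering.
#' @param table the `measurement_table` the labels refer to.
#' @return A canonical `partition`.
#' @export
canonicalize_partition <- function(labels, table) {
  labels <- as.integer(labels)
  stopifnot(length(labels) == nrow(table))
  f1 <- feature_matrix(table)[, 1L]
  ids <- setdiff(sort(unique(labels)), 0L)
  if (length(ids) == 0) return(partition(labels))
  means <- vapply(ids, function(g) mean(f1[labels == g]), numeric(1))
  remap <- integer(max(ids))
  remap[ids[order(means)]] <- seq_along(ids)
  out <- labels
  nz <- labels != 0L
  out[nz] <- remap[labels[nz]]
  partition(out)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two clusterings of the same specimens;
#' 1 means identical partitions. Noise (label 0) is treated as a class of its
#' own.
#'
#' @param a,b `partition` objects or label vectors of equal length.
#' @return The adjusted Rand index, a scalar in (-1, 1].
#' @export
adjusted_rand <- function(a, b) {
  la <- partition_labels(a)
  lb <- partition_labels(b)
  stopifnot(length(la) == length(lb))
  mclust::adjustedRandIndex(la, lb)
}
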