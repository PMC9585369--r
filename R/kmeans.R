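#' k-means clustering by Lloyd iteration
#'
#' Classical Lloyd iterations (assign to nearest center, recompute centers)
#' from `n_starts` random initializations; the solution with the lowest
#' within-cluster sum of squares (WSS) is returned. Iteration stops when no
#' label changes or after `max_iter` rounds. A cluster that empties is
#' repaired by reseeding its center at the point farthest from its assigned
#' center, so every returned cluster is non-empty. The per-iteration WSS
#' trace of the winning start is recorded; it is non-increasing.
#'
#' @param table a `measurement_table`.
#' @param k number of clusters, `1 <= k <= n`; the published comparison uses
#'   k = 4.
#' @param seed integer seed controlling the random initializations.
#' @param n_starts number of random initializations (default 10).
#' @param max_iter Lloyd iteration cap per start (default 300).
#' @return A `kmeans_fit`: list with `centers` (k x 3), `partition`
#'   (canonical), `wss` (total within-cluster sum of squares), `wss_trace`
#'   (per-iteration WSS of the winning start), `iterations`, `k`, `seed`.
#' @export
kmeans_lloyd <- function(table, k, seed = 1L, n_starts = 10L,
                         max_iter = 300L) {
  x <- feature_matrix(table)
  n <- nrow(x)
  k <- as.integer(k)
  if (k < 1L || k > n) stop("k must satisfy 1 <= k <= n (n = ", n, ")")
  set.seed(as.integer(seed))
  best <- NULL
  for (s in seq_len(n_starts)) {
    centers <- x[sample.int(n, k), , drop = FALSE]
    labels <- integer(n)
    trace <- numeric(0)
    for (it in seq_len(max_iter)) {
      d2 <- point_center_dist2(x, centers)
      new_labels <- max.col(-d2, ties.method = "first")
      # repair empty clusters: reseed at the point farthest from its center
      repeat {
        empties <- which(tabulate(new_labels, k) == 0L)
        if (length(empties) == 0L) break
        far <- which.max(d2[cbind(seq_len(n), new_labels)])
        centers[empties[1L], ] <- x[far, ]
        d2 <- point_center_dist2(x, centers)
        new_labels <- max.col(-d2, ties.method = "first")
      }
      trace <- c(trace, sum(d2[cbind(seq_len(n), new_labels)]))
      converged <- identical(new_labels, labels)
      labels <- new_labels
      for (j in seq_len(k)) {
        centers[j, ] <- colMeans(x[labels == j, , drop = FALSE])
      }
      if (converged) break
    }
    d2 <- point_center_dist2(x, centers)
    wss <- sum(d2[cbind(seq_len(n), labels)])
    if (is.null(best) || wss < best$wss) {
      best <- list(centers = centers, labels = labels, wss = wss,
                   wss_trace = trace, iterations = length(trace))
    }
  }
  part <- canonicalize_partition(best$labels, table)
  ord <- order(best$centers[, 1L])
  structure(list(centers = best$centers[ord, , drop = FALSE],
                 partition = part, wss = best$wss,
                 wss_trace = best$wss_trace,
                 iterations = best$iterations, k = k,
                 seed = as.integer(seed)),
            class = "kmeans_fit")
}

# squared Euclidean distances of every point to every center (n x k)
point_center_dist2 <- function(x, centers) {
  xs <- rowSums(x^2)
  cs <- rowSums(centers^2)
  outer(xs, cs, "+") - 2 * x %*% t(centers)
}
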