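#' k-nearest-neighbor distance diagnostic
#'
#' Computes, for every specimen, the Euclidean distance to its k-th nearest
#' other specimen (raw cm-scale features, no standardization), returns the
#' distances sorted ascending, and estimates the "knee" of the sorted curve —
#' the usual heuristic for choosing the DBSCAN neighborhood radius eps — as
#' the point of maximum curvature (largest second difference).
#'
#' @param table a `measurement_table`.
#' @param k neighbor rank, `1 <= k < n`.
#' @return A list with `distances` (sorted ascending, length n), `knee` (the
#'   estimated eps) and `knee_index` (position of the knee on the sorted
#'   curve).
#' @export
knn_distances <- function(table, k) {
  x <- feature_matrix(table)
  n <- nrow(x)
  k <- as.integer(k)
  if (k < 1L || k >= n) stop("k must satisfy 1 <= k < n (n = ", n, ")")
  d <- as.matrix(stats::dist(x))
  kd <- vapply(seq_len(n), function(i) sort(d[i, -i])[k], numeric(1))
  ds <- sort(kd)
  knee_index <- if (n >= 3L) {
    d2 <- ds[-(1:2)] - 2 * ds[-c(1L, n)] + ds[-((n - 1L):n)]
    which.max(d2) + 1L
  } else n
  list(distances = ds, knee = ds[knee_index], knee_index = knee_index)
}

#' OPTICS cluster-ordering of a measurement table
#'
#' Orders the specimens by density reachability: starting from an unprocessed
#' point, the algorithm repeatedly visits the seed point with the smallest
#' current reachability-distance, where the reachability-distance of p from q
#' is `max(core_distance(q), d(p, q))` and the core-distance of q is the
#' distance to its (minPts-1)-th nearest other point (`UNDEFINED`, stored as
#' `NA`, when fewer than `minPts` points lie within `eps` of q, the point
#' itself included). The visit order plus per-point core- and
#' reachability-distances are the result; flat clusterings are derived from
#' them with [extract_clusters_reachability()] or [extract_clusters_xi()].
#'
#' Ties in the seed queue (equal reachability) and in neighbor lists are
#' broken by lowest input index, so the ordering is deterministic. `eps` is a
#' computational bound only and defaults to `Inf`; unprocessed points with
#' undefined reachability start new batches in input order.
#'
#' @param table a `measurement_table`.
#' @param minPts density threshold (neighborhood size including the point
#'   itself); the published analysis uses 5.
#' @param eps neighborhood radius bound, default `Inf`.
#' @return An `optics_result`: list with `order`, `reachability`,
#'   `core_distance`, `predecessor` (all in input-index space; distances `NA`
#'   when undefined), `eps`, `minPts`, and `n`.
#' @export
optics_order <- function(table, minPts = 5L, eps = Inf) {
  x <- feature_matrix(table)
  n <- nrow(x)
  minPts <- as.integer(minPts)
  stopifnot(n >= 1L, minPts >= 1L, eps > 0)
  d <- as.matrix(stats::dist(x))
  core <- rep(NA_real_, n)
  nbrs <- vector("list", n)
  for (i in seq_len(n)) {
    within <- which(d[i, ] <= eps)          # includes i itself
    nbrs[[i]] <- setdiff(within, i)
    if (length(within) >= minPts) {
      core[i] <- if (minPts == 1L) 0 else sort(d[i, nbrs[[i]]])[minPts - 1L]
    }
  }
  reach <- rep(NA_real_, n)
  pred <- rep(NA_integer_, n)
  processed <- rep(FALSE, n)
  ord <- integer(n)
  pos <- 0L
  in_seeds <- rep(FALSE, n)

  update_seeds <- function(p) {
    for (o in nbrs[[p]]) {
      if (processed[o]) next
      newr <- max(core[p], d[p, o])
      if (is.na(reach[o]) || newr < reach[o]) {
        reach[o] <<- newr
        pred[o] <<- p
        in_seeds[o] <<- TRUE
      }
    }
  }
  for (start in seq_len(n)) {
    if (processed[start]) next
    processed[start] <- TRUE
    pos <- pos + 1L
    ord[pos] <- start
    if (!is.na(core[start])) update_seeds(start)
    repeat {
      cand <- which(in_seeds)
      if (length(cand) == 0L) break
      q <- cand[which.min(reach[cand])]     # ties: lowest input index
      in_seeds[q] <- FALSE
      processed[q] <- TRUE
      pos <- pos + 1L
      ord[pos] <- q
      if (!is.na(core[q])) update_seeds(q)
    }
  }
  structure(list(order = ord, reachability = reach, core_distance = core,
                 predecessor = pred, eps = eps, minPts = minPts, n = n),
            class = "optics_result")
}

#' @export
print.optics_result <- function(x, ...) {
  cat("OPTICS ordering: n =", x$n, " minPts =", x$minPts,
      " eps =", x$eps, "\n")
  cat("core-distances defined for", sum(!is.na(x$core_distance)),
      "points\n")
  invisible(x)
}

#' Flat cluster extraction from an OPTICS ordering at a reachability threshold
#'
#' Scans the points in OPTICS order: a point whose reachability-distance
#' exceeds `eps_cl` starts a new cluster if its core-distance is defined and
#' at most `eps_cl`, and is noise otherwise; any other point joins the
#' current cluster. This is the standard flat extraction, equivalent to
#' DBSCAN at radius `eps_cl` in its labeling of core points.
#'
#' @param res an `optics_result`.
#' @param table the `measurement_table` that was ordered (for canonical
#'   relabeling by ascending head-capsule-length mean).
#' @param eps_cl extraction radius, must not exceed the ordering `eps`.
#' @return A canonical `partition`.
#' @export
extract_clusters_reachability <- function(res, table, eps_cl) {
  stopifnot(inherits(res, "optics_result"))
  if (eps_cl > res$eps) stop("eps_cl exceeds the eps used for the ordering")
  labels <- integer(res$n)
  cur <- 0L
  have_cluster <- FALSE
  for (p in res$order) {
    r <- res$reachability[p]
    if (is.na(r) || r > eps_cl) {
      if (!is.na(res$core_distance[p]) && res$core_distance[p] <= eps_cl) {
        cur <- cur + 1L
        labels[p] <- cur
        have_cluster <- TRUE
      } else {
        labels[p] <- 0L
      }
    } else {
      labels[p] <- if (have_cluster) cur else 0L
    }
  }
  canonicalize_partition(labels, table)
}

#' Xi-method cluster extraction from an OPTICS ordering
#'
#' Detects clusters as regions of the reachability profile bounded by a
#' xi-steep down area and a xi-steep up area (a point is xi-steep down when
#' the next reachability is lower by at least a factor `1 - xi`, and
#' symmetrically for up). Returns the detected cluster intervals (a
#' hierarchy: intervals may nest) and a flat partition formed from the leaf
#' intervals; points in no leaf are noise. A profile with no steep
#' down/up pair yields a single all-points cluster.
#'
#' @param res an `optics_result`.
#' @param table the ordered `measurement_table`.
#' @param xi steepness fraction in (0, 1), default 0.05.
#' @param min_cluster_size minimum points per cluster; defaults to the
#'   ordering's `minPts`.
#' @return A list with `intervals` (data.frame of `start`, `end` positions in
#'   visit order) and `partition` (canonical `partition`).
#' @export
extract_clusters_xi <- function(res, table, xi = 0.05,
                                min_cluster_size = NULL) {
  stopifnot(inherits(res, "optics_result"), xi > 0, xi < 1)
  if (is.null(min_cluster_size)) min_cluster_size <- res$minPts
  n <- res$n
  r <- res$reachability[res$order]
  r[is.na(r)] <- Inf
  r <- c(r, Inf)                     # sentinel closes the final up area
  xic <- 1 - xi
  ratio <- r[1:n] / r[2:(n + 1)]
  ratio[is.nan(ratio)] <- 1          # Inf/Inf
  steep_up <- ratio <= xic
  steep_down <- ratio >= 1 / xic
  upward <- ratio < 1
  downward <- ratio > 1

  extend_region <- function(steep, inverse, start) {
    non_steep <- 0L
    end <- start
    i <- start
    while (i <= n) {
      if (steep[i]) {
        non_steep <- 0L
        end <- i
      } else if (!inverse[i]) {
        non_steep <- non_steep + 1L
        if (non_steep > res$minPts) break
      } else break
      i <- i + 1L
    }
    end
  }
  filter_sdas <- function(sdas, mib) {
    if (is.infinite(mib)) return(list())
    keep <- list()
    for (D in sdas) {
      if (mib <= r[D$start] * xic) {
        D$mib <- max(D$mib, mib)
        keep[[length(keep) + 1L]] <- D
      }
    }
    keep
  }

  sdas <- list()
  intervals <- list()
  steep_idx <- which(steep_up | steep_down)
  index <- 1L
  mib <- -Inf
  for (si in steep_idx) {
    if (si < index) next
    mib <- max(mib, max(r[index:si]))
    if (steep_down[si]) {
      sdas <- filter_sdas(sdas, mib)
      d_end <- extend_region(steep_down, upward, si)
      sdas[[length(sdas) + 1L]] <- list(start = si, end = d_end, mib = 0)
      index <- d_end + 1L
      mib <- r[index]
    } else {
      sdas <- filter_sdas(sdas, mib)
      u_start <- si
      u_end <- extend_region(steep_up, downward, si)
      index <- u_end + 1L
      mib <- r[index]
      found <- list()
      for (D in sdas) {
        c_start <- D$start
        c_end <- u_end
        if (r[c_end + 1L] * xic < D$mib) next
        d_max <- r[D$start]
        if (d_max * xic >= r[c_end + 1L]) {
          while (c_start < D$end && r[c_start + 1L] > r[c_end + 1L]) {
            c_start <- c_start + 1L
          }
        } else if (r[c_end + 1L] * xic >= d_max) {
          while (c_end > u_start && r[c_end - 1L] > d_max) {
            c_end <- c_end - 1L
          }
        }
        if (c_end - c_start + 1L < min_cluster_size) next
        if (c_start > D$end || c_end < u_start) next
        found[[length(found) + 1L]] <- c(c_start, c_end)
      }
      intervals <- c(intervals, rev(found))   # smaller (nested) first
    }
  }

  labels <- integer(n)
  if (length(intervals) == 0L) {
    labels[] <- 1L
    ivd <- data.frame(start = integer(0), end = integer(0))
  } else {
    nextlab <- 0L
    for (iv in intervals) {
      span <- iv[1]:iv[2]
      if (all(labels[span] == 0L)) {
        nextlab <- nextlab + 1L
        labels[span] <- nextlab
      }
    }
    ivd <- data.frame(start = vapply(intervals, `[`, integer(1), 1L),
                      end = vapply(intervals, `[`, integer(1), 2L))
  }
  input_labels <- integer(n)
  input_labels[res$order] <- labels
  list(intervals = ivd,
       partition = canonicalize_partition(input_labels, table))
}

#' DBSCAN clustering of a measurement table
#'
#' Density-based flat clustering at a fixed neighborhood radius: points with
#' at least `minPts` neighbors within `eps` (themselves included) are core
#' points; clusters are the connected components of core points under mutual
#' eps-reachability, expanded to the density-reachable border points; all
#' other points are noise. Distances are Euclidean on the raw cm-scale
#' features. The published comparison uses `eps = 0.04`, `minPts = 4`.
#'
#' @param table a `measurement_table`.
#' @param eps finite neighborhood radius (cm).
#' @param minPts density threshold including the point itself.
#' @return A canonical `partition` (noise labeled 0).
#' @export
dbscan_cluster <- function(table, eps, minPts) {
  x <- feature_matrix(table)
  n <- nrow(x)
  minPts <- as.integer(minPts)
  stopifnot(is.finite(eps), eps > 0, minPts >= 1L)
  d <- as.matrix(stats::dist(x))
  nbrs <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))  # incl. self
  is_core <- vapply(nbrs, length, integer(1)) >= minPts
  labels <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !is_core[i]) next
    cur <- cur + 1L
    queue <- i
    labels[i] <- cur
    while (length(queue) > 0L) {
      p <- queue[1L]
      queue <- queue[-1L]
      for (o in nbrs[[p]]) {
        if (labels[o] == 0L) {
          labels[o] <- cur
          if (is_core[o]) queue <- c(queue, o)
        }
      }
    }
  }
  canonicalize_partition(labels, table)
}
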