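# Independent oracles and fixture builders used across the suite.

# mclust serves as the independent mixture-model oracle; Mclust() resolves
# helper functions in the search path, so the package must be attached.
suppressPackageStartupMessages(library(mclust))

# Build a measurement_table from explicit feature columns; constant positive
# filler for unspecified features.
make_table <- function(f1, f2 = NULL, f3 = NULL, instar = NULL) {
  n <- length(f1)
  df <- data.frame(head_capsule_length_cm = f1,
                   head_capsule_width_cm = if (is.null(f2)) rep(0.5, n) else f2,
                   mandible_width_cm = if (is.null(f3)) rep(0.25, n) else f3)
  if (!is.null(instar)) df$instar <- instar
  measurement_table(df)
}

# Brute-force DBSCAN oracle, mechanically different from the package
# implementation: min-label propagation over the mutual-reachability graph
# instead of queue expansion. Labels: 0 noise, clusters renumbered 1..K in
# order of smallest member index.
oracle_dbscan <- function(x, eps, minPts) {
  n <- nrow(x)
  d <- as.matrix(dist(x))
  core <- rowSums(d <= eps) >= minPts      # diagonal counts the point itself
  lab <- ifelse(core, seq_len(n), 0L)
  repeat {
    changed <- FALSE
    for (i in which(core)) {
      nb <- which(core & d[i, ] <= eps)
      m <- min(lab[c(i, nb)])
      if (any(lab[c(i, nb)] != m)) {
        lab[c(i, nb)] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  for (i in which(!core)) {
    nb <- which(core & d[i, ] <= eps)
    lab[i] <- if (length(nb) > 0) lab[min(nb)] else 0L
  }
  ids <- setdiff(unique(lab[order(seq_len(n))]), 0L)
  out <- integer(n)
  for (j in seq_along(sort(ids))) out[lab == sort(ids)[j]] <- j
  out
}

# Random small measurement table for property tests.
random_table <- function(n, seed) {
  set.seed(seed)
  k <- sample(1:3, 1)
  centers <- matrix(runif(k * 3, 0.1, 1), k, 3)
  g <- sample(k, n, replace = TRUE)
  x <- centers[g, , drop = FALSE] + matrix(rnorm(n * 3, sd = 0.05), n, 3)
  x <- abs(x) + 1e-3
  make_table(x[, 1], x[, 2], x[, 3])
}

# Two tight, widely separated grid blobs: within-blob reachability is exactly
# constant, so xi-steep structure exists only at the blob boundary.
two_blob_table <- function(per_blob = 20L, step = 0.001, gap = 0.4) {
  a <- 0.1 + step * seq_len(per_blob)
  b <- 0.1 + gap + step * seq_len(per_blob)
  make_table(c(a, b))
}
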