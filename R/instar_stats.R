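#' Per-instar morphometric summary statistics
#'
#' For every non-noise cluster of the partition (taken as an instar, ordered
#' by ascending head-capsule-length mean) and every feature: count, mean,
#' SD, observed range and coefficient of variation, plus the Brooks-Dyar
#' index (ratio of successive instar means, defined from instar 2) and the
#' Crosby index (relative change of successive Brooks-Dyar indices, defined
#' from instar 2 when a successor exists). Noise points are excluded.
#'
#' @param table a `measurement_table`.
#' @param partition a `partition` over the table.
#' @return Data.frame with columns `feature`, `instar`, `n`, `mean`, `sd`,
#'   `min`, `max`, `cv`, `dyar`, `crosby` (the last two `NA` where
#'   undefined).
#' @export
summarize_instars <- function(table, partition) {
  labels <- partition_labels(partition)
  stopifnot(length(labels) == nrow(table))
  keep <- labels != 0L
  if (!any(keep)) stop("partition has no non-noise specimens")
  x <- feature_matrix(table)[keep, , drop = FALSE]
  labels <- labels[keep]
  instars <- sort(unique(labels))
  out <- list()
  for (f in feature_columns()) {
    v <- x[, f]
    means <- vapply(instars, function(g) mean(v[labels == g]), numeric(1))
    sds <- vapply(instars, function(g) stats::sd(v[labels == g]), numeric(1))
    sds[is.na(sds)] <- 0
    dyar <- if (length(instars) >= 2L) {
      c(NA_real_, brooks_dyar_indices(means))
    } else NA_real_
    crosby <- rep(NA_real_, length(instars))
    if (length(instars) >= 3L) {
      cr <- crosby_indices(dyar[-1L])$crosby
      crosby[seq_along(cr) + 1L] <- cr
    }
    out[[f]] <- data.frame(
      feature = f, instar = instars,
      n = vapply(instars, function(g) sum(labels == g), integer(1)),
      mean = means, sd = sds,
      min = vapply(instars, function(g) min(v[labels == g]), numeric(1)),
      max = vapply(instars, function(g) max(v[labels == g]), numeric(1)),
      cv = ifelse(means > 0, 100 * sds / means, NA_real_),
      dyar = dyar, crosby = crosby)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Brooks-Dyar growth indices of an instar mean sequence
#'
#' Dyar's rule: sclerotized structures grow geometrically across instars, so
#' the ratio of successive instar means is approximately constant. This
#' computes those ratios.
#'
#' @param means strictly positive per-instar mean sizes, at least 2.
#' @return Numeric vector of successive ratios, one fewer than `means`.
#' @export
brooks_dyar_indices <- function(means) {
  means <- as.numeric(means)
  if (length(means) < 2L) stop("need at least 2 instar means")
  if (any(!is.finite(means) | means <= 0)) stop("means must be positive")
  means[-1L] / means[-length(means)]
}

#' Crosby indices of a Brooks-Dyar sequence
#'
#' The Crosby rule flags an instar series as consistent (no missed or split
#' instar) when the relative change between successive Brooks-Dyar indices
#' stays below a threshold, conventionally 10%.
#'
#' @param dyar at least 2 Brooks-Dyar indices.
#' @param threshold pass threshold on `|C|` (default 0.10).
#' @return List with `crosby` (one fewer than `dyar`) and `pass`
#'   (`all(abs(crosby) < threshold)`).
#' @export
crosby_indices <- function(dyar, threshold = 0.10) {
  dyar <- as.numeric(dyar)
  if (length(dyar) < 2L) stop("need at least 2 Brooks-Dyar indices")
  crosby <- (dyar[-1L] - dyar[-length(dyar)]) / dyar[-length(dyar)]
  list(crosby = crosby, pass = all(abs(crosby) < threshold))
}

#' Brooks-Dyar log-linear growth regression
#'
#' Ordinary least squares of the natural log of a feature, converted from cm
#' to mm, on instar number (1..K from the partition labels), over all
#' non-noise specimens. Under geometric growth the slope b makes `exp(b)` the
#' growth-rate constant: the overall Brooks-Dyar ratio. The mm scale is the
#' one on which the fitted constants back-predict the instar means.
#'
#' @param table a `measurement_table`.
#' @param partition a `partition` with at least 2 instars.
#' @param feature one of [feature_columns()].
#' @return A `dyar_fit`: list with `feature`, `slope`, `intercept`,
#'   `growth_rate` (`exp(slope)`), `r_squared`, `rss`, `df` (n - 2),
#'   `p_value` (two-sided t-test of the slope), `n`.
#' @export
dyar_regression <- function(table, partition, feature = "mandible_width_cm") {
  stopifnot(feature %in% feature_columns())
  labels <- partition_labels(partition)
  keep <- labels != 0L
  y <- log(feature_matrix(table)[keep, feature] * 10)   # cm -> mm
  instar <- labels[keep]
  if (length(unique(instar)) < 2L) {
    stop("regression needs at least 2 instars")
  }
  if (length(y) < 3L) stop("regression needs at least 3 specimens")
  fit <- stats::lm(y ~ instar)
  # a noiseless geometric series fits exactly; the perfect-fit warning from
  # summary.lm is expected there and the slope p-value is still well-defined
  sm <- suppressWarnings(summary(fit))
  structure(list(feature = feature,
                 slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 growth_rate = exp(unname(stats::coef(fit)[2L])),
                 r_squared = sm$r.squared,
                 rss = sum(stats::residuals(fit)^2),
                 df = fit$df.residual,
                 p_value = sm$coefficients[2L, 4L],
                 n = length(y)),
            class = "dyar_fit")
}

#' @export
print.dyar_fit <- function(x, ...) {
  cat(sprintf("ln(%s, mm) = %.3f * instar %+.3f\n",
              sub("_cm$", "", x$feature), x$slope, x$intercept))
  cat(sprintf("growth rate e^b = %.3f  R^2 = %.3f  RSS = %.3f  df = %d\n",
              x$growth_rate, x$r_squared, x$rss, x$df))
  invisible(x)
}

#' Brooks-Dyar regression from grouped instar means
#'
#' Weighted least squares of the log instar means on instar number, weighted
#' by group sizes — the grouped form of [dyar_regression()] whose slope and
#' intercept depend only on the per-instar means and counts. Useful for
#' reproducing the published regression constants from a printed summary
#' table.
#'
#' @param means per-instar feature means in mm.
#' @param counts per-instar specimen counts (the weights).
#' @return List with `slope`, `intercept`, `growth_rate`.
#' @export
dyar_regression_grouped <- function(means, counts) {
  stopifnot(length(means) == length(counts), length(means) >= 2L,
            all(means > 0), all(counts > 0))
  instar <- seq_along(means)
  fit <- stats::lm(log(means) ~ instar, weights = counts)
  co <- stats::coef(fit)
  list(slope = unname(co[2L]), intercept = unname(co[1L]),
       growth_rate = exp(unname(co[2L])))
}

#' Size-frequency analysis of an instar partition
#'
#' Builds per-instar histograms of each feature on a shared grid and
#' measures the overlap of the observed ranges of adjacent instars. A clean
#' instar series shows non-overlapping size-frequency distributions.
#'
#' @param table a `measurement_table`.
#' @param partition a `partition`.
#' @param bin_width named numeric vector of histogram bin widths per feature
#'   (cm); defaults to 0.02 cm for the head-capsule features and 0.01 cm for
#'   mandible width, about half the smallest instar SD.
#' @return List per feature: `breaks` (shared bin edges), `counts` (matrix,
#'   instars x bins), `overlap` (length of range overlap between adjacent
#'   instars, cm), `any_overlap` flag. Top-level `any_overlap` aggregates all
#'   features.
#' @export
frequency_analysis <- function(table, partition, bin_width = NULL) {
  if (is.null(bin_width)) {
    bin_width <- stats::setNames(c(0.02, 0.02, 0.01), feature_columns())
  }
  labels <- partition_labels(partition)
  keep <- labels != 0L
  x <- feature_matrix(table)[keep, , drop = FALSE]
  labels <- labels[keep]
  instars <- sort(unique(labels))
  res <- list()
  for (f in feature_columns()) {
    v <- x[, f]
    bw <- bin_width[[f]]
    lo <- floor(min(v) / bw) * bw
    hi <- ceiling(max(v) / bw) * bw
    if (hi <= lo + bw / 2) hi <- lo + bw    # constant feature: one bin
    breaks <- seq(lo, hi, by = bw)
    counts <- t(vapply(instars, function(g) {
      graphics::hist(v[labels == g], breaks = breaks, plot = FALSE)$counts
    }, numeric(length(breaks) - 1L)))
    rng <- t(vapply(instars, function(g) range(v[labels == g]), numeric(2)))
    overlap <- if (length(instars) >= 2L) {
      vapply(seq_len(length(instars) - 1L), function(i) {
        max(0, min(rng[i, 2L], rng[i + 1L, 2L]) -
              max(rng[i, 1L], rng[i + 1L, 1L]))
      }, numeric(1))
    } else numeric(0)
    res[[f]] <- list(breaks = breaks, counts = counts, ranges = rng,
                     overlap = overlap, any_overlap = any(overlap > 0))
  }
  res$any_overlap <- any(vapply(res[feature_columns()],
                                function(z) z$any_overlap, logical(1)))
  res
}

#' Range overlap of adjacent instars
#'
#' Overlap length between two observed ranges:
#' `max(0, min(max1, max2) - max(min1, min2))`.
#'
#' @param range1,range2 numeric length-2 `(min, max)` vectors.
#' @return Nonnegative overlap length.
#' @export
range_overlap <- function(range1, range2) {
  max(0, min(range1[2L], range2[2L]) - max(range1[1L], range2[1L]))
}

#' Principal component projection of the feature space
#'
#' Eigen-decomposition of the covariance of the three centered (unscaled)
#' features; returns specimen scores on the first two principal axes and the
#' fractions of variance they explain.
#'
#' @param table a `measurement_table` with at least 3 specimens.
#' @return List with `scores` (n x 2), `variance_explained` (length 2),
#'   `loadings` (3 x 2).
#' @export
pca_projection <- function(table) {
  x <- feature_matrix(table)
  if (nrow(x) < 3L) stop("PCA needs at least 3 specimens")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x[, 1:2, drop = FALSE],
       variance_explained = ve[1:2],
       loadings = pc$rotation[, 1:2, drop = FALSE])
}
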