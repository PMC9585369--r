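#' Published Tuta absoluta instar reference statistics
#'
#' The per-instar, per-feature summary statistics of the published
#' 240-specimen *Tuta absoluta* larval measurement study: group sizes, means,
#' dispersions (SD, cm), observed ranges (cm) and coefficients of variation
#' (%), for four instars and the three canonical features. These are the
#' default parameters of the synthetic-data generator.
#'
#' @return A data.frame with one row per (feature, instar): columns `feature`,
#'   `instar`, `n`, `mean`, `sd`, `min`, `max`, `cv`.
#' @export
instar_reference <- function() {
  feats <- feature_columns()
  df <- rbind(
    data.frame(feature = feats[1], instar = 1:4, n = c(69L, 42L, 35L, 94L),
               mean = c(0.123, 0.212, 0.339, 0.532),
               sd   = c(0.012, 0.021, 0.016, 0.040),
               min  = c(0.098, 0.160, 0.308, 0.448),
               max  = c(0.148, 0.254, 0.371, 0.610),
               cv   = c(9.683, 9.997, 4.741, 7.464)),
    data.frame(feature = feats[2], instar = 1:4, n = c(69L, 42L, 35L, 94L),
               mean = c(0.190, 0.304, 0.492, 0.736),
               sd   = c(0.010, 0.017, 0.025, 0.032),
               min  = c(0.173, 0.271, 0.448, 0.670),
               max  = c(0.216, 0.340, 0.554, 0.811),
               cv   = c(5.227, 5.739, 5.093, 4.410)),
    data.frame(feature = feats[3], instar = 1:4, n = c(69L, 42L, 35L, 94L),
               mean = c(0.089, 0.145, 0.231, 0.332),
               sd   = c(0.008, 0.010, 0.012, 0.019),
               min  = c(0.069, 0.128, 0.202, 0.283),
               max  = c(0.113, 0.168, 0.254, 0.374),
               cv   = c(9.300, 6.716, 5.294, 5.724))
  )
  rownames(df) <- NULL
  df
}

#' Configure the synthetic instar-morphometrics generator
#'
#' Builds the configuration for [generate_instar_dataset()]. Defaults
#' reproduce the published four-instar study: group sizes 69/42/35/94 and the
#' per-instar per-feature means, coefficients of variation and observed
#' ranges of [instar_reference()].
#'
#' @param n_instars number of instars (default 4).
#' @param group_sizes integer vector of per-instar specimen counts.
#' @param feature_means `n_instars x 3` matrix of means (cm), columns in
#'   canonical feature order; within each feature the per-instar means must be
#'   strictly increasing.
#' @param feature_cvs `n_instars x 3` matrix of coefficients of variation in
#'   percent; per-feature SD is `cv/100 * mean`.
#' @param rho constant pairwise correlation among the three features within an
#'   instar, in `[0, 1)`. Larger larvae have jointly larger heads and
#'   mandibles; default 0.8.
#' @param truncation optional list of two `n_instars x 3` matrices `min` and
#'   `max` (cm): draws outside the interval are resampled (not clipped). Use
#'   `NULL` for no truncation. The default is the observed ranges of
#'   [instar_reference()].
#' @param seed integer random seed.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_instars = 4L,
                             group_sizes = NULL,
                             feature_means = NULL,
                             feature_cvs = NULL,
                             rho = 0.8,
                             truncation = "reference",
                             seed = 1L) {
  n_instars <- as.integer(n_instars)
  stopifnot(n_instars >= 1L, rho >= 0, rho < 1)
  ref <- instar_reference()
  as_mat <- function(col) {
    m <- matrix(ref[[col]], nrow = 4L, ncol = 3L,
                dimnames = list(NULL, feature_columns()))
    m
  }
  if (is.null(group_sizes)) {
    group_sizes <- if (n_instars == 4L) c(69L, 42L, 35L, 94L) else
      rep(60L, n_instars)
  }
  group_sizes <- as.integer(group_sizes)
  if (length(group_sizes) != n_instars || any(group_sizes < 1L)) {
    stop("group_sizes must have one positive count per instar")
  }
  if (is.null(feature_means)) {
    if (n_instars != 4L) stop("feature_means required when n_instars != 4")
    feature_means <- as_mat("mean")
  }
  feature_means <- as.matrix(feature_means)
  if (!all(dim(feature_means) == c(n_instars, 3L))) {
    stop("feature_means must be n_instars x 3")
  }
  if (n_instars > 1L && any(apply(feature_means, 2, diff) <= 0)) {
    stop("per-instar means must be strictly increasing within each feature")
  }
  if (is.null(feature_cvs)) {
    feature_cvs <- if (n_instars == 4L) as_mat("cv") else
      matrix(6, n_instars, 3L)
  }
  feature_cvs <- as.matrix(feature_cvs)
  if (!all(dim(feature_cvs) == c(n_instars, 3L)) || any(feature_cvs < 0)) {
    stop("feature_cvs must be a nonnegative n_instars x 3 matrix")
  }
  if (identical(truncation, "reference")) {
    truncation <- if (n_instars == 4L)
      list(min = as_mat("min"), max = as_mat("max")) else NULL
  }
  if (!is.null(truncation)) {
    tmin <- as.matrix(truncation$min); tmax <- as.matrix(truncation$max)
    stopifnot(all(dim(tmin) == c(n_instars, 3L)),
              all(dim(tmax) == c(n_instars, 3L)))
    if (any(tmin >= tmax)) stop("degenerate truncation interval")
    if (any(feature_means < tmin | feature_means > tmax)) {
      stop("truncation intervals must contain their means")
    }
    truncation <- list(min = tmin, max = tmax)
  }
  structure(list(n_instars = n_instars, group_sizes = group_sizes,
                 feature_means = feature_means, feature_cvs = feature_cvs,
                 rho = rho, truncation = truncation,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Generate a synthetic instar measurement table
#'
#' Draws each specimen of instar `i` from a trivariate normal with the
#' configured per-instar means, SD = cv/100 * mean per feature, and constant
#' inter-feature correlation `rho`; draws falling outside the truncation
#' interval of any feature are resampled until inside. The true instar label
#' is recorded per row. Fully reproducible given the config seed.
#'
#' @param config a [generator_config()].
#' @return A `measurement_table` with `sum(group_sizes)` rows and true
#'   `instar` labels.
#' @export
generate_instar_dataset <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  p <- 3L
  corr <- matrix(config$rho, p, p); diag(corr) <- 1
  rows <- vector("list", config$n_instars)
  for (i in seq_len(config$n_instars)) {
    n_i <- config$group_sizes[i]
    mu <- config$feature_means[i, ]
    sd_i <- config$feature_cvs[i, ] / 100 * mu
    if (all(sd_i == 0)) {
      x <- matrix(mu, n_i, p, byrow = TRUE)
    } else {
      sigma <- diag(sd_i) %*% corr %*% diag(sd_i)
      ch <- chol(sigma + diag(1e-18, p))
      draw <- function(m) {
        matrix(stats::rnorm(m * p), m, p) %*% ch +
          matrix(mu, m, p, byrow = TRUE)
      }
      x <- draw(n_i)
      if (!is.null(config$truncation)) {
        lo <- config$truncation$min[i, ]; hi <- config$truncation$max[i, ]
        for (iter in seq_len(10000L)) {
          bad <- which(apply(x, 1, function(r) any(r < lo | r > hi)))
          if (length(bad) == 0) break
          x[bad, ] <- draw(length(bad))
        }
        if (length(bad <- which(apply(x, 1, function(r)
          any(r < lo | r > hi)))) > 0) {
          stop("truncation interval too narrow: resampling did not converge")
        }
      }
    }
    colnames(x) <- feature_columns()
    rows[[i]] <- data.frame(x, instar = i)
  }
  df <- do.call(rbind, rows)
  df$specimen_id <- paste0("s", seq_len(nrow(df)))
  measurement_table(df)
}

#' True instar labels of a generated table, as a partition
#'
#' @param table a `measurement_table` carrying generator `instar` labels.
#' @return A `partition` with zero noise points.
#' @export
generated_truth <- function(table) {
  if (all(is.na(table$instar))) {
    stop("table carries no instar truth labels")
  }
  if (anyNA(table$instar)) stop("instar labels are incomplete")
  canonicalize_partition(table$instar, table)
}
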