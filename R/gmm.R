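#' Gaussian-mixture covariance families
#'
#' The six covariance parameterizations fitted by [gmm_em()], from most
#' constrained to unconstrained, with their common three-letter model codes:
#' spherical-equal (EII), spherical-varying (VII), diagonal-equal (EEI),
#' diagonal-varying (VVI), full-equal (EEE) and full-varying (VVV, the
#' unconstrained model).
#'
#' @return Named character vector mapping family ids to model codes.
#' @export
gmm_families <- function() {
  c("spherical-equal" = "EII", "spherical-varying" = "VII",
    "diagonal-equal" = "EEI", "diagonal-varying" = "VVI",
    "full-equal" = "EEE", "full-varying" = "VVV")
}

# number of free covariance parameters of a family, d dimensions, k components
gmm_cov_params <- function(family, d, k) {
  switch(family,
         "spherical-equal" = 1,
         "spherical-varying" = k,
         "diagonal-equal" = d,
         "diagonal-varying" = k * d,
         "full-equal" = d * (d + 1) / 2,
         "full-varying" = k * d * (d + 1) / 2,
         stop("unknown covariance family: ", family))
}

# per-point log densities under each component: n x k matrix
gmm_log_dens <- function(x, means, covs) {
  n <- nrow(x); d <- ncol(x); k <- nrow(means)
  out <- matrix(NA_real_, n, k)
  for (j in seq_len(k)) {
    ch <- tryCatch(chol(covs[[j]]), error = function(e) NULL)
    if (is.null(ch)) stop("singular component covariance after flooring")
    xc <- sweep(x, 2L, means[j, ])
    z <- t(forwardsolve(t(ch), t(xc)))   # whitened residuals
    out[, j] <- -0.5 * rowSums(z^2) - sum(log(diag(ch))) -
      0.5 * d * log(2 * pi)
  }
  out
}

# floor covariance eigenvalues so every component stays positive definite
gmm_floor_cov <- function(s, floor = 1e-10) {
  e <- eigen(s, symmetric = TRUE)
  if (min(e$values) >= floor) return((s + t(s)) / 2)
  v <- pmax(e$values, floor)
  sym <- e$vectors %*% (v * t(e$vectors))
  (sym + t(sym)) / 2
}

#' Fit a Gaussian mixture model by EM
#'
#' Expectation-maximization for a k-component trivariate Gaussian mixture
#' under one of the six covariance families of [gmm_families()].
#' Initialization is best-of-`n_starts` Lloyd k-means (hard assignments seed
#' the first M-step); EM iterates until the relative log-likelihood change
#' falls below `tol` or `max_iter` iterations. Component covariance
#' eigenvalues are floored at 1e-10. The log-likelihood trace is recorded and
#' checked to be non-decreasing at every iteration.
#'
#' @param table a `measurement_table`.
#' @param k number of mixture components.
#' @param family covariance family id (see [gmm_families()]); default the
#'   unconstrained `"full-varying"`.
#' @param seed integer seed (controls the k-means initialization).
#' @param n_starts k-means initializations (default 5).
#' @param tol relative log-likelihood convergence tolerance (default 1e-8).
#' @param max_iter EM iteration cap (default 500).
#' @return A `gmm_fit`: list with `weights`, `means` (k x 3), `covariances`
#'   (list of k), `loglik`, `loglik_trace`, `n_params`, `bic`
#'   (`2*logL - m*log(n)`, larger is better), `responsibilities`,
#'   `partition` (hard assignment by maximum responsibility, canonical
#'   labels), `k`, `family`, `iterations`, `converged`.
#' @export
gmm_em <- function(table, k, family = "full-varying", seed = 1L,
                   n_starts = 5L, tol = 1e-8, max_iter = 500L) {
  x <- feature_matrix(table)
  n <- nrow(x); d <- ncol(x)
  k <- as.integer(k)
  if (!family %in% names(gmm_families())) {
    stop("unknown covariance family: ", family)
  }
  if (k < 1L || k > n) stop("k must satisfy 1 <= k <= n")
  m_params <- (k - 1) + k * d + gmm_cov_params(family, d, k)
  if (n <= m_params / d) stop("too few points for family ", family,
                              " with k = ", k)
  init <- kmeans_lloyd(table, k, seed = seed, n_starts = n_starts)
  resp <- matrix(0, n, k)
  resp[cbind(seq_len(n), partition_labels(init$partition))] <- 1

  m_step <- function(resp) {
    nk <- pmax(colSums(resp), 1e-12)
    w <- nk / n
    means <- t(resp) %*% x / nk
    covs <- vector("list", k)
    scatter <- lapply(seq_len(k), function(j) {
      xc <- sweep(x, 2L, means[j, ])
      t(xc * resp[, j]) %*% xc
    })
    switch(family,
      "spherical-equal" = {
        s2 <- sum(vapply(scatter, function(s) sum(diag(s)), numeric(1))) /
          (n * d)
        covs <- rep(list(diag(max(s2, 1e-10), d)), k)
      },
      "spherical-varying" = {
        for (j in seq_len(k)) {
          s2 <- sum(diag(scatter[[j]])) / (nk[j] * d)
          covs[[j]] <- diag(max(s2, 1e-10), d)
        }
      },
      "diagonal-equal" = {
        dd <- Reduce(`+`, lapply(scatter, diag)) / n
        covs <- rep(list(diag(pmax(dd, 1e-10), d)), k)
      },
      "diagonal-varying" = {
        for (j in seq_len(k)) {
          covs[[j]] <- diag(pmax(diag(scatter[[j]]) / nk[j], 1e-10), d)
        }
      },
      "full-equal" = {
        s <- gmm_floor_cov(Reduce(`+`, scatter) / n)
        covs <- rep(list(s), k)
      },
      "full-varying" = {
        for (j in seq_len(k)) {
          covs[[j]] <- gmm_floor_cov(scatter[[j]] / nk[j])
        }
      })
    list(weights = w, means = means, covs = covs)
  }

  par <- m_step(resp)
  trace <- numeric(0)
  loglik <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    ld <- gmm_log_dens(x, par$means, par$covs)
    lw <- sweep(ld, 2L, log(par$weights), "+")
    mx <- apply(lw, 1L, max)
    lse <- mx + log(rowSums(exp(lw - mx)))
    new_ll <- sum(lse)
    if (new_ll < loglik - 1e-6 * max(1, abs(loglik))) {
      stop("EM log-likelihood decreased at iteration ", it)
    }
    trace <- c(trace, new_ll)
    resp <- exp(lw - lse)
    if (is.finite(loglik) &&
        abs(new_ll - loglik) < tol * max(1, abs(loglik))) {
      loglik <- new_ll
      converged <- TRUE
      break
    }
    loglik <- new_ll
    par <- m_step(resp)
  }
  bic <- 2 * loglik - m_params * log(n)
  labels <- max.col(resp, ties.method = "first")
  structure(list(weights = par$weights, means = par$means,
                 covariances = par$covs, loglik = loglik,
                 loglik_trace = trace, n_params = m_params, bic = bic,
                 responsibilities = resp,
                 partition = canonicalize_partition(labels, table),
                 k = k, family = family, iterations = length(trace),
                 converged = converged, seed = as.integer(seed)),
            class = "gmm_fit")
}

#' @export
print.gmm_fit <- function(x, ...) {
  cat("Gaussian mixture:", x$k, "components,", x$family,
      sprintf("(%s)", gmm_families()[[x$family]]), "\n")
  cat(sprintf("logL = %.3f  params = %d  BIC = %.3f  iterations = %d\n",
              x$loglik, x$n_params, x$bic, x$iterations))
  invisible(x)
}

#' Select a Gaussian mixture by BIC over components and families
#'
#' Fits every (k, family) combination with [gmm_em()] and selects the fit
#' with the largest BIC (`2*logL - m*log(n)`). Fits that fail (e.g. too few
#' points for an unconstrained covariance) are recorded as `NA` in the BIC
#' table.
#'
#' @param table a `measurement_table`.
#' @param k_range integer vector of component counts (default 1:9).
#' @param families covariance family ids (default all six).
#' @param seed integer seed passed to every fit.
#' @param ... further arguments to [gmm_em()].
#' @return A list with `bic_table` (matrix, rows = k, columns = family),
#'   `best` (the argmax-BIC `gmm_fit`), `best_k`, `best_family`, and
#'   `partition` (of the best fit).
#' @export
bic_select <- function(table, k_range = 1:9, families = names(gmm_families()),
                       seed = 1L, ...) {
  stopifnot(length(k_range) >= 1L, length(families) >= 1L)
  bic <- matrix(NA_real_, length(k_range), length(families),
                dimnames = list(as.character(k_range), families))
  best <- NULL
  for (ki in seq_along(k_range)) {
    for (fi in seq_along(families)) {
      fit <- tryCatch(
        gmm_em(table, k_range[ki], families[fi], seed = seed, ...),
        error = function(e) NULL)
      if (is.null(fit)) next
      bic[ki, fi] <- fit$bic
      if (is.null(best) || fit$bic > best$bic) best <- fit
    }
  }
  if (is.null(best)) stop("all mixture fits failed")
  list(bic_table = bic, best = best, best_k = best$k,
       best_family = best$family, partition = best$partition)
}
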