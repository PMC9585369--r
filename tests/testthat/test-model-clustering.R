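test_that("Lloyd k-means solves the two-blob case exactly", {
  tab <- make_table(c(0.1, 0.2, 0.3, 10.1, 10.2, 10.3))
  fit <- kmeans_lloyd(tab, k = 2L, seed = 1L)
  expect_equal(unname(fit$centers[, 1]), c(0.2, 10.2))
  expect_equal(fit$wss, 0.04, tolerance = 1e-12)
  expect_equal(partition_labels(fit$partition), c(1L, 1L, 1L, 2L, 2L, 2L))

  # oracle: enumerate every 2-partition and confirm 0.04 is the minimum WSS
  x <- feature_matrix(tab)
  wss_of <- function(assign) {
    sum(vapply(unique(assign), function(g) {
      xi <- x[assign == g, , drop = FALSE]
      sum(sweep(xi, 2, colMeans(xi))^2)
    }, numeric(1)))
  }
  all_wss <- vapply(1:(2^6 - 2), function(code) {
    assign <- as.integer(intToBits(code)[1:6])
    if (length(unique(assign)) < 2) return(Inf)
    wss_of(assign)
  }, numeric(1))
  expect_equal(min(all_wss), 0.04, tolerance = 1e-12)
})

test_that("k-means saturates at k = n and matches stats::kmeans otherwise", {
  tab <- generate_instar_dataset(generator_config(seed = 3L))
  small <- measurement_table(as.data.frame(tab)[1:12, ])
  sat <- kmeans_lloyd(small, k = 12L, seed = 1L)
  expect_equal(sat$wss, 0, tolerance = 1e-15)

  fit <- kmeans_lloyd(tab, k = 4L, seed = 1L)
  ref <- stats::kmeans(feature_matrix(tab), centers = 4L, nstart = 10L,
                       algorithm = "Lloyd", iter.max = 300L)
  expect_equal(fit$wss, ref$tot.withinss, tolerance = 1e-6)
  expect_equal(mclust::adjustedRandIndex(partition_labels(fit$partition),
                                         ref$cluster), 1)
  expect_error(kmeans_lloyd(tab, k = 500L), "k must satisfy")
})

test_that("k-means WSS trace is non-increasing and seeds are reproducible", {
  for (s in 1:5) {
    tab <- random_table(60, seed = 300 + s)
    fit <- kmeans_lloyd(tab, k = 3L, seed = s, n_starts = 3L)
    expect_true(all(diff(fit$wss_trace) <= 1e-10))
    expect_true(all(cluster_sizes(fit$partition) > 0))
    again <- kmeans_lloyd(tab, k = 3L, seed = s, n_starts = 3L)
    expect_identical(fit$partition, again$partition)
  }
})

test_that("one-component mixtures have the closed-form ML solution", {
  tab <- generate_instar_dataset(generator_config(seed = 2L))
  x <- feature_matrix(tab)
  for (fam in c("full-varying", "spherical-equal")) {
    fit <- gmm_em(tab, k = 1L, family = fam)
    expect_equal(unname(fit$weights), 1)
    expect_equal(unname(fit$means[1, ]), unname(colMeans(x)),
                 tolerance = 1e-10)
  }
  # unconstrained single component: ML covariance = (n-1)/n * sample cov
  fit <- gmm_em(tab, k = 1L, family = "full-varying")
  expect_equal(fit$covariances[[1]],
               unname(cov(x) * (nrow(x) - 1) / nrow(x)),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(fit$n_params, 3 + 6)
})

test_that("EM recovers the parameters of well-separated components", {
  cfg <- generator_config(
    n_instars = 2L, group_sizes = c(100L, 100L),
    feature_means = rbind(c(0.1, 0.1, 0.1), c(1.0, 1.0, 1.0)),
    feature_cvs = matrix(10, 2, 3), rho = 0, truncation = NULL, seed = 9L)
  tab <- generate_instar_dataset(cfg)
  fit <- gmm_em(tab, k = 2L, family = "spherical-varying", seed = 1L)
  ord <- order(fit$means[, 1])
  for (j in 1:2) {
    mu <- cfg$feature_means[j, 1]
    se <- (cfg$feature_cvs[j, 1] / 100 * mu) / sqrt(100)
    expect_lt(abs(fit$means[ord[j], 1] - mu), 3 * se)
  }
  expect_equal(unname(fit$weights[ord]), c(0.5, 0.5), tolerance = 0.05)
})

test_that("EM log-likelihood is monotone and families nest correctly", {
  tab <- generate_instar_dataset(generator_config(seed = 5L))
  lls <- c()
  for (fam in c("spherical-varying", "diagonal-varying", "full-varying")) {
    fit <- gmm_em(tab, k = 4L, family = fam, seed = 1L)
    expect_true(all(diff(fit$loglik_trace) >= -1e-6))
    expect_equal(sum(fit$weights), 1, tolerance = 1e-8)
    for (s in fit$covariances) {
      expect_true(all(eigen(s, symmetric = TRUE,
                            only.values = TRUE)$values > 0))
    }
    lls <- c(lls, fit$loglik)
  }
  # nested-family dominance: richer covariance never fits worse
  expect_true(all(diff(lls) >= -1e-4 * abs(lls[-3])))
})

test_that("mixture log-likelihood agrees with the mclust oracle", {
  tab <- generate_instar_dataset(generator_config(seed = 1L))
  x <- feature_matrix(tab)
  fit <- gmm_em(tab, k = 4L, family = "full-varying", seed = 1L)
  ref <- mclust::Mclust(x, G = 4, modelNames = "VVV", verbose = FALSE)
  # same local optimum on well-separated data, independent implementations
  expect_equal(fit$loglik, ref$loglik, tolerance = 1e-4)
  expect_equal(fit$n_params, mclust::nMclustParams("VVV", d = 3, G = 4))
  expect_equal(fit$bic, as.numeric(ref$bic), tolerance = 1e-3)
  expect_equal(mclust::adjustedRandIndex(
    partition_labels(fit$partition), ref$classification), 1)
})

test_that("BIC selection lands on the generating structure", {
  # no structure: a single blob prefers one component
  cfg <- generator_config(n_instars = 1L, group_sizes = 80L,
                          feature_means = matrix(c(0.3, 0.3, 0.3), 1, 3),
                          feature_cvs = matrix(5, 1, 3), truncation = NULL,
                          seed = 4L)
  blob <- generate_instar_dataset(cfg)
  sel1 <- bic_select(blob, k_range = 1:3,
                     families = c("spherical-equal", "full-varying"),
                     seed = 1L)
  expect_equal(sel1$best_k, 1L)

  # two separated blobs: BIC(k=2) beats BIC(k=1) for the spherical family,
  # cross-checked by direct log-likelihood computation
  cfg2 <- generator_config(
    n_instars = 2L, group_sizes = c(60L, 60L),
    feature_means = rbind(c(0.2, 0.2, 0.2), c(1, 1, 1)),
    feature_cvs = matrix(8, 2, 3), rho = 0, truncation = NULL, seed = 6L)
  tab2 <- generate_instar_dataset(cfg2)
  f1 <- gmm_em(tab2, 1L, "spherical-varying")
  f2 <- gmm_em(tab2, 2L, "spherical-varying")
  expect_gt(f2$bic, f1$bic)
  x <- feature_matrix(tab2)
  mu <- colMeans(x)
  s2 <- mean(rowSums(sweep(x, 2, mu)^2)) / 3
  ll1 <- sum(vapply(seq_len(nrow(x)), function(i) {
    sum(dnorm(x[i, ], mu, sqrt(s2), log = TRUE))
  }, numeric(1)))
  expect_equal(f1$loglik, ll1, tolerance = 1e-6)
  expect_equal(f1$bic, 2 * ll1 - (3 + 1) * log(nrow(x)), tolerance = 1e-6)
})
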