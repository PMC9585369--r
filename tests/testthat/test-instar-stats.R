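test_that("Brooks-Dyar and Crosby indices follow their definitions", {
  expect_equal(brooks_dyar_indices(c(1, 2, 4, 8)), c(2, 2, 2))
  # published head-capsule-width means give the published ratios to rounding
  hw <- brooks_dyar_indices(c(0.190, 0.304, 0.492, 0.736))
  expect_equal(hw, c(1.601, 1.616, 1.497), tolerance = 0.005)
  hl <- brooks_dyar_indices(c(0.123, 0.212, 0.339, 0.532))
  expect_equal(hl[3], 1.569, tolerance = 0.005)
  expect_error(brooks_dyar_indices(c(1, -2, 3)), "positive")

  # Crosby of an exactly geometric series is identically zero
  expect_equal(crosby_indices(brooks_dyar_indices(1.6^(0:4)))$crosby,
               c(0, 0, 0))
  expect_true(crosby_indices(c(1.6, 1.6, 1.6))$pass)
  cr <- crosby_indices(c(2.0, 1.5))
  expect_equal(cr$crosby, -0.25)
  expect_false(cr$pass)
  expect_error(crosby_indices(1.6), "at least 2")
  # published width ratios give Crosby values matching the printed table
  expect_true(all(abs(crosby_indices(hw)$crosby - c(0.010, -0.080)) < 0.02))
})

test_that("per-instar summary recovers the generating statistics", {
  tab <- generate_instar_dataset(generator_config(seed = 10L))
  sm <- summarize_instars(tab, generated_truth(tab))
  ref <- instar_reference()
  expect_equal(nrow(sm), 12L)
  expect_equal(sm$n, ref$n)
  for (r in seq_len(12)) {
    row <- sm[sm$feature == ref$feature[r] & sm$instar == ref$instar[r], ]
    se <- ref$sd[r] / sqrt(ref$n[r])
    expect_lt(abs(row$mean - ref$mean[r]), 3 * se)
    expect_lt(abs(row$cv - ref$cv[r]), 4)
  }
  # the instar-1 width row sits near the published 0.190 mean / 5.227 CV
  w1 <- sm[sm$feature == "head_capsule_width_cm" & sm$instar == 1, ]
  expect_lt(abs(w1$mean - 0.190), 3 * 0.010 / sqrt(69))
  expect_true(is.na(w1$dyar) && is.na(w1$crosby))

  # summary statistics are invariant under specimen reordering
  set.seed(7)
  perm <- sample(nrow(tab))
  tab2 <- measurement_table(as.data.frame(tab)[perm, ])
  sm2 <- summarize_instars(tab2, generated_truth(tab2))
  expect_equal(sm2, sm)
})

test_that("summary handles degenerate partitions at the definition edges", {
  const <- make_table(rep(0.2, 5), rep(0.3, 5), rep(0.1, 5))
  sm <- summarize_instars(const, partition(rep(1L, 5)))
  expect_equal(sm$mean, c(0.2, 0.3, 0.1))
  expect_equal(sm$sd, c(0, 0, 0))
  expect_equal(sm$cv, c(0, 0, 0))
  expect_true(all(is.na(sm$dyar)) && all(is.na(sm$crosby)))

  two <- make_table(c(1, 1, 2, 2), c(1, 1, 2, 2), c(1, 1, 2, 2))
  sm2 <- summarize_instars(two, partition(c(1L, 1L, 2L, 2L)))
  expect_equal(sm2$dyar[sm2$instar == 2], c(2, 2, 2))
  expect_true(all(is.na(sm2$crosby)))    # Crosby needs 3 instars
  expect_error(summarize_instars(two, partition(rep(0L, 4))), "no non-noise")
})

test_that("growth regression is exact on noiseless geometric data", {
  r <- 1.55
  m0 <- 0.09
  vals <- m0 * r^(0:3)
  tab <- make_table(rep(vals, each = 5), rep(vals, each = 5),
                    rep(vals, each = 5), instar = rep(1:4, each = 5))
  fit <- dyar_regression(tab, generated_truth(tab), "mandible_width_cm")
  expect_equal(fit$slope, log(r), tolerance = 1e-9)
  expect_equal(fit$growth_rate, r, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$rss, 0, tolerance = 1e-12)
  expect_equal(fit$df, 18L)
  # Dyar-regression consistency: e^b equals every Brooks-Dyar index
  expect_equal(rep(fit$growth_rate, 3), brooks_dyar_indices(vals),
               tolerance = 1e-9)
  expect_error(dyar_regression(tab, partition(rep(1L, 20))), "2 instars")
})

test_that("grouped regression reproduces the published mandible equation", {
  # weighted OLS on the printed group means (mm) and counts; expectations
  # frozen from the lm() oracle on these numbers
  fit <- dyar_regression_grouped(c(0.89, 1.45, 2.31, 3.32),
                                 c(69, 42, 35, 94))
  expect_equal(fit$slope, 0.4378542, tolerance = 1e-6)
  expect_equal(fit$intercept, -0.5330598, tolerance = 1e-6)
  # within rounding of the printed y = 0.440x - 0.543
  expect_lt(abs(fit$slope - 0.440), 0.01)
  expect_lt(abs(fit$intercept - (-0.543)), 0.02)
  # printed slopes exponentiate to the printed growth-rate constants
  expect_equal(round(exp(c(0.440, 0.452, 0.486)), 3), c(1.553, 1.571, 1.626))
})

test_that("regression p-value and R2 behave on sampled instar data", {
  tab <- generate_instar_dataset(generator_config(seed = 12L))
  fit <- dyar_regression(tab, generated_truth(tab), "mandible_width_cm")
  expect_lt(fit$p_value, 1e-4)
  expect_gt(fit$r_squared, 0.9)
  expect_equal(fit$df, 238L)
  expect_equal(fit$growth_rate, exp(fit$slope))
})

test_that("frequency analysis flags exactly the overlapping ranges", {
  # published variation ranges of head capsule width: disjoint
  ranges <- rbind(c(0.173, 0.216), c(0.271, 0.340),
                  c(0.448, 0.554), c(0.670, 0.811))
  for (i in 1:3) {
    expect_equal(range_overlap(ranges[i, ], ranges[i + 1, ]), 0)
  }
  expect_equal(range_overlap(c(0, 2), c(1, 3)), 1)

  tab <- generate_instar_dataset(generator_config(seed = 13L))
  fa <- frequency_analysis(tab, generated_truth(tab))
  for (f in feature_columns()) {
    expect_false(fa[[f]]$any_overlap)
    expect_equal(rowSums(fa[[f]]$counts), c(69, 42, 35, 94),
                 ignore_attr = TRUE)
  }
  expect_false(fa$any_overlap)

  overlapping <- make_table(c(1, 1.5, 2, 1.8, 2.5, 3))
  fo <- frequency_analysis(overlapping, partition(rep(1:2, each = 3L)))
  expect_true(fo$any_overlap)
  expect_equal(fo$head_capsule_length_cm$overlap, 0.2, tolerance = 1e-9)
})

test_that("PCA projection has the closed-form variance split", {
  # collinear features: one latent size axis explains everything
  latent <- seq(0.1, 1, length.out = 20)
  col <- make_table(latent, 2 * latent, 0.5 * latent)
  pc <- pca_projection(col)
  expect_equal(pc$variance_explained[1], 1, tolerance = 1e-9)

  # exact 2-effective-dimension construction: orthogonal contrasts with
  # variance ratio 4:1 embedded in 3-space -> fractions (0.8, 0.2)
  z1 <- c(1, -1, 1, -1)
  z2 <- c(1, 1, -1, -1)
  u1 <- c(1, 0, 0)
  u2 <- c(0, 1, 0)
  x <- 10 + 0.2 * outer(z1, u1) + 0.1 * outer(z2, u2)
  tab <- make_table(x[, 1], x[, 2], x[, 3])
  pc2 <- pca_projection(tab)
  expect_equal(unname(pc2$variance_explained), c(0.8, 0.2),
               tolerance = 1e-12)

  # the four generated instars separate along the first component
  big <- generate_instar_dataset(generator_config(seed = 14L))
  pcb <- pca_projection(big)
  s1 <- pcb$scores[, 1] * sign(pcb$loadings[1, 1])
  grp <- split(s1, big$instar)
  for (i in 1:3) expect_lt(max(grp[[i]]), min(grp[[i + 1]]))
  expect_error(pca_projection(make_table(c(0.1, 0.2))), "at least 3")
})
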