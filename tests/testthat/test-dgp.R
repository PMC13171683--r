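test_that("generated designs are balanced with cluster-constant level-2 variables", {
  for (cfg in list(dgp_config(25L, 40L, seed = 3L),
                   dgp_config(50L, 20L, seed = 4L))) {
    d <- generate_dataset(cfg)
    expect_equal(nrow(d), 1000L)
    tab <- table(d$cluster_id)
    expect_length(tab, cfg$n_clusters)
    expect_true(all(tab == cfg$cluster_size))
    expect_false(anyNA(d))
    for (l in level2_vars()) {
      expect_equal(max(tapply(d[[l]], d$cluster_id, stats::var)), 0)
    }
  }
})

test_that("identical config and seed give bit-identical datasets", {
  a <- generate_dataset(dgp_config(seed = 99L))
  b <- generate_dataset(dgp_config(seed = 99L))
  expect_identical(a, b)
  c <- generate_dataset(dgp_config(seed = 100L))
  expect_false(identical(a$Y, c$Y))
})

test_that("variance split of the latent variables follows eta2 (ANOVA oracle)", {
  # no cluster variance at eta2 = 0
  d0 <- generate_predictors(dgp_config(200L, 50L, eta2_range = c(0, 0),
                                       between_corr = 0, within_corr = 0,
                                       seed = 11L))
  icc0 <- vapply(paste0("X", 1:6),
                 function(v) anova_icc(d0[[v]], d0$cluster_id), 0)
  expect_true(all(abs(icc0) < 0.03))
  # fixed eta2 = 0.5 recovered within +-0.05
  d5 <- generate_predictors(dgp_config(500L, 50L,
                                       eta2_range = c(0.5, 0.5),
                                       between_corr = 0, within_corr = 0,
                                       seed = 12L))
  icc5 <- vapply(paste0("X", 1:6),
                 function(v) anova_icc(d5[[v]], d5$cluster_id), 0)
  expect_true(all(abs(icc5 - 0.5) < 0.05))
})

test_that("level-2 variables correlate positively with level-1 variables", {
  d <- generate_predictors(dgp_config(100L, 40L, seed = 21L))
  cors <- stats::cor(d[, paste0("X", 1:6)], d[, level2_vars()])
  expect_true(all(cors > 0))
})

test_that("degenerate truth gives a degenerate outcome", {
  d <- generate_predictors(dgp_config(5L, 4L, seed = 1L))
  tr <- truth_params(beta = rep(0, 13), sigma2_eps = 0,
                     tau2_intercept = 0)
  out <- generate_outcome(d, tr, seed = 1L)
  expect_equal(out$Y, rep(0, nrow(out)))
})

test_that("mixed-model fit on a large dataset recovers the generating coefficients", {
  cfg <- dgp_config(500L, 50L, seed = 31L)
  d <- generate_dataset(cfg)
  f <- fit_lmm(d, "random_intercept")
  idx <- match(c(paste0("X", 1:6), paste0("L", 1:6)),
               f$coefficients$term)
  err <- f$coefficients$estimate[idx] - attr(d, "truth")$beta[-1]
  # level-1 coefficients are estimated from 25,000 rows; level-2 ones
  # only from 500 clusters, so allow 3 standard errors there
  tol <- pmax(0.05, 3 * f$coefficients$se[idx])
  expect_true(all(abs(err) < tol))
  expect_true(all(abs(err[1:6]) < 0.05))
})

test_that("marginal R2 matches its closed-form edge cases", {
  d <- generate_predictors(dgp_config(10L, 10L, seed = 41L))
  zero <- truth_params(beta = rep(0, 13))
  expect_equal(marginal_r2(d, zero), 0)
  pure <- truth_params(beta = c(0, 1, rep(0, 11)), sigma2_eps = 0,
                       tau2_intercept = 0)
  expect_equal(marginal_r2(d, pure), 1)
})

test_that("invalid configurations are rejected", {
  expect_error(dgp_config(cluster_size = 1L), "cluster_size")
  expect_error(dgp_config(eta2_range = c(0, 1.2)), "eta2_range")
  expect_error(dgp_config(between_corr = -0.5), "positive-definite")
  expect_error(truth_params(beta = 1:5), "length 13")
})
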