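test_that("the analysis model recovers coefficients from a low-noise generator", {
  cfg <- dgp_config(200L, 10L, seed = 100L)
  tr <- truth_params(sigma2_eps = 1, tau2_intercept = 0)
  d <- generate_predictors(cfg)
  tr$eta2_draws <- attr(d, "eta2_draws")
  d <- generate_outcome(d, tr, seed = 100L)
  f <- fit_lmm(d, "random_intercept")
  idx <- match(coef_terms(), f$coefficients$term)
  err <- f$coefficients$estimate[idx] - tr$beta
  expect_true(all(abs(err) < pmax(0.05, 3 * f$coefficients$se[idx])))
  expect_true(f$converged)
  expect_true(all(f$coefficients$se > 0))
})

test_that("the random-slope analysis model fits its own generating process", {
  d <- tiny_dataset(J = 20L, n_j = 15L, model = "random_slope",
                    seed = 102L)
  f <- fit_lmm(d, "random_slope")
  expect_equal(nrow(f$coefficients), 13L)
  expect_true(all(f$coefficients$se > 0))
})

test_that("adding a constant to Y shifts only the intercept", {
  d <- tiny_dataset(J = 15L, n_j = 15L, seed = 101L)
  f1 <- fit_lmm(d, "random_intercept")
  d2 <- d
  d2$Y <- d$Y + 10
  f2 <- fit_lmm(d2, "random_intercept")
  i1 <- f1$coefficients$term == "(Intercept)"
  expect_equal(f2$coefficients$estimate[i1],
               f1$coefficients$estimate[i1] + 10, tolerance = 1e-6)
  expect_equal(f2$coefficients$estimate[!i1],
               f1$coefficients$estimate[!i1], tolerance = 1e-6)
})

test_that("Rubin pooling reproduces its defining identities", {
  # m identical fits: B = 0, T = W, Qbar = the common estimate
  f <- fake_fit(c(1, 2), c(0.5, 0.4))
  pl <- pool_rubin(list(f, f, f))
  expect_equal(pl$pooled$qbar, c(1, 2))
  expect_equal(pl$pooled$b, c(0, 0))
  expect_equal(pl$pooled$t_var, pl$pooled$w)
  # hand-computed example: estimates (0, 2), SE^2 = 1, m = 2
  pl2 <- pool_rubin(list(fake_fit(0, 1), fake_fit(2, 1)))
  expect_equal(pl2$pooled$qbar, 1)
  expect_equal(pl2$pooled$b, 2)
  expect_equal(pl2$pooled$t_var, 1 + 1.5 * 2)
  # T >= W always, strict when estimates differ
  expect_gt(pl2$pooled$t_var, pl2$pooled$w)
})

test_that("pooling is equivariant under scaling", {
  fits <- list(fake_fit(c(1, -2), c(0.3, 0.6)),
               fake_fit(c(1.4, -1.6), c(0.35, 0.5)),
               fake_fit(c(0.8, -2.2), c(0.28, 0.55)))
  pl <- pool_rubin(fits)
  c_ <- 3
  fits_c <- lapply(fits, function(f) {
    f$coefficients$estimate <- f$coefficients$estimate * c_
    f$coefficients$se <- f$coefficients$se * c_
    f
  })
  pl_c <- pool_rubin(fits_c)
  expect_equal(pl_c$pooled$qbar, pl$pooled$qbar * c_)
  expect_equal(pl_c$pooled$t_var, pl$pooled$t_var * c_^2)
  expect_equal(pl_c$pooled$p, pl$pooled$p)
})

test_that("pooling a single fit is rejected and misaligned fits fail", {
  expect_error(pool_rubin(list(fake_fit(1, 1))), "at least 2")
  a <- fake_fit(c(1, 2), c(1, 1), terms = c("x", "z"))
  b <- fake_fit(c(1, 2), c(1, 1), terms = c("z", "x"))
  expect_error(pool_rubin(list(a, b)), "misaligned")
})

test_that("pooled p-values do not depend on coefficient ordering", {
  fits <- list(fake_fit(c(0.2, 1.5), c(0.4, 0.3), terms = c("a", "b")),
               fake_fit(c(0.1, 1.2), c(0.45, 0.33), terms = c("a", "b")),
               fake_fit(c(0.3, 1.4), c(0.38, 0.31), terms = c("a", "b")))
  rev_fits <- lapply(fits, function(f) {
    f$coefficients <- f$coefficients[2:1, ]
    f
  })
  p1 <- pool_rubin(fits)$pooled
  p2 <- pool_rubin(rev_fits)$pooled
  expect_equal(p2$p[match(p1$term, p2$term)], p1$p)
})
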