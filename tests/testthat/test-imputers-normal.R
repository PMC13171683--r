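test_that("pmm_match returns nearest-donor values with stable ties", {
  # k = 1: the single nearest donor's value
  expect_equal(with_seed(1L, pmm_match(c(1, 2, 3), c(10, 20, 30), 2.1,
                                       k = 1L)), 20)
  # all observed values equal: imputation is that constant
  expect_equal(with_seed(2L, pmm_match(c(0, 1, 2), c(7, 7, 7),
                                       c(0.4, 1.9), k = 3L)), c(7, 7))
})

test_that("pmm_match samples the k-donor pool uniformly (frequency oracle)", {
  draws <- with_seed(42L, replicate(10000, pmm_match(
    c(0, 1, 2, 3), c(0, 10, 20, 30), 1.4, k = 3L)))
  # donor pool: distances (1.4, .4, .6, 1.6) -> values {10, 20, 0}
  expect_setequal(unique(draws), c(0, 10, 20))
  freq <- table(draws) / length(draws)
  expect_true(all(abs(freq - 1 / 3) < 0.02))
})

test_that("cluster-level PMM draws observed cluster values, constant within cluster", {
  d <- tiny_dataset(J = 20L, n_j = 8L, seed = 30L)
  a <- ampute_level2_mcar(d, rate = 0.4, seed = 31L)
  miss <- a$mask[, "L1"]
  x <- as.matrix(d[, paste0("L", 2:6)])
  imp <- with_seed(7L,
    impute_level2_pmm(a$data$L1, x, d$cluster_id, miss, k_donors = 5L))
  observed_cluster_values <- unique(d$L1[!miss])
  expect_true(all(imp %in% observed_cluster_values))
  filled <- a$data$L1
  filled[miss] <- imp
  expect_equal(max(tapply(filled, d$cluster_id, stats::var)), 0)
})

test_that("cluster-level PMM falls back to all observed clusters when donors are scarce", {
  d <- tiny_dataset(J = 8L, n_j = 5L, seed = 32L)
  miss <- d$cluster_id >= 5  # 4 observed clusters < 5 donors
  x <- as.matrix(d[, paste0("L", 2:6)])
  expect_warning(
    imp <- with_seed(8L, impute_level2_pmm(replace(d$L1, miss, NA), x,
                                           d$cluster_id, miss)),
    "fewer observed clusters")
  expect_true(all(imp %in% d$L1[!miss]))
})

test_that("two-level normal imputation is stochastic across chains and seeded", {
  d <- tiny_dataset(J = 12L, n_j = 12L, seed = 33L)
  a <- ampute_mcar(d, columns = "X1", rate = 0.3, seed = 34L)
  x <- as.matrix(d[, c(paste0("X", 2:6), "Y")])
  miss <- a$mask[, "X1"]
  imp1 <- with_seed(1L, impute_two_level_normal(a$data$X1, x,
                                                d$cluster_id, miss))
  imp1b <- with_seed(1L, impute_two_level_normal(a$data$X1, x,
                                                 d$cluster_id, miss))
  imp2 <- with_seed(2L, impute_two_level_normal(a$data$X1, x,
                                                d$cluster_id, miss))
  expect_identical(imp1, imp1b)
  expect_false(identical(imp1, imp2))
  expect_gt(stats::var(c(imp1[1], imp2[1],
                         with_seed(3L, impute_two_level_normal(
                           a$data$X1, x, d$cluster_id, miss))[1])), 0)
})

test_that("compiled and reference Gibbs loops agree to numerical precision", {
  d <- tiny_dataset(J = 15L, n_j = 10L, seed = 35L)
  a <- ampute_mcar(d, columns = "Y", rate = 0.4, seed = 36L)
  x <- as.matrix(d[, predictor_vars()])
  miss <- a$mask[, "Y"]
  cpp <- with_seed(9L, impute_two_level_normal(a$data$Y, x,
                                               d$cluster_id, miss,
                                               use_cpp = TRUE))
  ref <- with_seed(9L, impute_two_level_normal(a$data$Y, x,
                                               d$cluster_id, miss,
                                               use_cpp = FALSE))
  expect_equal(cpp, ref, tolerance = 1e-8)
  # the compiled path itself is exactly reproducible
  cpp2 <- with_seed(9L, impute_two_level_normal(a$data$Y, x,
                                                d$cluster_id, miss,
                                                use_cpp = TRUE))
  expect_identical(cpp, cpp2)
})

test_that("with zero cluster variance the two-level imputer matches a single-level Bayesian imputer", {
  # y = 1 + 2x + N(0,1), no cluster effect; compare pooled means of the
  # imputed values over replications
  n <- 300L
  cluster_id <- rep(1:10, each = 30)
  reps <- 60L
  mean_2l <- numeric(reps)
  mean_1l <- numeric(reps)
  for (r in seq_len(reps)) {
    set.seed(4000 + r)
    x <- stats::rnorm(n)
    y <- 1 + 2 * x + stats::rnorm(n)
    miss <- stats::runif(n) < 0.3
    ym <- replace(y, miss, NA)
    xm <- matrix(x, ncol = 1)
    mean_2l[r] <- mean(impute_two_level_normal(ym, xm, cluster_id, miss,
                                               n_sweeps = 50L))
    dr <- norm_draw(cbind(1, xm[!miss, , drop = FALSE]), y[!miss])
    pred <- drop(cbind(1, xm[miss, , drop = FALSE]) %*% dr$beta)
    mean_1l[r] <- mean(pred + stats::rnorm(sum(miss), 0, sqrt(dr$sigma2)))
  }
  diff <- mean(mean_2l) - mean(mean_1l)
  se <- sqrt(stats::var(mean_2l) / reps + stats::var(mean_1l) / reps)
  expect_lt(abs(diff), 3 * se + 0.02)
})
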