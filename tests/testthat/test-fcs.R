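test_that("initial fill obeys its strategy", {
  d <- tiny_dataset(seed = 80L)
  a <- ampute_mcar(d, columns = c("X1", "Y"), rate = 0.3, seed = 81L)
  # fully observed input: identity
  none <- ampute_mcar(d, rate = 0, seed = 1L)
  expect_identical(initial_fill(none$data, none$mask, "mean_mode"), d)
  # mean fill equals the observed mean
  filled <- initial_fill(a$data, a$mask, "mean_mode")
  expect_equal(unique(filled$X1[a$mask[, "X1"]]),
               mean(d$X1[!a$mask[, "X1"]]))
  # {1, 3} -> 2
  df <- data.frame(v = c(1, NA, 3, NA))
  mk <- matrix(is.na(df$v), ncol = 1, dimnames = list(NULL, "v"))
  expect_equal(initial_fill(df, mk, "mean_mode")$v, c(1, 2, 3, 2))
  # random draws are members of the observed set
  rnd <- with_seed(5L, initial_fill(a$data, a$mask,
                                    "random_observed_draw"))
  expect_true(all(rnd$Y[a$mask[, "Y"]] %in% d$Y[!a$mask[, "Y"]]))
  # a column with no observed values cannot be initialized
  df2 <- data.frame(v = c(NA_real_, NA_real_))
  mk2 <- matrix(TRUE, 2, 1, dimnames = list(NULL, "v"))
  expect_error(initial_fill(df2, mk2, "mean_mode"), "no observed")
})

test_that("a complete input returns m identical copies with no work", {
  d <- tiny_dataset(seed = 82L)
  a <- ampute_mcar(d, rate = 0, seed = 1L)
  out <- impute_method(a, "parametric", m = 3L, seed = 2L)
  expect_length(out$completions, 3L)
  expect_identical(out$completions[[1]], out$completions[[3]])
  expect_equal(out$iterations, rep(0L, 3L))
})

test_that("a deterministic mean imputer run through the chain reproduces the column mean", {
  register_imputer("test_mean", function(y, x, cluster_id, miss) {
    rep(mean(y[!miss]), sum(miss))
  })
  d <- tiny_dataset(seed = 83L)
  a <- ampute_mcar(d, columns = "X3", rate = 0, seed = 1L)
  a$mask[5L, "X3"] <- TRUE
  a$data$X3[5L] <- NA
  cfg <- fcs_config(method_map = c(X3 = "test_mean"), m = 2L,
                    max_iterations = 3L, initial_fill = "mean_mode",
                    seed = 4L)
  out <- run_fcs(a, cfg)
  expect_equal(out$completions[[1]]$X3[5L], mean(d$X3[-5L]))
  expect_equal(out$completions[[2]]$X3[5L], mean(d$X3[-5L]))
})

test_that("every method preserves observed cells, completes the data, and is seed-deterministic", {
  d <- tiny_dataset(J = 10L, n_j = 10L, seed = 84L)
  a <- ampute_condition(d, "MCAR", 0.3, seed = 85L)
  for (method in c("parametric", "ranger5", "boost.dummies")) {
    opts <- if (grepl("ranger", method)) fast_forest_opts else
      list(boost = boost_config(rounds = 20L))
    out <- impute_method(a, method, m = 2L, seed = 86L, opts = opts)
    for (comp in out$completions) {
      expect_false(anyNA(comp[, amputable_cols()]))
      for (cl in amputable_cols()) {
        obs <- !a$mask[, cl]
        expect_identical(comp[[cl]][obs], d[[cl]][obs])
      }
    }
    again <- impute_method(a, method, m = 2L, seed = 86L, opts = opts)
    expect_identical(out$completions, again$completions)
  }
})

test_that("stochastic chains differ across the m completions", {
  d <- tiny_dataset(J = 10L, n_j = 10L, seed = 87L)
  a <- ampute_condition(d, "MCAR", 0.3, seed = 88L)
  out <- impute_method(a, "parametric", m = 3L, seed = 89L)
  mi <- a$mask[, "X1"]
  vals <- sapply(out$completions, function(cc) cc$X1[mi])
  expect_gt(max(apply(vals, 1, stats::var)), 0)
})

test_that("an unmapped incomplete variable is rejected before any work", {
  d <- tiny_dataset(seed = 90L)
  a <- ampute_mcar(d, columns = c("X1", "X2"), rate = 0.3, seed = 91L)
  cfg <- fcs_config(method_map = c(X1 = "2l_norm"), seed = 1L)
  expect_error(run_fcs(a, cfg), "X2")
})

test_that("visit order sorts by ascending missingness with stable ties", {
  d <- tiny_dataset(J = 10L, n_j = 10L, seed = 92L)
  mask <- matrix(FALSE, 100L, 13L,
                 dimnames = list(NULL, c(level1_vars(), level2_vars())))
  mask[1:30, "X2"] <- TRUE
  mask[1:10, "X5"] <- TRUE
  mask[1:20, "Y"] <- TRUE
  dat <- d
  for (cl in c("X2", "X5", "Y")) dat[[cl]][mask[, cl]] <- NA
  a <- structure(list(data = dat, mask = mask, meta = NULL),
                 class = "amputed_dataset")
  # record visit order via a closure
  visits <- new.env()
  visits$order <- character()
  register_imputer("test_order", function(y, x, cluster_id, miss) {
    visits$order <- c(visits$order, paste0("n", sum(miss)))
    rep(0, sum(miss))
  })
  cfg <- fcs_config(method_map = c(X2 = "test_order", X5 = "test_order",
                                   Y = "test_order"),
                    m = 1L, max_iterations = 1L,
                    visit_order = "ascending_missingness", seed = 3L)
  run_fcs(a, cfg)
  expect_equal(visits$order, c("n10", "n20", "n30"))
})
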