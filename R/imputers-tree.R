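#' Cluster-membership dummy augmentation
#'
#' Appends one 0/1 indicator column per cluster (`cl_dummy_<j>`). No
#' reference category is dropped: tree learners do not need one, and
#' keeping all J indicators lets any tree split isolate any cluster.
#' The indicators are predictors only; they are never imputation
#' targets.
#'
#' @param data dataset with a `cluster_id` column.
#' @return `data` with J indicator columns appended.
#' @export
add_cluster_dummies <- function(data) {
  stop_if_not(!anyNA(data$cluster_id), "cluster_id must be complete")
  stop_if_not(!any(startsWith(names(data), "cl_dummy_")),
              "cluster dummies already present")
  clusters <- sort(unique(data$cluster_id))
  d <- outer(data$cluster_id, clusters, `==`) * 1L
  colnames(d) <- paste0("cl_dummy_", clusters)
  cbind(data, as.data.frame(d))
}

#' Hyperparameters of the tree-based imputers
#'
#' `forest_config()` holds the random-forest settings (300 trees,
#' 0.632 subsampling without replacement, fully grown CART trees,
#' `mtry = floor(sqrt(p))` computed at fit time) and the PMM donor
#' count (`0` = raw predictions, `5` = matched draws).
#' `boost_config()` pins the gradient-boosting settings: 100 rounds,
#' depth 6, learning rate 0.3, row subsample 0.7, histogram split
#' finding; PMM off by default.
#'
#' @param n_trees number of trees.
#' @param sample_fraction subsample fraction per tree (without
#'   replacement).
#' @param pmm_k predictive-mean-matching donors (0 disables PMM).
#' @export
forest_config <- function(n_trees = 300L, sample_fraction = 0.632,
                          pmm_k = 0L) {
  list(n_trees = as.integer(n_trees), sample_fraction = sample_fraction,
       pmm_k = as.integer(pmm_k))
}

#' @rdname forest_config
#' @param rounds boosting rounds.
#' @param max_depth tree depth.
#' @param eta learning rate.
#' @param subsample row subsample fraction per round.
#' @export
boost_config <- function(rounds = 100L, max_depth = 6L, eta = 0.3,
                         subsample = 0.7, pmm_k = 0L) {
  list(rounds = as.integer(rounds), max_depth = max_depth, eta = eta,
       subsample = subsample, pmm_k = as.integer(pmm_k))
}

#' Random-forest imputation of one variable
#'
#' Fits a regression forest (300 fully grown trees, CART
#' variance-reduction splitting, `mtry = floor(sqrt(p))`, 0.632
#' subsampling without replacement) on the rows where the target is
#' observed and fills the missing rows with either the forest
#' prediction (`pmm_k = 0`) or a predictive-mean-matching draw over
#' the forest predictions (`pmm_k = 5`), with out-of-bag predictions
#' as the donor-side predictions.
#'
#' @param y target column.
#' @param x predictor data.frame/matrix (fully observed).
#' @param miss logical missingness of `y`.
#' @param config a `forest_config()`.
#' @param seed integer seed for the forest and the donor draws.
#' @return numeric vector of imputations with attribute `oob_error`
#'   (the forest's out-of-bag mean squared error).
#' @export
impute_forest <- function(y, x, miss, config = forest_config(),
                          seed = 1L) {
  obs <- !miss
  yo <- y[obs]
  if (stats::var(yo) == 0) {
    out <- rep(yo[1L], sum(miss))
    attr(out, "oob_error") <- 0
    return(out)
  }
  df <- as.data.frame(x)
  fit <- ranger::ranger(
    x = df[obs, , drop = FALSE], y = yo,
    num.trees = config$n_trees,
    mtry = floor(sqrt(ncol(df))),
    sample.fraction = config$sample_fraction,
    replace = FALSE,
    splitrule = "variance",
    num.threads = 1L,
    seed = seed
  )
  pred_mis <- stats::predict(fit, data = df[miss, , drop = FALSE],
                             num.threads = 1L)$predictions
  out <- if (config$pmm_k >= 1L) {
    oob <- fit$predictions
    bad <- is.na(oob)  # rows never out of bag fall back to y itself
    oob[bad] <- yo[bad]
    with_seed(derive_seed(seed, 77L),
              pmm_match(oob, yo, pred_mis, k = config$pmm_k))
  } else {
    pred_mis
  }
  attr(out, "oob_error") <- fit$prediction.error
  out
}

#' Gradient-boosting imputation of one variable
#'
#' Fits a gradient-boosted tree regressor (histogram-based split
#' finding, row subsampling) on the observed rows and fills the
#' missing rows with its predictions (optionally a PMM draw over
#' them). Between-imputation variability comes from the subsampling
#' and from the chained-equations initialization.
#'
#' @inheritParams impute_forest
#' @param config a `boost_config()`.
#' @export
impute_boost <- function(y, x, miss, config = boost_config(), seed = 1L) {
  obs <- !miss
  yo <- y[obs]
  if (stats::var(yo) == 0) return(rep(yo[1L], sum(miss)))
  xm <- as.matrix(x)
  storage.mode(xm) <- "double"
  fit <- xgboost::xgboost(
    x = xm[obs, , drop = FALSE], y = yo,
    objective = "reg:squarederror",
    nrounds = config$rounds,
    max_depth = config$max_depth,
    learning_rate = config$eta,
    subsample = config$subsample,
    tree_method = "hist",
    nthreads = 1L,
    seed = seed %% 2147483647L,
    verbosity = 0
  )
  pred_mis <- stats::predict(fit, xm[miss, , drop = FALSE])
  if (config$pmm_k >= 1L) {
    pred_obs <- stats::predict(fit, xm[obs, , drop = FALSE])
    with_seed(derive_seed(seed, 78L),
              pmm_match(pred_obs, yo, pred_mis, k = config$pmm_k))
  } else {
    pred_mis
  }
}
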