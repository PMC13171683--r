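#' Configuration for the two-level data-generating process
#'
#' Describes a balanced two-level design: `n_clusters` clusters of
#' `cluster_size` units each, twelve correlated latent predictor
#' variables (six kept at level 1 as `X1`--`X6`, six aggregated to
#' cluster means as `L1`--`L6`), and an outcome from either a
#' random-intercept or a random-intercept-and-slope linear mixed model.
#'
#' Each latent variable has unit marginal variance split into a
#' between-cluster component with variance `eta2` (the variable's
#' intraclass correlation, drawn uniformly from `eta2_range` once per
#' dataset) and a within-cluster component with variance `1 - eta2`.
#' Across the twelve variables the between components share an
#' exchangeable correlation `between_corr` and the within components
#' share `within_corr`; the defaults are calibrated so the marginal R²
#' of the two outcome models matches the study conditions
#' (approximately 0.484 for the random-intercept model and 0.442 for
#' the random-slope model).
#'
#' @param n_clusters number of clusters J (25 or 50 in the study).
#' @param cluster_size units per cluster (40 or 20; `J * cluster_size`
#'   is the total sample size, 1000 in the study).
#' @param model `"random_intercept"` or `"random_slope"`.
#' @param eta2_range interval from which each variable's between-cluster
#'   variance share is drawn.
#' @param between_corr exchangeable correlation of the cluster-level
#'   components across the 12 latent variables.
#' @param within_corr exchangeable correlation of the within-cluster
#'   components.
#' @param seed integer seed; predictor and random-effect draws use
#'   distinct sub-streams derived from it.
#' @return an object of class `dgp_config`.
#' @export
dgp_config <- function(n_clusters = 25L,
                       cluster_size = 40L,
                       model = c("random_intercept", "random_slope"),
                       eta2_range = c(0, 0.85),
                       between_corr = 0.54,
                       within_corr = 0.20,
                       seed = 1L) {
  model <- match.arg(model)
  stop_if_not(n_clusters >= 2, "n_clusters must be at least 2")
  stop_if_not(cluster_size >= 2,
              "cluster_size must be at least 2 (cluster means degenerate)")
  stop_if_not(length(eta2_range) == 2 && all(eta2_range >= 0) &&
                all(eta2_range < 1) && eta2_range[1] <= eta2_range[2],
              "eta2_range must be an interval inside [0, 1)")
  n_vars <- 12L
  lo <- -1 / (n_vars - 1)
  stop_if_not(between_corr > lo && between_corr < 1,
              "between_corr outside the positive-definite range (-1/11, 1)")
  stop_if_not(within_corr > lo && within_corr < 1,
              "within_corr outside the positive-definite range (-1/11, 1)")
  structure(list(n_clusters = as.integer(n_clusters),
                 cluster_size = as.integer(cluster_size),
                 model = model,
                 eta2_range = as.numeric(eta2_range),
                 between_corr = between_corr,
                 within_corr = within_corr,
                 seed = as.integer(seed)),
            class = "dgp_config")
}

#' Generating truth for a simulated dataset
#'
#' @param model outcome model; the slope variances are only used by the
#'   random-slope model.
#' @param beta 13-vector: intercept followed by the coefficients of
#'   `X1`--`X6` and `L1`--`L6`. The study value is
#'   `c(0.3, 0.5, 1, 1.5, 0, 0, 0, 0.5, 1, 1.5, 0, 0, 0)`, so `X4`,
#'   `X5`, `X6`, `L4`, `L5`, `L6` are pure noise features.
#' @param sigma2_eps residual variance (10 in the study).
#' @param tau2_intercept random-intercept variance (1).
#' @param tau2_slope1,tau2_slope2 random-slope variances for `X1` and
#'   `X2` (1 each; random-slope model only).
#' @param eta2_draws optional 12-vector of realized intraclass
#'   correlations; filled in by [generate_predictors()].
#' @return an object of class `truth_params`.
#' @export
truth_params <- function(model = c("random_intercept", "random_slope"),
                         beta = c(0.3, 0.5, 1, 1.5, 0, 0, 0,
                                  0.5, 1, 1.5, 0, 0, 0),
                         sigma2_eps = 10,
                         tau2_intercept = 1,
                         tau2_slope1 = 1,
                         tau2_slope2 = 1,
                         eta2_draws = NULL) {
  model <- match.arg(model)
  stop_if_not(length(beta) == 13, "beta must have length 13")
  stop_if_not(sigma2_eps >= 0 && tau2_intercept >= 0 &&
                tau2_slope1 >= 0 && tau2_slope2 >= 0,
              "variances must be non-negative")
  structure(list(model = model,
                 beta = as.numeric(beta),
                 sigma2_eps = sigma2_eps,
                 tau2_intercept = tau2_intercept,
                 tau2_slope1 = if (model == "random_slope") tau2_slope1 else 0,
                 tau2_slope2 = if (model == "random_slope") tau2_slope2 else 0,
                 eta2_draws = eta2_draws),
            class = "truth_params")
}

# Names of the amputable columns, in the study's column order.
level1_vars <- function() c(paste0("X", 1:6), "Y")
level2_vars <- function() paste0("L", 1:6)
predictor_vars <- function() c(paste0("X", 1:6), paste0("L", 1:6))

exchangeable_chol <- function(p, rho) {
  r <- matrix(rho, p, p)
  diag(r) <- 1
  chol(r)
}

#' Generate the clustered predictors of a two-level dataset
#'
#' Draws twelve latent clustered variables with unit marginal variance
#' and per-variable between-cluster variance share `eta2_k` drawn from
#' `config$eta2_range`. Variables 1--6 become the level-1 predictors
#' `X1`--`X6`; variables 7--12 are averaged within cluster and
#' broadcast to all rows as the level-2 predictors `L1`--`L6` (constant
#' within cluster, correlated with the level-1 variables whenever
#' `between_corr > 0`).
#'
#' @param config a [dgp_config()].
#' @return a `data.frame` with columns `cluster_id`, `X1`--`X6`,
#'   `L1`--`L6` and an `eta2_draws` attribute holding the realized
#'   intraclass correlations.
#' @export
generate_predictors <- function(config) {
  stop_if_not(inherits(config, "dgp_config"), "config must be a dgp_config")
  J <- config$n_clusters
  n_j <- config$cluster_size
  n <- J * n_j
  p <- 12L
  with_seed(derive_seed(config$seed, 101L), {
    eta2 <- stats::runif(p, config$eta2_range[1], config$eta2_range[2])
    cb <- exchangeable_chol(p, config$between_corr)
    cw <- exchangeable_chol(p, config$within_corr)
    # correlated standard-normal components, then scale to the variance split
    b <- (matrix(stats::rnorm(J * p), J, p) %*% cb) *
      rep(sqrt(eta2), each = J)
    w <- (matrix(stats::rnorm(n * p), n, p) %*% cw) *
      rep(sqrt(1 - eta2), each = n)
    cluster_id <- rep(seq_len(J), each = n_j)
    z <- b[cluster_id, , drop = FALSE] + w
    x <- z[, 1:6, drop = FALSE]
    lmeans <- rowsum(z[, 7:12, drop = FALSE], cluster_id) / n_j
    l <- lmeans[cluster_id, , drop = FALSE]
    out <- data.frame(cluster_id = cluster_id, x, l)
    names(out) <- c("cluster_id", paste0("X", 1:6), paste0("L", 1:6))
    attr(out, "eta2_draws") <- eta2
    out
  })
}

#' Add the outcome of a two-level linear mixed model
#'
#' Fills `Y` according to the generating model:
#' \deqn{Y_{ij} = \beta_0 + \sum_k \beta_k X_{ijk} + \sum_k \beta_{6+k}
#'   L_{ijk} + \delta_{0j} (+ \delta_{1j} X_{ij1} + \delta_{2j} X_{ij2})
#'   + \epsilon_{ij}}
#' with \eqn{\delta_{0j} \sim N(0, \tau^2_0)},
#' \eqn{\delta_{1j}, \delta_{2j} \sim N(0, \tau^2)} (random-slope model
#' only) and \eqn{\epsilon_{ij} \sim N(0, \sigma^2_\epsilon)}. Random
#' effects are drawn once per cluster from a sub-stream distinct from
#' the predictor draws, so the same predictors can carry either outcome
#' model.
#'
#' @param data predictors from [generate_predictors()].
#' @param truth a [truth_params()].
#' @param seed integer seed for the outcome sub-stream.
#' @return `data` with a `Y` column appended and the truth attached as
#'   attribute `truth`.
#' @export
generate_outcome <- function(data, truth, seed) {
  stop_if_not(inherits(truth, "truth_params"), "truth must be truth_params")
  stop_if_not(all(c(predictor_vars(), "cluster_id") %in% names(data)),
              "data must contain cluster_id, X1..X6, L1..L6")
  xl <- as.matrix(data[, predictor_vars()])
  cluster_id <- data$cluster_id
  J <- length(unique(cluster_id))
  jidx <- match(cluster_id, sort(unique(cluster_id)))
  with_seed(derive_seed(seed, 202L), {
    fixed <- truth$beta[1] + drop(xl %*% truth$beta[-1])
    d0 <- stats::rnorm(J, 0, sqrt(truth$tau2_intercept))
    ranef <- d0[jidx]
    if (truth$model == "random_slope") {
      d1 <- stats::rnorm(J, 0, sqrt(truth$tau2_slope1))
      d2 <- stats::rnorm(J, 0, sqrt(truth$tau2_slope2))
      ranef <- ranef + d1[jidx] * data$X1 + d2[jidx] * data$X2
    }
    eps <- stats::rnorm(nrow(data), 0, sqrt(truth$sigma2_eps))
    data$Y <- fixed + ranef + eps
    attr(data, "truth") <- truth
    data
  })
}

#' Generate a complete two-level dataset
#'
#' Convenience wrapper: predictors, realized intraclass correlations,
#' and outcome in one call.
#'
#' @inheritParams generate_predictors
#' @param truth optional [truth_params()]; defaults to the study values
#'   for `config$model`.
#' @return a complete `data.frame` with `truth` attribute.
#' @export
generate_dataset <- function(config, truth = NULL) {
  dat <- generate_predictors(config)
  if (is.null(truth)) truth <- truth_params(model = config$model)
  truth$eta2_draws <- attr(dat, "eta2_draws")
  generate_outcome(dat, truth, seed = config$seed)
}

#' Marginal R-squared of a generated dataset
#'
#' Proportion of outcome variance explained by the fixed effects:
#' `Var(fixed linear predictor)` over `Var(fixed) + random-effect
#' variance + residual variance`. The fixed-effect variance is computed
#' empirically from the realized predictors; random-slope terms
#' contribute `tau2 * mean(X^2)` each.
#'
#' @param data a generated dataset (predictors present).
#' @param truth the generating [truth_params()]; defaults to the
#'   dataset's `truth` attribute.
#' @return the marginal R-squared, a proportion.
#' @export
marginal_r2 <- function(data, truth = attr(data, "truth")) {
  stop_if_not(inherits(truth, "truth_params"), "generating truth required")
  xl <- as.matrix(data[, predictor_vars()])
  fixed <- drop(xl %*% truth$beta[-1])
  var_fixed <- stats::var(fixed)
  var_ran <- truth$tau2_intercept +
    truth$tau2_slope1 * mean(data$X1^2) +
    truth$tau2_slope2 * mean(data$X2^2)
  total <- var_fixed + var_ran + truth$sigma2_eps
  stop_if_not(total > 0, "total outcome variance is zero; R2 undefined")
  var_fixed / total
}
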