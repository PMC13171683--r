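#' Predictive mean matching donor draw
#'
#' For each missing entry, the `k` observed entries whose predictions
#' are closest to the missing entry's prediction form the donor pool
#' (distance ties broken by stable index order); one donor is sampled
#' uniformly and its observed value is returned. Every imputed value is
#' therefore a member of the observed value set.
#'
#' @param predictions_obs predictions for the observed entries.
#' @param values_obs observed values, aligned with `predictions_obs`.
#' @param predictions_mis predictions for the missing entries.
#' @param k number of donors (5 in the study).
#' @return numeric vector of imputations, one per missing prediction.
#' @export
pmm_match <- function(predictions_obs, values_obs, predictions_mis, k = 5L) {
  stop_if_not(length(predictions_obs) == length(values_obs),
              "predictions_obs and values_obs must be aligned")
  stop_if_not(length(predictions_obs) >= 1, "empty observed set")
  k <- min(as.integer(k), length(values_obs))
  stop_if_not(k >= 1, "k_donors must be at least 1")
  vapply(predictions_mis, function(p) {
    d <- abs(predictions_obs - p)
    donors <- order(d)[seq_len(k)]  # order() is stable: ties keep index order
    values_obs[donors[sample.int(k, 1L)]]
  }, 0)
}

# Bayesian normal linear regression parameter draw (vague priors, with
# a small ridge jitter if the cross-product is singular). Returns the
# least-squares coefficients and a posterior draw of (beta, sigma2).
norm_draw <- function(x, y) {
  p <- ncol(x)
  n <- length(y)
  xtx <- crossprod(x)
  r <- tryCatch(chol(xtx), error = function(e) NULL)
  if (is.null(r)) {
    warning("singular predictor matrix; ridge-stabilizing", call. = FALSE)
    xtx <- xtx + diag(1e-5 * (mean(diag(xtx)) + 1), p)
    r <- chol(xtx)
  }
  v <- chol2inv(r)
  coef <- drop(v %*% crossprod(x, y))
  df <- max(n - p, 1L)
  ssr <- sum((y - drop(x %*% coef))^2)
  sigma2 <- max(ssr, 1e-10) / stats::rchisq(1L, df)
  beta <- coef + backsolve(r, stats::rnorm(p)) * sqrt(sigma2)
  list(coef = coef, beta = beta, sigma2 = sigma2)
}

#' Two-level normal imputation of a level-1 variable
#'
#' Bayesian random-intercept linear model of the target on the
#' predictors with heterogeneous within-cluster variances, estimated on
#' the observed rows by a Gibbs sampler in the Kasim--Raudenbush
#' scheme: cycle draws of the fixed effects (weighted by the current
#' per-cluster precisions), the per-cluster intercepts, one residual
#' variance per cluster, and the intercept variance, all under vague
#' priors. After `n_sweeps` sweeps the missing entries are drawn from
#' `N(x'beta + delta_j, sigma2_j)` at the final parameter state; a
#' cluster with no observed target rows receives an intercept drawn
#' from `N(0, tau2)` and the pooled residual variance.
#'
#' The per-cluster variance draws `sigma2_j = SS_j / chisq(n_j)` are
#' deliberately heavy-tailed for small observed cluster counts; this is
#' the behaviour of the reference two-level normal imputer and the main
#' source of between-imputation variability of the parametric method.
#'
#' @param y target column (with `NA`s allowed in `miss` positions).
#' @param x numeric predictor matrix, fully observed, without intercept.
#' @param cluster_id cluster membership vector.
#' @param miss logical: which entries of `y` to impute.
#' @param n_sweeps Gibbs sweeps per call (default 100).
#' @param use_cpp run the sweep loop in compiled code (default); the
#'   pure-R loop consumes the same pre-drawn randomness and agrees to
#'   floating-point accuracy, serving as a cross-check.
#' @return numeric vector of imputations for the `miss` entries.
#' @export
impute_two_level_normal <- function(y, x, cluster_id, miss,
                                    n_sweeps = 100L, use_cpp = TRUE) {
  obs <- !miss
  stop_if_not(sum(obs) > ncol(x) + 2, "too few observed rows")
  clusters <- sort(unique(cluster_id))
  jidx <- match(cluster_id, clusters)
  J <- length(clusters)
  xo <- cbind(1, x[obs, , drop = FALSE])
  yo <- y[obs]
  jo <- jidx[obs]
  n_obs <- length(yo)
  p <- ncol(xo)
  stop_if_not(length(unique(jo)) >= 2,
              "need observed target values in at least 2 clusters")

  xtx <- crossprod(xo)
  r <- tryCatch(chol(xtx), error = function(e) NULL)
  if (is.null(r)) {
    warning("singular predictor matrix; ridge-stabilizing", call. = FALSE)
    xtx <- xtx + diag(1e-5 * (mean(diag(xtx)) + 1), p)
    r <- chol(xtx)
  }
  # per-cluster sufficient statistics over ALL J clusters (zero for
  # clusters with no observed target); column 1 of xo is the intercept,
  # so G_j[1, ] doubles as the per-cluster column sums of X
  present <- sort(unique(jo))
  n_j <- tabulate(jo, nbins = J)
  gmat <- matrix(0, J, p * p)  # row j holds vec(X_j' X_j)
  xty <- matrix(0, J, p)       # row j holds X_j' y_j
  yty_j <- rep(0, J)
  for (j in present) {
    sel <- jo == j
    xj <- xo[sel, , drop = FALSE]
    gmat[j, ] <- as.vector(crossprod(xj))
    xty[j, ] <- crossprod(xj, yo[sel])
    yty_j[j] <- sum(yo[sel]^2)
  }
  cs <- gmat[, seq_len(p), drop = FALSE]  # X_j' 1 (first block of G_j)
  sum_y <- xty[, 1L]

  beta0 <- drop(chol2inv(r) %*% colSums(xty))
  sigma2_pool <- max(stats::var(yo - drop(xo %*% beta0)), 1e-8)
  has_obs <- n_j > 0
  j_obs <- sum(has_obs)
  # pre-draw the randomness for all sweeps so the loop is a pure
  # computation (and can run in compiled code without touching the RNG)
  z_beta <- matrix(stats::rnorm(p * n_sweeps), p, n_sweeps)
  z_delta <- matrix(stats::rnorm(J * n_sweeps), J, n_sweeps)
  chi_sigma <- matrix(stats::rchisq(J * n_sweeps,
                                    df = pmax(rep(n_j, n_sweeps), 1)),
                      J, n_sweeps)
  chi_tau <- stats::rchisq(n_sweeps, j_obs)
  if (use_cpp) {
    st <- .gibbs_2l_run(gmat, xty, yty_j, n_j, z_beta, z_delta,
                        chi_sigma, chi_tau, beta0, sigma2_pool)
    beta <- drop(st$beta)
    delta <- drop(st$delta)
    sigma2 <- drop(st$sigma2)
  } else {
    beta <- beta0
    sigma2 <- rep(sigma2_pool, J)
    tau2 <- 1
    delta <- rep(0, J)
    for (s in seq_len(n_sweeps)) {
      w <- ifelse(has_obs, 1 / sigma2, 0)
      # fixed effects | delta, sigma2_j: weighted least squares draw
      a <- matrix(colSums(gmat * w), p, p)
      bvec <- colSums((xty - delta * cs) * w)
      ch <- chol(a)
      mean_b <- backsolve(ch, forwardsolve(t(ch), bvec))
      beta <- mean_b + backsolve(ch, z_beta[, s])
      # cluster intercepts | beta, sigma2_j, tau2
      resj <- sum_y - drop(cs %*% beta)
      prec <- n_j / sigma2 + 1 / tau2
      delta <- (resj / sigma2) / prec + z_delta[, s] / sqrt(prec)
      # per-cluster residual variances | beta, delta (vague priors)
      quad <- drop(gmat %*% as.vector(outer(beta, beta)))
      ss <- yty_j - 2 * drop(xty %*% beta) + quad - 2 * delta * resj +
        n_j * delta^2
      sigma2 <- pmax(ss, 1e-10) / chi_sigma[, s]
      sigma2[!has_obs] <- sigma2_pool
      # intercept variance | delta (clusters with observed rows)
      tau2 <- max(sum(delta[has_obs]^2), 1e-10) / chi_tau[s]
    }
  }
  tau2 <- if (use_cpp) st$tau2 else tau2
  # empty clusters: intercept from the population distribution, pooled
  # residual variance
  if (any(!has_obs)) {
    delta[!has_obs] <- stats::rnorm(sum(!has_obs), 0, sqrt(tau2))
    sigma2[!has_obs] <- sigma2_pool
  }
  xm <- cbind(1, x[miss, , drop = FALSE])
  jm <- jidx[miss]
  drop(xm %*% beta) + delta[jm] +
    stats::rnorm(sum(miss), 0, sqrt(sigma2[jm]))
}

#' Cluster-level predictive mean matching for a level-2 variable
#'
#' Collapses the data to one row per cluster (cluster means of the
#' predictors), fits a Bayesian normal regression on the clusters with
#' the target observed, and matches each missing cluster to the
#' `k_donors` observed clusters with nearest predictions. Type-1
#' matching: donor predictions come from the least-squares fit,
#' recipient predictions from a posterior parameter draw. The sampled
#' donor's observed value is assigned to every row of the recipient
#' cluster, so imputed level-2 columns stay constant within cluster.
#'
#' @param y target level-2 column.
#' @param x numeric predictor matrix (level-2 predictors), one column
#'   per variable, row-level; collapsed to cluster means internally.
#' @param cluster_id cluster membership vector.
#' @param miss logical row-level missingness of `y` (all-or-none within
#'   cluster).
#' @param k_donors donor pool size (5); if fewer observed clusters are
#'   available the whole observed pool is used, with a warning.
#' @return numeric vector of imputations for the `miss` entries.
#' @export
impute_level2_pmm <- function(y, x, cluster_id, miss, k_donors = 5L) {
  clusters <- sort(unique(cluster_id))
  jidx <- match(cluster_id, clusters)
  J <- length(clusters)
  xc <- cbind(1, rowsum(x, jidx) / tabulate(jidx, J))
  # cluster-level target value and missingness
  miss_j <- as.logical(rowsum(as.numeric(miss), jidx) > 0)
  yc <- rep(NA_real_, J)
  yc[!miss_j] <- vapply(which(!miss_j),
                        function(j) y[jidx == j & !miss][1L], 0)
  n_obs <- sum(!miss_j)
  stop_if_not(n_obs >= 1, "no cluster observes the target")
  if (n_obs < k_donors) {
    warning("fewer observed clusters than donors; using all of them",
            call. = FALSE)
    k_donors <- n_obs
  }
  dr <- norm_draw(xc[!miss_j, , drop = FALSE], yc[!miss_j])
  pred_obs <- drop(xc[!miss_j, , drop = FALSE] %*% dr$coef)
  pred_mis <- drop(xc[miss_j, , drop = FALSE] %*% dr$beta)
  imp_j <- pmm_match(pred_obs, yc[!miss_j], pred_mis, k = k_donors)
  filled <- yc
  filled[miss_j] <- imp_j
  filled[jidx][miss]
}
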