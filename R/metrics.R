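#' Monte Carlo standard errors
#'
#' `mcse_proportion(p, n_reps)` returns `sqrt(p (1 - p) / n_reps)`, the
#' MCSE of an estimated rejection rate. `mcse_bias(estimates)` returns
#' `sd / sqrt(N)` and `mcse_sd(estimates)` returns `sd / sqrt(2 N)`,
#' the MCSEs of a bias and of an empirical standard deviation over `N`
#' replications.
#'
#' @param p estimated proportion in `[0, 1]`.
#' @param n_reps number of replications.
#' @return the Monte Carlo standard error.
#' @export
mcse_proportion <- function(p, n_reps) {
  stop_if_not(all(p >= 0 & p <= 1), "p must be a proportion")
  stop_if_not(n_reps >= 1, "n_reps must be at least 1")
  sqrt(p * (1 - p) / n_reps)
}

#' @rdname mcse_proportion
#' @param estimates vector of per-replication estimates (length >= 2).
#' @export
mcse_bias <- function(estimates) {
  n <- length(estimates)
  stop_if_not(n >= 2, "need at least 2 estimates")
  stats::sd(estimates) / sqrt(n)
}

#' @rdname mcse_proportion
#' @export
mcse_sd <- function(estimates) {
  mcse_bias(estimates) / sqrt(2)
}

#' The full factorial study design
#'
#' Crossing of cluster count (25 x 40 or 50 x 20, total N = 1000) by
#' outcome model by missingness mechanism by missing rate: 2 x 2 x 2 x
#' 3 = 24 condition cells.
#'
#' @return a data.frame with one row per condition.
#' @export
condition_grid <- function() {
  g <- expand.grid(n_clusters = c(25L, 50L),
                   model = c("random_intercept", "random_slope"),
                   mechanism = c("MCAR", "MAR"),
                   miss_rate = c(0.10, 0.30, 0.50),
                   stringsAsFactors = FALSE)
  g$cluster_size <- 1000L %/% g$n_clusters
  g[, c("n_clusters", "cluster_size", "model", "mechanism", "miss_rate")]
}

coef_terms <- function() c("(Intercept)", paste0("X", 1:6), paste0("L", 1:6))

true_beta_by_term <- function(truth = truth_params()) {
  stats::setNames(truth$beta, coef_terms())
}

#' Run one simulation replication of a condition
#'
#' Generate a dataset, fit the complete-data reference model, ampute,
#' and for each requested method impute (`m` completions), fit, and
#' pool. Fully determined by `seed`.
#'
#' @param n_clusters,model,mechanism,miss_rate the condition cell.
#' @param methods character vector of [study_methods()] entries.
#' @param seed integer replication seed.
#' @param m number of imputations.
#' @param opts imputer option overrides (see [method_config()]).
#' @param complete_test reference test for the complete-data fit:
#'   `"satterthwaite"` (t test with Satterthwaite degrees of freedom)
#'   or `"normal"` (Wald z).
#' @return data.frame with one row per method (including
#'   `"complete"`) x coefficient: `method`, `term`, `estimate`, `se`,
#'   `p`, `converged`.
#' @export
run_replication <- function(n_clusters, model, mechanism, miss_rate,
                            methods, seed, m = 5L, opts = list(),
                            complete_test = c("satterthwaite",
                                              "normal")) {
  complete_test <- match.arg(complete_test)
  cfg <- dgp_config(n_clusters = n_clusters,
                    cluster_size = 1000L %/% n_clusters,
                    model = model, seed = seed)
  dat <- generate_dataset(cfg)
  ref <- fit_lmm(dat, model,
                 satterthwaite = complete_test == "satterthwaite")
  rc <- ref$coefficients
  if (complete_test == "normal") {
    rc$p <- 2 * stats::pnorm(-abs(rc$estimate / rc$se))
  }
  out <- data.frame(method = "complete", term = rc$term,
                    estimate = rc$estimate, se = rc$se, p = rc$p,
                    converged = ref$converged)
  amp <- ampute_condition(dat, mechanism, miss_rate,
                          seed = derive_seed(seed, 601L))
  for (k in seq_along(methods)) {
    method <- methods[k]
    row <- tryCatch({
      imp <- impute_method(amp, method, m = m,
                           seed = derive_seed(seed, 602L, k), opts = opts)
      fits <- fit_imputed(imp, model)
      pl <- pool_rubin(fits)$pooled
      data.frame(method = method, term = pl$term, estimate = pl$qbar,
                 se = pl$se, p = pl$p, converged = TRUE)
    }, error = function(e) {
      data.frame(method = method, term = coef_terms(),
                 estimate = NA_real_, se = NA_real_, p = NA_real_,
                 converged = FALSE)
    })
    out <- rbind(out, row)
  }
  out$replication <- seed
  out
}

#' Evaluate imputation methods on one study condition
#'
#' Runs `n_reps` independent replications of a condition cell and
#' aggregates the evaluation metrics per method and coefficient:
#' rejection rate at `alpha` (type I error for the true-zero
#' coefficients `X4`--`X6`, `L4`--`L6`; power for the nonzero ones),
#' bias and relative bias of the pooled estimates, their empirical
#' standard deviation, the ratio of that standard deviation to the
#' complete-data one (`sd_ratio`), the ratio of the mean model-based
#' standard error to the empirical standard deviation
#' (`se_calibration`), and the matching Monte Carlo standard errors.
#'
#' @inheritParams run_replication
#' @param n_reps number of replications.
#' @param seed integer base seed; replication r uses a derived
#'   sub-seed.
#' @param alpha significance level (0.05).
#' @param progress print a dot every 10 replications.
#' @return list with `metrics` (one row per method x coefficient),
#'   `estimates` (the raw per-replication results), and `n_failed`
#'   (non-converged or failed method runs, excluded from metrics).
#' @export
evaluate_condition <- function(n_clusters, model, mechanism, miss_rate,
                               methods = study_methods(), n_reps = 100L,
                               seed = 1L, m = 5L, alpha = 0.05,
                               opts = list(),
                               complete_test = c("satterthwaite",
                                                 "normal"),
                               progress = FALSE) {
  complete_test <- match.arg(complete_test)
  reps <- lapply(seq_len(n_reps), function(r) {
    if (progress && r %% 10 == 0) cat(".")
    run_replication(n_clusters, model, mechanism, miss_rate, methods,
                    seed = derive_seed(seed, 701L, r), m = m,
                    opts = opts, complete_test = complete_test)
  })
  if (progress) cat("\n")
  est <- do.call(rbind, reps)
  metrics <- summarize_estimates(est, alpha = alpha)
  metrics$n_clusters <- n_clusters
  metrics$model <- model
  metrics$mechanism <- mechanism
  metrics$miss_rate <- miss_rate
  list(metrics = metrics, estimates = est,
       n_failed = sum(!est$converged) / length(coef_terms()))
}

#' Aggregate per-replication pooled estimates into evaluation metrics
#'
#' @param estimates data.frame as returned by [run_replication()]
#'   (rows from several replications stacked).
#' @param truth generating [truth_params()]; defaults to the study
#'   coefficients.
#' @param alpha significance level.
#' @return data.frame of metrics per method x coefficient.
#' @export
summarize_estimates <- function(estimates, truth = truth_params(),
                                alpha = 0.05) {
  beta <- true_beta_by_term(truth)
  est <- estimates[estimates$converged & !is.na(estimates$estimate), ]
  sd_complete <- tapply(est$estimate[est$method == "complete"],
                        est$term[est$method == "complete"], stats::sd)
  sd_complete_of <- function(term) {
    if (term %in% names(sd_complete)) sd_complete[[term]] else NA_real_
  }
  groups <- unique(est[, c("method", "term")])
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    g <- est[est$method == groups$method[i] & est$term == groups$term[i], ]
    n <- nrow(g)
    b_true <- beta[[groups$term[i]]]
    rej <- mean(g$p < alpha)
    bias <- mean(g$estimate) - b_true
    emp_sd <- if (n >= 2) stats::sd(g$estimate) else NA_real_
    data.frame(
      method = groups$method[i], term = groups$term[i], n_reps = n,
      true_beta = b_true,
      rejection_rate = rej,
      bias = bias,
      relative_bias = if (b_true != 0) bias / b_true else NA_real_,
      emp_sd = emp_sd,
      sd_ratio = emp_sd / sd_complete_of(groups$term[i]),
      se_calibration = mean(g$se) / emp_sd,
      mcse_rejection = mcse_proportion(rej, n),
      mcse_bias = if (n >= 2) mcse_bias(g$estimate) else NA_real_,
      mcse_sd = if (n >= 2) mcse_sd(g$estimate) else NA_real_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Coefficient classification helpers
#'
#' `zero_terms()` are the noise coefficients whose rejection rate is a
#' type I error; `nonzero_terms()` carry the power comparison;
#' `level2_terms()` are the cluster-level coefficients.
#' @export
zero_terms <- function() c("X4", "X5", "X6", "L4", "L5", "L6")

#' @rdname zero_terms
#' @export
nonzero_terms <- function() c("X1", "X2", "X3", "L1", "L2", "L3")

#' @rdname zero_terms
#' @export
level2_terms <- function() paste0("L", 1:6)
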