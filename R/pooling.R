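#' Fit the linear mixed analysis model
#'
#' REML fit of `Y` on `X1`--`X6`, `L1`--`L6` with a cluster random
#' intercept (`random_intercept`) or additionally independent random
#' slopes for `X1` and `X2` (`random_slope`), matching the
#' data-generating model.
#'
#' @param data a completed dataset.
#' @param model analysis model.
#' @param satterthwaite also compute Satterthwaite denominator degrees
#'   of freedom (via \pkg{lmerTest}) for complete-data reference
#'   inference; pooled inference uses Rubin's rules instead and does
#'   not need them.
#' @return an object of class `lmm_fit`: a data.frame `coefficients`
#'   with `term`, `estimate`, `se` (and `df`, `p` when
#'   `satterthwaite`), plus `converged`, `n`, `n_clusters`.
#' @export
fit_lmm <- function(data,
                    model = c("random_intercept", "random_slope"),
                    satterthwaite = FALSE) {
  model <- match.arg(model)
  stop_if_not(!anyNA(data[, amputable_cols()]), "data must be complete")
  stop_if_not(length(unique(data$cluster_id)) >= 2,
              "need at least 2 clusters")
  rhs <- paste(predictor_vars(), collapse = " + ")
  re <- if (model == "random_intercept") {
    "(1 | cluster_id)"
  } else {
    "(1 | cluster_id) + (0 + X1 | cluster_id) + (0 + X2 | cluster_id)"
  }
  form <- stats::as.formula(paste("Y ~", rhs, "+", re))
  ctrl <- lme4::lmerControl(calc.derivs = FALSE,
                            check.conv.singular = "ignore")
  fit <- if (satterthwaite) {
    stop_if_not(requireNamespace("lmerTest", quietly = TRUE),
                "lmerTest is required for satterthwaite = TRUE")
    lmerTest::lmer(form, data = data, REML = TRUE,
                   control = lme4::lmerControl(check.conv.singular = "ignore"))
  } else {
    lme4::lmer(form, data = data, REML = TRUE, control = ctrl)
  }
  sm <- summary(fit)$coefficients
  co <- data.frame(term = rownames(sm),
                   estimate = sm[, "Estimate"],
                   se = sm[, "Std. Error"],
                   row.names = NULL)
  if (satterthwaite) {
    co$df <- sm[, "df"]
    co$p <- sm[, "Pr(>|t|)"]
  }
  conv <- length(fit@optinfo$conv$lme4$messages) == 0 &&
    fit@optinfo$conv$opt == 0
  structure(list(coefficients = co, converged = conv,
                 n = nrow(data),
                 n_clusters = length(unique(data$cluster_id)),
                 model = model),
            class = "lmm_fit")
}

#' Fit the analysis model to every completion of an imputed set
#'
#' @param imputed an `imputed_set`.
#' @inheritParams fit_lmm
#' @return list of `lmm_fit` objects.
#' @export
fit_imputed <- function(imputed,
                        model = c("random_intercept", "random_slope")) {
  model <- match.arg(model)
  lapply(imputed$completions, fit_lmm, model = model)
}

#' Pool mixed-model fits with Rubin's rules
#'
#' Per coefficient: pooled estimate `Qbar` (mean of the estimates),
#' within-imputation variance `W` (mean squared standard error),
#' between-imputation variance `B` (sample variance of the estimates),
#' total variance `T = W + (1 + 1/m) B`, degrees of freedom by the
#' Barnard--Rubin small-sample adjustment with complete-data degrees of
#' freedom `dfcom` (sample size minus the number of fixed effects), and
#' a two-sided t test of zero.
#'
#' @param fits list of `m >= 2` converged `lmm_fit` objects.
#' @param dfcom complete-data degrees of freedom; defaults to
#'   `n - #coefficients` of the first fit.
#' @param alpha significance level carried along for convenience.
#' @return a `pooled_fit`: data.frame `pooled` with `term`, `qbar`,
#'   `w`, `b`, `t_var`, `se`, `df`, `statistic`, `p`, plus `m`, `alpha`.
#' @export
pool_rubin <- function(fits, dfcom = NULL, alpha = 0.05) {
  fits <- Filter(function(f) isTRUE(f$converged), fits)
  m <- length(fits)
  stop_if_not(m >= 2, "pooling needs at least 2 converged fits")
  terms <- fits[[1]]$coefficients$term
  k <- length(terms)
  est <- matrix(vapply(fits, function(f) f$coefficients$estimate,
                       numeric(k)), nrow = k)
  se <- matrix(vapply(fits, function(f) f$coefficients$se,
                      numeric(k)), nrow = k)
  stop_if_not(all(vapply(fits, function(f)
    identical(f$coefficients$term, terms), TRUE)),
    "fits have misaligned coefficients")
  if (is.null(dfcom)) dfcom <- fits[[1]]$n - length(terms)
  qbar <- rowMeans(est)
  w <- rowMeans(se^2)
  b <- apply(est, 1, stats::var)
  t_var <- w + (1 + 1 / m) * b
  lambda <- (1 + 1 / m) * b / t_var
  lambda <- pmin(pmax(lambda, 0), 1)
  df_old <- ifelse(lambda > 0, (m - 1) / lambda^2, Inf)
  df_obs <- (dfcom + 1) / (dfcom + 3) * dfcom * (1 - lambda)
  df <- ifelse(is.finite(df_old),
               df_old * df_obs / (df_old + df_obs), df_obs)
  statistic <- qbar / sqrt(t_var)
  p <- 2 * stats::pt(-abs(statistic), df)
  structure(list(pooled = data.frame(term = terms, qbar = qbar, w = w,
                                     b = b, t_var = t_var,
                                     se = sqrt(t_var), df = df,
                                     statistic = statistic, p = p,
                                     row.names = NULL),
                 m = m, dfcom = dfcom, alpha = alpha),
            class = "pooled_fit")
}
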