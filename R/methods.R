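#' The study's imputation method variants
#'
#' Seven registered variants: the parametric multilevel method
#' (two-level normal model for the level-1 variables, cluster-level
#' predictive mean matching for the level-2 variables) and six
#' tree-based configurations — chained random forests with and without
#' predictive mean matching (k = 5 donors) and gradient boosting, each
#' with and without cluster-membership dummy variables.
#'
#' @return character vector of method names accepted by
#'   [impute_method()].
#' @export
study_methods <- function() {
  c("parametric", "ranger", "ranger5", "ranger.dummies",
    "ranger5.dummies", "boost", "boost.dummies")
}

#' Build the chained-equations configuration for a named method
#'
#' Encodes the study's hyperparameters: the parametric chain visits
#' variables in column order for 10 iterations; the forest chains visit
#' in ascending missingness, initialize with observed means, use 300
#' fully grown trees with 0.632 subsampling and stop early (capped at
#' 10 iterations) when the mean out-of-bag error stops improving; the
#' boosting chains initialize with random observed draws and run 5
#' iterations with 100 rounds, depth 6, learning rate 0.3 and row
#' subsample 0.7.
#'
#' @param method one of [study_methods()].
#' @param m number of imputations.
#' @param seed integer seed.
#' @param opts overrides merged into the imputer options.
#' @return an [fcs_config()].
#' @export
method_config <- function(method, m = 5L, seed = 1L, opts = list()) {
  method <- match.arg(method, study_methods())
  l1 <- level1_vars()
  l2 <- level2_vars()
  all_cols <- c(l1, l2)
  base <- switch(method,
    parametric = fcs_config(
      method_map = stats::setNames(
        c(rep("2l_norm", length(l1)), rep("2lonly_pmm", length(l2))),
        c(l1, l2)),
      max_iterations = 10L,
      visit_order = "column_order",
      initial_fill = "random_observed_draw"),
    ranger = ,
    ranger.dummies = fcs_config(
      method_map = stats::setNames(rep("ranger", 13L), all_cols),
      max_iterations = 10L,
      visit_order = "ascending_missingness",
      initial_fill = "mean_mode",
      early_stop = TRUE,
      opts = list(forest = forest_config(pmm_k = 0L))),
    ranger5 = ,
    ranger5.dummies = fcs_config(
      method_map = stats::setNames(rep("ranger", 13L), all_cols),
      max_iterations = 10L,
      visit_order = "ascending_missingness",
      initial_fill = "mean_mode",
      early_stop = TRUE,
      opts = list(forest = forest_config(pmm_k = 5L))),
    boost = ,
    boost.dummies = fcs_config(
      method_map = stats::setNames(rep("boost", 13L), all_cols),
      max_iterations = 5L,
      visit_order = "ascending_missingness",
      initial_fill = "random_observed_draw",
      opts = list(boost = boost_config()))
  )
  base$dummies <- grepl("dummies", method, fixed = TRUE)
  base$label <- method
  base$m <- as.integer(m)
  base$seed <- as.integer(seed)
  base$opts <- utils::modifyList(base$opts, opts)
  base
}

#' Impute an amputed dataset with a named study method
#'
#' @param amputed an `amputed_dataset`.
#' @inheritParams method_config
#' @return an `imputed_set` of `m` completions.
#' @export
impute_method <- function(amputed, method, m = 5L, seed = 1L,
                          opts = list()) {
  run_fcs(amputed, method_config(method, m = m, seed = seed, opts = opts))
}
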