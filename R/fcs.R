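#' Fully conditional specification (chained equations) engine
#'
#' Produces `m` completed copies of an incomplete dataset by cycling
#' univariate imputations over the incomplete variables: initialize the
#' missing cells, then on each iteration visit the incomplete variables
#' in order, regress the observed part of the target on all other
#' (currently completed) variables with the mapped imputer, and replace
#' the target's missing entries with the imputer's draws. Each of the
#' `m` chains runs on an independent random sub-stream.
#'
#' @name fcs
NULL

# registry for user-supplied univariate imputers
.imputer_registry <- new.env(parent = emptyenv())

#' Register a custom univariate imputer
#'
#' @param name string key usable in an `fcs_config` method map.
#' @param fn `function(y, x, cluster_id, miss)` returning one value per
#'   missing entry; `x` is a data.frame of the other (completed)
#'   columns.
#' @export
register_imputer <- function(name, fn) {
  stop_if_not(is.function(fn), "fn must be a function")
  assign(name, fn, envir = .imputer_registry)
  invisible(name)
}

#' Chained-equations configuration
#'
#' @param method_map named character vector mapping each incomplete
#'   variable to an imputer name (`"2l_norm"`, `"2lonly_pmm"`,
#'   `"ranger"`, `"boost"`, or a registered custom imputer).
#' @param m number of imputations (5 in the study).
#' @param max_iterations iterations of the variable-by-variable cycle
#'   (10 for the parametric and forest chains, 5 for boosting).
#' @param visit_order `"column_order"` (study column order, used by the
#'   parametric chain) or `"ascending_missingness"` (fewest missing
#'   first, used by the tree chains).
#' @param initial_fill `"mean_mode"` (observed column mean) or
#'   `"random_observed_draw"` (uniform draw from the observed values).
#' @param early_stop stop when the mean out-of-bag error across targets
#'   stops improving and keep the previous iteration's values (forest
#'   chain behaviour); only meaningful for imputers that report an
#'   `oob_error`.
#' @param dummies augment the predictor set with cluster-membership
#'   indicator columns (tree methods only).
#' @param opts list of imputer options: `n_sweeps` (Gibbs sweeps for
#'   `2l_norm`), `k_donors` (`2lonly_pmm`), `forest` (a
#'   `forest_config()`), `boost` (a `boost_config()`).
#' @param label method label carried into results.
#' @param seed integer seed.
#' @export
fcs_config <- function(method_map,
                       m = 5L,
                       max_iterations = 10L,
                       visit_order = c("column_order",
                                       "ascending_missingness"),
                       initial_fill = c("random_observed_draw",
                                        "mean_mode"),
                       early_stop = FALSE,
                       dummies = FALSE,
                       opts = list(),
                       label = "fcs",
                       seed = 1L) {
  stop_if_not(m >= 1, "m must be at least 1")
  stop_if_not(max_iterations >= 1, "max_iterations must be at least 1")
  structure(list(method_map = method_map, m = as.integer(m),
                 max_iterations = as.integer(max_iterations),
                 visit_order = match.arg(visit_order),
                 initial_fill = match.arg(initial_fill),
                 early_stop = early_stop, dummies = dummies,
                 opts = opts, label = label, seed = as.integer(seed)),
            class = "fcs_config")
}

#' Initial fill of missing cells
#'
#' @param data incomplete data.frame.
#' @param mask logical missingness matrix over the amputable columns.
#' @param strategy `"mean_mode"` fills numeric columns with the
#'   observed mean; `"random_observed_draw"` draws each missing cell
#'   uniformly from the column's observed values (uses the current RNG
#'   stream).
#' @return the completed data.frame.
#' @export
initial_fill <- function(data, mask,
                         strategy = c("mean_mode",
                                      "random_observed_draw")) {
  strategy <- match.arg(strategy)
  for (cl in colnames(mask)) {
    mi <- mask[, cl]
    if (!any(mi)) next
    obs_vals <- data[[cl]][!mi]
    stop_if_not(length(obs_vals) > 0,
                paste0("column ", cl, " has no observed values"))
    data[[cl]][mi] <- if (strategy == "mean_mode") {
      mean(obs_vals)
    } else {
      obs_vals[sample.int(length(obs_vals), sum(mi), replace = TRUE)]
    }
  }
  data
}

# one univariate imputation step; called inside the chain's RNG stream
impute_one <- function(name, data, target, miss, cluster_id, dummy_cols,
                       opts) {
  if (exists(name, envir = .imputer_registry, inherits = FALSE)) {
    fn <- get(name, envir = .imputer_registry)
    x <- data[, setdiff(amputable_cols(), target), drop = FALSE]
    return(fn(data[[target]], x, cluster_id, miss))
  }
  switch(name,
    "2l_norm" = {
      x <- as.matrix(data[, setdiff(amputable_cols(), target)])
      impute_two_level_normal(data[[target]], x, cluster_id, miss,
                              n_sweeps = opts$n_sweeps %||% 100L)
    },
    "2lonly_pmm" = {
      x <- as.matrix(data[, setdiff(level2_vars(), target)])
      impute_level2_pmm(data[[target]], x, cluster_id, miss,
                        k_donors = opts$k_donors %||% 5L)
    },
    "ranger" = {
      x <- data[, setdiff(amputable_cols(), target), drop = FALSE]
      if (!is.null(dummy_cols)) x <- cbind(x, dummy_cols)
      impute_forest(data[[target]], x, miss,
                    config = opts$forest %||% forest_config(),
                    seed = sample.int(2147483646L, 1L))
    },
    "boost" = {
      x <- data[, setdiff(amputable_cols(), target), drop = FALSE]
      if (!is.null(dummy_cols)) x <- cbind(x, dummy_cols)
      impute_boost(data[[target]], x, miss,
                   config = opts$boost %||% boost_config(),
                   seed = sample.int(2146483646L, 1L))
    },
    stop("unknown imputer: ", name)
  )
}

#' Run the chained-equations imputation
#'
#' @param amputed an `amputed_dataset` (from the amputation functions).
#' @param config an [fcs_config()].
#' @return an object of class `imputed_set`: `completions` (list of `m`
#'   complete data.frames), `method`, `iterations` run per chain, and
#'   the seed.
#' @export
run_fcs <- function(amputed, config) {
  stop_if_not(inherits(amputed, "amputed_dataset"),
              "amputed must be an amputed_dataset")
  stop_if_not(inherits(config, "fcs_config"), "config must be fcs_config")
  data <- amputed$data
  mask <- amputed$mask
  n_miss <- colSums(mask)
  incomplete <- colnames(mask)[n_miss > 0]
  if (length(incomplete) == 0) {
    return(structure(list(completions = rep(list(data), config$m),
                          method = config$label,
                          iterations = rep(0L, config$m),
                          m = config$m, seed = config$seed),
                     class = "imputed_set"))
  }
  unmapped <- setdiff(incomplete, names(config$method_map))
  stop_if_not(length(unmapped) == 0,
              paste("no imputer mapped for:",
                    paste(unmapped, collapse = ", ")))
  visit <- if (config$visit_order == "ascending_missingness") {
    incomplete[order(n_miss[incomplete])]  # order() stable: ties keep column order
  } else {
    intersect(amputable_cols(), incomplete)
  }
  dummy_cols <- if (config$dummies) {
    aug <- add_cluster_dummies(data["cluster_id"])
    aug[, -1, drop = FALSE]
  } else NULL
  cluster_id <- data$cluster_id

  completions <- vector("list", config$m)
  iterations <- integer(config$m)
  for (i in seq_len(config$m)) {
    chain_seed <- derive_seed(config$seed, 401L, i)
    res <- with_seed(chain_seed, {
      cur <- initial_fill(data, mask, config$initial_fill)
      prev <- cur
      prev_oob <- Inf
      it_done <- 0L
      for (it in seq_len(config$max_iterations)) {
        oob <- c()
        for (target in visit) {
          mi <- mask[, target]
          imp <- impute_one(config$method_map[[target]], cur, target, mi,
                            cluster_id, dummy_cols, config$opts)
          e <- attr(imp, "oob_error")
          if (!is.null(e)) oob <- c(oob, e)
          cur[[target]][mi] <- as.numeric(imp)
        }
        if (config$early_stop && length(oob) > 0) {
          m_oob <- mean(oob)
          if (m_oob >= prev_oob) {  # no improvement: keep previous state
            cur <- prev
            break
          }
          prev <- cur
          prev_oob <- m_oob
        }
        it_done <- it
      }
      list(data = cur, iterations = it_done)
    })
    completions[[i]] <- res$data
    iterations[i] <- res$iterations
  }
  structure(list(completions = completions, method = config$label,
                 iterations = iterations, m = config$m,
                 seed = config$seed),
            class = "imputed_set")
}
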