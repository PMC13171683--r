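#' Amputation: turning complete simulated data into incomplete data
#'
#' Missingness is induced in the level-1 columns (`X1`--`X6`, `Y`)
#' either completely at random (cell-wise MCAR) or through a binned MAR
#' mechanism driven by a fully observed reference variable, and in the
#' level-2 columns (`L1`--`L6`) completely at random at the cluster
#' level (a cluster loses an `L` variable for all of its rows or none).
#'
#' @name amputation
NULL

new_amputed <- function(data, mask, meta) {
  stop_if_not(all(dim(mask) == c(nrow(data), length(colnames(mask)))),
              "mask shape must match data")
  structure(list(data = data, mask = mask, meta = meta),
            class = "amputed_dataset")
}

amputable_cols <- function() c(level1_vars(), level2_vars())

empty_mask <- function(data, columns = amputable_cols()) {
  m <- matrix(FALSE, nrow(data), length(columns),
              dimnames = list(NULL, columns))
  m
}

apply_mask <- function(data, mask) {
  for (cl in colnames(mask)) data[[cl]][mask[, cl]] <- NA_real_
  data
}

#' Cell-wise MCAR amputation
#'
#' Each cell in each listed column is set missing independently with
#' probability `rate`.
#'
#' @param data complete dataset.
#' @param columns columns to ampute (default: the level-1 variables).
#' @param rate missingness probability in `[0, 1)`.
#' @param seed integer seed.
#' @return an `amputed_dataset`: `data` with `NA`s, logical `mask`
#'   (`TRUE` = missing) over the amputable columns, and `meta` with the
#'   realized per-column rates.
#' @export
ampute_mcar <- function(data, columns = level1_vars(), rate, seed = 1L) {
  stop_if_not(rate >= 0 && rate < 1, "rate must be in [0, 1)")
  stop_if_not(all(columns %in% names(data)), "unknown columns")
  mask <- empty_mask(data)
  with_seed(derive_seed(seed, 301L), {
    for (cl in columns) {
      mask[, cl] <- stats::runif(nrow(data)) < rate
    }
  })
  new_amputed(apply_mask(data, mask), mask,
              list(mechanism = "MCAR", rate = rate,
                   realized = colMeans(mask[, columns, drop = FALSE])))
}

#' Binned MAR amputation of the level-1 variables
#'
#' The reference variable (default `X1`) is first amputed MCAR at the
#' reference rate, which equals `rate` except at 50% missingness, where
#' it is lowered to `reference_rate_at_50` (30%) so that no bin ends up
#' fully missing. The observed reference values are binned into
#' `n_bins` equal-width intervals over their range; every other level-1
#' column receives per-bin selection weights equal to the bin's
#' non-missing reference frequency times an independent Uniform(0,1)
#' draw (fresh per bin and per target column), rescaled so the expected
#' column-wise missing proportion equals `rate`. Each cell is then made
#' missing with its row's bin probability; rows whose reference value
#' is missing fall back to the base probability `rate`. Probabilities
#' forced above 1 by rescaling are clipped with the excess mass
#' redistributed over the remaining bins (with a warning).
#'
#' @param data complete dataset.
#' @param rate target missing proportion for the non-reference level-1
#'   columns.
#' @param reference_variable fully observed level-1 column that drives
#'   the mechanism.
#' @param n_bins number of equal-width intervals.
#' @param reference_rate_at_50 reference-column rate used when
#'   `rate == 0.5`.
#' @param seed integer seed.
#' @return an `amputed_dataset`; `meta` records the bin weights.
#' @export
ampute_mar_binned <- function(data, rate,
                              reference_variable = "X1",
                              n_bins = 25L,
                              reference_rate_at_50 = 0.30,
                              seed = 1L) {
  stop_if_not(rate >= 0 && rate < 1, "rate must be in [0, 1)")
  stop_if_not(n_bins >= 2, "n_bins must be at least 2")
  stop_if_not(reference_variable %in% level1_vars(),
              "reference_variable must be a level-1 variable")
  stop_if_not(!anyNA(data[[reference_variable]]),
              "reference variable must be fully observed")
  targets <- setdiff(level1_vars(), reference_variable)
  ref_rate <- if (isTRUE(all.equal(rate, 0.5))) reference_rate_at_50 else rate
  mask <- empty_mask(data)
  n <- nrow(data)
  bin_weights <- list()
  with_seed(derive_seed(seed, 302L), {
    mask[, reference_variable] <- stats::runif(n) < ref_rate
    ref <- data[[reference_variable]]
    obs <- !mask[, reference_variable]
    # equal-width bins over the observed range
    rng <- range(ref[obs])
    brk <- seq(rng[1], rng[2], length.out = n_bins + 1)
    bin <- findInterval(ref, brk, rightmost.closed = TRUE,
                        all.inside = TRUE)
    freq <- tabulate(bin[obs], nbins = n_bins)
    n_obs <- sum(obs)
    for (cl in targets) {
      if (rate == 0) break
      w <- freq * stats::runif(n_bins)
      # scale so expected missing count among observed-reference rows
      # is rate * n_obs; clip probabilities at 1 and redistribute
      p_bin <- rep(0, n_bins)
      need <- rate * n_obs
      active <- freq > 0
      repeat {
        tot <- sum((freq * w)[active])
        if (tot <= 0) break
        scl <- need / tot
        p <- pmin(w * scl, 1)
        over <- active & (w * scl > 1)
        if (!any(over)) {
          p_bin[active] <- p[active]
          break
        }
        warning("MAR bin probability clipped at 1; renormalizing",
                call. = FALSE)
        p_bin[over] <- 1
        need <- need - sum(freq[over])
        active <- active & !over
        if (need <= 0 || !any(active)) break
      }
      pr <- ifelse(obs, p_bin[bin], rate)
      mask[, cl] <- stats::runif(n) < pr
      bin_weights[[cl]] <- p_bin
    }
  })
  new_amputed(apply_mask(data, mask), mask,
              list(mechanism = "MAR", rate = rate,
                   reference_variable = reference_variable,
                   reference_rate = ref_rate, n_bins = n_bins,
                   bin_weights = bin_weights,
                   realized = colMeans(mask[, level1_vars(), drop = FALSE])))
}

#' Cluster-level MCAR amputation of the level-2 variables
#'
#' Independently for each (cluster, `L` column) pair, with probability
#' `rate` the variable is set missing for every row of the cluster, so
#' within-cluster missingness of a level-2 column is all-or-none.
#'
#' @inheritParams ampute_mcar
#' @param columns level-2 columns to ampute.
#' @export
ampute_level2_mcar <- function(data, columns = level2_vars(), rate,
                               seed = 1L) {
  stop_if_not(rate >= 0 && rate < 1, "rate must be in [0, 1)")
  clusters <- sort(unique(data$cluster_id))
  jidx <- match(data$cluster_id, clusters)
  mask <- empty_mask(data)
  with_seed(derive_seed(seed, 303L), {
    for (cl in columns) {
      hit <- stats::runif(length(clusters)) < rate
      mask[, cl] <- hit[jidx]
    }
  })
  new_amputed(apply_mask(data, mask), mask,
              list(mechanism = "level2_MCAR", rate = rate,
                   realized = colMeans(mask[, columns, drop = FALSE])))
}

combine_masks <- function(data, m1, m2) {
  mask <- m1 | m2
  new_amputed(apply_mask(data, mask), mask, NULL)
}

#' Ampute a dataset under a study condition
#'
#' Applies the condition's mechanism to the level-1 columns (cell-wise
#' MCAR or binned MAR) and cluster-level MCAR to the level-2 columns,
#' both at `rate`.
#'
#' @param data complete dataset.
#' @param mechanism `"MCAR"` or `"MAR"` (level-1 mechanism; level-2 is
#'   always cluster-level MCAR).
#' @param rate missing proportion (0.10, 0.30 or 0.50 in the study).
#' @param seed integer seed.
#' @return an `amputed_dataset` covering all 13 amputable columns.
#' @export
ampute_condition <- function(data, mechanism = c("MCAR", "MAR"), rate,
                             seed = 1L) {
  mechanism <- match.arg(mechanism)
  a1 <- if (mechanism == "MCAR") {
    ampute_mcar(data, level1_vars(), rate, seed = derive_seed(seed, 11L))
  } else {
    ampute_mar_binned(data, rate, seed = derive_seed(seed, 12L))
  }
  a2 <- ampute_level2_mcar(data, level2_vars(), rate,
                           seed = derive_seed(seed, 13L))
  out <- combine_masks(data, a1$mask, a2$mask)
  out$meta <- list(mechanism = mechanism, rate = rate,
                   level1 = a1$meta, level2 = a2$meta,
                   realized = colMeans(out$mask))
  out
}
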