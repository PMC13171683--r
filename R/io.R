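#' Dataset and result input/output
#'
#' Datasets travel as headered CSV (`cluster_id`, `X1`--`X6`,
#' `L1`--`L6`, `Y`) with the generating truth in a JSON sidecar;
#' amputed data as CSV with empty cells plus a parallel 0/1 mask CSV;
#' imputed sets as indexed CSVs with a JSON manifest; configurations as
#' YAML or JSON.
#'
#' @name io
NULL

#' @param data dataset to write.
#' @param path CSV path; the truth sidecar (if any) goes to
#'   `<path>.truth.json`.
#' @rdname io
#' @export
write_dataset <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE)
  truth <- attr(data, "truth")
  if (!is.null(truth)) {
    jsonlite::write_json(unclass(truth), paste0(path, ".truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

#' @rdname io
#' @export
read_dataset <- function(path) {
  data <- utils::read.csv(path)
  sidecar <- paste0(path, ".truth.json")
  if (file.exists(sidecar)) {
    tr <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    attr(data, "truth") <- structure(tr, class = "truth_params")
  }
  data
}

#' @param amputed an `amputed_dataset`.
#' @param stem path stem; writes `<stem>.csv` (empty cells for missing)
#'   and `<stem>.mask.csv` (0/1, 1 = missing).
#' @rdname io
#' @export
write_amputed <- function(amputed, stem) {
  utils::write.csv(amputed$data, paste0(stem, ".csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(as.data.frame(amputed$mask * 1L),
                   paste0(stem, ".mask.csv"), row.names = FALSE)
  invisible(stem)
}

#' @rdname io
#' @export
read_amputed <- function(stem) {
  data <- utils::read.csv(paste0(stem, ".csv"),
                          na.strings = c("NA", ""))
  mask <- as.matrix(utils::read.csv(paste0(stem, ".mask.csv"))) > 0
  new_amputed(data, mask, list(restored_from = stem))
}

#' @param imputed an `imputed_set`.
#' @param dir output directory; writes `imp_1.csv` ... `imp_m.csv` and
#'   `manifest.json` (method, seed, iterations).
#' @rdname io
#' @export
write_imputed_set <- function(imputed, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(imputed$completions)) {
    utils::write.csv(imputed$completions[[i]],
                     file.path(dir, paste0("imp_", i, ".csv")),
                     row.names = FALSE)
  }
  jsonlite::write_json(
    list(method = imputed$method, m = imputed$m, seed = imputed$seed,
         iterations = imputed$iterations),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @param config a list-like configuration (e.g. the fields of a
#'   [dgp_config()] or [fcs_config()]).
#' @param path `.yaml`/`.yml` or `.json` file.
#' @rdname io
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x$method_map <- as.list(x$method_map)
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(x, path)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  }
  invisible(path)
}

#' @rdname io
#' @export
read_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

#' @param manifest named list describing a run (seeds, condition,
#'   replication count, convergence failures).
#' @rdname io
#' @export
write_manifest <- function(manifest, path) {
  manifest$r_version <- as.character(getRversion())
  manifest$package_version <-
    as.character(utils::packageVersion("mlmisim"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
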