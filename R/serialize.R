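# JSON / CSV serialization boundaries: Gaussian summaries and posterior
# tables cache between increments; run histories and loss logs persist for
# later evaluation.

#' Serialize a Gaussian summary (or a per-class map of them) to JSON
#'
#' @param x A `gaussian_summary` or a named list of them.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
write_gaussian_json <- function(x, path = NULL) {
  payload <- if (inherits(x, "gaussian_summary")) {
    gaussian_payload(x)
  } else {
    lapply(x, gaussian_payload)
  }
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}

gaussian_payload <- function(s) {
  list(mean = s$mean, covariance = s$covariance, count = s$count,
       ridge = s$ridge, d = s$d)
}

#' Restore Gaussian summaries written by [write_gaussian_json()]
#'
#' @param json A JSON string or file path.
#' @return A `gaussian_summary` or a named list of them.
#' @export
read_gaussian_json <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyMatrix = TRUE)
  rebuild <- function(o) {
    structure(
      list(mean = as.numeric(o$mean),
           covariance = matrix(as.numeric(o$covariance), o$d, o$d),
           count = as.integer(o$count), ridge = as.numeric(o$ridge),
           d = as.integer(o$d)),
      class = "gaussian_summary"
    )
  }
  if (!is.null(obj$d)) rebuild(obj) else lapply(obj, rebuild)
}

#' Serialize a posterior table to JSON
#'
#' @param x A `posterior_table`.
#' @param path Optional file path.
#' @return The JSON string, invisibly when written to a file.
#' @export
write_posterior_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "posterior_table"))
  json <- jsonlite::toJSON(
    list(log_likelihood = x$log_likelihood, log_posterior = x$log_posterior,
         class_ids = as.character(x$class_ids)),
    auto_unbox = TRUE, digits = NA, na = "null"
  )
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}

#' Restore a posterior table written by [write_posterior_json()]
#'
#' @param json A JSON string or file path.
#' @return A `posterior_table`.
#' @export
read_posterior_json <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyMatrix = TRUE)
  ids <- as.character(obj$class_ids)
  ll <- matrix(as.numeric(obj$log_likelihood), ncol = length(ids),
               dimnames = list(NULL, ids))
  lp <- matrix(as.numeric(obj$log_posterior), ncol = length(ids),
               dimnames = list(NULL, ids))
  structure(list(log_likelihood = ll, log_posterior = lp, class_ids = ids),
            class = "posterior_table")
}

#' Persist a run history as JSON plus a CSV loss log
#'
#' Writes `history.json` (per-increment metrics, per-class accuracies,
#' registry, and a full config echo) and `loss_log.csv` (one row per
#' optimisation step) under `dir`.
#'
#' @param history An `mdcl_history`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory path.
#' @export
write_history <- function(history, dir) {
  stopifnot(inherits(history, "mdcl_history"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  payload <- list(
    config = unclass(history$config),
    registry = history$registry,
    increments = history$increments,
    per_class = history$per_class
  )
  jsonlite::write_json(payload, file.path(dir, "history.json"),
                       auto_unbox = TRUE, digits = NA)
  readr::write_csv(history$log, file.path(dir, "loss_log.csv"))
  invisible(dir)
}
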