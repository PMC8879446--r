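#' Tidy a run history into one row per increment
#'
#' @param x An `mdcl_history`.
#' @param ... Unused.
#' @return The per-increment tibble (metrics plus memory accounting).
#' @export
tidy.mdcl_history <- function(x, ...) {
  x$increments
}

#' One-row summary of a run history
#'
#' @param x An `mdcl_history`.
#' @param ... Unused.
#' @return A one-row tibble: variant, temperature, number of increments and
#'   classes, final cumulative accuracy and F1, and final memory reduction.
#' @export
glance.mdcl_history <- function(x, ...) {
  last <- x$increments[nrow(x$increments), ]
  tibble::tibble(
    variant = x$config$variant, temperature = x$config$temperature,
    n_increments = nrow(x$increments), n_classes = length(x$registry),
    final_accuracy = last$accuracy, final_f1 = last$f1,
    memory_reduction = last$memory_reduction
  )
}

#' Tidy a metric report into per-class rows
#'
#' @param x A `metric_report`.
#' @param ... Unused.
#' @return The per-class metrics tibble.
#' @export
tidy.metric_report <- function(x, ...) {
  x$per_class
}

#' One-row macro summary of a metric report
#'
#' @param x A `metric_report`.
#' @param ... Unused.
#' @return The one-row overall tibble.
#' @export
glance.metric_report <- function(x, ...) {
  x$overall
}
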