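#' One-vs-rest confusion counts per class
#'
#' @param predictions Predicted label per sample.
#' @param truths True label per sample.
#' @param registry Ordered label universe; predictions and truths must lie in
#'   it.
#' @return An object of class `confusion_counts`: a tibble with columns
#'   `class`, `tp`, `fp`, `tn`, `fn` and an `n` attribute.
#' @export
confusion_counts <- function(predictions, truths, registry) {
  predictions <- as.character(predictions)
  truths <- as.character(truths)
  if (inherits(registry, "label_space")) registry <- registry$class_ids
  if (length(predictions) != length(truths)) {
    stop_mdcl("predictions and truths must have equal length", "mdcl_validation_error")
  }
  if (!all(c(predictions, truths) %in% registry)) {
    stop_mdcl("labels outside the registry", "mdcl_validation_error")
  }
  n <- length(truths)
  counts <- purrr::map_dfr(registry, function(cls) {
    pred_pos <- predictions == cls
    true_pos <- truths == cls
    tibble::tibble(
      class = cls,
      tp = sum(pred_pos & true_pos), fp = sum(pred_pos & !true_pos),
      tn = sum(!pred_pos & !true_pos), fn = sum(!pred_pos & true_pos)
    )
  })
  structure(counts, n = n, class = c("confusion_counts", class(counts)))
}

#' Standard classification metrics from confusion counts
#'
#' Per class: sensitivity `tpr = TP/(TP+FN)`, specificity `tnr = TN/(TN+FP)`,
#' precision `ppv = TP/(TP+FP)` and `f1 = 2*ppv*tpr/(ppv+tpr)`. Overall
#' accuracy is top-1 multiclass accuracy (`sum(TP)/n`). Macro averages are
#' taken over classes present in the truth (support > 0); ratios with a zero
#' denominator resolve to 0 and are flagged rather than dropped, so reports
#' stay comparable across increments.
#'
#' @param counts A [confusion_counts()] table.
#' @return An object of class `metric_report`: a list with `overall` (one-row
#'   tibble: `acc`, `tpr`, `tnr`, `ppv`, `f1`, `averaging`, `n_undefined`)
#'   and `per_class` (tibble with per-class metrics, support, and an
#'   `undefined` flag).
#' @export
compute_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  n <- attr(counts, "n")
  if (n < 1) stop_mdcl("need >= 1 sample", "mdcl_validation_error")
  safe_div <- function(num, den) ifelse(den > 0, num / ifelse(den > 0, den, 1), 0)
  per <- dplyr::mutate(
    tibble::as_tibble(counts),
    support = .data$tp + .data$fn,
    tpr = safe_div(.data$tp, .data$tp + .data$fn),
    tnr = safe_div(.data$tn, .data$tn + .data$fp),
    ppv = safe_div(.data$tp, .data$tp + .data$fp),
    f1 = ifelse(.data$ppv + .data$tpr > 0,
                2 * .data$ppv * .data$tpr / (.data$ppv + .data$tpr), 0),
    undefined = (.data$tp + .data$fn == 0) | (.data$tn + .data$fp == 0) |
      (.data$tp + .data$fp == 0)
  )
  present <- per[per$support > 0, ]
  overall <- tibble::tibble(
    acc = sum(per$tp) / n,
    tpr = mean(present$tpr), tnr = mean(present$tnr),
    ppv = mean(present$ppv), f1 = mean(present$f1),
    averaging = "macro", n_undefined = sum(per$undefined)
  )
  structure(list(overall = overall, per_class = per, n = n),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(
    "<metric_report> n = %d | acc %.4f, tpr %.4f, tnr %.4f, ppv %.4f, f1 %.4f (macro)\n",
    x$n, x$overall$acc, x$overall$tpr, x$overall$tnr, x$overall$ppv, x$overall$f1
  ))
  invisible(x)
}

#' Per-increment forgetting curve from a run history
#'
#' Extracts the cumulative-test metric series (one row per increment) and the
#' per-class accuracy drops between consecutive increments for classes that
#' were already present, the standard view of catastrophic forgetting.
#'
#' @param history An [run_sequence()] history.
#' @return An object of class `forgetting_curve`: a list with `series` (per-
#'   increment overall metrics) and `drops` (tibble: `increment`, `label`,
#'   `accuracy`, `previous`, `drop`).
#' @export
forgetting_curve <- function(history) {
  stopifnot(inherits(history, "mdcl_history"))
  if (nrow(history$increments) == 0L) {
    stop_mdcl("history is empty", "mdcl_validation_error")
  }
  drops <- list()
  if (length(history$per_class) >= 2L) {
    for (k in 2:length(history$per_class)) {
      prev <- history$per_class[[k - 1]]
      cur <- history$per_class[[k]]
      joined <- dplyr::inner_join(
        dplyr::select(cur, "label", accuracy = "accuracy"),
        dplyr::select(prev, "label", previous = "accuracy"),
        by = "label"
      )
      drops[[k - 1]] <- dplyr::mutate(joined, increment = k,
                                      drop = .data$previous - .data$accuracy)
    }
  }
  structure(
    list(
      series = history$increments[, c("increment", "domain", "accuracy",
                                      "tpr", "tnr", "ppv", "f1")],
      drops = if (length(drops)) dplyr::bind_rows(drops) else
        tibble::tibble(label = character(0), accuracy = numeric(0),
                       previous = numeric(0), increment = integer(0),
                       drop = numeric(0))
    ),
    class = "forgetting_curve"
  )
}

#' Intra-domain transferability grid
#'
#' Tests every trained model against every domain's test set. Labels are
#' translated between domains by their unprefixed class names (e.g.
#' `"a/gun"` matches `"b/gun"`), mirroring testing a model trained on one
#' dataset against another dataset of the same application. Each cell holds
#' the top-1 accuracy and a `"n_correct/n_total"` count string.
#'
#' @param models Named list (by training domain) of `mdcl_model`s or
#'   `mdcl_history` objects.
#' @param test_sets Named list (by domain) of datasets with `images` and
#'   `labels`.
#' @param pool Feature pooling used by the models.
#' @return A tibble with columns `train_domain`, `test_domain`, `accuracy`,
#'   `classified` (the count string), `n_correct`, `n_total`.
#' @export
transferability_matrix <- function(models, test_sets, pool = 8) {
  strip <- function(x) sub("^[^/]+/", "", x)
  rows <- list()
  for (tr in names(models)) {
    model <- models[[tr]]
    if (inherits(model, "mdcl_history")) model <- model$model
    for (te in names(test_sets)) {
      ds <- test_sets[[te]]
      truth_base <- strip(ds$labels)
      if (!all(truth_base %in% strip(model$class_ids))) {
        stop_mdcl(
          sprintf("classes of domain %s cannot be translated to model %s", te, tr),
          "mdcl_mapping_error"
        )
      }
      feats <- ds$features %||% extract_features(ds$images, pool = pool)
      preds <- strip(model_predict(model, feats))
      n_correct <- sum(preds == truth_base)
      n_total <- length(truth_base)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        train_domain = tr, test_domain = te,
        accuracy = n_correct / n_total,
        classified = sprintf("%d/%d", n_correct, n_total),
        n_correct = n_correct, n_total = n_total
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Temperature sweep over full incremental runs
#'
#' Runs the complete sequence once per (temperature, seed) pair and reports
#' the mean and standard deviation of the final cumulative top-1 test error
#' per temperature.
#'
#' @param taus Positive temperatures to sweep.
#' @param tasks A `task_sequence`.
#' @param config Base [train_config()]; its temperature and seed are
#'   overridden per run.
#' @param seeds Integer training seeds.
#' @param csv Optional path; when given, the summary is also written as CSV.
#' @return A tibble of class `tau_sweep` with columns `tau`, `mean_error`,
#'   `sd_error`, `n_seeds`, plus a `runs` attribute with per-run results.
#' @export
tau_sweep <- function(taus, tasks, config = train_config(), seeds = 1L, csv = NULL) {
  if (any(taus <= 0)) stop_mdcl("all temperatures must be positive", "mdcl_validation_error")
  runs <- purrr::map_dfr(seq_along(taus), function(k) {
    purrr::map_dfr(seeds, function(sd_) {
      cfg <- config
      cfg$temperature <- taus[k]
      cfg$seed <- as.integer(sd_)
      hist <- run_sequence(tasks, cfg)
      final_acc <- hist$increments$accuracy[nrow(hist$increments)]
      tibble::tibble(tau_index = k, tau = taus[k], seed = sd_, error = 1 - final_acc)
    })
  })
  # summarised per list position so duplicated temperatures keep their rows
  out <- dplyr::summarise(
    runs,
    tau = .data$tau[1],
    mean_error = mean(.data$error),
    sd_error = if (dplyr::n() > 1) stats::sd(.data$error) else 0,
    n_seeds = dplyr::n(),
    .by = "tau_index"
  )
  out <- out[, c("tau", "mean_error", "sd_error", "n_seeds")]
  class(out) <- c("tau_sweep", class(out))
  attr(out, "runs") <- runs
  if (!is.null(csv)) readr::write_csv(out, csv)
  out
}

#' Compare objective variants on one benchmark
#'
#' Trains each variant on the identical benchmark and seed set and reports
#' the mean final cumulative-test top-1 accuracy per variant (the loss-
#' comparison table layout: one row per objective).
#'
#' @param variants Subset of `c("kl_distill", "cross_entropy", "lcl",
#'   "lcl_no_md")` (>= 1).
#' @param tasks A `task_sequence`.
#' @param config Base [train_config()].
#' @param seeds Integer training seeds shared by all variants.
#' @return A tibble of class `loss_comparison` with columns `variant`,
#'   `mean_accuracy`, `sd_accuracy`, `n_seeds`, plus a `runs` attribute.
#' @export
loss_comparison <- function(variants = c("kl_distill", "cross_entropy", "lcl", "lcl_no_md"),
                            tasks, config = train_config(), seeds = 1L) {
  variants <- match.arg(variants, several.ok = TRUE)
  runs <- purrr::map_dfr(variants, function(v) {
    purrr::map_dfr(seeds, function(sd_) {
      cfg <- config
      cfg$variant <- v
      if (v == "lcl_no_md") cfg$include_md <- FALSE
      if (v == "cross_entropy") cfg$temperature <- 1
      cfg$seed <- as.integer(sd_)
      hist <- run_sequence(tasks, cfg)
      tibble::tibble(
        variant = v, seed = sd_,
        accuracy = hist$increments$accuracy[nrow(hist$increments)]
      )
    })
  })
  out <- dplyr::summarise(
    runs,
    mean_accuracy = mean(.data$accuracy),
    sd_accuracy = if (dplyr::n() > 1) stats::sd(.data$accuracy) else 0,
    n_seeds = dplyr::n(),
    .by = "variant"
  )
  class(out) <- c("loss_comparison", class(out))
  attr(out, "runs") <- runs
  out
}
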