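# Class-incremental training protocol: label-space growth, teacher
# snapshotting, exemplar memory, and an epoch loop minimising the continual
# loss. Gaussian class-conditionals are refit once per epoch from the current
# teacher/student soft representations and treated as constants within the
# epoch's gradient steps (standard distillation practice: the density fits
# are not differentiated through).

#' Training configuration for the incremental protocol
#'
#' Defaults: 20 epochs per increment, ADADELTA,
#' temperature 2, a 20-exemplar-per-class replay memory, and the full
#' continual loss.
#'
#' @param epochs Epochs per increment (>= 0; 0 leaves the model untouched).
#' @param optimizer Optimizer name; only `"adadelta"` is built in.
#' @param batch_size Minibatch size `bs`.
#' @param temperature Softening temperature \eqn{\tau}.
#' @param exemplars_per_class Replay budget per old class (`Inf` keeps all).
#' @param ridge Diagonal ridge for the per-class Gaussian fits.
#' @param seed Root seed; every random draw in a run derives from it.
#' @param include_md Whether the mutual distillation term participates
#'   (the ablation switch).
#' @param md_scale `"tau_sq"` or `"none"`, see [mutual_distillation_loss()].
#' @param variant Objective variant: `"lcl"` (full continual loss),
#'   `"lcl_no_md"` (ablation), `"cross_entropy"` (plain fine-tuning, no
#'   teacher, no exemplars, temperature 1), or `"kl_distill"` (classic
#'   distillation: new-label loss plus KL against the teacher's soft
#'   targets, no exemplar memory).
#' @param hidden Hidden width of the reference network.
#' @param pool Feature pooling grid side (see [extract_features()]).
#' @return A list of class `train_config`.
#' @export
train_config <- function(epochs = 20, optimizer = "adadelta", batch_size = 8,
                         temperature = 2, exemplars_per_class = 20,
                         ridge = 0.05, seed = 1, include_md = TRUE,
                         md_scale = c("tau_sq", "none"),
                         variant = c("lcl", "lcl_no_md", "cross_entropy", "kl_distill"),
                         hidden = 32, pool = 8) {
  md_scale <- match.arg(md_scale)
  variant <- match.arg(variant)
  if (epochs < 0) stop_mdcl("epochs must be >= 0", "mdcl_validation_error")
  if (!identical(optimizer, "adadelta")) {
    stop_mdcl("only the adadelta optimizer is built in", "mdcl_validation_error")
  }
  if (temperature <= 0) stop_mdcl("temperature must be positive", "mdcl_validation_error")
  if (variant == "lcl_no_md") include_md <- FALSE
  if (variant == "cross_entropy") temperature <- 1
  structure(
    list(
      epochs = as.integer(epochs), optimizer = optimizer,
      batch_size = as.integer(batch_size), temperature = temperature,
      exemplars_per_class = exemplars_per_class, ridge = ridge,
      seed = as.integer(seed), include_md = include_md, md_scale = md_scale,
      variant = variant, hidden = as.integer(hidden), pool = as.integer(pool)
    ),
    class = "train_config"
  )
}

variant_uses <- function(config, teacher) {
  has_teacher <- !is.null(teacher)
  switch(config$variant,
    lcl = list(
      teacher = has_teacher, exemplars = TRUE,
      md = has_teacher && config$include_md, lo = has_teacher, kl = FALSE
    ),
    lcl_no_md = list(teacher = has_teacher, exemplars = TRUE,
                     md = FALSE, lo = has_teacher, kl = FALSE),
    cross_entropy = list(teacher = FALSE, exemplars = FALSE,
                         md = FALSE, lo = FALSE, kl = FALSE),
    kl_distill = list(teacher = has_teacher, exemplars = FALSE,
                      md = FALSE, lo = FALSE, kl = has_teacher)
  )
}

#' Ordered label space with per-increment provenance
#'
#' @param class_ids Initial ordered labels.
#' @param increment Increment index the initial labels belong to.
#' @return An object of class `label_space`.
#' @export
label_space <- function(class_ids = character(0), increment = 1L) {
  structure(
    list(class_ids = as.character(class_ids),
         provenance = setNames(rep(as.integer(increment), length(class_ids)),
                               as.character(class_ids))),
    class = "label_space"
  )
}

#' Append new classes to a label space
#'
#' Existing labels keep their indices; new labels are appended in order.
#'
#' @param space A [label_space()].
#' @param new_classes Labels to append (must be disjoint from existing ones;
#'   an empty vector returns the space unchanged).
#' @param increment Increment index recorded as the new classes' provenance.
#' @return The grown `label_space`.
#' @export
expand_label_space <- function(space, new_classes, increment = NULL) {
  stopifnot(inherits(space, "label_space"))
  new_classes <- as.character(new_classes)
  if (length(new_classes) == 0L) return(space)
  if (anyDuplicated(new_classes) || any(new_classes %in% space$class_ids)) {
    stop_mdcl("new classes must be distinct and disjoint from existing ones",
              "mdcl_validation_error")
  }
  increment <- increment %||% (max(c(space$provenance, 0L)) + 1L)
  space$class_ids <- c(space$class_ids, new_classes)
  space$provenance <- c(space$provenance,
                        setNames(rep(as.integer(increment), length(new_classes)), new_classes))
  space
}

#' Freeze the current model as a teacher snapshot
#'
#' Deep copy of a trained model with optimizer state dropped; its outputs on
#' any input are unaffected by subsequent student training and cover exactly
#' the classes known at snapshot time.
#'
#' @param model A trained `mdcl_model` (>= 1 increment).
#' @return An object of class `teacher_snapshot` (also an `mdcl_model`).
#' @export
snapshot_teacher <- function(model) {
  stopifnot(inherits(model, "mdcl_model"))
  if (model$increments_trained < 1L) {
    stop_mdcl("cannot snapshot an untrained model", "mdcl_snapshot_of_untrained_error")
  }
  model$opt <- NULL
  class(model) <- unique(c("teacher_snapshot", class(model)))
  model
}

# Teacher soft probabilities zero-padded to the student's (wider) registry.
# Padding positions carry no probability mass; old exemplars' one-hot labels
# never land on them.
teacher_soft_padded <- function(teacher, features, temperature, class_ids) {
  probs <- soften(model_logits(teacher, features), temperature, stream = "old")$probs
  out <- matrix(0, nrow(probs), length(class_ids), dimnames = list(NULL, class_ids))
  out[, match(teacher$class_ids, class_ids)] <- probs
  out
}

#' Select a replay exemplar set from a dataset
#'
#' Uniform sampling without replacement of at most `per_class_budget` items
#' per class; deterministic given the seed.
#'
#' @param dataset A dataset list (`images`/`features`, `labels`, `ids`, ...).
#' @param per_class_budget Non-negative budget (may be `Inf`).
#' @param seed Integer seed.
#' @return A dataset of the same shape containing only the selected items.
#' @export
select_exemplars <- function(dataset, per_class_budget, seed = 1) {
  if (per_class_budget < 0) stop_mdcl("per_class_budget must be >= 0", "mdcl_validation_error")
  keep <- integer(0)
  classes <- unique(dataset$labels)
  for (i in seq_along(classes)) {
    rows <- which(dataset$labels == classes[i])
    k <- min(per_class_budget, length(rows))
    if (k > 0) {
      withr::with_seed(derive_seed(seed, i), {
        keep <- c(keep, sort(sample(rows, k)))
      })
    }
  }
  dataset_subset(dataset, keep)
}

dataset_subset <- function(dataset, rows) {
  out <- dataset
  for (nm in names(dataset)) {
    out[[nm]] <- if (is.matrix(dataset[[nm]])) {
      dataset[[nm]][rows, , drop = FALSE]
    } else {
      dataset[[nm]][rows]
    }
  }
  out
}

#' Continual loss and its gradient with respect to student logits
#'
#' Computes the loss breakdown for one batch and the analytic gradient of
#' \eqn{L_{CL}} with respect to the student's raw logits, holding the
#' Gaussian conditionals, class prior and teacher outputs fixed (they are
#' refit between epochs, not differentiated through). The mutual distillation
#' gradient flows through the new-stream half of each joint representation
#' point and the temperature-scaled softmax Jacobian.
#'
#' @param logits Student logits `n x w` for the batch.
#' @param labels True class label per row.
#' @param is_old Logical vector: `TRUE` for replayed exemplar rows.
#' @param teacher_probs Teacher soft probabilities padded to width `w`
#'   (or `NULL` when no teacher exists).
#' @param conditionals,prior Frozen [fit_class_conditionals()] /
#'   [class_prior()] state for the mutual distillation posteriors (`NULL`
#'   disables the term).
#' @param config A [train_config()].
#' @return A list with `breakdown` (a [continual_loss()] row) and `grad`
#'   (matrix `n x w`, \eqn{\partial L_{CL} / \partial z}).
#' @export
continual_loss_grad <- function(logits, labels, is_old, teacher_probs,
                                conditionals, prior, config) {
  n <- nrow(logits); w <- ncol(logits)
  tau <- config$temperature
  bs <- n
  class_ids <- colnames(logits)
  uses <- variant_uses(config, teacher = if (is.null(teacher_probs)) NULL else TRUE)
  onehot <- one_hot(labels, class_ids)
  q <- soften(logits, tau, stream = "new", class_ids = class_ids)$probs
  grad_q <- matrix(0, n, w) # dL/dq, chained through the softmax at the end
  grad_z <- matrix(0, n, w) # direct dL/dz contributions

  new_rows <- which(!is_old)
  old_rows <- which(is_old)

  # acquisition: KL(one-hot new labels || student soft probs) over new rows
  l_n <- 0
  if (length(new_rows) > 0L) {
    l_n <- new_knowledge_loss(onehot[new_rows, , drop = FALSE],
                              q[new_rows, , drop = FALSE], batch_size = bs)
    grad_z[new_rows, ] <- grad_z[new_rows, , drop = FALSE] +
      (q[new_rows, , drop = FALSE] - onehot[new_rows, , drop = FALSE]) / (bs * tau)
  }

  # retention: cross-entropy of the teacher's (padded) soft targets against
  # the student's soft outputs, over the whole batch; gradients flow through
  # the student so old knowledge is actively retained
  l_o <- 0
  if (uses$lo) {
    l_o <- old_knowledge_loss(teacher_probs, q, batch_size = bs)
    grad_q <- grad_q - (teacher_probs / pmax(q, PROB_FLOOR)) / bs
  }

  # classic-distillation baseline: KL(teacher soft targets || student), all rows
  if (uses$kl) {
    p <- teacher_probs
    ratio <- log(pmax(p, PROB_FLOOR)) - log(pmax(q, PROB_FLOOR))
    contrib <- p * ratio
    contrib[p == 0] <- 0
    l_o <- l_o + sum(contrib) / bs
    grad_q <- grad_q - (p / pmax(q, PROB_FLOOR)) / bs
  }

  # mutual distillation over the joint [teacher; student] representations
  l_md <- 0
  if (uses$md && !is.null(conditionals)) {
    points <- cbind(teacher_probs, q)
    post <- class_posterior(conditionals, prior, points)
    scale <- if (config$md_scale == "tau_sq") 1 / tau^2 else 1
    l_md <- mutual_distillation_loss(
      old_targets = if (length(old_rows)) onehot[old_rows, , drop = FALSE],
      new_targets = if (length(new_rows)) onehot[new_rows, , drop = FALSE],
      posterior_old = if (length(old_rows)) posterior_subset(post, old_rows),
      posterior_new = if (length(new_rows)) posterior_subset(post, new_rows),
      temperature = tau, scale = config$md_scale
    )
    v_full <- md_point_grad(post, conditionals, prior, points, labels)
    grad_q <- grad_q + scale * v_full[, w + seq_len(w), drop = FALSE]
  }

  # chain dL/dq through the temperature-scaled softmax Jacobian
  if (any(grad_q != 0)) {
    inner <- rowSums(q * grad_q)
    grad_z <- grad_z + (q * grad_q - q * inner) / tau
  }

  breakdown <- continual_loss(
    l_n = l_n, l_md = l_md, l_o = l_o,
    temperature = tau, include_md = uses$md
  )
  list(breakdown = breakdown, grad = grad_z)
}

posterior_subset <- function(post, rows) {
  structure(
    list(log_likelihood = post$log_likelihood[rows, , drop = FALSE],
         log_posterior = post$log_posterior[rows, , drop = FALSE],
         class_ids = post$class_ids),
    class = "posterior_table"
  )
}

# d(-log posterior_true) / d point for each row; n x d matrix.
md_point_grad <- function(post, conditionals, prior, points, labels) {
  n <- nrow(points); d <- ncol(points)
  ids <- prior$class_ids
  s <- exp(post$log_posterior) # responsibilities
  acc <- matrix(0, n, d)
  u_true <- matrix(0, n, d)
  true_j <- match(as.character(labels), ids)
  for (j in seq_along(ids)) {
    if (prior$probs[j] <= 0 || is.null(conditionals[[ids[j]]])) next
    summ <- conditionals[[ids[j]]]
    ch <- effective_chol(summ)
    sinv <- chol2inv(ch)
    u <- -sweep(points, 2L, summ$mean) %*% sinv # rows: dg_j/dy
    acc <- acc + s[, j] * u
    rows_j <- which(true_j == j)
    if (length(rows_j)) u_true[rows_j, ] <- u[rows_j, , drop = FALSE]
  }
  acc - u_true
}

#' Train the model for one increment
#'
#' Runs `epochs` passes over the union of the current increment's training
#' data and the replayed exemplars (when the variant uses them). At the start
#' of each epoch the class prior and per-class Gaussian conditionals of the
#' joint teacher/student representations are refit; within the epoch they are
#' constants. Every ADADELTA step appends one row to the loss log. A first
#' increment (`teacher = NULL`) trains with the acquisition term only.
#'
#' @param model An `mdcl_model` whose registry already covers the new labels.
#' @param teacher A [snapshot_teacher()] result, or `NULL`.
#' @param new_data Dataset for the current increment (non-empty), with a
#'   `features` matrix (see [extract_features()]).
#' @param exemplars Replay dataset (possibly empty) with `features`.
#' @param config A [train_config()].
#' @param increment Increment index, used only to decorrelate epoch shuffles.
#' @return A list with the updated `model` and `log` (a tibble with one row
#'   per optimisation step: `increment`, `epoch`, `step`, `l_md`, `l_o`,
#'   `l_n`, `l_cl`, `temperature`).
#' @export
train_increment <- function(model, teacher, new_data, exemplars, config,
                            increment = 1L) {
  stopifnot(inherits(model, "mdcl_model"), inherits(config, "train_config"))
  if (is.null(new_data) || length(new_data$labels) == 0L) {
    stop_mdcl("new_data must be non-empty", "mdcl_validation_error")
  }
  empty_log <- tibble::tibble(
    increment = integer(0), epoch = integer(0), step = integer(0),
    l_md = numeric(0), l_o = numeric(0), l_n = numeric(0), l_cl = numeric(0),
    temperature = numeric(0)
  )
  if (config$epochs == 0L) return(list(model = model, log = empty_log))

  uses <- variant_uses(config, teacher)
  use_ex <- uses$teacher && uses$exemplars && length(exemplars$labels %||% character(0)) > 0L
  feats <- rbind(new_data$features,
                 if (use_ex) exemplars$features)
  labels <- c(new_data$labels, if (use_ex) exemplars$labels)
  is_old <- c(rep(FALSE, length(new_data$labels)),
              rep(TRUE, if (use_ex) length(exemplars$labels) else 0L))
  n <- length(labels)
  logs <- list()

  for (epoch in seq_len(config$epochs)) {
    teacher_probs <- if (uses$teacher) {
      teacher_soft_padded(teacher, feats, config$temperature, model$class_ids)
    }
    conditionals <- NULL; prior <- NULL
    if (uses$md) {
      q_all <- soften(model_logits(model, feats), config$temperature)$probs
      prior <- class_prior(labels, registry = model$class_ids)
      conditionals <- fit_class_conditionals(teacher_probs, q_all, labels,
                                             ridge = config$ridge)
    }
    withr::with_seed(derive_seed(config$seed, 1000L * increment + epoch), {
      order_ <- sample.int(n)
    })
    batch_starts <- seq(1L, n, by = config$batch_size)
    for (b in seq_along(batch_starts)) {
      rows <- order_[batch_starts[b]:min(batch_starts[b] + config$batch_size - 1L, n)]
      fwd <- model_forward(model, feats[rows, , drop = FALSE])
      res <- continual_loss_grad(
        fwd$logits, labels[rows], is_old[rows],
        if (uses$teacher) teacher_probs[rows, , drop = FALSE],
        conditionals, prior, config
      )
      if (!is.finite(res$breakdown$l_cl)) {
        stop_mdcl(
          sprintf(
            "non-finite loss at increment %d, epoch %d, step %d (l_n=%g, l_md=%g, l_o=%g); batch labels: %s",
            increment, epoch, b, res$breakdown$l_n, res$breakdown$l_md,
            res$breakdown$l_o, paste(unique(labels[rows]), collapse = ", ")
          ),
          "mdcl_nonfinite_loss_error"
        )
      }
      grads <- model_backward(model, feats[rows, , drop = FALSE], fwd, res$grad)
      model <- adadelta_step(model, grads)
      logs[[length(logs) + 1L]] <- dplyr::mutate(
        res$breakdown[, c("l_md", "l_o", "l_n", "l_cl", "temperature")],
        increment = as.integer(increment), epoch = epoch, step = b,
        .before = 1L
      )
    }
  }
  model$increments_trained <- model$increments_trained + 1L
  list(model = model, log = if (length(logs)) dplyr::bind_rows(logs) else empty_log)
}

#' Run a full class-incremental training sequence
#'
#' For each increment: grow the label space (widening the classifier head),
#' train with [train_increment()], snapshot the teacher, refresh the exemplar
#' memory, and evaluate on the cumulative test set of all classes seen so
#' far. Memory accounting records the items held in memory for the increment
#' (new training items plus replayed exemplars) against the cumulative
#' training-set size a joint retraining would need.
#'
#' @param tasks A `task_sequence` (e.g. [bundled_benchmark()]).
#' @param config A [train_config()].
#' @return An object of class `mdcl_history`: a list with `increments` (a
#'   tibble, one row per increment, with metric and per-class list-columns),
#'   `log` (the concatenated step-level loss log), `model` (final state),
#'   `registry` and `config`.
#' @export
run_sequence <- function(tasks, config = train_config()) {
  stopifnot(inherits(tasks, "task_sequence"), inherits(config, "train_config"))
  if (length(tasks$increments) < 1L) stop_mdcl("need >= 1 increment", "mdcl_validation_error")
  space <- label_space()
  model <- NULL
  teacher <- NULL
  memory <- NULL
  logs <- list()
  rows <- list()
  reports <- list()
  per_class_acc <- list()
  cum_test_feats <- NULL
  cum_test_labels <- character(0)
  cum_train_items <- 0L
  uses_any <- variant_uses(config, teacher = TRUE)

  for (k in seq_along(tasks$increments)) {
    inc <- tasks$increments[[k]]
    new_classes <- setdiff(inc$classes, space$class_ids)
    space <- expand_label_space(space, new_classes, increment = k)
    train_ds <- inc$train
    train_ds$features <- extract_features(train_ds$images, pool = config$pool)
    if (is.null(model)) {
      model <- init_model(ncol(train_ds$features), space$class_ids,
                          hidden = config$hidden, seed = derive_seed(config$seed, 11L))
    } else if (length(new_classes) > 0L) {
      model <- widen_head(model, new_classes, seed = derive_seed(config$seed, 11L + k))
    }
    fit <- train_increment(model, teacher, train_ds, memory, config, increment = k)
    model <- fit$model
    logs[[k]] <- fit$log

    n_new <- length(train_ds$labels)
    n_memory <- if (uses_any$exemplars && !is.null(memory)) length(memory$labels) else 0L
    cum_train_items <- cum_train_items + n_new
    items_in_memory <- n_new + n_memory
    memory_reduction <- 1 - items_in_memory / cum_train_items

    # cumulative evaluation over everything seen so far
    test_feats <- extract_features(inc$test$images, pool = config$pool)
    cum_test_feats <- rbind(cum_test_feats, test_feats)
    cum_test_labels <- c(cum_test_labels, inc$test$labels)
    preds <- model_predict(model, cum_test_feats)
    counts <- confusion_counts(preds, cum_test_labels, space$class_ids)
    report <- compute_metrics(counts)
    reports[[k]] <- report
    per_class_acc[[k]] <- dplyr::summarise(
      tibble::tibble(label = cum_test_labels, correct = preds == cum_test_labels),
      accuracy = mean(.data$correct), n = dplyr::n(), .by = "label"
    )

    rows[[k]] <- tibble::tibble(
      increment = k, name = inc$name, domain = inc$domain,
      n_new_classes = length(new_classes), n_train_new = n_new,
      items_in_memory = items_in_memory, cumulative_items = cum_train_items,
      memory_reduction = memory_reduction,
      accuracy = report$overall$acc, tpr = report$overall$tpr,
      tnr = report$overall$tnr, ppv = report$overall$ppv, f1 = report$overall$f1
    )

    # prepare replay state for the next increment (an untrained model --
    # zero-epoch runs -- yields no teacher)
    teacher <- if (model$increments_trained >= 1L) snapshot_teacher(model) else NULL
    selected <- select_exemplars(train_ds, config$exemplars_per_class,
                                 seed = derive_seed(config$seed, 500L + k))
    memory <- dataset_bind(memory, selected)
  }

  structure(
    list(
      increments = dplyr::bind_rows(rows),
      reports = reports, per_class = per_class_acc,
      log = dplyr::bind_rows(logs), model = model,
      registry = space$class_ids, label_space = space, config = config
    ),
    class = "mdcl_history"
  )
}

#' @export
print.mdcl_history <- function(x, ...) {
  cat(sprintf("<mdcl_history> %d increments, variant = %s, tau = %g\n",
              nrow(x$increments), x$config$variant, x$config$temperature))
  print(x$increments[, c("increment", "domain", "accuracy", "f1",
                         "items_in_memory", "memory_reduction")])
  invisible(x)
}
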