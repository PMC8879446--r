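PROB_FLOOR <- 1e-12

#' Temperature-scaled softmax over logits
#'
#' Converts raw logits into soft probabilities
#' \eqn{p_{ij} = \exp(z_{ij}/\tau) / \sum_k \exp(z_{ik}/\tau)}, computed with
#' per-row max subtraction for numerical stability. Larger temperatures
#' flatten the distribution towards uniform; `temperature = 1` is the plain
#' softmax.
#'
#' @param logits Numeric matrix `n x w` (a vector is treated as one row).
#' @param temperature Positive scalar \eqn{\tau}.
#' @param stream Which knowledge stream the representation belongs to
#'   (`"new"` for the student, `"old"` for the teacher).
#' @param class_ids Optional label vector naming the columns.
#' @return An object of class `soft_representation` with fields `probs`,
#'   `temperature`, `stream` and `class_ids`.
#' @examples
#' soften(matrix(c(2, 0), nrow = 1), temperature = 2)
#' @export
soften <- function(logits, temperature, stream = c("new", "old"), class_ids = NULL) {
  stream <- match.arg(stream)
  if (!is.numeric(temperature) || length(temperature) != 1L || temperature <= 0) {
    stop_mdcl("temperature must be a single positive number", "mdcl_validation_error")
  }
  logits <- if (is.matrix(logits)) logits else matrix(logits, nrow = 1L)
  check_finite_matrix(logits, "logits")
  z <- logits / temperature
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  probs <- e / rowSums(e)
  if (!is.null(class_ids)) colnames(probs) <- class_ids
  structure(
    list(
      probs = probs, temperature = temperature, stream = stream,
      class_ids = class_ids %||% colnames(probs)
    ),
    class = "soft_representation"
  )
}

#' @export
print.soft_representation <- function(x, ...) {
  cat(sprintf(
    "<soft_representation> %d x %d, stream = %s, tau = %g\n",
    nrow(x$probs), ncol(x$probs), x$stream, x$temperature
  ))
  invisible(x)
}

soft_probs <- function(x) if (inherits(x, "soft_representation")) x$probs else x

#' One-hot label indicator matrix
#'
#' @param labels Class label per sample.
#' @param class_ids Ordered label registry giving the column order.
#' @return A 0/1 matrix `n x w` with exactly one 1 per row.
#' @export
one_hot <- function(labels, class_ids) {
  labels <- as.character(labels)
  if (!all(labels %in% class_ids)) {
    stop_mdcl("labels contain classes absent from the registry", "mdcl_validation_error")
  }
  m <- matrix(0, length(labels), length(class_ids), dimnames = list(NULL, class_ids))
  m[cbind(seq_along(labels), match(labels, class_ids))] <- 1
  m
}

#' Mutual distillation loss over old and new posterior tables
#'
#' The coupling term of the continual objective: the sum of two cross-entropies
#' of true-label indicators against the Bayes log-posteriors of the joint
#' old/new representations, one sum over the `n1` replayed old samples and one
#' over the `n2` new samples, scaled by \eqn{1/\tau^2}. The printed form of the
#' objective divides both the indicator and the log-posterior by \eqn{\tau};
#' taken literally that is a constant \eqn{1/\tau^2} rescale of the
#' cross-entropy sums, which is what `scale = "tau_sq"` computes. Set
#' `scale = "none"` for the unscaled reading.
#'
#' Either stream may be absent (`NULL` targets and posteriors), in which case
#' its sum is empty; the first increment has no old stream.
#'
#' @param old_targets One-hot matrix over the `n1` old samples, or `NULL`.
#' @param new_targets One-hot matrix over the `n2` new samples, or `NULL`.
#' @param posterior_old [class_posterior()] table for the old samples' joints.
#' @param posterior_new [class_posterior()] table for the new samples' joints.
#' @param temperature Positive scalar \eqn{\tau}.
#' @param scale `"tau_sq"` (default) or `"none"`.
#' @return A single numeric loss value; `+Inf` (with a warning) when a one-hot
#'   entry lands on a zero-posterior class.
#' @export
mutual_distillation_loss <- function(old_targets, new_targets,
                                     posterior_old = NULL, posterior_new = NULL,
                                     temperature = 2,
                                     scale = c("tau_sq", "none")) {
  scale <- match.arg(scale)
  if (!is.numeric(temperature) || temperature <= 0) {
    stop_mdcl("temperature must be positive", "mdcl_validation_error")
  }
  term <- function(targets, posterior) {
    if (is.null(targets)) return(0)
    stopifnot(inherits(posterior, "posterior_table"))
    if (nrow(targets) == 0L) return(0)
    if (ncol(targets) != length(posterior$class_ids) ||
        nrow(targets) != nrow(posterior$log_posterior)) {
      stop_mdcl("targets and posterior table are misaligned", "mdcl_validation_error")
    }
    if (!is.null(colnames(targets)) &&
        !identical(colnames(targets), posterior$class_ids)) {
      stop_mdcl("target registry does not match the posterior registry", "mdcl_validation_error")
    }
    hit <- targets * posterior$log_posterior
    hit[targets == 0] <- 0 # 0 * -Inf convention
    -sum(hit)
  }
  total <- term(old_targets, posterior_old) + term(new_targets, posterior_new)
  if (!is.finite(total)) {
    warn("a true label received zero posterior mass; mutual distillation loss is +Inf")
  }
  if (scale == "tau_sq") total / temperature^2 else total
}

#' Retention (old-knowledge) cross-entropy loss
#'
#' Categorical cross-entropy of target indicators against soft probabilities,
#' averaged over the batch size:
#' \eqn{-\frac{1}{bs}\sum_i\sum_j y_{ij}\log p_{ij}}. Probabilities are
#' floored at `1e-12` before the log. The incremental trainer uses this
#' kernel with the frozen teacher's soft outputs as targets and the student's
#' softened probabilities as predictions, so minimising it preserves the
#' teacher's response pattern (one-hot targets are also accepted, giving the
#' plain supervised cross-entropy).
#'
#' @param new_targets Target matrix `n x w` (one-hot indicators or soft
#'   targets).
#' @param old_stream_probs Soft probabilities `n x w` (matrix or
#'   [soften()] output) the targets are scored against.
#' @param batch_size Positive integer `bs` used as the averaging denominator.
#' @return A single numeric loss value.
#' @export
old_knowledge_loss <- function(new_targets, old_stream_probs, batch_size) {
  p <- soft_probs(old_stream_probs)
  if (!identical(dim(new_targets), dim(p))) {
    stop_mdcl("targets and old-stream probabilities must have the same shape", "mdcl_validation_error")
  }
  if (batch_size < 1) stop_mdcl("batch_size must be >= 1", "mdcl_validation_error")
  -sum(new_targets * log(pmax(p, PROB_FLOOR))) / batch_size
}

#' Acquisition (new-knowledge) KL divergence loss
#'
#' KL divergence from target distributions to new-stream soft probabilities,
#' averaged over the batch size:
#' \eqn{\frac{1}{bs}\sum_i\sum_j t_{ij}\log(t_{ij}/q_{ij})}, with the
#' conventions \eqn{0\log(0/q)=0} and a `1e-12` floor inside the log ratio.
#' With one-hot targets this equals the cross-entropy (the target entropy is
#' zero); general row-stochastic targets are also accepted.
#'
#' @param new_targets Row-stochastic target matrix `n x w` (one-hot or soft).
#' @param new_stream_probs Soft probabilities `n x w` from the new stream.
#' @param batch_size Positive integer `bs`.
#' @return A single numeric loss value, always `>= 0` for stochastic inputs.
#' @export
new_knowledge_loss <- function(new_targets, new_stream_probs, batch_size) {
  q <- soft_probs(new_stream_probs)
  t_ <- soft_probs(new_targets)
  if (!identical(dim(t_), dim(q))) {
    stop_mdcl("targets and new-stream probabilities must have the same shape", "mdcl_validation_error")
  }
  check_simplex_rows(t_, "new_targets")
  check_simplex_rows(q, "new_stream_probs")
  if (batch_size < 1) stop_mdcl("batch_size must be >= 1", "mdcl_validation_error")
  ratio <- log(pmax(t_, PROB_FLOOR)) - log(pmax(q, PROB_FLOOR))
  contrib <- t_ * ratio
  contrib[t_ == 0] <- 0
  sum(contrib) / batch_size
}

#' Assemble the combined continual-learning loss
#'
#' \eqn{L_{CL} = L_N + L_{MD} + L_O}. With `include_md = FALSE` (the ablation)
#' the mutual distillation term is zeroed and \eqn{L_{CL} = L_N + L_O}.
#'
#' @param l_n Acquisition loss value.
#' @param l_md Mutual distillation loss value.
#' @param l_o Retention loss value.
#' @param temperature Temperature the components were computed at.
#' @param include_md Whether the mutual distillation term participates.
#' @return A one-row tibble of class `loss_breakdown` with columns `l_md`,
#'   `l_o`, `l_n`, `l_cl`, `temperature` and `include_md`.
#' @examples
#' continual_loss(l_n = 0.5, l_md = 0.25, l_o = 0.125)
#' @export
continual_loss <- function(l_n, l_md = 0, l_o = 0, temperature = 2, include_md = TRUE) {
  l_md_eff <- if (include_md) l_md else 0
  out <- tibble::tibble(
    l_md = l_md_eff, l_o = l_o, l_n = l_n,
    l_cl = l_n + l_md_eff + l_o,
    temperature = temperature, include_md = include_md
  )
  class(out) <- c("loss_breakdown", class(out))
  out
}
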