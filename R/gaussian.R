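#' Fit a multivariate Gaussian summary to sample rows
#'
#' Estimates the mean vector and the unbiased (\eqn{n-1} denominator) sample
#' covariance of a set of representation vectors. The covariance is stored as
#' estimated; a diagonal ridge is recorded separately and only added when the
#' density is evaluated, so the raw estimate remains inspectable. Soft
#' representations live on the probability simplex and therefore have
#' rank-deficient covariance by construction; a positive ridge (default
#' `0.05` throughout the package) guarantees a positive-definite effective
#' covariance and bounds the per-dimension precision -- and with it the scale
#' of posterior gradients -- at `1/ridge`.
#'
#' @param samples Numeric matrix with one sample per row (a plain vector is
#'   treated as a single-column matrix of univariate samples).
#' @param ridge Non-negative scalar added to the covariance diagonal at
#'   density-evaluation time.
#' @return An object of class `gaussian_summary` with fields `mean`,
#'   `covariance`, `count`, `ridge` and `d`.
#' @examples
#' fit_gaussian(matrix(c(0, 2), ncol = 1))
#' @export
fit_gaussian <- function(samples, ridge = 0) {
  samples <- as_row_matrix(samples)
  n <- nrow(samples)
  d <- ncol(samples)
  if (n == 0L) stop_mdcl("cannot fit a Gaussian to zero samples", "mdcl_empty_sample_error")
  if (d == 0L) stop_mdcl("samples must have at least one column", "mdcl_validation_error")
  check_finite_matrix(samples, "samples")
  if (!is.numeric(ridge) || length(ridge) != 1L || ridge < 0) {
    stop_mdcl("ridge must be a single non-negative number", "mdcl_validation_error")
  }
  if (n == 1L && ridge == 0) {
    stop_mdcl(
      "a single sample with ridge = 0 yields a degenerate covariance (density undefined)",
      "mdcl_degenerate_covariance_error"
    )
  }
  mu <- colMeans(samples)
  if (n >= 2L) {
    centered <- sweep(samples, 2L, mu)
    sigma <- crossprod(centered) / (n - 1)
  } else {
    sigma <- matrix(0, d, d)
  }
  structure(
    list(mean = mu, covariance = sigma, count = n, ridge = ridge, d = d),
    class = "gaussian_summary"
  )
}

#' @export
print.gaussian_summary <- function(x, ...) {
  cat(sprintf(
    "<gaussian_summary> d = %d, n = %d, ridge = %g\n", x$d, x$count, x$ridge
  ))
  invisible(x)
}

# Cholesky factor of the effective covariance (Sigma + ridge * I).
effective_chol <- function(summary) {
  sigma <- summary$covariance + diag(summary$ridge, summary$d)
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(ch)) {
    stop_mdcl(
      "effective covariance is not positive definite; increase the ridge",
      "mdcl_degenerate_covariance_error"
    )
  }
  ch
}

#' Log-density of a multivariate Gaussian summary
#'
#' Evaluates \eqn{\log N(x \mid \mu, \Sigma + \lambda I)} with the standard
#' multivariate normal normaliser \eqn{(2\pi)^{-d/2} |\Sigma|^{-1/2}}, via a
#' Cholesky factorisation (no explicit matrix inverse is ever formed).
#'
#' @param point Numeric vector of length `d`, or a matrix with one point per
#'   row for vectorised evaluation.
#' @param summary A [fit_gaussian()] result.
#' @return A numeric vector of log-densities, one per point.
#' @examples
#' s <- fit_gaussian(matrix(rnorm(100), ncol = 1), ridge = 0)
#' gaussian_log_density(0, s)
#' @export
gaussian_log_density <- function(point, summary) {
  stopifnot(inherits(summary, "gaussian_summary"))
  pts <- if (is.matrix(point)) point else matrix(point, nrow = 1L)
  if (ncol(pts) != summary$d) {
    stop_mdcl("point dimension does not match the summary", "mdcl_validation_error")
  }
  check_finite_matrix(pts, "point")
  ch <- effective_chol(summary)
  logdet <- 2 * sum(log(diag(ch)))
  centered <- sweep(pts, 2L, summary$mean)
  # quadratic form via triangular solve: || L^{-1} (x - mu) ||^2
  z <- backsolve(ch, t(centered), transpose = TRUE)
  quad <- colSums(z^2)
  -0.5 * (summary$d * log(2 * pi) + logdet + quad)
}

#' Empirical class prior from a label vector
#'
#' Counts each class and normalises, \eqn{p(t = t_i) = n_{t_i} / s_n}. Classes
#' are ordered by first appearance unless an explicit registry is supplied, in
#' which case registry order is kept and registry classes absent from `labels`
#' receive count 0 (and zero prior mass).
#'
#' @param labels Character (or factor) vector of class labels, one per sample.
#' @param registry Optional character vector fixing class order and the full
#'   class universe.
#' @return An object of class `class_prior` with fields `class_ids`, `counts`,
#'   `total` and `probs`.
#' @examples
#' class_prior(c("a", "a", "b", "b"))
#' @export
class_prior <- function(labels, registry = NULL) {
  labels <- as.character(labels)
  if (length(labels) == 0L) {
    stop_mdcl("labels must be non-empty", "mdcl_validation_error")
  }
  ids <- if (is.null(registry)) unique(labels) else as.character(registry)
  if (!all(labels %in% ids)) {
    stop_mdcl("labels contain classes absent from the registry", "mdcl_validation_error")
  }
  counts <- vapply(ids, function(id) sum(labels == id), integer(1))
  structure(
    list(
      class_ids = ids,
      counts = unname(counts),
      total = length(labels),
      probs = unname(counts) / length(labels)
    ),
    class = "class_prior"
  )
}

#' @export
print.class_prior <- function(x, ...) {
  cat("<class_prior>\n")
  print(setNames(x$probs, x$class_ids))
  invisible(x)
}

#' Fit one joint Gaussian per class on concatenated representations
#'
#' Concatenates the old-stream and new-stream soft representations row-wise
#' into joint vectors of length `d = w_old + w_new` and fits one
#' [fit_gaussian()] summary per class. For Gaussians the joint density of the
#' concatenation equals both conditional-times-marginal factorisations
#' (old given new, and new given old), so a single fit serves either direction.
#'
#' @param old_reps Numeric matrix `n x w_old`; rows on the probability simplex.
#' @param new_reps Numeric matrix `n x w_new`; rows on the probability simplex.
#' @param labels Class label per row.
#' @param ridge Diagonal ridge recorded in each per-class summary.
#' @return A named list of `gaussian_summary` objects, one per class, in
#'   first-appearance order.
#' @export
fit_class_conditionals <- function(old_reps, new_reps, labels, ridge = 0.05) {
  old_reps <- as_row_matrix(old_reps)
  new_reps <- as_row_matrix(new_reps)
  labels <- as.character(labels)
  if (ncol(old_reps) == 0L || ncol(new_reps) == 0L) {
    stop_mdcl("both representation streams must have width >= 1", "mdcl_validation_error")
  }
  if (nrow(old_reps) != length(labels) || nrow(new_reps) != length(labels)) {
    stop_mdcl("representations and labels must be row-aligned", "mdcl_validation_error")
  }
  check_simplex_rows(old_reps, "old_reps")
  check_simplex_rows(new_reps, "new_reps")
  joint <- cbind(old_reps, new_reps)
  ids <- unique(labels)
  out <- lapply(ids, function(id) {
    rows <- which(labels == id)
    if (length(rows) == 0L) {
      stop_mdcl(paste0("class ", id, " has no samples"), "mdcl_missing_class_error")
    }
    fit_gaussian(joint[rows, , drop = FALSE], ridge = ridge)
  })
  setNames(out, ids)
}

#' Bayes posterior over classes for joint representation points
#'
#' Combines per-class Gaussian log-likelihoods with log prior mass and
#' normalises with a row-wise log-sum-exp, entirely in log space. Classes with
#' zero prior mass contribute `-Inf` log-posterior columns; exponentiated rows
#' sum to one over the remaining classes.
#'
#' @param conditionals Named list of `gaussian_summary` objects (one per
#'   class), as from [fit_class_conditionals()].
#' @param prior A [class_prior()]. Every class with positive prior mass must
#'   have a conditional.
#' @param points Numeric matrix `n x d` of joint representation points.
#' @return An object of class `posterior_table` with matrices
#'   `log_likelihood`, `log_posterior` (both `n x w`) and `class_ids`.
#' @export
class_posterior <- function(conditionals, prior, points) {
  stopifnot(inherits(prior, "class_prior"))
  points <- as_row_matrix(points)
  ids <- prior$class_ids
  w <- length(ids)
  n <- nrow(points)
  missing <- setdiff(ids[prior$probs > 0], names(conditionals))
  if (length(missing) > 0L) {
    stop_mdcl(
      paste0("classes with prior mass lack a conditional: ", paste(missing, collapse = ", ")),
      "mdcl_missing_class_error"
    )
  }
  log_lik <- matrix(NA_real_, n, w, dimnames = list(NULL, ids))
  for (j in seq_len(w)) {
    id <- ids[j]
    if (!is.null(conditionals[[id]])) {
      log_lik[, j] <- gaussian_log_density(points, conditionals[[id]])
    }
  }
  log_prior <- ifelse(prior$probs > 0, log(prior$probs), -Inf)
  unnorm <- sweep(ifelse(is.na(log_lik), -Inf, log_lik), 2L, log_prior, `+`)
  log_post <- unnorm - logsumexp_rows(unnorm)
  structure(
    list(log_likelihood = log_lik, log_posterior = log_post, class_ids = ids),
    class = "posterior_table"
  )
}

#' @export
print.posterior_table <- function(x, ...) {
  cat(sprintf(
    "<posterior_table> %d samples x %d classes (%s)\n",
    nrow(x$log_posterior), length(x$class_ids), paste(x$class_ids, collapse = ", ")
  ))
  invisible(x)
}

#' @rdname class_posterior
#' @param x A `posterior_table`.
#' @return `posterior_probs()` returns the exponentiated posterior matrix.
#' @export
posterior_probs <- function(x) {
  stopifnot(inherits(x, "posterior_table"))
  exp(x$log_posterior)
}
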