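# Independent oracles and fixture builders shared across tests. Every oracle
# is a deliberately naive re-derivation (loops, direct space, literal sums)
# kept separate from the package's computation paths.

# random row-stochastic matrix
rand_simplex <- function(n, w) {
  m <- matrix(stats::rexp(n * w), n, w)
  m / rowSums(m)
}

# literal double-sum of the mutual distillation objective: indicator / tau
# times log-posterior / tau, summed term by term over samples and classes
md_literal_oracle <- function(old_onehot, new_onehot, logpost_old, logpost_new, tau) {
  total <- 0
  if (!is.null(old_onehot)) {
    for (j in seq_len(nrow(old_onehot))) {
      for (i in seq_len(ncol(old_onehot))) {
        if (old_onehot[j, i] > 0) { # 0 * log 0 convention
          total <- total - (old_onehot[j, i] / tau) * (logpost_old[j, i] / tau)
        }
      }
    }
  }
  if (!is.null(new_onehot)) {
    for (j in seq_len(nrow(new_onehot))) {
      for (i in seq_len(ncol(new_onehot))) {
        if (new_onehot[j, i] > 0) {
          total <- total - (new_onehot[j, i] / tau) * (logpost_new[j, i] / tau)
        }
      }
    }
  }
  unname(total)
}

# elementwise cross-entropy oracle
ce_oracle <- function(targets, probs, bs) {
  total <- 0
  for (i in seq_len(nrow(targets))) {
    for (j in seq_len(ncol(targets))) {
      total <- total - targets[i, j] * log(max(probs[i, j], 1e-12))
    }
  }
  unname(total) / bs
}

# elementwise KL oracle with 0 log 0 = 0
kl_oracle <- function(targets, probs, bs) {
  total <- 0
  for (i in seq_len(nrow(targets))) {
    for (j in seq_len(ncol(targets))) {
      if (targets[i, j] > 0) {
        total <- total + targets[i, j] *
          log(max(targets[i, j], 1e-12) / max(probs[i, j], 1e-12))
      }
    }
  }
  unname(total) / bs
}

# direct-space Bayes oracle: multiply densities by priors and normalise
# without logs (valid where nothing underflows)
bayes_direct_oracle <- function(conditionals, prior, points) {
  n <- nrow(points)
  w <- length(prior$class_ids)
  post <- matrix(0, n, w)
  for (j in seq_len(w)) {
    dens <- exp(gaussian_log_density(points, conditionals[[prior$class_ids[j]]]))
    post[, j] <- dens * prior$probs[j]
  }
  post / rowSums(post)
}

# brute-force one-vs-rest confusion tally
confusion_oracle <- function(predictions, truths, registry) {
  out <- list()
  for (cls in registry) {
    tp <- 0; fp <- 0; tn <- 0; fn <- 0
    for (i in seq_along(truths)) {
      if (predictions[i] == cls && truths[i] == cls) tp <- tp + 1
      if (predictions[i] == cls && truths[i] != cls) fp <- fp + 1
      if (predictions[i] != cls && truths[i] != cls) tn <- tn + 1
      if (predictions[i] != cls && truths[i] == cls) fn <- fn + 1
    }
    out[[cls]] <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  }
  out
}

# a posterior_table with prescribed posterior probabilities (for loss tests)
fake_posterior <- function(probs, class_ids = colnames(probs)) {
  if (is.null(class_ids)) class_ids <- paste0("c", seq_len(ncol(probs)))
  structure(
    list(log_likelihood = log(probs), log_posterior = log(probs),
         class_ids = class_ids),
    class = "posterior_table"
  )
}

# random per-class Gaussian conditionals on [0,1]-scale representations
rand_conditionals <- function(class_ids, d, n_per = 15, ridge = 0.05) {
  out <- lapply(class_ids, function(id) {
    centre <- stats::runif(d)
    fit_gaussian(matrix(stats::rnorm(n_per * d, mean = centre, sd = 0.15),
                        n_per, d, byrow = TRUE), ridge = ridge)
  })
  stats::setNames(out, class_ids)
}

# tiny single-domain two-class benchmark for fast trainer tests
tiny_benchmark <- function(seed = 1, items = 40, increments = 1) {
  specs <- list(
    domain_spec("alpha", c(left = "bar", round = "disc"), channels = 1,
                image_size = 16, noise_sigma = 0.1, items_per_class = items,
                seed = seed + 50),
    domain_spec("beta", c(hole = "ring", slice = "wedge"), channels = 1,
                image_size = 16, noise_sigma = 0.1, items_per_class = items,
                seed = seed + 51)
  )
  sched <- list(
    list(domain = "alpha", classes = c("left", "round")),
    list(domain = "beta", classes = c("hole", "slice"))
  )
  generate_benchmark(specs[seq_len(max(1, min(2, increments)))],
                     sched[seq_len(increments)], split_fraction = 0.2,
                     seed = seed)
}
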