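# Small reference classifier: block-average-pooled pixel features feeding a
# one-hidden-layer tanh network, trained with ADADELTA. Deliberately tiny so
# the full incremental protocol runs in seconds on one CPU core; any backbone
# exposing logits + gradient-by-logits updates can be plugged in instead.

#' Extract pooled pixel features from images
#'
#' Converts each image (a `h x w` matrix or `h x w x c` array with values in
#' \[0, 1\]) into a fixed-length feature vector: channels are expanded to 3
#' (grayscale replicated), each channel is block-average-pooled to a
#' `pool x pool` grid, and the grids are concatenated. All domains therefore
#' share one input space regardless of native channel count or resolution.
#'
#' @param images List of image arrays.
#' @param pool Pooling grid side length (default 8, i.e. 192 features).
#' @return Numeric matrix `n x (3 * pool^2)`.
#' @export
extract_features <- function(images, pool = 8) {
  pool_channel <- function(ch) {
    h <- nrow(ch); w <- ncol(ch)
    ri <- ceiling(seq_len(h) / h * pool)
    ci <- ceiling(seq_len(w) / w * pool)
    sums <- rowsum(ch, ri)
    sums <- t(rowsum(t(sums), ci))
    cnt <- outer(tabulate(ri, pool), tabulate(ci, pool))
    as.numeric(sums / cnt)
  }
  feats <- vapply(images, function(img) {
    if (is.matrix(img)) img <- array(img, c(dim(img), 1L))
    chans <- if (dim(img)[3] == 1L) list(img[, , 1], img[, , 1], img[, , 1]) else
      list(img[, , 1], img[, , 2], img[, , 3])
    unlist(lapply(chans, pool_channel))
  }, numeric(3 * pool^2))
  t(feats)
}

#' Initialise the reference network
#'
#' @param input_dim Feature dimension (see [extract_features()]).
#' @param class_ids Initial ordered label registry.
#' @param hidden Hidden-layer width.
#' @param seed Integer seed for weight initialisation.
#' @return An object of class `mdcl_model`.
#' @export
init_model <- function(input_dim, class_ids, hidden = 32, seed = 1) {
  w <- length(class_ids)
  stopifnot(w >= 1, input_dim >= 1, hidden >= 1)
  withr::with_seed(seed, {
    model <- structure(
      list(
        W1 = matrix(rnorm(input_dim * hidden, sd = 1 / sqrt(input_dim)), input_dim, hidden),
        b1 = rep(0, hidden),
        W2 = matrix(rnorm(hidden * w, sd = 1 / sqrt(hidden)), hidden, w),
        b2 = rep(0, w),
        class_ids = as.character(class_ids),
        input_dim = input_dim, hidden = hidden,
        increments_trained = 0L,
        opt = NULL
      ),
      class = "mdcl_model"
    )
    model$opt <- adadelta_init(model)
    model
  })
}

#' @export
print.mdcl_model <- function(x, ...) {
  cat(sprintf(
    "<mdcl_model> %d -> %d -> %d classes (%s); increments trained: %d\n",
    x$input_dim, x$hidden, length(x$class_ids),
    paste(x$class_ids, collapse = ", "), x$increments_trained
  ))
  invisible(x)
}

# Forward pass; returns hidden activations alongside logits for backprop.
model_forward <- function(model, features) {
  h <- tanh(sweep(features %*% model$W1, 2L, model$b1, `+`))
  logits <- sweep(h %*% model$W2, 2L, model$b2, `+`)
  colnames(logits) <- model$class_ids
  list(hidden = h, logits = logits)
}

#' Logits of the reference network on a feature matrix
#'
#' @param model An `mdcl_model`.
#' @param features Numeric matrix `n x input_dim`.
#' @return Numeric matrix `n x w` of raw logits, columns named by class.
#' @export
model_logits <- function(model, features) {
  model_forward(model, features)$logits
}

#' Predict class labels with the reference network
#'
#' @inheritParams model_logits
#' @return Character vector of arg-max class labels.
#' @export
model_predict <- function(model, features) {
  z <- model_logits(model, features)
  model$class_ids[max.col(z, ties.method = "first")]
}

# Backprop from dL/dlogits to parameter gradients.
model_backward <- function(model, features, forward, dlogits) {
  dW2 <- crossprod(forward$hidden, dlogits)
  db2 <- colSums(dlogits)
  dh <- (dlogits %*% t(model$W2)) * (1 - forward$hidden^2)
  dW1 <- crossprod(features, dh)
  db1 <- colSums(dh)
  list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2)
}

# --- ADADELTA (rho = 0.95, eps = 1e-6): accumulate squared gradients and
# squared updates, step size is RMS(dx)/RMS(g). No learning rate to tune.

adadelta_init <- function(model) {
  zeros <- lapply(model[c("W1", "b1", "W2", "b2")], function(p) p * 0)
  list(Eg2 = zeros, Edx2 = zeros, rho = 0.95, eps = 1e-6)
}

adadelta_step <- function(model, grads) {
  opt <- model$opt
  for (nm in c("W1", "b1", "W2", "b2")) {
    g <- grads[[nm]]
    opt$Eg2[[nm]] <- opt$rho * opt$Eg2[[nm]] + (1 - opt$rho) * g^2
    dx <- -sqrt(opt$Edx2[[nm]] + opt$eps) / sqrt(opt$Eg2[[nm]] + opt$eps) * g
    opt$Edx2[[nm]] <- opt$rho * opt$Edx2[[nm]] + (1 - opt$rho) * dx^2
    model[[nm]] <- model[[nm]] + dx
  }
  model$opt <- opt
  model
}

#' Widen the classifier head for newly added classes
#'
#' Appends freshly initialised output columns for `new_class_ids` while
#' leaving every pre-existing weight (and its optimizer accumulators)
#' untouched, so logits for already-known classes are bitwise unchanged.
#'
#' @param model An `mdcl_model`.
#' @param new_class_ids Labels to append; must be disjoint from the current
#'   registry.
#' @param seed Seed for the new columns' initialisation.
#' @return The widened model.
#' @export
widen_head <- function(model, new_class_ids, seed = 1) {
  new_class_ids <- as.character(new_class_ids)
  if (length(new_class_ids) == 0L) return(model)
  if (any(new_class_ids %in% model$class_ids)) {
    stop_mdcl("new classes must be disjoint from the existing registry", "mdcl_validation_error")
  }
  k <- length(new_class_ids)
  withr::with_seed(seed, {
    new_cols <- matrix(rnorm(model$hidden * k, sd = 1 / sqrt(model$hidden)), model$hidden, k)
  })
  model$W2 <- cbind(model$W2, new_cols)
  model$b2 <- c(model$b2, rep(0, k))
  model$class_ids <- c(model$class_ids, new_class_ids)
  for (acc in c("Eg2", "Edx2")) {
    model$opt[[acc]]$W2 <- cbind(model$opt[[acc]]$W2, matrix(0, model$hidden, k))
    model$opt[[acc]]$b2 <- c(model$opt[[acc]]$b2, rep(0, k))
  }
  model
}
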