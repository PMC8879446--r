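# Internal helpers shared across modules.

# Row-wise log-sum-exp that tolerates -Inf columns (zero-prior classes).
logsumexp_rows <- function(m) {
  mx <- apply(m, 1L, max)
  mx[!is.finite(mx)] <- 0 # all -Inf row would give NaN otherwise
  mx + log(rowSums(exp(m - mx)))
}

stop_mdcl <- function(msg, class) {
  abort(msg, class = c(class, "mdcl_error"))
}

check_finite_matrix <- function(m, what) {
  if (!is.numeric(m) || anyNA(m) || any(!is.finite(m))) {
    stop_mdcl(paste0(what, " must be a finite numeric matrix"), "mdcl_validation_error")
  }
  invisible(m)
}

as_row_matrix <- function(x) {
  if (is.matrix(x)) x else matrix(x, ncol = 1L)
}

# Deterministic sub-seed derivation: one root seed, stable counter expansion.
# Keeps every derived seed a valid 32-bit integer.
derive_seed <- function(seed, counter) {
  as.integer((as.double(seed) * 48271 + counter * 7919) %% 2147483647)
}

check_simplex_rows <- function(m, what, tol = 1e-6) {
  check_finite_matrix(m, what)
  if (any(m < -tol)) {
    stop_mdcl(paste0(what, " has negative entries"), "mdcl_validation_error")
  }
  s <- rowSums(m)
  if (any(abs(s - 1) > tol)) {
    stop_mdcl(paste0(what, " rows must sum to 1"), "mdcl_validation_error")
  }
  invisible(m)
}
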