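test_that("fit_gaussian reproduces hand-computed mean and unbiased covariance", {
  s <- fit_gaussian(matrix(c(0, 2), ncol = 1))
  expect_equal(s$mean, 1)
  expect_equal(s$covariance[1, 1], 2) # ((0-1)^2 + (2-1)^2) / (2-1)
  expect_equal(s$count, 2L)

  # zero spread: ten identical points, ridge supplies the effective spread
  pts <- matrix(rep(c(0.3, 0.7), each = 10), ncol = 2)
  s2 <- fit_gaussian(pts, ridge = 1e-4)
  expect_equal(s2$mean, c(0.3, 0.7))
  expect_equal(s2$covariance, matrix(0, 2, 2))
  expect_equal(s2$ridge, 1e-4)
})

test_that("fit_gaussian rejects degenerate inputs", {
  expect_error(fit_gaussian(matrix(numeric(0), ncol = 2)),
               class = "mdcl_empty_sample_error")
  expect_error(fit_gaussian(matrix(c(1, NA), ncol = 2)),
               class = "mdcl_validation_error")
  expect_error(fit_gaussian(matrix(1:3, nrow = 1), ridge = 0),
               class = "mdcl_degenerate_covariance_error")
  expect_silent(fit_gaussian(matrix(1:3, nrow = 1), ridge = 1e-3))
})

test_that("fit_gaussian recovers generating parameters from seeded draws", {
  mu <- c(0.5, -1, 2)
  a <- matrix(c(1, 0.3, 0, 0.3, 0.8, 0.2, 0, 0.2, 1.5), 3, 3)
  sigma <- crossprod(a)
  withr::with_seed(99, {
    z <- matrix(rnorm(10000 * 3), ncol = 3)
    x <- sweep(z %*% chol(sigma), 2, mu, `+`)
  })
  s <- fit_gaussian(x)
  expect_lt(max(abs(s$mean - mu)), 0.05)
  expect_lt(max(abs(s$covariance - sigma)), 0.1)

  # bias shrinks with sample size
  withr::with_seed(7, x100 <- matrix(rnorm(100 * 3), ncol = 3))
  err100 <- max(abs(fit_gaussian(x100)$mean))
  err10k <- max(abs(s$mean - mu))
  expect_lt(err10k, err100 + 0.05)
})

test_that("gaussian_log_density matches the standard normal closed form", {
  std <- structure(
    list(mean = 0, covariance = matrix(1, 1, 1), count = 100, ridge = 0, d = 1L),
    class = "gaussian_summary"
  )
  expect_equal(gaussian_log_density(0, std), -0.5 * log(2 * pi), tolerance = 1e-12)

  # at the mean the quadratic term vanishes in any dimension
  withr::with_seed(3, x <- matrix(rnorm(60), ncol = 3))
  s3 <- fit_gaussian(x, ridge = 0.01)
  sig_eff <- s3$covariance + diag(0.01, 3)
  expect_equal(
    gaussian_log_density(s3$mean, s3),
    -0.5 * (3 * log(2 * pi) + determinant(sig_eff)$modulus[1]),
    tolerance = 1e-10
  )
  expect_error(gaussian_log_density(c(0, 0), std), class = "mdcl_validation_error")
})

test_that("density integrates to one under quadrature in d = 1", {
  withr::with_seed(5, s <- fit_gaussian(matrix(rnorm(50, 2, 0.5), ncol = 1), ridge = 1e-4))
  sd_eff <- sqrt(s$covariance[1, 1] + s$ridge)
  q <- stats::integrate(function(x) {
    exp(gaussian_log_density(matrix(x, ncol = 1), s))
  }, s$mean - 10 * sd_eff, s$mean + 10 * sd_eff, rel.tol = 1e-9)
  expect_equal(q$value, 1, tolerance = 1e-6)
})

test_that("class_prior counts in first-seen order and normalises", {
  p <- class_prior(c("a", "a", "b", "b"))
  expect_equal(p$probs, c(0.5, 0.5))
  expect_equal(class_prior(c("a", "a", "a"))$probs, 1)
  p2 <- class_prior(c("y", "x", "y", "y"))
  expect_equal(p2$class_ids, c("y", "x"))
  expect_equal(p2$probs, c(0.75, 0.25))
  expect_lt(abs(sum(p2$probs) - 1), 1e-12)
  # registry order and zero-count classes
  p3 <- class_prior(c("b", "b"), registry = c("a", "b", "c"))
  expect_equal(p3$probs, c(0, 1, 0))
  expect_error(class_prior(character(0)), class = "mdcl_validation_error")
})

test_that("fit_class_conditionals reduces to fit_gaussian for one class", {
  withr::with_seed(11, {
    old <- rand_simplex(8, 3)
    new <- rand_simplex(8, 3)
  })
  cond <- fit_class_conditionals(old, new, rep("a", 8), ridge = 0.01)
  ref <- fit_gaussian(cbind(old, new), ridge = 0.01)
  expect_equal(cond$a$mean, ref$mean)
  expect_equal(cond$a$covariance, ref$covariance)
})

test_that("joint Gaussian is symmetric under stream concatenation order", {
  withr::with_seed(12, {
    old <- rand_simplex(20, 2)
    new <- rand_simplex(20, 3)
    pts_old <- rand_simplex(5, 2)
    pts_new <- rand_simplex(5, 3)
  })
  labels <- rep(c("a", "b"), each = 10)
  c1 <- fit_class_conditionals(old, new, labels, ridge = 0.01)
  c2 <- fit_class_conditionals(new, old, labels, ridge = 0.01)
  d1 <- gaussian_log_density(cbind(pts_old, pts_new), c1$a)
  d2 <- gaussian_log_density(cbind(pts_new, pts_old), c2$a)
  expect_equal(d1, d2, tolerance = 1e-12)
})

test_that("per-class means recover well-separated cluster centres", {
  withr::with_seed(21, {
    softmax <- function(m) exp(m) / rowSums(exp(m))
    old_a <- softmax(matrix(rnorm(400, 0, 0.2), 200, 2) + rep(c(3, 0), each = 200))
    old_b <- softmax(matrix(rnorm(400, 0, 0.2), 200, 2) + rep(c(0, 3), each = 200))
  })
  old <- rbind(old_a, old_b)
  labels <- rep(c("a", "b"), each = 200)
  cond <- fit_class_conditionals(old, old, labels, ridge = 0.01)
  expect_lt(max(abs(cond$a$mean - colMeans(cbind(old_a, old_a)))), 1e-12)
  expect_lt(max(abs(cond$a$mean[1] - mean(old_a[, 1]))), 0.05)
  expect_error(fit_class_conditionals(old, old[, 0], labels),
               class = "mdcl_validation_error")
})

test_that("class_posterior matches direct-space Bayes on random instances", {
  withr::with_seed(31, {
    ids <- c("a", "b", "c", "d")
    cond <- rand_conditionals(ids, d = 3)
    prior <- class_prior(sample(ids, 40, replace = TRUE, prob = c(0.4, 0.3, 0.2, 0.1)))
    pts <- matrix(runif(20 * 3), 20, 3)
  })
  post <- class_posterior(cond, prior, pts)
  direct <- bayes_direct_oracle(cond, prior, pts)
  expect_equal(unname(posterior_probs(post)), direct, tolerance = 1e-9)
  expect_equal(unname(rowSums(posterior_probs(post))), rep(1, 20), tolerance = 1e-9)
})

test_that("equal likelihoods leave the prior; likelihoods cancel in rows", {
  withr::with_seed(32, cond1 <- rand_conditionals("a", d = 2))
  cond <- list(a = cond1$a, b = cond1$a) # identical densities
  prior <- class_prior(c(rep("a", 9), "b"))
  post <- class_posterior(cond, prior, matrix(runif(10), 5, 2))
  expect_equal(unname(posterior_probs(post)),
               matrix(rep(c(0.9, 0.1), each = 5), 5, 2), tolerance = 1e-12)
})

test_that("posterior is invariant to per-row log-likelihood shifts", {
  withr::with_seed(33, {
    ids <- c("a", "b", "c")
    cond <- rand_conditionals(ids, d = 2)
    prior <- class_prior(sample(ids, 30, replace = TRUE))
    pts <- matrix(runif(16), 8, 2)
  })
  post <- class_posterior(cond, prior, pts)
  ll <- post$log_likelihood
  renorm <- function(u) u - log(rowSums(exp(u - apply(u, 1, max)))) - apply(u, 1, max)
  lp1 <- renorm(sweep(ll, 2, log(prior$probs), `+`))
  lp2 <- renorm(sweep(ll + 7.3, 2, log(prior$probs), `+`))
  expect_equal(lp1, lp2, tolerance = 1e-9)
})

test_that("zero-prior classes receive -Inf posterior and missing conditionals are caught", {
  withr::with_seed(34, cond <- rand_conditionals(c("a", "b"), d = 2))
  prior <- class_prior(c("a", "b", "b"), registry = c("a", "b", "ghost"))
  post <- class_posterior(cond, prior, matrix(runif(6), 3, 2))
  expect_true(all(post$log_posterior[, "ghost"] == -Inf))
  expect_equal(unname(rowSums(posterior_probs(post))), rep(1, 3), tolerance = 1e-9)
  bad_prior <- class_prior(c("a", "b", "ghost"))
  expect_error(class_posterior(cond, bad_prior, matrix(runif(6), 3, 2)),
               class = "mdcl_missing_class_error")
})

test_that("gaussian summaries and posterior tables round-trip through JSON", {
  withr::with_seed(41, {
    cond <- rand_conditionals(c("a", "b"), d = 3)
    prior <- class_prior(c("a", "a", "b"))
    pts <- matrix(runif(9), 3, 3)
  })
  json <- write_gaussian_json(cond)
  back <- read_gaussian_json(json)
  expect_equal(back$a$mean, cond$a$mean)
  expect_equal(back$b$covariance, cond$b$covariance)
  post <- class_posterior(cond, prior, pts)
  post2 <- read_posterior_json(write_posterior_json(post))
  expect_equal(post2$log_posterior, post$log_posterior)
  expect_equal(post2$class_ids, post$class_ids)
  # file round-trip
  f <- withr::local_tempfile(fileext = ".json")
  write_gaussian_json(cond$a, f)
  expect_equal(read_gaussian_json(f)$mean, cond$a$mean)
})
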