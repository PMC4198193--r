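toy_binary <- function(n = 20, p = 3, seed = 40, beta = NULL) {
  if (is.null(beta)) beta <- rep_len(c(1.2, -0.8, 0.5), p)
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p)
  x <- scale(x)[, ]  # standardized, as the model assumes
  eta <- x %*% beta
  y <- rbinom(n, 1, plogis(eta))
  if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
  make_dataset(x, y)
}

test_that("tau = 0 reproduces plain gradient ascent on the mean log-likelihood", {
  d <- toy_binary(n = 10, p = 4, beta = c(1, -1, 0.5, 0))
  fit <- fit_tgdr(d, tau = 0, delta_nu = 0.05, k_iters = 30, standardize = FALSE)
  # independent re-derivation with explicit logistic algebra
  x <- as.matrix(d[paste0("F", 1:4)])
  y <- as.numeric(as.character(d$class))
  b <- rep(0, 4); b0 <- 0
  for (i in 1:30) {
    p <- plogis(b0 + x %*% b)
    b <- b + 0.05 * colMeans(x * as.vector(y - p))
    b0 <- b0 + 0.05 * mean(y - p)
  }
  expect_equal(unname(fit$coefficients[, 1]), unname(b), tolerance = 1e-12)
  expect_equal(unname(fit$intercepts), b0, tolerance = 1e-12)
})

test_that("tau = 1 moves at most the argmax-gradient coefficients per step", {
  d <- toy_binary(n = 30, p = 8, seed = 41, beta = c(2, 1, 0.5, 0, 0, 0, 0, 0))
  for (k in 1:4) {
    fit <- fit_tgdr(d, tau = 1, delta_nu = 0.01, k_iters = k, standardize = FALSE)
    expect_lte(length(selected_features(fit)), k)
  }
})

test_that("long tau = 0 runs converge to the logistic MLE", {
  d <- toy_binary(n = 20, p = 3, seed = 42)
  fit <- fit_tgdr(d, tau = 0, delta_nu = 0.01, k_iters = 60000,
                  standardize = FALSE)
  x <- as.matrix(d[paste0("F", 1:3)])
  y <- as.numeric(as.character(d$class))
  mle <- glm(y ~ x, family = binomial())  # Newton-Raphson oracle
  expect_equal(unname(fit$intercepts), unname(coef(mle)[1]), tolerance = 1e-3)
  expect_equal(unname(fit$coefficients[, 1]), unname(coef(mle)[-1]),
               tolerance = 1e-3)
})

test_that("long tau = 0 multiclass runs converge to the multinomial MLE", {
  skip_if_not_installed("nnet")
  set.seed(43)
  x <- scale(matrix(rnorm(12 * 4), 12, 4))[, ]
  y <- rep(1:3, each = 4)
  d <- make_dataset(x, y)
  fit <- fit_multi_tgdr(d, tau = 0, delta_nu = 0.01, k_iters = 80000,
                        standardize = FALSE)
  m <- nnet::multinom(factor(y) ~ x, trace = FALSE, maxit = 2000,
                      reltol = 1e-14)
  ref <- t(coef(m))  # (intercept + features) x (K-1), class 1 reference
  expect_equal(unname(fit$intercepts), unname(ref[1, ]), tolerance = 1e-3)
  expect_equal(unname(fit$coefficients), unname(ref[-1, ]), tolerance = 1e-3)
})

test_that("with two classes both multiclass variants collapse to binary TGDR", {
  d <- toy_binary(n = 25, p = 5, seed = 44, beta = c(1, -1, 0, 0.5, 0))
  args <- list(tau = 0.4, delta_nu = 0.02, k_iters = 80, standardize = FALSE)
  bin <- do.call(fit_tgdr, c(list(d), args))
  glo <- do.call(fit_multi_tgdr, c(list(d), args, variant = "multi_global"))
  loc <- do.call(fit_multi_tgdr, c(list(d), args, variant = "multi_local"))
  expect_equal(unname(glo$coefficients), unname(bin$coefficients))
  expect_equal(unname(loc$coefficients), unname(bin$coefficients))
  expect_equal(glo$intercepts, bin$intercepts)
})

test_that("with tau = 0 the global and local variants coincide for K = 3", {
  set.seed(45)
  x <- scale(matrix(rnorm(30 * 6), 30, 6))[, ]
  y <- rep(1:3, each = 10)
  d <- make_dataset(x, y)
  glo <- fit_multi_tgdr(d, tau = 0, k_iters = 120, variant = "multi_global",
                        standardize = FALSE)
  loc <- fit_multi_tgdr(d, tau = 0, k_iters = 120, variant = "multi_local",
                        standardize = FALSE)
  expect_equal(glo$coefficients, loc$coefficients)
})

test_that("selected feature count is non-increasing in tau", {
  set.seed(46)
  x <- scale(matrix(rnorm(40 * 12), 40, 12))[, ]
  y <- rbinom(40, 1, plogis(x %*% c(2, -1.5, 1, rep(0, 9))))
  if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
  d <- make_dataset(x, y)
  counts <- vapply(c(0, 0.2, 0.5, 0.8, 1), function(tau) {
    length(selected_features(fit_tgdr(d, tau = tau, delta_nu = 0.01,
                                      k_iters = 100, standardize = FALSE)))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_equal(counts[1], 12)  # tau = 0 never thresholds anything out
})

test_that("training log-likelihood is non-decreasing for a small step size", {
  d <- toy_binary(n = 30, p = 5, seed = 47, beta = c(1, 1, -1, 0, 0))
  fit <- fit_tgdr(d, tau = 0.3, delta_nu = 0.01, k_iters = 300,
                  standardize = FALSE)
  expect_true(all(diff(fit$ll_trace) > -1e-12))
})

test_that("fits are invariant to the order of training samples", {
  d <- toy_binary(n = 24, p = 4, seed = 48, beta = c(1, -1, 0.5, 0))
  perm <- sample(nrow(d))
  a <- fit_tgdr(d, tau = 0.5, k_iters = 60)
  b <- fit_tgdr(d[perm, ], tau = 0.5, k_iters = 60)
  expect_equal(a$coefficients, b$coefficients)
})

test_that("cross-validation selects k sensibly", {
  d <- toy_binary(n = 30, p = 4, seed = 49)
  expect_equal(cv_select_k(d, k_grid = 37, seed = 1)$k, 37L)

  # pure noise: large k overfits, so the small end of the grid should win
  hits <- 0L
  for (s in 1:20) {
    set.seed(500 + s)
    x <- matrix(rnorm(40 * 10), 40, 10)
    dn <- make_dataset(x, rep(0:1, 20))
    sel <- cv_select_k(dn, k_grid = c(10, 2000), delta_nu = 0.05, seed = s)
    hits <- hits + (sel$k == 10L)
  }
  expect_gte(hits, 14L)

  # strongly separated data: more iterations keep helping early on
  db <- make_blobs(n_per = 15, p = 4, sep = 3, seed = 50)
  cv <- cv_select_k(db, k_grid = c(5, 25, 100), seed = 2)$cv
  expect_true(all(diff(cv$mean_loglik) > 0))
})

test_that("invalid TGDR settings are rejected", {
  d <- toy_binary()
  expect_error(fit_tgdr(d, tau = 1.2), "tau")
  expect_error(fit_tgdr(d, delta_nu = 0), "delta_nu")
  d3 <- make_dataset(matrix(rnorm(30), 10, 3), rep(1:2, 5))
  d3$class <- factor(rep(1:2, 5))
  expect_error(fit_multi_tgdr(d3, variant = "nope"))
})
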