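test_that("projection score is perfect for tight separated clusters and zero for
           the alternating-corner layout", {
  lay <- tibble::tibble(x = c(0, 0.01, 0.02, 1, 1.01, 1.02),
                        y = c(0, 0.01, 0.02, 0, 0.01, 0.02))
  y <- rep(c("a", "b"), each = 3)
  expect_equal(score_projection(lay, y, k = 1), 100)

  # unit-square corners, classes alternating along every edge: each corner's
  # nearest neighbours (distance 1, tie broken by index) are opposite-class
  corners <- tibble::tibble(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1))
  expect_equal(score_projection(corners, c("a", "b", "a", "b"), k = 1), 0)
})

test_that("randomly permuted balanced labels score about 50", {
  set.seed(10)
  lay <- tibble::tibble(x = runif(40), y = runif(40))
  base <- rep(c("a", "b"), 20)
  scores <- replicate(200, score_projection(lay, sample(base), k = round(sqrt(40))))
  expect_gt(mean(scores), 47)
  expect_lt(mean(scores), 53)
})

test_that("projection score equals the brute-force LOO k-NN oracle", {
  set.seed(11)
  for (rep in 1:25) {
    n <- sample(5:30, 1)
    k <- sample.int(n - 1, 1)
    px <- runif(n); py <- runif(n)
    # duplicated points exercise the distance-tie rule
    if (rep %% 3 == 0) { px[2] <- px[1]; py[2] <- py[1] }
    y <- sample(c("a", "b", "c"), n, replace = TRUE)
    if (length(unique(y)) < 2) y[1:2] <- c("a", "b")
    lay <- tibble::tibble(x = px, y = py)
    expect_equal(score_projection(lay, y, k = k), oracle_loo_knn(px, py, y, k))
  }
})

test_that("score is invariant to rigid motions of the layout and class relabeling", {
  set.seed(12)
  lay <- tibble::tibble(x = runif(25), y = runif(25))
  y <- sample(c("a", "b", "c"), 25, replace = TRUE)
  s <- score_projection(lay, y, k = 5)
  th <- 0.7
  rot <- tibble::tibble(x = cos(th) * lay$x - sin(th) * lay$y,
                        y = sin(th) * lay$x + cos(th) * lay$y)
  expect_equal(score_projection(rot, y, k = 5), s)
  expect_equal(score_projection(tibble::tibble(x = -lay$x, y = lay$y), y, k = 5), s)
  relab <- c(a = "z", b = "q", c = "m")[y]
  expect_equal(score_projection(lay, relab, k = 5), s)
})

test_that("SNR ranking matches hand computation and its edge rules", {
  x <- cbind(flat = rep(1, 4),
             perfect = c(0, 0, 1, 1),
             mid = c(0, 2, 3, 5))
  d <- make_dataset(x, c("g1", "g1", "g2", "g2"))
  r <- snr_rank(d)
  expect_equal(r$feature, c("perfect", "mid", "flat"))
  expect_equal(r$snr, c(Inf, 3 / (2 * sqrt(2)), 0))
  expect_equal(r$snr[2], 1.0607, tolerance = 1e-4)
  expect_error(snr_rank(make_dataset(x, c("g1", "g1", "g2", "g3"))), ">= 2")
})

test_that("search respects the budget accounting and is deterministic", {
  d <- make_blobs(n_per = 10, p = 8, sep = 2, seed = 20)
  one <- vizrank_search(d, max_features = 3, budget = 1, seed = 1)
  expect_equal(one$evaluated_count, 1L)
  expect_equal(nrow(one$top), 1)

  a <- vizrank_search(d, max_features = 5, budget = 300, seed = 7)
  b <- vizrank_search(d, max_features = 5, budget = 300, seed = 7)
  expect_identical(a$top, b$top)
  expect_identical(a$frequency, b$frequency)
  expect_gte(a$evaluated_count, 300)

  # frequency counts total = sum of subset sizes over evaluated projections;
  # with max_features = 3 every projection has exactly 3 features
  f3 <- vizrank_search(d, max_features = 3, budget = 200, seed = 3)
  expect_equal(sum(f3$frequency$count), 3L * f3$evaluated_count)
  expect_true(all(diff(a$top$score) <= 0))
})

test_that("top-1 score is non-decreasing in budget for a fixed seed stream", {
  d <- make_blobs(n_per = 8, p = 10, sep = 1, seed = 21)
  s_small <- vizrank_search(d, max_features = 4, budget = 100, seed = 5)$top$score[1]
  s_big <- vizrank_search(d, max_features = 4, budget = 1000, seed = 5)$top$score[1]
  expect_gte(s_big, s_small)
})

test_that("local optimization never worsens the best projection", {
  d <- make_blobs(n_per = 10, p = 10, sep = 1, seed = 22)
  res <- vizrank_search(d, max_features = 5, budget = 400, seed = 2)
  same <- local_optimize(res, d, iterations = 0, seed = 3)
  expect_equal(same$top, res$top)
  opt <- local_optimize(res, d, iterations = 300, seed = 3)
  expect_gte(opt$top$score[1], res$top$score[1])
  expect_equal(opt$evaluated_count, res$evaluated_count + 300L)
  # mutants enter the frequency table too
  expect_gte(sum(opt$frequency$count), sum(res$frequency$count) + 3L * 300L)
})

test_that("local optimization finds improvements on under-searched data", {
  wins <- 0L
  for (s in 1:10) {
    sim <- simulate_design(1, n_features = 60, seed = 100 + s)
    res <- vizrank_search(sim$data, max_features = 5, budget = 300, seed = s)
    opt <- local_optimize(res, sim$data, iterations = 300, seed = 1000 + s)
    wins <- wins + (opt$top$score[1] > res$top$score[1])
  }
  expect_gte(wins, 5L)
})

test_that("search rejects invalid settings", {
  d <- make_blobs()
  expect_error(vizrank_search(d, budget = 0), "budget")
  expect_error(vizrank_search(d, max_features = 2), "max_features")
  expect_error(score_projection(tibble::tibble(x = 1:3, y = 1:3),
                                c("a", "b", "a"), k = 3), "smaller")
})
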