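test_that("error rate counts mismatches in percent", {
  expect_equal(error_rate(c(1, 2, 3), c(1, 2, 3)), 0)
  truth <- rep(c("AC", "SCC"), length.out = 151)
  pred <- truth
  pred[1:23] <- ifelse(truth[1:23] == "AC", "SCC", "AC")
  expect_equal(error_rate(pred, truth), 100 * 23 / 151, tolerance = 1e-12)
  expect_equal(round(error_rate(pred, truth), 2), 15.23)
  expect_error(error_rate(c(1, 2), c(1, 2, 3)), "mismatch")
})

test_that("generalized Brier score hits its closed-form landmarks", {
  y <- c("a", "b", "c")
  perfect <- diag(3); colnames(perfect) <- y
  expect_equal(gbs(perfect, y), 0)
  uniform <- matrix(1 / 3, 3, 3, dimnames = list(NULL, y))
  expect_equal(gbs(uniform, y), 2 / 3)
  wrong <- rbind(c(0, 1, 0), c(0, 0, 1), c(1, 0, 0))
  colnames(wrong) <- y
  expect_equal(gbs(wrong, y), 2)
  expect_equal(gbs(uniform, y, halved = TRUE), 1 / 3)
})

test_that("binary GBS equals twice the Brier score of the true-class probability", {
  set.seed(70)
  p1 <- runif(40)
  post <- cbind(a = p1, b = 1 - p1)
  y <- sample(c("a", "b"), 40, replace = TRUE)
  brier <- mean((as.numeric(y == "a") - p1)^2)
  expect_equal(gbs(post, y), 2 * brier, tolerance = 1e-12)
})

test_that("belief confusion metric is the macro-averaged true-class belief", {
  y <- c("a", "b", "c")
  perfect <- diag(3); colnames(perfect) <- y
  expect_equal(bcm(perfect, y), 1)
  uniform <- matrix(1 / 3, 3, 3, dimnames = list(NULL, y))
  expect_equal(bcm(uniform, y), 1 / 3)
  # balanced 2-class toy: beliefs 0.8 and 0.6 for own classes
  post <- rbind(c(0.8, 0.2), c(0.8, 0.2), c(0.4, 0.6), c(0.4, 0.6))
  colnames(post) <- c("a", "b")
  expect_equal(bcm(post, c("a", "a", "b", "b")), 0.7)
})

test_that("AUPR matches its closed-form cases", {
  y <- factor(c("a", "a", "b", "b"))
  perfect <- cbind(a = c(0.9, 0.8, 0.1, 0.2), b = c(0.1, 0.2, 0.9, 0.8))
  expect_equal(aupr(perfect, y), 1)
  # single positive ranked last among n
  n <- 8
  score <- seq(n, 1)
  pos <- c(rep(FALSE, n - 1), TRUE)
  expect_equal(radvizr:::average_precision(score, pos), 1 / n)
  # constant scores: one tie block, AP = prevalence
  expect_equal(radvizr:::average_precision(rep(0.5, 10), rep(c(TRUE, FALSE), 5)),
               0.5)
  expect_equal(radvizr:::average_precision(rep(0.3, 10),
                                           c(rep(TRUE, 2), rep(FALSE, 8))),
               0.2)
})

test_that("AUPR and ROC AUC agree with enumeration oracles on small inputs", {
  set.seed(71)
  for (rep in 1:40) {
    n <- sample(4:12, 1)
    # coarse scores force plenty of ties
    score <- sample(seq(0, 1, 0.25), n, replace = TRUE)
    pos <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(pos)) pos[1] <- TRUE
    if (all(pos)) pos[n] <- FALSE
    expect_equal(radvizr:::average_precision(score, pos), oracle_ap(score, pos))
    y <- factor(ifelse(pos, "pos", "neg"), levels = c("neg", "pos"))
    expect_equal(roc_auc(score, y), oracle_auc(score, pos))
  }
})

test_that("ROC AUC reproduces hand-enumerated values and agrees with pROC", {
  y <- factor(c(0, 0, 1, 1))
  expect_equal(roc_auc(c(1, 2, 3, 4), y), 1)
  expect_equal(roc_auc(c(2, 2, 2, 2), y), 0.5)
  expect_equal(roc_auc(c(1, 2, 3, 4), factor(c(0, 1, 0, 1))), 0.75)
  skip_if_not_installed("pROC")
  set.seed(72)
  s <- rnorm(30)
  yy <- sample(0:1, 30, replace = TRUE)
  if (length(unique(yy)) < 2) yy[1:2] <- 0:1
  ref <- as.numeric(pROC::auc(pROC::roc(yy, s, direction = "<", quiet = TRUE)))
  expect_equal(roc_auc(s, factor(yy)), ref)
})

test_that("BCM and AUPR are invariant to class relabeling", {
  set.seed(73)
  p <- matrix(runif(30), 10, 3)
  p <- p / rowSums(p)
  colnames(p) <- c("a", "b", "c")
  y <- sample(c("a", "b", "c"), 10, replace = TRUE)
  y[1:3] <- c("a", "b", "c")
  relab <- c(a = "z2", b = "z3", c = "z1")
  p2 <- p; colnames(p2) <- relab[colnames(p)]
  expect_equal(bcm(p2, relab[y]), bcm(p, y))
  expect_equal(aupr(p2, relab[y]), aupr(p, y))
})

test_that("feature correlation matches the closed formula and rejects constants", {
  d <- make_dataset(cbind(a = c(1, 2, 3), b = c(2, 4, 7),
                          neg = c(-1, -2, -3), flat = c(1, 1, 1)))
  expect_equal(feature_correlation(d, "a", "a"), 1)
  expect_equal(feature_correlation(d, "a", "neg"), -1)
  expect_equal(feature_correlation(d, "a", "b"), 5 / (sqrt(2) * sqrt(114 / 9)),
               tolerance = 1e-12)
  expect_error(feature_correlation(d, "a", "flat"), "constant")
})

test_that("the combined report carries all four metrics with valid posteriors only", {
  set.seed(74)
  p <- matrix(runif(60), 20, 3)
  p <- p / rowSums(p)
  colnames(p) <- c("1", "2", "3")
  y <- factor(sample(1:3, 20, replace = TRUE))
  y[1:3] <- factor(1:3)
  rep_tbl <- evaluate_classifier(p, y)
  expect_named(rep_tbl, c("error_pct", "gbs", "bcm", "aupr"))
  expect_true(rep_tbl$gbs >= 0 && rep_tbl$gbs <= 2)
  expect_true(rep_tbl$bcm >= 0 && rep_tbl$bcm <= 1)
  bad <- p; bad[1, ] <- c(0.9, 0.9, 0.1)
  expect_error(gbs(bad, y), "sum to 1")
})
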