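test_that("subtractive clustering finds density peaks", {
  # all points identical: exactly one centre at that point
  X <- matrix(rep(c(0.3, 0.7), each = 20), ncol = 2)
  cen <- subtractive_clustering(X, roi = 0.3)
  expect_equal(nrow(cen), 1)
  expect_equal(unname(cen[1, ]), c(0.3, 0.7))

  # two tight clusters: two centres near the centroids; first centre is the
  # brute-force potential argmax
  set.seed(3)
  A <- matrix(rnorm(100, sd = 0.01), ncol = 2)
  B <- matrix(1 + rnorm(100, sd = 0.01), ncol = 2)
  X <- rbind(A, B)
  cen <- subtractive_clustering(X, roi = 0.3)
  expect_equal(nrow(cen), 2)
  d_to <- function(c0) apply(cen, 1, function(cc) sqrt(sum((cc - c0)^2)))
  expect_lt(min(d_to(colMeans(A))), 0.05)
  expect_lt(min(d_to(colMeans(B))), 0.05)
  P <- rowSums(exp(-4 * as.matrix(dist(X))^2 / 0.3^2))
  expect_equal(unname(cen[1, ]), unname(X[which.max(P), ]))

  # larger range of influence never yields more clusters
  set.seed(4)
  for (rep in 1:5) {
    X <- matrix(runif(60), ncol = 2)
    n_small <- nrow(subtractive_clustering(X, roi = 0.1))
    n_large <- nrow(subtractive_clustering(X, roi = 0.6))
    expect_lte(n_large, n_small)
  }
  expect_error(subtractive_clustering(matrix(numeric(0), ncol = 2), 0.3),
               "non-empty")
})

test_that("initialisation recovers linear and constant targets exactly", {
  x <- matrix(seq(0, 1, length.out = 50))
  fit <- init_fis(x, 2 * x[, 1] + 1, roi = 1)
  expect_equal(nrow(fit$centers), 1)    # rules = clusters
  expect_equal(evaluate(fit, x), 2 * x[, 1] + 1, tolerance = 1e-6)

  fitc <- init_fis(x, rep(3.5, 50), roi = 0.5)
  expect_equal(evaluate(fitc, x), rep(3.5, 50), tolerance = 1e-8)
})

test_that("hybrid training is monotone and preserves the zero-epoch model", {
  set.seed(12)
  x <- matrix(runif(80))
  y <- sin(2 * pi * x[, 1])
  m0 <- init_fis(x, y, roi = 0.3)
  expect_identical(train_hybrid(m0, x, y, epochs = 0), m0)
  m <- train_hybrid(m0, x, y, epochs = 30)
  expect_true(all(diff(m$history) <= 1e-9))
})

test_that("evaluation follows the weighted Sugeno rule", {
  # single rule: output is the consequent line for any input
  m <- postsway:::new_anfis(
    centers = matrix(0.5), sigmas = matrix(0.2),
    consequents = matrix(c(2, 1), nrow = 1),
    ranges = rbind(min = 0, max = 1), roi = 0.5)
  for (x0 in c(-1, 0.2, 3)) expect_equal(evaluate(m, x0), 2 * x0 + 1)

  # two symmetric rules with constants 0 and 1: midpoint gives 0.5
  m2 <- postsway:::new_anfis(
    centers = matrix(c(0.2, 0.8)), sigmas = matrix(c(0.1, 0.1)),
    consequents = matrix(c(0, 0, 0, 1), nrow = 2, byrow = TRUE),
    ranges = rbind(min = 0, max = 1), roi = 0.5)
  expect_equal(evaluate(m2, 0.5), 0.5)

  # trained linear model evaluates the line
  x <- matrix(seq(0, 1, length.out = 50))
  fit <- anfis(x, 2 * x[, 1] + 1, roi = 1, epochs = 5)
  expect_equal(evaluate(fit, 0.3), 1.6, tolerance = 1e-6)

  # far outside every rule support the nearest rule dominates smoothly
  # (relative firing strengths keep the weighted average well defined)
  expect_equal(evaluate(m2, 1e3), 1)    # consequent constant of nearer rule
  expect_equal(evaluate(m2, -1e3), 0)

  expect_error(evaluate(m2, c(1, 2)), "dimensionality")
})

test_that("status prediction rounds at 0.5 and clips the reliability index", {
  m <- postsway:::new_anfis(
    centers = matrix(0), sigmas = matrix(1),
    consequents = matrix(c(1, 0), nrow = 1),  # y = x
    ranges = rbind(min = -2, max = 2), roi = 0.5)
  ps <- predict_status(m, matrix(c(0.5, 1.0, 1.3, 0.2)))
  expect_equal(ps$ps_round, c(1L, 1L, 1L, 0L))  # tie at 0.5 rounds unstable
  expect_equal(ps$ri, c(0, 100, 100, 60))       # 1.3 clipped to 100
})

test_that("training recovers a known two-rule Sugeno generator", {
  set.seed(101)
  x <- matrix(runif(500))
  y <- two_rule_sugeno(x[, 1]) + rnorm(500, sd = 0.01)
  fit <- anfis(x, y, roi = 0.5, epochs = 50)
  out <- evaluate(fit, x)
  expect_lt(sqrt(mean((out - two_rule_sugeno(x[, 1]))^2)), 0.02)
})

test_that("separable sway features train to a perfect classifier", {
  fx <- sway_fixture(per_class = 10, seed = 2)
  tr <- fx$time[fx$split$train, ]
  feat <- setdiff(names(tr), c("label", "pattern_id"))
  fit <- anfis(as.matrix(tr[, feat]), tr$label, roi = 0.3, epochs = 30)
  ps <- predict(fit, tr)
  expect_equal(ps$ps_round, tr$label)
})

test_that("anfis models survive a JSON round trip", {
  set.seed(6)
  x <- matrix(runif(60), ncol = 2)
  y <- as.numeric(x[, 1] + x[, 2] > 1)
  fit <- anfis(x, y, roi = 0.5, epochs = 10)
  path <- withr::local_tempfile(fileext = ".json")
  write_anfis(fit, path)
  fit2 <- read_anfis(path)
  expect_equal(evaluate(fit2, x), evaluate(fit, x), tolerance = 1e-12)
})
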