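test_that("fitted thresholds attain the exhaustive Youden optimum", {
  # clean separation: cut lands in the gap, perfect sensitivity/specificity
  x <- c(0.1, 0.2, 0.3, 2.1, 2.2)
  y <- c(0, 0, 0, 1, 1)
  m <- fit_thresholds(data.frame(F1 = x), y, feature_names = "F1",
                      or_groups = list())
  expect_gt(m$thresholds[["F1"]], 0.3)
  expect_lt(m$thresholds[["F1"]], 2.1)
  expect_equal(youden_j_of(m, "F1", x, y), 1)

  # two points: midpoint rule
  m2 <- fit_thresholds(data.frame(F1 = c(0, 1)), c(0, 1),
                       feature_names = "F1", or_groups = list())
  expect_equal(m2$thresholds[["F1"]], 0.5)

  # non-informative feature: J = 0 at every cut
  x3 <- c(1, 2, 3, 1, 2, 3)
  y3 <- c(0, 0, 0, 1, 1, 1)
  m3 <- fit_thresholds(data.frame(F1 = x3), y3, feature_names = "F1",
                       or_groups = list())
  expect_equal(youden_j_of(m3, "F1", x3, y3), 0)
  expect_equal(roc_oracle(x3, y3), 0)

  # randomised tables: achieved J equals the brute-force optimum,
  # including features where low values mark the unstable class
  set.seed(77)
  for (rep in 1:20) {
    n <- sample(6:25, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    x <- rnorm(n) + y * rnorm(1)   # random direction and effect size
    m <- fit_thresholds(data.frame(F1 = x), y, feature_names = "F1",
                        or_groups = list())
    expect_equal(youden_j_of(m, "F1", x, y), roc_oracle(x, y),
                 tolerance = 1e-12)
  }

  expect_error(fit_thresholds(data.frame(F1 = 1:4), c(1, 1, 1, 1)),
               "both classes")
  expect_warning(fit_thresholds(data.frame(F1 = rep(1, 4),
                                           F2 = c(1, 2, 3, 4)),
                                c(0, 0, 1, 1),
                                feature_names = c("F1", "F2"),
                                or_groups = list()),
                 "constant")
})

test_that("binarisation applies strict inequalities and OR grouping", {
  m <- structure(list(
    thresholds = c(A = 1, B = 2, C = 3),
    directions = c(A = 1, B = 1, C = 1),
    normalizers = c(A = 1, B = 1, C = 1),
    feature_order = c("A", "B", "C"),
    or_groups = list(c("A", "B")),
    effective = list("A|B" = c("A", "B"), "C" = "C")
  ), class = "threshold_model")

  # all under: zeros
  v <- binarize(c(A = 0, B = 0, C = 0), m)
  expect_equal(unname(v$jfbin), c(0L, 0L))
  expect_equal(v$fraction_over, 0)

  # A over, B under: OR group contributes 1
  v <- binarize(c(A = 2, B = 0, C = 0), m)
  expect_equal(v$jfbin[["A|B"]], 1L)
  expect_equal(v$n_effective, 2L)

  # value exactly at threshold counts as under (strict inequality)
  v <- binarize(c(A = 1, B = 2, C = 3), m)
  expect_equal(unname(v$jfbin), c(0L, 0L))

  expect_error(binarize(c(A = 1, B = 2), m), "missing")
})

test_that("the at-least-50% vote rule and RI_Th follow their definitions", {
  mkvote <- function(bits) {
    structure(list(jfbin = bits, raw = bits, n_effective = length(bits),
                   fraction_over = mean(bits)), class = "binary_vote")
  }
  expect_equal(classify_vote(mkvote(c(1, 1, 1, 0, 0))), 1L)  # 3 of 5
  expect_equal(classify_vote(mkvote(rep(0, 5))), 0L)
  expect_equal(classify_vote(mkvote(c(1, 1, 0, 0))), 1L)     # exactly 50%

  expect_equal(reliability_th(mkvote(rep(1, 4))), 100)
  expect_equal(reliability_th(mkvote(rep(0, 4))), 100)
  expect_equal(reliability_th(mkvote(c(1, 1, 1, 0, 0))), 20) # mean 0.6
  expect_equal(reliability_th(mkvote(c(1, 1, 0, 0))), 0)     # at separator
})

test_that("RI_JF weighs aligned feature-threshold distances", {
  m <- structure(list(
    thresholds = c(A = 1, B = 2),
    directions = c(A = 1, B = 1),
    normalizers = c(A = 2, B = 4),
    feature_order = c("A", "B"),
    or_groups = list(),
    effective = list(A = "A", B = "B")
  ), class = "threshold_model")

  # every feature exactly at threshold: RI_JF = 0
  expect_equal(reliability_jf(c(A = 1, B = 2), m, 1), 0)

  # one feature at its training max distance on the predicted side
  m1 <- structure(list(
    thresholds = c(A = 1), directions = c(A = 1), normalizers = c(A = 2),
    feature_order = "A", or_groups = list(), effective = list(A = "A")
  ), class = "threshold_model")
  expect_equal(reliability_jf(c(A = 3), m1, 1), 100)

  # aligned at half distance plus one disagreeing feature: (0.5 + 0)/2
  expect_equal(reliability_jf(c(A = 2, B = 1), m, 1), 25)

  # JND clipped to [-1, 1]: distances beyond the training max cap at 100
  expect_equal(reliability_jf(c(A = 100), m1, 1), 100)

  # scale invariance under joint affine rescaling of feature + model
  m2 <- m
  m2$thresholds <- 10 * m$thresholds + 3
  m2$normalizers <- 10 * m$normalizers
  expect_equal(reliability_jf(c(A = 10 * 2 + 3, B = 10 * 1 + 3), m2, 1),
               reliability_jf(c(A = 2, B = 1), m, 1))

  # monotonicity: growing an over-threshold aligned feature never lowers RI_JF
  vals <- seq(1.1, 6, by = 0.4)
  ri <- vapply(vals, function(v) reliability_jf(c(A = v, B = 3), m, 1),
               numeric(1))
  expect_true(all(diff(ri) >= -1e-12))
})

test_that("a separable training set yields perfect, unanimous votes", {
  fx <- sway_fixture(per_class = 10, seed = 2)
  tr <- fx$time[fx$split$train, ]
  m <- fit_thresholds(tr, tr$label)
  pr <- predict(m, tr)
  expect_equal(q_index(pr$ps_pred, tr$label), 100)
  expect_equal(pr$ri_th, rep(100, nrow(tr)))
})

test_that("threshold models survive a JSON round trip", {
  fx <- sway_fixture(per_class = 2, seed = 6)
  tr <- fx$time[fx$split$train, ]
  m <- fit_thresholds(tr, tr$label)
  path <- withr::local_tempfile(fileext = ".json")
  write_threshold_model(m, path)
  m2 <- read_threshold_model(path)
  expect_equal(m2$thresholds, m$thresholds)
  expect_equal(m2$directions, m$directions)
  te <- fx$time[fx$split$test, ]
  expect_equal(predict(m2, te), predict(m, te))
})
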