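test_that("the percentile threshold selects the top magnitude fraction", {
  expect_equal(threshold_percentile(c(4, -3, 2, -1), 0.5), 3)
  expect_equal(threshold_percentile(c(4, -3, 2, -1), 1), 1)   # all potentiate
  expect_equal(threshold_percentile(rep(2.5, 6), 0.3), 2.5)   # constant patch
  expect_equal(threshold_percentile(c(-9, 1), 0.5), 9)
  expect_error(threshold_percentile(numeric(0), 0.5), "non-empty")
})

test_that("the mean-correlation threshold is the mean sign-corrected activation", {
  x <- c(0.5, 1.5, -2, 3)
  expect_equal(threshold_mean_correlation(x, rep(1, 4), 2), mean(x))
  expect_equal(threshold_mean_correlation(c(-1, 1, -2, 2), rep(1, 4), 1), 0)
  w <- c(-1, 2, -3, 4); y <- -0.7
  t1 <- threshold_mean_correlation(x, w, y)
  expect_equal(threshold_mean_correlation(3 * x, w, y), 3 * t1) # scales with contrast
  expect_error(threshold_mean_correlation(x, w, 0), "nonzero")
  expect_error(threshold_mean_correlation(x, 1:3, 1), "length")
})

test_that("the update rule reproduces all six LTP/LTD table cells for both weight signs", {
  Tl <- 0.5
  cells <- expand.grid(
    x = c(-0.9, 0.1, 0.9),  # x < -T, -T < x < T, x > T
    y = c(1, -1),
    w = c(0.3, -0.3)
  )
  # printed table: rows y > 0 then y < 0; columns x < -T, |x| < T, x > T
  expected <- function(x, y, w) {
    if (abs(x) > Tl) sign(x) * sign(y) else -sign(w)
  }
  for (i in seq_len(nrow(cells))) {
    with(cells[i, ], {
      expect_equal(
        delta_w(x, y, w, Tl),
        expected(x, y, w),
        info = sprintf("x=%g y=%g w=%g", x, y, w)
      )
    })
  }
})

test_that("branch and compact forms of the update rule agree elementwise", {
  set.seed(67)
  n_draw <- 1e4
  for (i in seq_len(n_draw / 25)) {
    x <- rnorm(25)
    w <- rnorm(25)
    y <- sample(c(-1, 1), 1) * runif(1, 0.1, 2)
    Tl <- threshold_mean_correlation(x, w, y)
    # avoid exact-zero sign arguments (probability zero, but be explicit)
    if (any(x == 0 | w == 0 | x * sign(y) * sign(w) == Tl)) next
    expect_identical(delta_w(x, y, w, Tl), delta_w_compact(x, y, w, Tl))
  }
  # both reduce to sign(x - Tl) when w > 0 and y > 0
  x <- rnorm(10); Tl <- 0.2
  expect_equal(delta_w_compact(x, 1, rep(1, 10), Tl), sign(x - Tl))
  # threshold below the minimum sign-corrected activation: pure reinforcement
  x <- runif(10, 0.5, 1)
  expect_equal(delta_w(x, 1, rep(1, 10), 0.1), rep(1, 10))
})

test_that("update direction is invariant to patch contrast under the adaptive threshold", {
  set.seed(71)
  for (i in 1:20) {
    x <- rnorm(16); w <- rnorm(16); y <- sample(c(-1, 1), 1)
    d1 <- delta_w(x, y, w, threshold_mean_correlation(x, w, y))
    cc <- runif(1, 0.1, 10)
    d2 <- delta_w(cc * x, y, w, threshold_mean_correlation(cc * x, w, y))
    expect_identical(d1, d2)
  }
})

test_that("batch aggregation sums evidence and binarization maps to strict +/-1", {
  expect_equal(aggregate_batch(list(1, 1, -1)), 1)
  expect_equal(aggregate_batch(list(), n_syn = 4), rep(0, 4))
  set.seed(73)
  ds <- lapply(1:5, function(i) sample(c(-1, 1), 8, replace = TRUE))
  expect_equal(aggregate_batch(ds), aggregate_batch(rev(ds)))
  expect_error(aggregate_batch(list(c(1, -1), 1)), "length")

  expect_equal(binarize_update(0), -1)
  expect_equal(binarize_update(3), 1)
  expect_equal(binarize_update(-2), -1)
  U <- matrix(c(-2, 0, 1, 5), 2, 2)
  expect_equal(binarize_update(U), matrix(c(-1, -1, 1, 1), 2, 2))
  expect_true(all(binarize_update(U) %in% c(-1, 1)))
})

test_that("applying a binary update moves every weight by exactly lambda", {
  W <- matrix(c(0.5, -0.2, 0, 1), 2, 2)
  dW <- matrix(c(1, -1, 1, -1), 2, 2)
  out <- apply_update(W, dW, 0.1)
  expect_equal(out[1, 1], 0.6)
  expect_equal(max(abs(out - W)), 0.1)
  expect_equal(min(abs(out - W)), 0.1)
  # inverse restores the weights (to float round-off)
  expect_equal(apply_update(out, -dW, 0.1), W, tolerance = 1e-15)
  expect_error(apply_update(W, dW, -1), "lam")
})
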