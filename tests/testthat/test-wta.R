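test_that("the WTA operator keeps one signed winner and preserves shape", {
  expect_equal(wta(c(3, -5, 2), 1), c(0, -5, 0))
  expect_equal(wta(c(0, 0, 0), 1), c(0, 0, 0))
  expect_equal(wta(c(4, -4), 1), c(4, 0)) # tie: lowest index wins
  m <- array(c(1, -2, 3, 4), c(2, 2))
  expect_equal(dim(wta(m, 2)), dim(m))
  expect_error(wta(m, 3), "axes")
  expect_error(wta(m, c(1, 1)), "axes")
})

test_that("vectorized WTA matches the per-slice oracle across axes and ties", {
  set.seed(41)
  for (rep in 1:10) {
    x <- array(sample(c(-2, -1, 0, 1, 2), 2 * 3 * 4 * 3, replace = TRUE),
               c(2, 3, 4, 3))
    for (dims in list(2L, c(3L, 4L), c(2L, 3L, 4L))) {
      expect_equal(wta(x, dims), wta_slow(x, dims),
                   info = paste("dims:", paste(dims, collapse = ",")))
    }
  }
})

test_that("WTA stages are idempotent", {
  set.seed(43)
  x <- array(rnorm(3 * 4 * 5 * 5), c(3, 4, 5, 5))
  cw <- channel_wta(x)
  expect_equal(channel_wta(cw), cw)
  sw <- spatial_wta(cw)
  expect_equal(spatial_wta(sw), sw)
  p <- neighborhood_inhibition(x, 2, 2)
  p2 <- neighborhood_inhibition(p$pooled, 1, 1)
  expect_equal(p2$pooled, p$pooled)
})

test_that("neighbourhood inhibition pools magnitudes, keeps signs and coordinates", {
  a <- array(0, c(1, 1, 2, 2)); a[1, 1, , ] <- matrix(c(1, 3, -7, 2), 2, 2)
  p <- neighborhood_inhibition(a, 2, 2)
  expect_equal(p$pooled[1, 1, 1, 1], -7)
  expect_equal(p$rows[1, 1, 1, 1], 1L)
  expect_equal(p$cols[1, 1, 1, 1], 2L)

  # identity pooling keeps values with self-coordinates
  set.seed(47)
  x <- array(rnorm(2 * 3 * 4 * 4), c(2, 3, 4, 4))
  id <- neighborhood_inhibition(x, 1, 1)
  expect_equal(id$pooled, x)
  expect_equal(id$rows[1, 1, , ], matrix(rep(1:4, 4), 4, 4))

  # windows are disjoint when stride >= kernel: no coordinate selected twice
  p2 <- neighborhood_inhibition(x, 2, 2)
  for (n in 1:2) for (ch in 1:3) {
    coords <- paste(p2$rows[n, ch, , ], p2$cols[n, ch, , ])
    expect_equal(anyDuplicated(coords), 0L)
  }

  # truncated edge windows: 5 rows with stride 2 -> 3 windows
  y <- array(1, c(1, 1, 5, 5))
  expect_equal(dim(neighborhood_inhibition(y, 2, 2)$pooled), c(1, 1, 3, 3))

  # all-zero window selects nothing
  z <- neighborhood_inhibition(array(0, c(1, 1, 2, 2)), 2, 2)
  expect_equal(z$pooled[1, 1, 1, 1], 0)
  expect_true(is.na(z$rows[1, 1, 1, 1]))
})

test_that("channel competition leaves at most one winner per position", {
  one <- array(rnorm(2 * 1 * 3 * 3), c(2, 1, 3, 3))
  expect_equal(channel_wta(one), one)

  v <- array(0, c(1, 3, 1, 1)); v[1, , 1, 1] <- c(0.2, -0.9, 0.5)
  expect_equal(as.vector(channel_wta(v)[1, , 1, 1]), c(0, -0.9, 0))

  set.seed(53)
  x <- array(rnorm(3 * 5 * 4 * 4), c(3, 5, 4, 4))
  cw <- channel_wta(x)
  nz <- apply(cw != 0, c(1, 3, 4), sum)
  expect_true(all(nz <= 1))
})

test_that("spatial competition keeps the n_keep strongest entries per map", {
  single <- array(0, c(1, 1, 2, 2)); single[1, 1, 2, 1] <- 0.4
  expect_equal(spatial_wta(single), single)

  m <- array(0, c(1, 1, 2, 2)); m[1, 1, , ] <- matrix(c(0.3, 0, 0, -0.8), 2, 2)
  out <- spatial_wta(m, 1)
  expect_equal(out[1, 1, , ], matrix(c(0, 0, 0, -0.8), 2, 2))

  set.seed(59)
  x <- array(rnorm(2 * 2 * 3 * 3), c(2, 2, 3, 3))
  expect_equal(spatial_wta(x, 9), x) # n_keep >= #entries: identity
  k2 <- spatial_wta(x, 2)
  expect_true(all(apply(k2 != 0, c(1, 2), sum) == 2))
})

test_that("selection pipeline satisfies m_k <= N and the patch round-trip identity", {
  set.seed(61)
  bank <- generate_pattern_bank(3, c(1, 4, 4), seed = 6)
  ib <- generate_images(bank, 12, noise_sigma = 0.3, occurrences = 1,
                        canvas = c(10, 10), seed = 7)
  spec <- layer_spec(1, 6, 4)
  W <- init_weights(16, 6, seed = 9)
  sel <- select_patches(ib, W, spec)
  m <- vapply(sel$channels, function(ch) ch$m, integer(1))
  expect_true(all(m <= 12))
  acts <- conv_forward(ib, W, spec)
  pooled <- neighborhood_inhibition(acts, spec$k_pool, spec$s_pool)
  n_positions <- prod(dim(pooled$pooled)[3:4])
  expect_lte(sum(m), 12 * n_positions)
  for (k in which(m > 0)) {
    ch <- sel$channels[[k]]
    # master self-test: w_k . x reproduces the winner's conv value
    expect_equal(as.vector(ch$X %*% W[, k, drop = FALSE]), ch$y,
                 tolerance = 1e-10)
    # and the winner value is the conv output at the recorded coordinates
    for (j in seq_len(ch$m)) {
      expect_equal(acts[ch$coords$image[j], k, ch$coords$row[j],
                        ch$coords$col[j]], ch$y[j])
    }
  }
})

test_that("degenerate selections are handled: 1x1 kernels and empty winner volumes", {
  x <- array(rnorm(2 * 1 * 3 * 3), c(2, 1, 3, 3))
  spec <- layer_spec(1, 1, 1)
  W <- matrix(1.5, 1, 1)
  expect_error(extract_selection(x, neighborhood_inhibition(conv_forward(x, W, spec), 1, 1), spec), NA)
  sel <- select_patches(x, W, spec)
  ch <- sel$channels[[1]]
  for (j in seq_len(ch$m)) {
    expect_equal(ch$X[j, 1] * 1.5, ch$y[j])
  }

  z <- array(0, c(2, 1, 3, 3))
  selz <- select_patches(z, W, spec)
  expect_equal(selz$channels[[1]]$m, 0L)
})
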