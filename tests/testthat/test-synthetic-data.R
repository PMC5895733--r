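test_that("pattern banks are standardized, distinguishable, and reproducible", {
  b1 <- generate_pattern_bank(1, c(1, 4, 4), seed = 5)
  v <- c(b1$patterns[[1]])
  expect_equal(mean(v), 0, tolerance = 1e-12)
  expect_equal(mean((v - mean(v))^2), 1, tolerance = 1e-12)

  b <- generate_pattern_bank(4, c(1, 5, 5), seed = 0)
  for (i in 1:3) for (j in (i + 1):4) {
    cs <- sum(c(b$patterns[[i]]) * c(b$patterns[[j]])) /
      (sqrt(sum(c(b$patterns[[i]])^2)) * sqrt(sum(c(b$patterns[[j]])^2)))
    expect_lte(abs(cs), 0.5)
  }

  b2 <- generate_pattern_bank(4, c(1, 5, 5), seed = 0)
  expect_identical(b$patterns, b2$patterns)

  expect_error(
    generate_pattern_bank(50, c(1, 2, 2), seed = 1, max_abs_cos = 0.01,
                          max_tries = 3),
    "could not draw"
  )
})

test_that("scatter images plant exact templates and are seed-reproducible", {
  bank <- generate_pattern_bank(2, c(1, 4, 4), seed = 2)
  ib <- generate_images(bank, 6, noise_sigma = 0, occurrences = 1,
                        canvas = c(10, 10), seed = 9)
  pl <- ib$provenance$placements
  expect_equal(nrow(pl), 6)
  for (i in 1:6) {
    p <- pl[pl$image == i, ]
    patch <- ib$pixels[i, 1, p$row:(p$row + 3), p$col:(p$col + 3)]
    expect_equal(array(patch, c(1, 4, 4)), bank$patterns[[p$pattern]])
    # background is exactly zero
    total <- sum(abs(ib$pixels[i, 1, , ]))
    expect_equal(total, sum(abs(bank$patterns[[p$pattern]])))
    expect_equal(ib$labels[i], p$pattern)
  }
  ib2 <- generate_images(bank, 6, noise_sigma = 0, occurrences = 1,
                         canvas = c(10, 10), seed = 9)
  expect_identical(ib$pixels, ib2$pixels)

  empty <- generate_images(bank, 0, canvas = c(10, 10))
  expect_equal(dim(empty$pixels)[1], 0)

  expect_error(
    generate_images(bank, 1, occurrences = 4, canvas = c(6, 6)),
    "too small"
  )
})

test_that("tile placement fills every cell with a planted template", {
  bank <- generate_pattern_bank(4, c(1, 5, 5), seed = 0)
  ib <- generate_images(bank, 3, noise_sigma = 0, canvas = c(10, 10),
                        placement = "tile", seed = 4)
  pl <- ib$provenance$placements
  expect_equal(nrow(pl), 3 * 4)
  expect_setequal(unique(paste(pl$row, pl$col)), c("1 1", "1 6", "6 1", "6 6"))
  for (r in seq_len(nrow(pl))) {
    patch <- ib$pixels[pl$image[r], 1,
                       pl$row[r]:(pl$row[r] + 4), pl$col[r]:(pl$col[r] + 4)]
    expect_equal(array(patch, c(1, 5, 5)), bank$patterns[[pl$pattern[r]]])
  }
  expect_error(
    generate_images(bank, 1, canvas = c(12, 12), placement = "tile"),
    "multiple"
  )
})

test_that("ON/OFF difference-of-Gaussians encoding has zero DC response and is linear", {
  const <- image_batch(array(3, c(2, 1, 9, 9)))
  enc <- on_off_encode(const, 0.6, 1.2)
  expect_lt(max(abs(enc$pixels)), 1e-12)

  set.seed(21)
  img <- image_batch(array(rnorm(2 * 1 * 9 * 9), c(2, 1, 9, 9)))
  neg <- image_batch(-img$pixels)
  expect_equal(on_off_encode(neg, 0.6, 1.2)$pixels,
               -on_off_encode(img, 0.6, 1.2)$pixels)

  # bright dot on dark ground: positive centre, negative surround ring
  dot <- array(0, c(1, 1, 11, 11)); dot[1, 1, 6, 6] <- 1
  r <- on_off_encode(image_batch(dot), 0.6, 1.2)$pixels
  ctr <- (dim(r)[3] + 1) / 2
  expect_gt(r[1, 1, ctr, ctr], 0)
  expect_lt(r[1, 1, ctr, ctr - 2], 0)

  expect_error(on_off_encode(const, 2, 1), "sigma_surround")
})

test_that("IDX files round-trip exactly, honoring big-endian asymmetric dims", {
  # 2 images of 2x3: asymmetric dims catch endianness/transposition errors
  set.seed(5)
  px <- array(sample(0:255, 2 * 2 * 3, replace = TRUE) / 255, c(2, 1, 2, 3))
  ib <- image_batch(px)
  path <- tempfile(fileext = ".idx")
  write_idx(ib, path)
  back <- read_idx(path)
  expect_equal(back$pixels, ib$pixels)
  expect_equal(dim(back$pixels), c(2, 1, 2, 3))
  # header bytes: magic 00 00 08 03, then dims 2, 2, 3 big-endian
  hdr <- readBin(path, "raw", 16)
  expect_identical(hdr[1:4], as.raw(c(0, 0, 8, 3)))
  expect_identical(hdr[5:8], as.raw(c(0, 0, 0, 2)))
  expect_identical(hdr[13:16], as.raw(c(0, 0, 0, 3)))

  labs <- c(0L, 3L, 9L, 1L)
  lp <- tempfile(fileext = ".idx")
  write_idx(labs, lp)
  expect_identical(read_idx(lp), labs)
})

test_that("malformed IDX files produce format errors naming the offset", {
  bad <- tempfile()
  writeBin(as.raw(c(1, 2, 8, 3, rep(0, 12))), bad)
  expect_error(read_idx(bad), "offset 0")

  trunc <- tempfile()
  writeBin(as.raw(c(0, 0, 8, 3)), trunc)
  con <- file(trunc, "ab")
  writeBin(c(2L, 2L, 3L), con, size = 4, endian = "big")
  writeBin(as.raw(1:5), con) # payload should be 12 bytes
  close(con)
  expect_error(read_idx(trunc), "truncated payload")

  wrongtype <- tempfile()
  writeBin(as.raw(c(0, 0, 13, 1, 0, 0, 0, 1, 7)), wrongtype)
  expect_error(read_idx(wrongtype), "type code")
})
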