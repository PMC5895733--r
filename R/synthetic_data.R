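#' Image batch container
#'
#' Lightweight container for a batch of single- or multi-channel images as a
#' dense numeric array indexed `(image, channel, row, col)`.
#'
#' @param pixels Numeric array of dimension `(N, C, H, W)`.
#' @param labels Optional per-image labels (e.g. planted pattern identity).
#' @param provenance Optional list of generator parameters and seed.
#'
#' @return An object of class `image_batch` with elements `pixels`, `labels`,
#'   and `provenance`.
#' @export
image_batch <- function(pixels, labels = NULL, provenance = list()) {
  if (!is.array(pixels) || length(dim(pixels)) != 4L) {
    stop("`pixels` must be a 4-d array (image, channel, row, col)")
  }
  if (any(!is.finite(pixels))) stop("`pixels` must be finite")
  if (!is.null(labels) && length(labels) != dim(pixels)[1]) {
    stop("`labels` must have one entry per image")
  }
  structure(
    list(pixels = pixels, labels = labels, provenance = provenance),
    class = "image_batch"
  )
}

#' @export
print.image_batch <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf(
    "<image_batch> %d image(s), %d channel(s), %d x %d%s\n",
    d[1], d[2], d[3], d[4],
    if (is.null(x$labels)) "" else ", labelled"
  ))
  invisible(x)
}

#' @export
dim.image_batch <- function(x) dim(x$pixels)

#' Generate a bank of planted pattern templates
#'
#' Draws `k` small zero-mean, unit-variance templates that are mutually
#' distinguishable (pairwise absolute cosine similarity at most
#' `max_abs_cos`). These are the "repeating patterns" that the synthetic
#' generator embeds in images and that STDP training is expected to recover.
#'
#' Templates are i.i.d. Gaussian, then standardized per template using the
#' population variance. The whole bank is redrawn until the similarity bound
#' holds, failing explicitly after `max_tries` attempts.
#'
#' @param k Number of templates (>= 1).
#' @param shape Template shape `c(channels, height, width)`.
#' @param seed Integer seed; the bank is deterministic given the seed.
#' @param max_abs_cos Pairwise similarity bound, default 0.5.
#' @param max_tries Redraw budget before giving up.
#'
#' @return An object of class `pattern_bank`: list with `patterns` (a list of
#'   `k` arrays of dimension `shape`), `shape`, and `seed`.
#' @export
generate_pattern_bank <- function(k, shape = c(1, 5, 5), seed = 1L,
                                  max_abs_cos = 0.5, max_tries = 100L) {
  if (k < 1) stop("`k` must be >= 1")
  stopifnot(length(shape) == 3L, all(shape >= 1))
  n_el <- prod(shape)
  if (n_el < 2) stop("templates need at least 2 elements to standardize")
  with_seed(seed, {
    for (try in seq_len(max_tries)) {
      pats <- lapply(seq_len(k), function(i) {
        v <- stats::rnorm(n_el)
        v <- (v - mean(v)) / pop_sd(v)
        array(v, dim = shape)
      })
      ok <- TRUE
      if (k > 1) {
        for (i in seq_len(k - 1)) {
          for (j in seq(i + 1, k)) {
            if (abs(cosine(c(pats[[i]]), c(pats[[j]]))) > max_abs_cos) {
              ok <- FALSE
            }
          }
        }
      }
      if (ok) {
        return(structure(
          list(patterns = pats, shape = shape, seed = seed),
          class = "pattern_bank"
        ))
      }
    }
  })
  stop(sprintf(
    "could not draw %d templates with pairwise |cos| <= %g in %d tries",
    k, max_abs_cos, max_tries
  ))
}

#' @export
print.pattern_bank <- function(x, ...) {
  cat(sprintf(
    "<pattern_bank> %d template(s) of shape (%s), seed %d\n",
    length(x$patterns), paste(x$shape, collapse = " x "), x$seed
  ))
  invisible(x)
}

#' Generate images with planted repeating patterns
#'
#' Each image is an i.i.d. Gaussian noise background (`noise_sigma`) to which
#' `occurrences` templates from the bank are added at uniformly random,
#' non-overlapping positions. Pattern identities are drawn uniformly.
#' Placement metadata is recorded in `provenance$placements` and, when
#' `occurrences == 1`, the per-image pattern identity is returned as the
#' batch labels.
#'
#' Because the convolutional learner is translation-equivariant, an isolated
#' template on a noise background makes every shifted fragment of it an
#' equally consistent repeating stimulus, and filters may lock onto
#' fragments. The `"tile"` placement removes this ambiguity for recovery
#' experiments: templates fill a grid of template-sized cells (identity
#' drawn uniformly per cell), so a misaligned window sees a different random
#' mixture on every image and only the aligned templates repeat.
#'
#' @param bank A [generate_pattern_bank()] object.
#' @param n Number of images (0 gives an empty batch).
#' @param noise_sigma Standard deviation of the background noise (>= 0).
#' @param occurrences Planted templates per image (`"scatter"` placement
#'   only; `"tile"` fills every cell).
#' @param canvas Image size `c(H, W)`; must fit the requested occurrences
#'   without overlap, and be a multiple of the template size for `"tile"`.
#' @param placement `"scatter"` (uniform random non-overlapping positions on
#'   a noise background, the default) or `"tile"` (full grid of templates).
#' @param seed Integer seed; the batch is reproducible from parameters + seed.
#'
#' @return An [image_batch()] of dimension `(n, channels, H, W)`.
#' @export
generate_images <- function(bank, n, noise_sigma = 0.2, occurrences = 1L,
                            canvas = c(12, 12),
                            placement = c("scatter", "tile"), seed = 1L) {
  stopifnot(inherits(bank, "pattern_bank"))
  placement <- match.arg(placement)
  if (n < 0) stop("`n` must be >= 0")
  if (noise_sigma < 0) stop("`noise_sigma` must be >= 0")
  ch <- bank$shape[1]; ph <- bank$shape[2]; pw <- bank$shape[3]
  H <- canvas[1]; W <- canvas[2]
  if (ph > H || pw > W) stop("canvas smaller than the pattern templates")
  if (placement == "tile") {
    if (H %% ph != 0 || W %% pw != 0) {
      stop("`tile` placement needs the canvas to be a multiple of the template size")
    }
    return(generate_images_tile(bank, n, noise_sigma, canvas, seed))
  }
  if (occurrences * ph * pw > H * W) {
    stop("canvas too small to place the requested occurrences without overlap")
  }
  pix <- array(0, dim = c(n, ch, H, W))
  placements <- vector("list", n)
  labels <- rep(NA_integer_, n)
  if (n > 0) {
    with_seed(seed, {
      for (img in seq_len(n)) {
        canvas_arr <- array(stats::rnorm(ch * H * W, sd = noise_sigma),
                            dim = c(ch, H, W))
        placed <- matrix(numeric(0), ncol = 4) # row0, col0, row1, col1
        recs <- list()
        for (occ in seq_len(occurrences)) {
          id <- sample.int(length(bank$patterns), 1)
          pos <- NULL
          for (try in 1:200) {
            r0 <- sample.int(H - ph + 1, 1)
            c0 <- sample.int(W - pw + 1, 1)
            r1 <- r0 + ph - 1; c1 <- c0 + pw - 1
            overlap <- FALSE
            if (nrow(placed) > 0) {
              overlap <- any(
                placed[, 1] <= r1 & placed[, 3] >= r0 &
                  placed[, 2] <= c1 & placed[, 4] >= c0
              )
            }
            if (!overlap) { pos <- c(r0, c0, r1, c1); break }
          }
          if (is.null(pos)) {
            stop("could not place patterns without overlap; enlarge the canvas")
          }
          placed <- rbind(placed, pos)
          canvas_arr[, pos[1]:pos[3], pos[2]:pos[4], drop = FALSE] ->
            region
          canvas_arr[, pos[1]:pos[3], pos[2]:pos[4]] <-
            region + bank$patterns[[id]]
          recs[[occ]] <- data.frame(
            image = img, pattern = id, row = pos[1], col = pos[2]
          )
        }
        pix[img, , , ] <- canvas_arr
        placements[[img]] <- do.call(rbind, recs)
        if (occurrences == 1L) labels[img] <- recs[[1]]$pattern
      }
    })
  }
  image_batch(
    pix,
    labels = if (occurrences == 1L && n > 0) labels else NULL,
    provenance = list(
      generator = "planted_patterns", placement = "scatter", n = n,
      noise_sigma = noise_sigma, occurrences = occurrences, canvas = canvas,
      seed = seed, bank_seed = bank$seed,
      placements = if (n > 0) do.call(rbind, placements) else NULL
    )
  )
}

# Tile placement: every template-sized cell of the canvas receives one
# template with uniformly random identity, on top of the noise background.
generate_images_tile <- function(bank, n, noise_sigma, canvas, seed) {
  ch <- bank$shape[1]; ph <- bank$shape[2]; pw <- bank$shape[3]
  H <- canvas[1]; W <- canvas[2]
  cell_r <- seq(1L, H, by = ph)
  cell_c <- seq(1L, W, by = pw)
  k <- length(bank$patterns)
  pix <- array(0, dim = c(n, ch, H, W))
  placements <- vector("list", n)
  if (n > 0) {
    with_seed(seed, {
      for (img in seq_len(n)) {
        canvas_arr <- array(stats::rnorm(ch * H * W, sd = noise_sigma),
                            dim = c(ch, H, W))
        recs <- list()
        for (i in seq_along(cell_r)) {
          for (j in seq_along(cell_c)) {
            id <- sample.int(k, 1)
            r0 <- cell_r[i]; c0 <- cell_c[j]
            region <- canvas_arr[, r0:(r0 + ph - 1), c0:(c0 + pw - 1),
                                 drop = FALSE]
            canvas_arr[, r0:(r0 + ph - 1), c0:(c0 + pw - 1)] <-
              region + bank$patterns[[id]]
            recs[[length(recs) + 1L]] <- data.frame(
              image = img, pattern = id, row = r0, col = c0
            )
          }
        }
        pix[img, , , ] <- canvas_arr
        placements[[img]] <- do.call(rbind, recs)
      }
    })
  }
  image_batch(
    pix,
    provenance = list(
      generator = "planted_patterns", placement = "tile", n = n,
      noise_sigma = noise_sigma, canvas = canvas, seed = seed,
      bank_seed = bank$seed,
      placements = if (n > 0) do.call(rbind, placements) else NULL
    )
  )
}

#' Apply ON/OFF difference-of-Gaussians retinal encoding
#'
#' Convolves each channel with a single centre-surround
#' difference-of-Gaussians ("Mexican hat") kernel and keeps the signed
#' result: positive values are ON (centre-on) activity and negative values
#' are OFF activity of the symmetric filter, so only one of the two filters
#' needs to be applied. The kernel is normalized to sum exactly to zero, so a
#' constant image maps to an all-zero response.
#'
#' @param batch An [image_batch()].
#' @param sigma_center Centre Gaussian width (> 0).
#' @param sigma_surround Surround Gaussian width (> `sigma_center`).
#'
#' @return An [image_batch()] of signed responses; spatial dimensions shrink
#'   by the kernel size minus one (valid convolution, no padding).
#' @export
on_off_encode <- function(batch, sigma_center = 1, sigma_surround = 2) {
  stopifnot(inherits(batch, "image_batch"))
  if (!(sigma_surround > sigma_center && sigma_center > 0)) {
    stop("need sigma_surround > sigma_center > 0")
  }
  ker <- dog_kernel(sigma_center, sigma_surround)
  ksz <- nrow(ker)
  d <- dim(batch$pixels)
  C <- d[2]
  # one DoG per channel, channels kept independent (block structure)
  Wb <- matrix(0, nrow = C * ksz * ksz, ncol = C)
  for (ch in seq_len(C)) {
    idx <- ((ch - 1) * ksz * ksz + 1):(ch * ksz * ksz)
    Wb[idx, ch] <- as.vector(t(ker)) # (row, col) flatten, col fastest
  }
  spec <- layer_spec(c_in = C, c_out = C, k_conv = ksz)
  out <- conv_forward(batch, Wb, spec)
  image_batch(out, labels = batch$labels,
              provenance = c(batch$provenance,
                             list(encoding = "on_off_dog",
                                  sigma_center = sigma_center,
                                  sigma_surround = sigma_surround)))
}

# Zero-sum difference-of-Gaussians kernel (centre minus surround, each
# normalized to unit mass before differencing; residual mean removed so the
# kernel sums to exactly zero).
dog_kernel <- function(sigma_center, sigma_surround) {
  half <- ceiling(2.5 * sigma_surround)
  g <- function(s) {
    x <- (-half):half
    m <- exp(-outer(x^2, x^2, "+") / (2 * s^2))
    m / sum(m)
  }
  ker <- g(sigma_center) - g(sigma_surround)
  ker - mean(ker)
}

#' Read an IDX-format file
#'
#' Reads the IDX binary layout used by the MNIST distribution: a 4-byte magic
#' number `0x00 0x00 <type> <ndim>`, `ndim` big-endian 32-bit dimension
#' fields, then an unsigned-byte payload in row-major order (last dimension
#' fastest). Only the unsigned-byte type code (0x08) is supported.
#'
#' @param path Path to an IDX file.
#'
#' @return For a 3-d file (images), an [image_batch()] with one channel and
#'   pixels scaled to `[0, 1]`. For a 1-d file (labels), an integer vector.
#' @seealso [write_idx()]
#' @export
read_idx <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 4)
  if (length(magic) < 4) {
    stop("IDX format error at offset 0: truncated magic number")
  }
  if (magic[1] != as.raw(0) || magic[2] != as.raw(0)) {
    stop(sprintf(
      "IDX format error at offset 0: bad magic bytes %02x %02x (expected 00 00)",
      as.integer(magic[1]), as.integer(magic[2])
    ))
  }
  type <- as.integer(magic[3])
  ndim <- as.integer(magic[4])
  if (type != 8L) {
    stop(sprintf(
      "IDX format error at offset 2: unsupported type code 0x%02x (only unsigned byte 0x08)",
      type
    ))
  }
  dims <- readBin(con, "integer", ndim, size = 4, endian = "big")
  if (length(dims) < ndim) {
    stop(sprintf("IDX format error at offset %d: truncated dimension header",
                 4 + 4 * length(dims)))
  }
  n <- prod(dims)
  payload <- readBin(con, "integer", n, size = 1, signed = FALSE)
  if (length(payload) < n) {
    stop(sprintf("IDX format error at offset %d: truncated payload (%d of %d bytes)",
                 4 + 4 * ndim + length(payload), length(payload), n))
  }
  if (ndim == 1L) {
    return(as.integer(payload))
  }
  if (ndim != 3L) {
    stop(sprintf("unsupported IDX rank %d (expected 1 or 3)", ndim))
  }
  # payload is row-major (last dim fastest); R arrays are column-major
  arr <- array(payload / 255, dim = rev(dims))          # (W, H, N)
  arr <- aperm(arr, c(3, 2, 1))                         # (N, H, W)
  pix <- array(arr, dim = c(dims[1], 1, dims[2], dims[3]))
  pix[, 1, , ] <- arr
  image_batch(pix, provenance = list(source = path, format = "idx"))
}

#' Write an IDX-format file
#'
#' Inverse of [read_idx()]. Image batches must be single-channel with pixels
#' in `[0, 1]`; values are scaled to 0..255 and rounded. Integer vectors are
#' written as 1-d label files.
#'
#' @param x An [image_batch()] (single channel) or an integer vector.
#' @param path Output path.
#'
#' @return `path`, invisibly.
#' @export
write_idx <- function(x, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  if (inherits(x, "image_batch")) {
    d <- dim(x$pixels)
    if (d[2] != 1L) stop("IDX image files are single-channel")
    if (any(x$pixels < 0 | x$pixels > 1)) {
      stop("pixels must lie in [0, 1] to write unsigned bytes")
    }
    writeBin(as.raw(c(0, 0, 8, 3)), con)
    writeBin(as.integer(c(d[1], d[3], d[4])), con, size = 4, endian = "big")
    arr <- array(x$pixels[, 1, , ], dim = c(d[1], d[3], d[4]))
    bytes <- as.integer(round(aperm(arr, c(3, 2, 1)) * 255)) # W fastest
    writeBin(as.raw(bytes), con)
  } else {
    v <- as.integer(x)
    if (any(v < 0 | v > 255)) stop("labels must lie in 0..255")
    writeBin(as.raw(c(0, 0, 8, 1)), con)
    writeBin(length(v), con, size = 4, endian = "big")
    writeBin(as.raw(v), con)
  }
  invisible(path)
}
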