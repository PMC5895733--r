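#' Winner-takes-all operator
#'
#' Along the competition axes `dims`, keeps the single entry of largest
#' magnitude in each slice at its original signed value and zeroes all
#' others. The output has the same shape as the input: unlike max-pooling,
#' the competed dimensions are preserved, not squeezed.
#'
#' Ties are broken by the lowest index in `(channel, row, col)` priority
#' order. An all-zero slice stays all-zero: a zero activation corresponds to
#' "no spike" under the LIF equivalence and never wins.
#'
#' @param x A numeric array.
#' @param dims Axes of `x` along which the competition runs (at least one,
#'   each a valid axis).
#'
#' @return An array of the same shape as `x`.
#' @export
wta <- function(x, dims) {
  d <- dim(x)
  was_vector <- is.null(d)
  if (was_vector) {
    d <- length(x)
    dim(x) <- d
  }
  dims <- as.integer(dims)
  if (!length(dims) || anyNA(dims) || any(dims < 1 | dims > length(d)) ||
      anyDuplicated(dims)) {
    stop("`dims` must be distinct valid axes of `x`")
  }
  margin <- setdiff(seq_along(d), dims)
  # competed axes ordered so that scanning visits candidates in ascending
  # (channel, row, col) lexicographic order: highest-priority axis slowest
  comp <- rev(sort(dims))
  perm <- c(comp, margin)
  xp <- aperm(x, perm)
  k <- prod(d[comp])
  ns <- prod(d[margin])
  m <- matrix(xp, nrow = k, ncol = ns)
  best <- max.col(t(abs(m)), ties.method = "first")
  mx <- abs(m)[cbind(best, seq_len(ns))]
  res <- matrix(0, k, ns)
  sel <- which(mx > 0)
  res[cbind(best[sel], sel)] <- m[cbind(best[sel], sel)]
  dim(res) <- d[perm]
  res <- aperm(res, order(perm))
  if (was_vector) dim(res) <- NULL
  res
}

#' Neighbourhood inhibition (first WTA stage)
#'
#' Magnitude max-pooling over spatial windows of size `k_pool` advancing by
#' `s_pool`, keeping the signed value of each window's largest-magnitude
#' entry and recording its pre-pool coordinates. This acts as lateral
#' inhibition: two winners cannot come from the same local region. Edge
#' windows that would exceed the map are truncated.
#'
#' @param acts Signed activation array `(N, C, H, W)` from [conv_forward()].
#' @param k_pool Pooling window size.
#' @param s_pool Pooling stride.
#'
#' @return A list of class `pooled_acts`: `pooled` (array
#'   `(N, C, H_p, W_p)`), and `rows`/`cols` (same shape) giving each pooled
#'   winner's pre-pool coordinates (`NA` for all-zero windows).
#' @export
neighborhood_inhibition <- function(acts, k_pool, s_pool) {
  stopifnot(is.array(acts), length(dim(acts)) == 4L,
            k_pool >= 1, s_pool >= 1)
  d <- dim(acts)
  starts_r <- seq(1L, d[3], by = s_pool)
  starts_c <- seq(1L, d[4], by = s_pool)
  Hp <- length(starts_r); Wp <- length(starts_c)
  pooled <- array(0, dim = c(d[1], d[2], Hp, Wp))
  rows <- array(NA_integer_, dim = c(d[1], d[2], Hp, Wp))
  cols <- array(NA_integer_, dim = c(d[1], d[2], Hp, Wp))
  nc <- d[1] * d[2]
  for (i in seq_len(Hp)) {
    rs <- starts_r[i]:min(starts_r[i] + k_pool - 1L, d[3])
    for (j in seq_len(Wp)) {
      cs <- starts_c[j]:min(starts_c[j] + k_pool - 1L, d[4])
      sub <- acts[, , rs, cs, drop = FALSE]
      m <- matrix(sub, nrow = nc)
      am <- abs(m)
      best <- max.col(am, ties.method = "first")
      pick <- cbind(seq_len(nc), best)
      vals <- m[pick]
      mx <- am[pick]
      vals[mx == 0] <- 0
      rloc <- rs[(best - 1L) %% length(rs) + 1L]
      cloc <- cs[(best - 1L) %/% length(rs) + 1L]
      rloc[mx == 0] <- NA_integer_
      cloc[mx == 0] <- NA_integer_
      pooled[, , i, j] <- vals
      rows[, , i, j] <- rloc
      cols[, , i, j] <- cloc
    }
  }
  structure(list(pooled = pooled, rows = rows, cols = cols),
            class = "pooled_acts")
}

#' Channel competition (second WTA stage)
#'
#' Applies the [wta()] operator along the channel axis at every pooled
#' position: at each `(image, row, col)` only the neuron that would spike
#' first (largest magnitude) survives, forcing different kernels to learn
#' from different input patches. At most one nonzero per position remains.
#'
#' @param pooled A `pooled_acts` object from [neighborhood_inhibition()], or
#'   a plain `(N, C, H, W)` array.
#'
#' @return The same type as the input, with losing channels zeroed.
#' @export
channel_wta <- function(pooled) {
  if (inherits(pooled, "pooled_acts")) {
    pooled$pooled <- wta(pooled$pooled, dims = 2L)
    return(pooled)
  }
  wta(pooled, dims = 2L)
}

#' Spatial competition (third WTA stage)
#'
#' Per image and channel, keeps the `n_keep` largest-magnitude surviving
#' entries across the spatial axes and zeroes the rest. The default
#' `n_keep = 1` leaves at most one winner per channel and image, which
#' enforces `m_k <= N` in the selection that follows.
#'
#' @param cw A `pooled_acts` object or `(N, C, H, W)` array (typically the
#'   output of [channel_wta()]).
#' @param n_keep Number of winners kept per `(image, channel)` map (>= 1).
#'
#' @return Same type as the input.
#' @export
spatial_wta <- function(cw, n_keep = 1L) {
  if (n_keep < 1) stop("`n_keep` must be >= 1")
  if (inherits(cw, "pooled_acts")) {
    cw$pooled <- spatial_wta(cw$pooled, n_keep)
    return(cw)
  }
  if (n_keep == 1L) {
    return(wta(cw, dims = c(3L, 4L)))
  }
  d <- dim(cw)
  res <- cw
  for (n in seq_len(d[1])) {
    for (ch in seq_len(d[2])) {
      # visit candidates in (row, col) order so ties resolve consistently
      v <- as.vector(t(cw[n, ch, , ]))
      keep <- order(-abs(v))[seq_len(min(n_keep, length(v)))]
      keep <- keep[abs(v[keep]) > 0]
      out <- numeric(length(v))
      out[keep] <- v[keep]
      res[n, ch, , ] <- t(matrix(out, nrow = d[4]))
    }
  }
  res
}

#' Extract selected outputs and their input patches
#'
#' For every winner surviving the three WTA stages, maps its pooled position
#' back to the pre-pool convolution coordinates and extracts the exact input
#' receptive-field window that produced it. Patches are flattened in
#' `(channel, row, col)` order, matching the weight-bank layout, so that for
#' every selected pair `patch %*% W[, k]` reproduces the winner's
#' convolution output exactly.
#'
#' @param batch The [image_batch()] (or 4-d array) that fed the layer.
#' @param winners A `pooled_acts` object after [channel_wta()] and
#'   [spatial_wta()] (its `rows`/`cols` carry the pre-pool coordinates).
#' @param spec The [layer_spec()] of the producing layer.
#'
#' @return An object of class `selection_result`: list with `channels` (per
#'   output channel `k`: `y` = signed selected outputs, `X` = `m_k` by
#'   `c_in * k_conv^2` patch matrix, `m` = `m_k`, `coords` = data frame of
#'   `(image, row, col)` conv coordinates), plus `c_out`, `n_images`, and
#'   `patch_dim`.
#' @export
extract_selection <- function(batch, winners, spec) {
  stopifnot(inherits(winners, "pooled_acts"), inherits(spec, "layer_spec"))
  pix <- if (inherits(batch, "image_batch")) batch$pixels else batch
  d <- dim(pix)
  im <- im2col_index(d[2], d[3], d[4], spec$k_conv, spec$k_conv,
                     spec$conv_stride)
  n_el <- ncol(im$idx)
  wv <- winners$pooled
  nz <- which(wv != 0, arr.ind = TRUE)
  channels <- lapply(seq_len(spec$c_out), function(k) {
    list(y = numeric(0), X = matrix(0, 0, n_el), m = 0L,
         coords = data.frame(image = integer(0), row = integer(0),
                             col = integer(0)))
  })
  if (nrow(nz) > 0) {
    n_img <- nz[, 1]
    k_ch <- nz[, 2]
    r_conv <- winners$rows[nz]
    c_conv <- winners$cols[nz]
    if (anyNA(r_conv)) {
      stop("internal consistency failure: nonzero winner without coordinates")
    }
    if (any(r_conv > im$h_out | c_conv > im$w_out)) {
      stop("internal consistency failure: winner coordinate out of bounds")
    }
    p <- r_conv + im$h_out * (c_conv - 1L)
    pm <- matrix(pix, nrow = d[1])
    idx_mat <- im$idx[p, , drop = FALSE]
    patch_vec <- pm[cbind(rep(n_img, n_el), as.vector(idx_mat))]
    patches <- matrix(patch_vec, nrow = nrow(nz), ncol = n_el)
    yv <- wv[nz]
    for (k in seq_len(spec$c_out)) {
      rows_k <- which(k_ch == k)
      channels[[k]] <- list(
        y = yv[rows_k],
        X = patches[rows_k, , drop = FALSE],
        m = length(rows_k),
        coords = data.frame(image = n_img[rows_k], row = r_conv[rows_k],
                            col = c_conv[rows_k])
      )
    }
  }
  structure(
    list(channels = channels, c_out = spec$c_out,
         n_images = d[1], patch_dim = n_el),
    class = "selection_result"
  )
}

#' @export
print.selection_result <- function(x, ...) {
  m <- vapply(x$channels, function(ch) ch$m, integer(1))
  cat(sprintf(
    "<selection_result> %d channel(s), %d image(s); m_k = [%s]\n",
    x$c_out, x$n_images, paste(m, collapse = ", ")
  ))
  invisible(x)
}

#' Run the full three-stage selection pipeline
#'
#' Convenience wrapper: [conv_forward()] then [neighborhood_inhibition()],
#' [channel_wta()], [spatial_wta()], and [extract_selection()]. Guarantees
#' `m_k <= N` for every output channel.
#'
#' @inheritParams conv_forward
#' @param n_keep Spatial winners kept per `(image, channel)`; default 1.
#'
#' @return A `selection_result` (see [extract_selection()]).
#' @export
select_patches <- function(batch, W, spec, n_keep = 1L) {
  acts <- conv_forward(batch, W, spec)
  pooled <- neighborhood_inhibition(acts, spec$k_pool, spec$s_pool)
  pooled <- channel_wta(pooled)
  pooled <- spatial_wta(pooled, n_keep)
  extract_selection(batch, pooled, spec)
}
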