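#' Convolutional layer specification
#'
#' Describes one convolutional layer: kernel geometry, the winner-takes-all
#' pooling used during learning, and the optional inference-time post-ops
#' (nonlinearity, downsampling, normalization) applied when the layer is used
#' as a feature extractor.
#'
#' The pooling kernel must satisfy `k_pool >= k_conv` and its stride defaults
#' to `s_pool = k_conv`, so that neighbouring winners come from
#' non-overlapping input regions (lateral inhibition).
#'
#' @param c_in,c_out Input/output channel counts.
#' @param k_conv Square convolution kernel size.
#' @param conv_stride Convolution stride (default 1).
#' @param k_pool Winner-takes-all pooling kernel; default `k_conv`.
#' @param s_pool Pooling stride; default `k_conv`.
#' @param act Inference nonlinearity: `"linear"` keeps signed activations
#'   (the symmetric-neuron reading, where a negative value is the activity of
#'   the partner neuron with opposite weights), `"relu"` rectifies, `"abs"`
#'   takes magnitudes.
#' @param down_type,down_k,down_s Inference-time downsampling after the
#'   nonlinearity: `"none"`, `"avg"`, or `"max_abs"` (magnitude max-pooling,
#'   sign preserved), with kernel `down_k` and stride `down_s`.
#' @param norm Optional inference normalization: `"none"` or `"l2"`
#'   (per-image unit L2 norm).
#'
#' @return An object of class `layer_spec`.
#' @export
layer_spec <- function(c_in, c_out, k_conv, conv_stride = 1L,
                       k_pool = k_conv, s_pool = k_conv,
                       act = c("linear", "relu", "abs"),
                       down_type = c("none", "avg", "max_abs"),
                       down_k = 2L, down_s = down_k,
                       norm = c("none", "l2")) {
  act <- match.arg(act)
  down_type <- match.arg(down_type)
  norm <- match.arg(norm)
  stopifnot(c_in >= 1, c_out >= 1, k_conv >= 1, conv_stride >= 1,
            s_pool >= 1, down_k >= 1, down_s >= 1)
  if (k_pool < k_conv) {
    stop("`k_pool` must be >= `k_conv`")
  }
  structure(
    list(c_in = as.integer(c_in), c_out = as.integer(c_out),
         k_conv = as.integer(k_conv), conv_stride = as.integer(conv_stride),
         k_pool = as.integer(k_pool), s_pool = as.integer(s_pool),
         act = act, down_type = down_type, down_k = as.integer(down_k),
         down_s = as.integer(down_s), norm = norm),
    class = "layer_spec"
  )
}

#' @export
print.layer_spec <- function(x, ...) {
  cat(sprintf(
    "<layer_spec> conv %dx%d/%d: %d -> %d ch; wta pool %d/%d; act %s; down %s\n",
    x$k_conv, x$k_conv, x$conv_stride, x$c_in, x$c_out,
    x$k_pool, x$s_pool, x$act,
    if (x$down_type == "none") "none"
    else sprintf("%s %d/%d", x$down_type, x$down_k, x$down_s)
  ))
  invisible(x)
}

#' Multi-layer architecture configuration
#'
#' An ordered list of [layer_spec()]s with channel compatibility checked
#' between adjacent layers.
#'
#' @param ... One or more [layer_spec()] objects, input layer first.
#'
#' @return An object of class `arch_config` (a list of layer specs).
#' @export
arch_config <- function(...) {
  layers <- list(...)
  if (length(layers) == 1L && is.list(layers[[1]]) &&
      !inherits(layers[[1]], "layer_spec")) {
    layers <- layers[[1]]
  }
  if (!length(layers) || !all(vapply(layers, inherits, TRUE, "layer_spec"))) {
    stop("`arch_config()` takes one or more layer_spec objects")
  }
  if (length(layers) > 1) {
    for (i in seq_len(length(layers) - 1)) {
      if (layers[[i + 1]]$c_in != layers[[i]]$c_out) {
        stop(sprintf("layer %d expects %d input channels but layer %d outputs %d",
                     i + 1, layers[[i + 1]]$c_in, i, layers[[i]]$c_out))
      }
    }
  }
  structure(layers, class = "arch_config")
}

#' Architecture presets
#'
#' Named single- and multi-layer architectures mirroring the feature
#' extractors used in the reference experiments: a LeNet-style 8-filter
#' 5x5 layer for 28x28 digit images; a 64-filter 7x7 layer with average
#' pooling to a 4x4 grid for 32x32 and 96x96 natural images; and a two-layer
#' stack with stride-4 pooling for 96x96 object images. Details the source
#' material leaves open (padding, convolution stride) are fixed here as valid
#' convolution with stride 1.
#'
#' @param name One of `"mnist"`, `"cifar10"`, `"stl10"`, `"eth80"`.
#'
#' @return An [arch_config()].
#' @export
arch_preset <- function(name = c("mnist", "cifar10", "stl10", "eth80")) {
  name <- match.arg(name)
  switch(name,
    mnist = arch_config(
      layer_spec(1, 8, 5, down_type = "avg", down_k = 2, down_s = 2)
    ),
    cifar10 = arch_config(
      layer_spec(3, 64, 7, down_type = "avg", down_k = 6, down_s = 6)
    ),
    stl10 = arch_config(
      layer_spec(3, 64, 7, down_type = "avg", down_k = 24, down_s = 22)
    ),
    eth80 = arch_config(
      layer_spec(3, 8, 5, k_pool = 5, down_type = "max_abs",
                 down_k = 4, down_s = 4),
      layer_spec(8, 16, 5, k_pool = 5, down_type = "max_abs",
                 down_k = 4, down_s = 4)
    )
  )
}

# Patch/convolution index map. Returns, for a (C, H, W) input cube, the
# linear indices of every receptive-field element for every output position.
# idx[p, j]: output position p = r + h_out * (c - 1) (row fastest), patch
# element j flattened in (channel, row, col) order with col fastest --
# the same order used for weight-bank columns.
im2col_index <- function(C, H, W, kh, kw, stride = 1L) {
  h_out <- (H - kh) %/% stride + 1L
  w_out <- (W - kw) %/% stride + 1L
  if (H < kh || W < kw) stop("kernel larger than input")
  el <- expand.grid(cc = seq_len(kw), r = seq_len(kh), ch = seq_len(C))
  pos <- expand.grid(r0 = seq_len(h_out), c0 = seq_len(w_out))
  top <- (pos$r0 - 1L) * stride
  left <- (pos$c0 - 1L) * stride
  idx <- outer(seq_len(nrow(pos)), seq_len(nrow(el)), function(p, j) {
    el$ch[j] + C * ((top[p] + el$r[j] - 1L) + H * (left[p] + el$cc[j] - 1L))
  })
  list(idx = idx, h_out = h_out, w_out = w_out)
}

#' Convolutional forward pass
#'
#' Valid (no padding) cross-correlation of an image batch with a weight
#' bank, replacing time-stepped LIF integration: output magnitudes encode
#' first-spike order, larger meaning earlier. Activations are kept signed; a
#' negative output is read as the activity of the synaptically symmetric
#' partner neuron. Output spatial size is
#' `floor((H - k_conv) / stride) + 1` per side.
#'
#' @param batch An [image_batch()] or a 4-d pixel array `(N, C, H, W)`.
#' @param W Weight bank of shape `(c_in * k_conv * k_conv, c_out)`; column
#'   `k` is filter `k` flattened in `(channel, row, col)` order.
#' @param spec A [layer_spec()].
#'
#' @return A signed activation array of dimension `(N, c_out, H_out, W_out)`.
#' @export
conv_forward <- function(batch, W, spec) {
  pix <- if (inherits(batch, "image_batch")) batch$pixels else batch
  stopifnot(is.array(pix), length(dim(pix)) == 4L)
  d <- dim(pix)
  if (d[2] != spec$c_in) {
    stop(sprintf("batch has %d channels but spec expects %d", d[2], spec$c_in))
  }
  if (nrow(W) != spec$c_in * spec$k_conv^2 || ncol(W) != spec$c_out) {
    stop("weight bank shape does not match the layer spec")
  }
  if (d[3] < spec$k_conv || d[4] < spec$k_conv) {
    stop("kernel larger than input")
  }
  im <- im2col_index(d[2], d[3], d[4], spec$k_conv, spec$k_conv,
                     spec$conv_stride)
  if (d[1] == 0L) {
    return(array(0, dim = c(0L, spec$c_out, im$h_out, im$w_out)))
  }
  pm <- matrix(pix, nrow = d[1])
  A <- pm[, as.vector(im$idx), drop = FALSE]
  dim(A) <- c(d[1] * nrow(im$idx), ncol(im$idx))
  O <- A %*% W
  out <- array(O, dim = c(d[1], im$h_out, im$w_out, spec$c_out))
  aperm(out, c(1, 4, 2, 3))
}

# Inference-time transform of one layer: conv -> nonlinearity -> downsample
# -> normalization. Used by encode() and to feed upper layers during
# training.
layer_transform <- function(pix, W, spec) {
  a <- conv_forward(pix, W, spec)
  a <- switch(spec$act,
    linear = a,
    relu = pmax(a, 0),
    abs = abs(a)
  )
  if (spec$down_type == "avg") {
    a <- pool_avg(a, spec$down_k, spec$down_s)
  } else if (spec$down_type == "max_abs") {
    a <- neighborhood_inhibition(a, spec$down_k, spec$down_s)$pooled
  }
  if (spec$norm == "l2") {
    n_img <- dim(a)[1]
    for (i in seq_len(n_img)) {
      nrm <- sqrt(sum(a[i, , , ]^2))
      if (nrm > 0) a[i, , , ] <- a[i, , , ] / nrm
    }
  }
  a
}

# Average pooling with truncated edge windows.
pool_avg <- function(a, k, s) {
  d <- dim(a)
  starts_r <- seq(1L, d[3], by = s)
  starts_c <- seq(1L, d[4], by = s)
  out <- array(0, dim = c(d[1], d[2], length(starts_r), length(starts_c)))
  for (i in seq_along(starts_r)) {
    rs <- starts_r[i]:min(starts_r[i] + k - 1L, d[3])
    for (j in seq_along(starts_c)) {
      cs <- starts_c[j]:min(starts_c[j] + k - 1L, d[4])
      sub <- a[, , rs, cs, drop = FALSE]
      out[, , i, j] <- apply(sub, c(1, 2), mean)
    }
  }
  out
}

#' Encode a batch through a trained architecture
#'
#' Full deterministic inference pass: each layer applies its convolution,
#' configured nonlinearity, downsampling, and normalization in order. With a
#' single layer and no post-ops this reduces to [conv_forward()].
#'
#' @param batch An [image_batch()] or 4-d pixel array.
#' @param weights A list with one weight bank per layer (or a single matrix
#'   for a one-layer architecture).
#' @param arch An [arch_config()].
#'
#' @return The top-layer activation array `(N, C, H, W)`.
#' @export
encode <- function(batch, weights, arch) {
  stopifnot(inherits(arch, "arch_config"))
  if (is.matrix(weights)) weights <- list(weights)
  if (length(weights) != length(arch)) {
    stop("need exactly one weight bank per layer")
  }
  a <- if (inherits(batch, "image_batch")) batch$pixels else batch
  for (l in seq_along(arch)) {
    a <- layer_transform(a, weights[[l]], arch[[l]])
  }
  a
}
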