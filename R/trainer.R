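#' Train one convolutional layer with WTA binary STDP
#'
#' Runs the full unsupervised learning loop on one layer. Per mini-batch:
#' forward convolution, the three WTA stages ([neighborhood_inhibition()],
#' [channel_wta()], [spatial_wta()]), patch extraction, the per-pair binary
#' Hebbian update with the configured threshold strategy, batch aggregation
#' and binarization into a single `+/- lambda` step, and heterosynaptic
#' normalization of every updated column. Channels that selected no patch in
#' a batch receive no update (and are not re-normalized), so unlearned
#' neurons do not drift. The learning rate halves after each epoch.
#'
#' The run is deterministic given the data and `cfg$seed`, which drives
#' weight initialization and the per-epoch shuffling of images into
#' mini-batches.
#'
#' @param batch An [image_batch()] holding the training images.
#' @param spec A [layer_spec()].
#' @param cfg A [learning_config()].
#' @param W0 Optional initial weight bank; defaults to
#'   [init_weights()] under `cfg$seed`.
#'
#' @return A list of class `trained_layer`: `W` (the learned weight bank),
#'   `spec`, `cfg`, and `log` (per-batch data frame with `epoch`, `batch`,
#'   `lambda`, `n_selected`, and `w_change_max`).
#' @export
train_layer <- function(batch, spec, cfg, W0 = NULL) {
  stopifnot(inherits(spec, "layer_spec"), inherits(cfg, "learning_config"))
  pix <- if (inherits(batch, "image_batch")) batch$pixels else batch
  n_img <- dim(pix)[1]
  n_syn <- spec$c_in * spec$k_conv^2
  W <- if (is.null(W0)) init_weights(n_syn, spec$c_out, cfg$seed) else W0
  log_rows <- list()
  if (n_img == 0L || cfg$epochs == 0L) {
    if (n_img == 0L) warning("empty image stream; returning initial weights")
    return(structure(list(W = W, spec = spec, cfg = cfg,
                          log = empty_training_log()),
                     class = "trained_layer"))
  }
  with_seed(cfg$seed + 1L, {
    for (epoch in seq_len(cfg$epochs) - 1L) {
      lam <- lr_schedule(cfg$lambda0, epoch)
      ord <- sample.int(n_img)
      splits <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
      for (bi in seq_along(splits)) {
        sub <- pix[splits[[bi]], , , , drop = FALSE]
        res <- stdp_step(sub, W, spec, cfg, lam)
        W <- res$W
        log_rows[[length(log_rows) + 1L]] <- data.frame(
          epoch = epoch, batch = bi, lambda = lam,
          n_selected = res$n_selected, w_change_max = res$w_change_max
        )
      }
    }
  })
  structure(
    list(W = W, spec = spec, cfg = cfg, log = do.call(rbind, log_rows)),
    class = "trained_layer"
  )
}

empty_training_log <- function() {
  data.frame(epoch = integer(0), batch = integer(0), lambda = numeric(0),
             n_selected = integer(0), w_change_max = numeric(0))
}

# One STDP update step on a mini-batch of pixels. Returns the new weights
# and step statistics.
stdp_step <- function(pix, W, spec, cfg, lam) {
  sel <- select_patches(pix, W, spec, cfg$n_keep)
  W_before <- W
  updated <- integer(0)
  n_selected <- 0L
  for (k in seq_len(spec$c_out)) {
    ch <- sel$channels[[k]]
    if (ch$m == 0L) next
    n_selected <- n_selected + ch$m
    wk <- W[, k]
    deltas <- vector("list", ch$m)
    for (j in seq_len(ch$m)) {
      xj <- ch$X[j, ]
      Tl <- if (cfg$threshold_strategy == "hard_percentile") {
        threshold_percentile(xj, cfg$p_n)
      } else {
        threshold_mean_correlation(xj, wk, ch$y[j])
      }
      deltas[[j]] <- delta_w(xj, ch$y[j], wk, Tl)
    }
    U <- aggregate_batch(deltas)
    dWk <- binarize_update(U)
    W[, k] <- apply_update(wk, dWk, lam)
    updated <- c(updated, k)
  }
  if (length(updated)) W <- normalize_weights(W, updated)
  list(
    W = W, n_selected = n_selected,
    w_change_max = if (length(updated)) max(abs(W - W_before)) else 0
  )
}

#' Train a multi-layer architecture
#'
#' Trains all convolutional layers simultaneously, without greedy layer-wise
#' phases: for each mini-batch every layer performs one STDP step, reading
#' as input the batch propagated through the current (same-batch) weights of
#' the layers below via their inference transforms. With a single layer this
#' reduces exactly to [train_layer()].
#'
#' @param batch An [image_batch()] of training images.
#' @param arch An [arch_config()].
#' @param cfg A [learning_config()].
#'
#' @return A list of class `wtastdp_model`: `weights` (one bank per layer),
#'   `arch`, `cfg`, and `log` (per-layer list of training logs).
#' @export
train_network <- function(batch, arch, cfg) {
  stopifnot(inherits(arch, "arch_config"), inherits(cfg, "learning_config"))
  pix <- if (inherits(batch, "image_batch")) batch$pixels else batch
  n_img <- dim(pix)[1]
  n_layers <- length(arch)
  weights <- lapply(seq_len(n_layers), function(l) {
    sp <- arch[[l]]
    init_weights(sp$c_in * sp$k_conv^2, sp$c_out, cfg$seed + l - 1L)
  })
  logs <- replicate(n_layers, list(), simplify = FALSE)
  if (n_img == 0L || cfg$epochs == 0L) {
    if (n_img == 0L) warning("empty image stream; returning initial weights")
    return(structure(list(weights = weights, arch = arch, cfg = cfg,
                          log = lapply(seq_len(n_layers),
                                       function(l) empty_training_log())),
                     class = "wtastdp_model"))
  }
  with_seed(cfg$seed + 1L, {
    for (epoch in seq_len(cfg$epochs) - 1L) {
      lam <- lr_schedule(cfg$lambda0, epoch)
      ord <- sample.int(n_img)
      splits <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
      for (bi in seq_along(splits)) {
        inp <- pix[splits[[bi]], , , , drop = FALSE]
        for (l in seq_len(n_layers)) {
          res <- stdp_step(inp, weights[[l]], arch[[l]], cfg, lam)
          logs[[l]][[length(logs[[l]]) + 1L]] <- data.frame(
            epoch = epoch, batch = bi, lambda = lam,
            n_selected = res$n_selected, w_change_max = res$w_change_max
          )
          if (l < n_layers) {
            # feed the next layer through this layer's current weights
            inp <- layer_transform(inp, weights[[l]], arch[[l]])
          }
          weights[[l]] <- res$W
        }
      }
    }
  })
  structure(
    list(weights = weights, arch = arch, cfg = cfg,
         log = lapply(logs, function(lg) do.call(rbind, lg))),
    class = "wtastdp_model"
  )
}

#' @export
print.wtastdp_model <- function(x, ...) {
  cat(sprintf("<wtastdp_model> %d layer(s)\n", length(x$weights)))
  for (l in seq_along(x$arch)) print(x$arch[[l]])
  invisible(x)
}

#' Serialize a trained model to JSON
#'
#' Writes weights (full double precision), architecture, and learning
#' configuration to a JSON file that [load_model()] restores bit-exactly.
#'
#' @param model A `wtastdp_model` from [train_network()].
#' @param path Output file path.
#'
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "wtastdp_model"))
  payload <- list(
    format = "wtastdp_model",
    version = 1L,
    # weights as %.17g strings: shortest text that round-trips IEEE doubles
    weights = lapply(model$weights, function(W) {
      list(dim = dim(W), values = sprintf("%.17g", as.vector(W)))
    }),
    arch = lapply(model$arch, function(sp) unclass(sp)),
    cfg = unclass(model$cfg)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Restore a model saved with [save_model()]
#'
#' @param path Path to a JSON model file.
#'
#' @return A `wtastdp_model`.
#' @export
load_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(payload$format) || payload$format != "wtastdp_model") {
    stop("not a wtastdp model file")
  }
  weights <- lapply(seq_len(nrow_or_len(payload$weights)), function(i) {
    w <- if (is.data.frame(payload$weights)) {
      list(dim = payload$weights$dim[[i]], values = payload$weights$values[[i]])
    } else {
      payload$weights[[i]]
    }
    matrix(as.numeric(w$values), nrow = w$dim[1], ncol = w$dim[2])
  })
  arch <- arch_config(lapply(seq_len(nrow_or_len(payload$arch)), function(i) {
    a <- if (is.data.frame(payload$arch)) as.list(payload$arch[i, ]) else payload$arch[[i]]
    layer_spec(a$c_in, a$c_out, a$k_conv, a$conv_stride, a$k_pool, a$s_pool,
               a$act, a$down_type, a$down_k, a$down_s, a$norm)
  }))
  cfg <- learning_config(payload$cfg$threshold_strategy, payload$cfg$p_n,
                         payload$cfg$lambda0, payload$cfg$epochs,
                         payload$cfg$batch_size, payload$cfg$n_keep,
                         payload$cfg$seed)
  structure(list(weights = weights, arch = arch, cfg = cfg, log = NULL),
            class = "wtastdp_model")
}

nrow_or_len <- function(x) if (is.data.frame(x)) nrow(x) else length(x)
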