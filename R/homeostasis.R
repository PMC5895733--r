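#' Heterosynaptic normalization of one neuron's weights
#'
#' Mean-centres and standardizes a neuron's synaptic weight vector to unit
#' variance (population variance: the column is the whole population of that
#' neuron's synapses), then clips to `[-2, 2]`. Equalizing the first two
#' moments keeps the total energy of the weights identical across neurons,
#' so even a neuron that has learned little can still win competitions;
#' clipping prevents a few extreme synapses from turning neurons into
#' near-duplicates of already-learned patterns.
#'
#' A constant column (zero variance) is a degenerate neuron: it is
#' re-initialized from the standard-normal weight-init distribution (then
#' normalized), with a warning.
#'
#' @param Wk Weight column vector (length >= 2).
#' @param clip_range Clipping bounds applied after standardization.
#'
#' @return The normalized, clipped column.
#' @export
normalize_neuron <- function(Wk, clip_range = c(-2, 2)) {
  if (length(Wk) < 2L) stop("a neuron needs at least 2 synapses to normalize")
  s <- pop_sd(Wk)
  if (s == 0) {
    warning("degenerate neuron (constant weights); re-initializing")
    Wk <- stats::rnorm(length(Wk))
    s <- pop_sd(Wk)
  }
  clip((Wk - mean(Wk)) / s, clip_range[1], clip_range[2])
}

#' Normalize every column of a weight bank
#'
#' Applies [normalize_neuron()] to the selected columns of a weight matrix.
#'
#' @param W Weight matrix `(n_synapses, c_out)`.
#' @param columns Columns to normalize; defaults to all.
#' @param clip_range Passed to [normalize_neuron()].
#'
#' @return The weight matrix with the selected columns normalized.
#' @export
normalize_weights <- function(W, columns = seq_len(ncol(W)),
                              clip_range = c(-2, 2)) {
  for (k in columns) W[, k] <- normalize_neuron(W[, k], clip_range)
  W
}

#' Learning-rate schedule
#'
#' The learning rate starts at `lambda0` (default 0.1, an order of magnitude
#' of 1e-1) and is halved after each epoch:
#' `lambda = lambda0 * 2^(-epoch)` with 0-based epochs.
#'
#' @param lambda0 Initial rate (> 0).
#' @param epoch 0-based epoch index.
#'
#' @return The learning rate in force during `epoch`.
#' @export
lr_schedule <- function(lambda0 = 0.1, epoch = 0L) {
  stop_if_not_scalar(lambda0, "lambda0", positive = TRUE)
  if (any(epoch < 0)) stop("`epoch` must be >= 0")
  lambda0 * 2^(-epoch)
}

#' Initialize a weight bank
#'
#' Draws i.i.d. standard-normal weights and normalizes each column with
#' [normalize_neuron()], so the post-normalization invariant (zero mean,
#' unit variance per neuron, entries in `[-2, 2]`) holds from step zero.
#'
#' @param n_in Synapses per neuron (`c_in * k_conv^2`).
#' @param c_out Number of neurons (output channels).
#' @param seed Integer seed.
#'
#' @return A weight matrix `(n_in, c_out)`.
#' @export
init_weights <- function(n_in, c_out, seed = 1L) {
  stopifnot(n_in >= 2, c_out >= 1)
  with_seed(seed, {
    W <- matrix(stats::rnorm(n_in * c_out), nrow = n_in, ncol = c_out)
    normalize_weights(W)
  })
}
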