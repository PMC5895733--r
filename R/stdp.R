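#' Learning configuration
#'
#' Hyper-parameters of the binary STDP learning phase.
#'
#' @param threshold_strategy LTP/LTD threshold rule: `"mean_correlation"`
#'   (adaptive, contrast-invariant; the default) or `"hard_percentile"`.
#' @param p_n Percentile fraction in (0, 1) for the hard strategy: the top
#'   `p_n` fraction of patch entries by magnitude potentiate.
#' @param lambda0 Initial learning rate (> 0); each synapse moves by exactly
#'   `+/- lambda` per batch. Default 0.1.
#' @param epochs Training epochs; the rate halves after each.
#' @param batch_size Mini-batch size for update aggregation.
#' @param n_keep Spatial WTA winners per (image, channel); default 1.
#' @param seed Integer seed controlling weight initialization and shuffling.
#'
#' @return An object of class `learning_config`.
#' @export
learning_config <- function(threshold_strategy = c("mean_correlation",
                                                   "hard_percentile"),
                            p_n = 0.25, lambda0 = 0.1, epochs = 3L,
                            batch_size = 64L, n_keep = 1L, seed = 1L) {
  threshold_strategy <- match.arg(threshold_strategy)
  if (!(p_n > 0 && p_n < 1)) stop("`p_n` must lie in (0, 1)")
  stop_if_not_scalar(lambda0, "lambda0", positive = TRUE)
  stopifnot(epochs >= 0, batch_size >= 1, n_keep >= 1)
  structure(
    list(threshold_strategy = threshold_strategy, p_n = p_n,
         lambda0 = lambda0, epochs = as.integer(epochs),
         batch_size = as.integer(batch_size), n_keep = as.integer(n_keep),
         seed = as.integer(seed)),
    class = "learning_config"
  )
}

#' Hard percentile LTP/LTD threshold
#'
#' Threshold for the fixed-sparsity strategy: `T_l` is the smallest
#' magnitude among the top-`p_n` fraction of patch entries ranked by
#' magnitude (lowest index first on ties), so entries at or above `T_l` form
#' the LTP set.
#'
#' @param x Patch vector (non-empty).
#' @param p_n Fraction in (0, 1) of entries to potentiate.
#'
#' @return The scalar threshold `T_l`.
#' @export
threshold_percentile <- function(x, p_n) {
  if (!length(x)) stop("`x` must be non-empty")
  if (!(p_n > 0 && p_n <= 1)) stop("`p_n` must lie in (0, 1]")
  n_top <- max(1L, ceiling(p_n * length(x)))
  a <- abs(x)
  top <- order(-a)[seq_len(n_top)]
  min(a[top])
}

#' Mean sign-corrected activation threshold
#'
#' Adaptive threshold of the recommended strategy: each patch entry is
#' sign-corrected by its synapse and the selected output,
#' `x_hat_i = x_i * sign(w_i) * sign(y)`, and `T_l` is the mean of `x_hat`.
#' Scaling the patch by any `c > 0` scales `T_l` by `c`, which makes the
#' resulting update invariant to local contrast.
#'
#' @param x Patch vector.
#' @param w Weight vector, same length as `x`.
#' @param y Selected (nonzero) output value.
#'
#' @return The scalar threshold `T_l`.
#' @export
threshold_mean_correlation <- function(x, w, y) {
  if (length(x) != length(w)) stop("`x` and `w` must have the same length")
  if (length(y) != 1L || y == 0) {
    stop("`y` must be a single nonzero selected output")
  }
  mean(x * sign(w) * sign(y))
}

#' Binary Hebbian weight update for one selected pair
#'
#' Element-wise update direction for one (patch, output) pair. With the
#' sign-corrected activation `x_hat_i = x_i * sign(y) * sign(w_i)`, a
#' synapse potentiates in its current direction (`+sign(w_i)`) when
#' `x_hat_i > T_l` -- the input drove the selected output through this
#' synapse more strongly than the adaptive threshold -- and depresses
#' (`-sign(w_i)`) otherwise. For any threshold `T_l >= 0` this reproduces
#' the classic six-cell LTP/LTD table: inputs beyond the threshold move the
#' weight toward `sign(x) * sign(y)`, inputs inside it decay the weight
#' toward zero.
#'
#' `sign(0)` is taken as 0: a zero input or weight carries no Hebbian
#' evidence and contributes 0.
#'
#' @param x Patch vector.
#' @param y Selected (nonzero) output.
#' @param w Weight vector, same length as `x`.
#' @param T_l Scalar LTP/LTD threshold (from [threshold_percentile()] or
#'   [threshold_mean_correlation()]).
#'
#' @return An update vector with entries in `{-1, 0, +1}` (0 only where a
#'   sign argument is exactly zero).
#' @seealso [delta_w_compact()] for the equivalent branch-free form.
#' @export
delta_w <- function(x, y, w, T_l) {
  if (length(x) != length(w)) stop("`x` and `w` must have the same length")
  if (length(y) != 1L || y == 0) stop("`y` must be a single nonzero output")
  x_hat <- x * sign(y) * sign(w)
  ifelse(x_hat > T_l, sign(w), -sign(w))
}

#' Branch-free form of the binary Hebbian update
#'
#' The same rule as [delta_w()] written as a single sign expression,
#' `sign(x_i * sign(y) * sign(w_i) - T_l) * sign(w_i)`, which avoids
#' conditional branching. Whenever no argument of `sign()` is exactly zero
#' this equals [delta_w()] elementwise.
#'
#' @inheritParams delta_w
#' @return An update vector with entries in `{-1, 0, +1}`.
#' @export
delta_w_compact <- function(x, y, w, T_l) {
  if (length(x) != length(w)) stop("`x` and `w` must have the same length")
  if (length(y) != 1L || y == 0) stop("`y` must be a single nonzero output")
  sign(x * sign(y) * sign(w) - T_l) * sign(w)
}

#' Aggregate per-pair updates over a batch
#'
#' Element-wise integer sum of the update vectors collected for one output
#' channel over a mini-batch. Order of summation is irrelevant and each
#' entry is bounded by the number of contributing pairs.
#'
#' @param deltas List of update vectors of equal length (possibly empty).
#' @param n_syn Vector length, required when `deltas` is empty.
#'
#' @return Integer-valued accumulator vector `U`.
#' @export
aggregate_batch <- function(deltas, n_syn = NULL) {
  if (!length(deltas)) {
    if (is.null(n_syn)) stop("`n_syn` needed for an empty delta list")
    return(numeric(n_syn))
  }
  len <- unique(vapply(deltas, length, integer(1)))
  if (length(len) != 1L) stop("all update vectors must have the same length")
  Reduce(`+`, deltas)
}

#' Binarize an aggregated update
#'
#' Maps the accumulator to a strict `{-1, +1}` update: `-1` where the summed
#' evidence is `<= 0`, `+1` where it is positive. Channels that selected no
#' patch in the batch should not be passed through this rule (they receive
#' no update at all); see [train_layer()].
#'
#' @param U Accumulator vector or matrix from [aggregate_batch()].
#'
#' @return Object of the same shape with entries in `{-1, +1}`.
#' @export
binarize_update <- function(U) {
  out <- ifelse(U > 0, 1, -1)
  if (!is.null(dim(U))) dim(out) <- dim(U)
  out
}

#' Apply a binary update to a weight bank
#'
#' Moves every weight by exactly `+/- lambda`.
#'
#' @param W Weight matrix (or column vector).
#' @param dW Binary update of the same shape, entries in `{-1, +1}`.
#' @param lam Learning rate (> 0).
#'
#' @return The updated weights.
#' @export
apply_update <- function(W, dW, lam) {
  stop_if_not_scalar(lam, "lam", positive = TRUE)
  if (length(W) != length(dW)) stop("`W` and `dW` shapes must match")
  W + lam * dW
}
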