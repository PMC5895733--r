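#' Score learned filters against the planted patterns
#'
#' Cosine similarity between every learned filter (weight-bank column) and
#' every planted template, computed after mean-centring both vectors.
#' Because a filter and its sign-flipped partner encode the same feature
#' (symmetric neurons), similarity is assessed as `|cosine|`. A greedy
#' assignment pairs filters with patterns in decreasing `|cosine|` order,
#' and the per-pattern best match over all filters is reported; the report
#' is invariant under filter sign flips and filter permutation.
#'
#' @param W Weight bank `(c_in * h * w, c_out)` or a `trained_layer`.
#' @param bank A [generate_pattern_bank()] whose template size matches the
#'   filter length.
#'
#' @return A list of class `recovery_report`: `similarity` (filters x
#'   patterns signed cosine matrix), `assignment` (data frame `filter`,
#'   `pattern`, `abs_cosine` from the greedy matching), and
#'   `pattern_best` (per-pattern max `|cosine|` over all filters).
#' @export
filter_pattern_similarity <- function(W, bank) {
  if (inherits(W, "trained_layer")) W <- W$W
  stopifnot(inherits(bank, "pattern_bank"), is.matrix(W))
  n_el <- prod(bank$shape)
  if (nrow(W) != n_el) {
    stop(sprintf("filter length %d does not match template size %d",
                 nrow(W), n_el))
  }
  k_f <- ncol(W)
  k_p <- length(bank$patterns)
  S <- matrix(NA_real_, k_f, k_p)
  for (i in seq_len(k_f)) {
    f <- W[, i] - mean(W[, i])
    for (j in seq_len(k_p)) {
      # flatten the template in weight-bank order: (channel, row, col),
      # col fastest
      p <- as.vector(aperm(bank$patterns[[j]], c(3, 2, 1)))
      S[i, j] <- cosine(f, p - mean(p))
    }
  }
  A <- abs(S)
  assignment <- data.frame(filter = integer(0), pattern = integer(0),
                           abs_cosine = numeric(0))
  Awork <- A
  for (step in seq_len(min(k_f, k_p))) {
    best <- which(Awork == max(Awork, na.rm = TRUE), arr.ind = TRUE)[1, ]
    assignment <- rbind(assignment, data.frame(
      filter = best[1], pattern = best[2],
      abs_cosine = A[best[1], best[2]]
    ))
    Awork[best[1], ] <- -Inf
    Awork[, best[2]] <- -Inf
  }
  structure(
    list(similarity = S,
         assignment = assignment[order(assignment$pattern), ],
         pattern_best = apply(A, 2, max)),
    class = "recovery_report"
  )
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("<recovery_report> per-pattern best |cosine|:\n")
  print(round(x$pattern_best, 3))
  invisible(x)
}

#' Fraction of first-layer weights inside an interval
#'
#' With unit-variance normalized columns and a learning rate of order 0.1,
#' most trained weights are expected to concentrate well inside the clip
#' range; this measures the fraction of first-layer weights in
#' `[lo, hi]`. Monotone in interval inclusion, and always 1 on `[-2, 2]`
#' because of clipping.
#'
#' @param model A `wtastdp_model`, `trained_layer`, or weight matrix.
#' @param lo,hi Interval bounds, `lo <= hi`.
#'
#' @return The fraction in `[0, 1]`.
#' @export
weight_interval_fraction <- function(model, lo = -1.5, hi = 1.5) {
  if (lo > hi) stop("`lo` must be <= `hi`")
  W <- if (inherits(model, "wtastdp_model")) {
    model$weights[[1]]
  } else if (inherits(model, "trained_layer")) {
    model$W
  } else {
    model
  }
  if (!length(W)) stop("model has no weights")
  mean(W >= lo & W <= hi)
}

#' Linear readout accuracy on labelled features
#'
#' Trains a seeded multinomial logistic regression on flattened feature
#' volumes with a held-out split and reports test accuracy. This is a
#' deliberately simple pluggable readout used to compare feature sets (for
#' example, STDP-learned filters against frozen random ones); any classifier
#' with the same fit/predict contract can be substituted via `fit_fun`.
#'
#' @param features Activation array `(N, C, H, W)` (or a matrix of `N`
#'   rows).
#' @param labels One label per image (>= 2 classes).
#' @param seed Integer seed controlling the train/test split.
#' @param train_frac Fraction of images used for fitting.
#' @param fit_fun Optional `function(x_train, y_train)` returning an object
#'   whose `predict(obj, x_test)` yields class labels; defaults to
#'   `nnet::multinom`.
#'
#' @return The held-out accuracy in `[0, 1]`, with attributes `n_train` and
#'   `n_test`.
#' @export
linear_readout <- function(features, labels, seed = 1L, train_frac = 0.6,
                           fit_fun = NULL) {
  X <- if (is.matrix(features)) features else
    matrix(features, nrow = dim(features)[1])
  y <- factor(labels)
  if (nrow(X) != length(y)) stop("one label per image is required")
  if (nlevels(y) < 2L) stop("labels must contain at least 2 classes")
  n <- nrow(X)
  idx <- with_seed(seed, sample.int(n, size = max(1L, round(train_frac * n))))
  test <- setdiff(seq_len(n), idx)
  if (!length(test)) stop("train_frac leaves no held-out images")
  if (is.null(fit_fun)) {
    fit_fun <- function(xt, yt) {
      df <- data.frame(.y = yt, xt)
      nnet::multinom(.y ~ ., data = df, trace = FALSE,
                     MaxNWts = max(1000L, (ncol(xt) + 2L) * (nlevels(yt) + 2L)),
                     maxit = 200)
    }
  }
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  fit <- fit_fun(X[idx, , drop = FALSE], y[idx])
  pred <- predict(fit, data.frame(X[test, , drop = FALSE]))
  acc <- mean(as.character(pred) == as.character(y[test]))
  attr(acc, "n_train") <- length(idx)
  attr(acc, "n_test") <- length(test)
  acc
}
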