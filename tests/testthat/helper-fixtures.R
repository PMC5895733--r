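# Shared fixtures, built in code at test time.

default_params <- function() lif_params(tau = 20, u_res = 0, theta = 1)

# Small labelled scatter batch for quick pipeline tests.
tiny_batch <- function(n = 5, seed = 3) {
  bank <- generate_pattern_bank(4, c(1, 5, 5), seed = 0)
  generate_images(bank, n, noise_sigma = 0.2, occurrences = 1,
                  canvas = c(12, 12), seed = seed)
}

# Study conditions for the pattern-recovery experiments: four 5x5 templates
# tiling a 10x10 canvas (2x2 cells), noise sigma 0.2.
recovery_bank <- function() generate_pattern_bank(4, c(1, 5, 5), seed = 0)

recovery_images <- function(n = 2000, seed = 11, noise_sigma = 0.2) {
  generate_images(recovery_bank(), n, noise_sigma = noise_sigma,
                  canvas = c(10, 10), placement = "tile", seed = seed)
}

recovery_spec <- function() layer_spec(1, 8, 5)

# Reference WTA implementation: slow per-slice loop used as an independent
# oracle for the vectorized operator. Ties resolve to the candidate with the
# lexicographically smallest index tuple over the competed axes (ascending
# axis order = channel, then row, then col priority).
wta_slow <- function(x, dims) {
  d <- dim(x)
  dims <- sort(dims)
  margin <- setdiff(seq_along(d), dims)
  res <- array(0, d)
  grid <- if (length(margin)) expand.grid(lapply(d[margin], seq_len))
          else data.frame(row.names = 1)
  cand <- expand.grid(lapply(d[dims], seq_len))
  for (g in seq_len(nrow(grid))) {
    best_val <- 0; best_idx <- NULL
    for (s in seq_len(nrow(cand))) {
      idx <- integer(length(d))
      if (length(margin)) idx[margin] <- as.integer(unlist(grid[g, ]))
      idx[dims] <- as.integer(unlist(cand[s, ]))
      v <- x[matrix(idx, 1)]
      better <- abs(v) > best_val ||
        (abs(v) == best_val && abs(v) > 0 &&
           !is.null(best_idx) &&
           paste(sprintf("%06d", idx[dims]), collapse = "") <
             paste(sprintf("%06d", best_idx[dims]), collapse = ""))
      if (better) { best_val <- abs(v); best_idx <- idx }
    }
    if (!is.null(best_idx) && best_val > 0) {
      res[matrix(best_idx, 1)] <- x[matrix(best_idx, 1)]
    }
  }
  res
}
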