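# Independent brute-force re-implementations of the feature scorers,
# written as naive loops so they share no code path with the package.

brute_t <- function(X, labels) {
  lv <- sort(unique(as.character(labels)))
  sapply(seq_len(ncol(X)), function(j) {
    x0 <- X[labels == lv[1], j]; x1 <- X[labels == lv[2], j]
    den <- sqrt(stats::var(x1) / length(x1) + stats::var(x0) / length(x0))
    if (den == 0) return(if (mean(x0) == mean(x1)) 0 else Inf)
    abs(mean(x0) - mean(x1)) / den
  })
}

brute_w <- function(X, labels) {
  lv <- sort(unique(as.character(labels)))
  sapply(seq_len(ncol(X)), function(j) {
    x0 <- X[labels == lv[1], j]; x1 <- X[labels == lv[2], j]
    den <- stats::sd(x1) + stats::sd(x0)
    if (den == 0) return(if (mean(x0) == mean(x1)) 0 else Inf)
    abs(mean(x0) - mean(x1)) / den
  })
}

brute_relief <- function(X, labels) {
  labels <- as.character(labels)
  n <- nrow(X)
  sapply(seq_len(ncol(X)), function(j) {
    total <- 0
    for (i in seq_len(n)) {
      best_hit <- Inf; best_miss <- Inf
      hit_val <- NA; miss_val <- NA
      for (o in seq_len(n)) {
        if (o == i) next
        d <- abs(X[o, j] - X[i, j])
        if (labels[o] == labels[i]) {
          if (d < best_hit) { best_hit <- d; hit_val <- X[o, j] }
        } else {
          if (d < best_miss) { best_miss <- d; miss_val <- X[o, j] }
        }
      }
      total <- total + abs(X[i, j] - miss_val) - abs(X[i, j] - hit_val)
    }
    total / n
  })
}

# hand-rolled exhaustive local-maximum scan (plateaus -> leftmost point)
brute_peaks <- function(y) {
  out <- integer(0)
  for (i in 2:(length(y) - 1)) {
    left <- y[i - 1]
    j <- i
    while (j < length(y) && y[j + 1] == y[i]) j <- j + 1
    if (j == length(y)) next        # plateau runs to the boundary
    if (y[i] > left && y[i] > y[j + 1] && (i == 2 || y[i] != y[i - 1]))
      out <- c(out, i)
  }
  out
}

# two-spectrum fixture on a tiny grid
tiny_set <- function(A = c(0, 2, 1, 3, 1), B = c(1, 0, 2, 1, 0),
                     grid = c(400, 410, 420, 430, 440),
                     labels = c("control", "trc")) {
  spectrum_set(rbind(A, B), grid, labels, c("S01/L01", "S09/L01"))
}

# fast, fully deterministic generator settings for unit tests
quiet_config <- function(...) {
  defaults <- list(grid_step = 4, n_control = 6L, n_trc = 4L,
                   n_samples_control = 3L, n_samples_trc = 2L,
                   intensity_jitter = 0, sample_effect_sd = 0,
                   shift_jitter = 0, noise_sd = 0, baseline_scale = 0)
  do.call(generator_config, utils::modifyList(defaults, list(...)))
}
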