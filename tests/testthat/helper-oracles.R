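# Independent brute-force oracles, deliberately naive (O(N*W) / O(N*P)),
# against which the package's filters and peak finder are checked exactly.

reflect_pad_oracle <- function(x, p) {
  n <- length(x)
  c(x[(p + 1):2], x, x[(n - 1):(n - p)])
}

# Naive running median with reflection padding.
oracle_running_median <- function(x, window) {
  half <- (window - 1) / 2
  padded <- reflect_pad_oracle(x, half)
  vapply(seq_along(x), function(i) {
    stats::median(padded[i:(i + window - 1)])
  }, numeric(1))
}

# Naive centered moving average with reflection padding.
oracle_moving_average <- function(x, points) {
  half <- (points - 1) / 2
  padded <- reflect_pad_oracle(x, half)
  vapply(seq_along(x), function(i) {
    mean(padded[i:(i + points - 1)])
  }, numeric(1))
}

oracle_background <- function(x, window, ma_points) {
  oracle_moving_average(oracle_running_median(x, window), ma_points)
}

# Brute-force peak scan: strict local maxima above threshold, with
# full-trace prominence scans and highest-first minimum-separation pruning.
# Returns apex indices sorted ascending.
oracle_find_peaks <- function(x, threshold, prominence_fraction, min_separation) {
  n <- length(x)
  if (n < 3) return(integer(0))
  apex <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] > x[3:n]) + 1L
  apex <- apex[x[apex] >= threshold]
  keep <- logical(length(apex))
  for (k in seq_along(apex)) {
    i <- apex[k]
    v <- x[i]
    higher_left <- which(x[seq_len(i - 1)] > v)
    lo <- if (length(higher_left) > 0) max(higher_left) else 0L
    left_min <- if (i > 1) min(x[max(1L, lo + 1L):(i - 1)]) else v
    if (lo == 0L && i == 1L) left_min <- v
    higher_right <- which(x[(i + 1):n] > v) + i
    hi <- if (length(higher_right) > 0) min(higher_right) else n + 1L
    right_min <- if (i < n) min(x[(i + 1):min(n, hi - 1L)]) else v
    prom <- v - max(left_min, right_min)
    keep[k] <- prom >= prominence_fraction * threshold
  }
  apex <- apex[keep]
  if (length(apex) > 1 && min_separation > 1) {
    ord <- order(x[apex], decreasing = TRUE)
    kept <- integer(0)
    for (k in ord) {
      if (length(kept) == 0 || all(abs(apex[kept] - apex[k]) >= min_separation)) {
        kept <- c(kept, k)
      }
    }
    apex <- sort(apex[kept])
  }
  apex
}
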