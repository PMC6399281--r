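# Internal helpers shared across modules. All filters use reflection padding
# at the edges (pad does not repeat the edge sample).

pad_reflect <- function(x, p) {
  n <- length(x)
  if (p <= 0) return(x)
  if (p >= n) stop("reflection pad length must be shorter than the series", call. = FALSE)
  c(x[(p + 1):2], x, x[(n - 1):(n - p)])
}

# Centered moving average of an odd number of points, reflection-padded so
# output length equals input length.
moving_average <- function(x, points) {
  stopifnot(points >= 1)
  if (points %% 2 == 0) stop("moving-average window must be an odd number of points", call. = FALSE)
  if (points == 1) return(x)
  half <- (points - 1) / 2
  padded <- pad_reflect(x, half)
  out <- stats::filter(padded, rep(1 / points, points), sides = 2)
  as.numeric(out[(half + 1):(half + length(x))])
}

# Running median with an odd window, reflection-padded. Uses the C
# implementation in stats::runmed on the padded series.
running_median <- function(x, window) {
  stopifnot(window >= 1)
  if (window %% 2 == 0) stop("median window must be an odd number of samples", call. = FALSE)
  if (window == 1) return(x)
  if (length(x) < window) stop("trace is shorter than the median-filter window", call. = FALSE)
  half <- (window - 1) / 2
  padded <- pad_reflect(x, half)
  out <- stats::runmed(padded, window, endrule = "keep")
  as.numeric(out[(half + 1):(half + length(x))])
}

odd_window_samples <- function(seconds, sample_rate) {
  k <- max(1L, as.integer(round(seconds * sample_rate)))
  if (k %% 2L == 0L) k <- k + 1L
  k
}

# Column names of the channel series in a trace tibble (everything but time).
trace_channels <- function(trace) {
  setdiff(names(trace), "time_s")
}

check_trace <- function(trace) {
  if (!is.data.frame(trace) || !"time_s" %in% names(trace) || length(trace_channels(trace)) < 1) {
    stop("trace must be a data frame with a 'time_s' column and at least one channel column",
         call. = FALSE)
  }
  invisible(trace)
}

trace_sample_rate <- function(trace) {
  sr <- attr(trace, "sample_rate")
  if (!is.null(sr)) return(sr)
  dt <- diff(trace$time_s[seq_len(min(nrow(trace), 1000L))])
  1 / stats::median(dt)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
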