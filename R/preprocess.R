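#' Preprocessing configuration
#'
#' Parameters for background estimation, smoothing, and inter-channel
#' normalization. Defaults follow the instrument's processing chain: the
#' autofluorescence background is estimated with a 2.5 s running median
#' followed by a 7-point moving average, the background-subtracted signal is
#' smoothed with a 3-point (3 ms at 1 kHz) moving average, and channel 2 is
#' rescaled to channel 1 to correct for coupling-efficiency differences.
#'
#' @param median_window Running-median window, seconds (default 2.5).
#' @param background_ma_points Moving-average applied to the median-filtered
#'   background, points (odd; default 7).
#' @param smooth_ma_points Moving-average applied after background
#'   subtraction, points (odd; default 3 = 3 ms at 1 kHz).
#' @param normalize Whether [preprocess_scan()] rescales channel 2 to
#'   channel 1.
#' @return A list of class `difc_preprocess_config`.
#' @export
preprocess_config <- function(median_window = 2.5,
                              background_ma_points = 7,
                              smooth_ma_points = 3,
                              normalize = TRUE) {
  if (median_window <= 0) stop("median_window must be positive", call. = FALSE)
  if (background_ma_points %% 2 == 0 || smooth_ma_points %% 2 == 0) {
    stop("moving-average point counts must be odd", call. = FALSE)
  }
  structure(
    list(median_window = median_window,
         background_ma_points = background_ma_points,
         smooth_ma_points = smooth_ma_points,
         normalize = normalize),
    class = "difc_preprocess_config"
  )
}

#' Estimate the autofluorescence background of a trace
#'
#' Applies a running median (window `median_window` seconds, rounded to an
#' odd sample count) followed by a centered `background_ma_points`-point
#' moving average to each channel. Both filters use reflection padding, so
#' the output has the same length as the input. The long median window
#' rejects cell-transit pulses (~10 ms) while tracking slow drift.
#'
#' @param trace Trace tibble (`time_s` plus one column per channel).
#' @param cfg A [preprocess_config()].
#' @param sample_rate Sampling rate in Hz; taken from the trace's
#'   `sample_rate` attribute (or estimated from `time_s`) when `NULL`.
#' @return A tibble of the same shape as `trace` holding the background of
#'   each channel.
#' @export
estimate_background <- function(trace, cfg = preprocess_config(), sample_rate = NULL) {
  check_trace(trace)
  sr <- sample_rate %||% trace_sample_rate(trace)
  k <- odd_window_samples(cfg$median_window, sr)
  if (nrow(trace) < k) {
    stop("trace (", nrow(trace), " samples) is shorter than the median window (",
         k, " samples)", call. = FALSE)
  }
  out <- trace
  for (col in trace_channels(trace)) {
    bg <- running_median(trace[[col]], k)
    out[[col]] <- moving_average(bg, cfg$background_ma_points)
  }
  attr(out, "sample_rate") <- sr
  out
}

#' Subtract the background and smooth the residual signal
#'
#' Pointwise subtraction of the estimated background followed by a centered
#' `smooth_ma_points`-point moving average (reflection-padded edges).
#'
#' @param trace Raw trace tibble.
#' @param background Background tibble from [estimate_background()] (same
#'   shape as `trace`).
#' @param cfg A [preprocess_config()].
#' @return A processed trace tibble (same columns; channel values are now
#'   background-subtracted, smoothed currents in nA).
#' @export
subtract_and_smooth <- function(trace, background, cfg = preprocess_config()) {
  check_trace(trace)
  if (nrow(trace) != nrow(background)) {
    stop("trace and background lengths differ (", nrow(trace), " vs ",
         nrow(background), ")", call. = FALSE)
  }
  out <- trace
  for (col in trace_channels(trace)) {
    if (!col %in% names(background)) {
      stop("background is missing channel column '", col, "'", call. = FALSE)
    }
    out[[col]] <- moving_average(trace[[col]] - background[[col]], cfg$smooth_ma_points)
  }
  attr(out, "sample_rate") <- attr(trace, "sample_rate") %||% trace_sample_rate(trace)
  out
}

#' Normalize channel 2 amplitude to channel 1
#'
#' Corrects for minor differences in probe coupling efficiency. Provisional
#' peak candidates are detected on both channels at `provisional_threshold`;
#' channel 2 is multiplied by `s = median(candidate amplitudes on ch1) /
#' median(on ch2)`. If either channel has fewer than 5 provisional
#' candidates, the scale falls back to the ratio of mean backgrounds
#' (`background` must then be supplied).
#'
#' @param trace Processed two-channel trace tibble (`ch1_nA`, `ch2_nA`).
#' @param provisional_threshold Detection threshold for provisional
#'   candidates, nA.
#' @param background Optional background tibble, used by the fallback.
#' @param cfg Detection configuration for the provisional candidate search.
#' @return The trace with channel 2 rescaled; the applied factor is stored in
#'   the `scale_factor` attribute.
#' @export
normalize_channels <- function(trace, provisional_threshold = 250,
                               background = NULL,
                               cfg = detection_config(threshold = provisional_threshold)) {
  check_trace(trace)
  chans <- trace_channels(trace)
  if (length(chans) != 2) stop("normalization requires exactly two channels", call. = FALSE)
  cfg$threshold <- provisional_threshold
  cand <- find_candidates(trace, cfg)
  a1 <- cand$amp_nA[cand$channel == 1]
  a2 <- cand$amp_nA[cand$channel == 2]
  if (length(a1) >= 5 && length(a2) >= 5) {
    denom <- stats::median(a2)
    if (denom == 0) stop("channel-2 median candidate amplitude is zero", call. = FALSE)
    s <- stats::median(a1) / denom
  } else {
    if (is.null(background)) {
      stop("fewer than 5 provisional candidates on a channel and no background ",
           "supplied for the fallback scale", call. = FALSE)
    }
    denom <- mean(background[[chans[2]]])
    if (denom == 0) stop("channel-2 mean background is zero", call. = FALSE)
    s <- mean(background[[chans[1]]]) / denom
  }
  out <- trace
  out[[chans[2]]] <- trace[[chans[2]]] * s
  attr(out, "sample_rate") <- attr(trace, "sample_rate") %||% trace_sample_rate(trace)
  attr(out, "scale_factor") <- s
  out
}

#' Full preprocessing chain for a scan
#'
#' Background estimation, subtraction + smoothing, and (optionally)
#' channel-2 amplitude normalization, in one call.
#'
#' @inheritParams estimate_background
#' @param provisional_threshold Threshold (nA) for the provisional candidates
#'   used by normalization.
#' @return The processed trace tibble with attributes `background` (tibble),
#'   `scale_factor` (1 when normalization is off), and `sample_rate`.
#' @examples
#' scan <- simulate_scan(sim_config(duration = 20, concentration = 200, seed = 2))
#' proc <- preprocess_scan(scan$trace)
#' attr(proc, "scale_factor")
#' @export
preprocess_scan <- function(trace, cfg = preprocess_config(),
                            provisional_threshold = 250, sample_rate = NULL) {
  bg <- estimate_background(trace, cfg, sample_rate = sample_rate)
  proc <- subtract_and_smooth(trace, bg, cfg)
  s <- 1
  if (isTRUE(cfg$normalize) && length(trace_channels(trace)) == 2) {
    proc <- normalize_channels(proc, provisional_threshold, background = bg)
    s <- attr(proc, "scale_factor")
  }
  attr(proc, "background") <- bg
  attr(proc, "scale_factor") <- s
  proc
}
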