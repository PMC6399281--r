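#' Plot a trace with optional detected candidates
#'
#' @param trace Trace tibble (raw or preprocessed).
#' @param candidates Optional candidate tibble from [find_candidates()];
#'   apexes are marked.
#' @param xlim Optional time window, seconds.
#' @return A ggplot object (channels faceted).
#' @export
plot_trace <- function(trace, candidates = NULL, xlim = NULL) {
  check_trace(trace)
  long <- tidyr::pivot_longer(trace, -"time_s",
                              names_to = "channel", values_to = "current_nA")
  if (!is.null(xlim)) {
    long <- dplyr::filter(long, .data$time_s >= xlim[1], .data$time_s <= xlim[2])
  }
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$time_s, .data$current_nA)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~channel, ncol = 1) +
    ggplot2::labs(x = "time (s)", y = "current (nA)")
  if (!is.null(candidates) && nrow(candidates) > 0) {
    chans <- trace_channels(trace)
    cand <- dplyr::mutate(candidates, channel = chans[.data$channel])
    if (!is.null(xlim)) {
      cand <- dplyr::filter(cand, .data$t_s >= xlim[1], .data$t_s <= xlim[2])
    }
    p <- p + ggplot2::geom_point(
      data = cand,
      ggplot2::aes(.data$t_s, .data$amp_nA),
      colour = "red", shape = 4
    )
  }
  p
}

#' Plot amplitude and speed distributions of matched events
#'
#' @param object A `difc_match` result.
#' @param ... Unused.
#' @return A ggplot object: amplitude and consensus-speed histograms split by
#'   flow direction.
#' @method autoplot difc_match
#' @export
autoplot.difc_match <- function(object, ...) {
  ev <- object$events
  if (nrow(ev) == 0) stop("no matched events to plot", call. = FALSE)
  long <- dplyr::bind_rows(
    tibble::tibble(direction = ev$direction, quantity = "mean amplitude (nA)",
                   value = (ev$amp1_nA + ev$amp2_nA) / 2),
    tibble::tibble(direction = ev$direction, quantity = "consensus speed (mm/s)",
                   value = ev$v_consensus)
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$value, fill = .data$direction)) +
    ggplot2::geom_histogram(bins = 30, position = "identity", alpha = 0.6) +
    ggplot2::facet_wrap(~quantity, scales = "free") +
    ggplot2::labs(x = NULL, y = "events")
}

#' Plot a false-alarm-rate threshold sweep
#'
#' @param far Tibble from [matched_far()].
#' @return A ggplot object comparing single-fiber and matched rates versus
#'   threshold (log-10 rate axis; zero rates are shown at the axis floor).
#' @export
plot_far_sweep <- function(far) {
  long <- tidyr::pivot_longer(
    far[, c("threshold_nA", "single_rate_per_min", "matched_rate_per_min")],
    -"threshold_nA", names_to = "mode", values_to = "rate_per_min"
  )
  floor_rate <- max(min(long$rate_per_min[long$rate_per_min > 0], na.rm = TRUE) / 10,
                    1e-4)
  long$rate_per_min <- pmax(long$rate_per_min, floor_rate)
  ggplot2::ggplot(long, ggplot2::aes(.data$threshold_nA, .data$rate_per_min,
                                     colour = .data$mode)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "detection threshold (nA)", y = "false-alarm rate (1/min)")
}
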