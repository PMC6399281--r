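#' Detection signal-to-noise ratio in dB
#'
#' `SNR = 20 log10(I / sigma)` where `I` is the (mean) peak amplitude and
#' `sigma` the system noise standard deviation, both in nA.
#'
#' @param amplitude Peak amplitude(s), nA (> 0).
#' @param sigma Noise standard deviation, nA (> 0).
#' @return SNR in dB.
#' @examples
#' snr_db(503, 40)  # ~22.0 dB
#' @export
snr_db <- function(amplitude, sigma) {
  if (any(amplitude <= 0) || any(sigma <= 0)) {
    stop("amplitude and sigma must be positive", call. = FALSE)
  }
  20 * log10(amplitude / sigma)
}

#' Convert between count rate and circulating-cell concentration
#'
#' The instrument interrogates a fixed blood volume per unit time (the
#' sampling rate, ~0.284 mL/min in the calibrated system), so a count rate
#' divides by it to give a concentration and vice versa. The two functions
#' are exact inverses.
#'
#' @param count_rate Detected cells per minute.
#' @param concentration Cells per mL.
#' @param sampling_rate Sampled blood volume per minute, mL/min.
#' @return `concentration_from_rate()`: cells/mL; `rate_from_concentration()`:
#'   counts/min.
#' @examples
#' concentration_from_rate(10, 0.283)  # ~35 cells/mL
#' @export
concentration_from_rate <- function(count_rate, sampling_rate = 0.284) {
  if (any(sampling_rate <= 0)) stop("sampling_rate must be positive", call. = FALSE)
  count_rate / sampling_rate
}

#' @rdname concentration_from_rate
#' @export
rate_from_concentration <- function(concentration, sampling_rate = 0.284) {
  if (any(sampling_rate <= 0)) stop("sampling_rate must be positive", call. = FALSE)
  concentration * sampling_rate
}

#' Sampling rate implied by the count interval at unit concentration
#'
#' If a concentration of 1 cell/mL yields one count every
#' `minutes_per_count` minutes, the sampled volume per minute is
#' `1 / minutes_per_count` mL/min (e.g. one count every 3.52 min implies
#' 0.284 mL/min, i.e. 284 uL/min).
#'
#' @param minutes_per_count Minutes between counts at 1 cell/mL.
#' @return Sampling rate, mL/min.
#' @export
sampling_rate_from_count_interval <- function(minutes_per_count) {
  if (any(minutes_per_count <= 0)) {
    stop("minutes_per_count must be positive", call. = FALSE)
  }
  1 / minutes_per_count
}

#' Volumetric flow rate of a cylindrical vessel under plug flow
#'
#' `pi * (diameter / 2)^2 * speed`, with mm and mm/s in, microliters/second
#' out (1 mm^3 = 1 uL).
#'
#' @param speed Flow speed, mm/s.
#' @param diameter Vessel diameter, mm.
#' @return Flow rate, uL/s.
#' @examples
#' vessel_flow_rate(112.3, 0.25)  # ~5.5 uL/s
#' @export
vessel_flow_rate <- function(speed, diameter) {
  if (any(speed <= 0) || any(diameter <= 0)) {
    stop("speed and diameter must be positive", call. = FALSE)
  }
  pi * (diameter / 2)^2 * speed
}

#' Bin a scan into count-rate intervals with per-direction statistics
#'
#' @param match A `difc_match` result.
#' @param candidates The candidate tibble the match was built from.
#' @param interval Bin width, seconds (> 0).
#' @param duration Scan duration, seconds; defaults to the candidates'
#'   `duration` attribute.
#' @return A tibble with one row per bin: candidate counts per channel,
#'   forward/reverse event counts, matched fractions (fraction of the bin's
#'   candidates consumed by events of each direction), and mean amplitude,
#'   FWHM and consensus speed per direction (NA for empty bins, with
#'   `empty_forward` / `empty_reverse` flags).
#' @export
summarize_scan <- function(match, candidates, interval, duration = NULL) {
  if (interval <= 0) stop("interval must be positive", call. = FALSE)
  duration <- duration %||% attr(candidates, "duration") %||% match$duration
  if (is.null(duration)) stop("scan duration unknown; supply `duration`", call. = FALSE)
  n_bins <- max(1L, as.integer(ceiling(duration / interval - 1e-9)))
  breaks <- interval * (0:n_bins)
  bin_of <- function(t) pmin(findInterval(t, breaks), length(breaks) - 1L)
  ev <- match$events
  ev_bin <- bin_of(pmin(ev$t1_s, ev$t2_s))
  cand_bin <- bin_of(candidates$t_s)
  purrr::map_dfr(seq_len(length(breaks) - 1L), function(b) {
    in_ev <- ev[ev_bin == b, ]
    fwd <- in_ev[in_ev$direction == "forward", ]
    rev <- in_ev[in_ev$direction == "reverse", ]
    n1 <- sum(cand_bin == b & candidates$channel == 1)
    n2 <- sum(cand_bin == b & candidates$channel == 2)
    nc <- n1 + n2
    dir_stats <- function(e) {
      if (nrow(e) == 0) {
        tibble::tibble(mean_amp_nA = NA_real_, mean_fwhm_ms = NA_real_,
                       mean_speed_mm_s = NA_real_)
      } else {
        tibble::tibble(
          mean_amp_nA = mean(c(e$amp1_nA, e$amp2_nA)),
          mean_fwhm_ms = mean(c(e$fwhm1_s, e$fwhm2_s)) * 1000,
          mean_speed_mm_s = mean(e$v_consensus)
        )
      }
    }
    sf <- dir_stats(fwd)
    sr <- dir_stats(rev)
    tibble::tibble(
      bin_start_s = breaks[b],
      counts_ch1 = n1, counts_ch2 = n2,
      counts_forward = nrow(fwd), counts_reverse = nrow(rev),
      matched_fraction_forward = if (nc > 0) 2 * nrow(fwd) / nc else NA_real_,
      matched_fraction_reverse = if (nc > 0) 2 * nrow(rev) / nc else NA_real_,
      mean_amp_forward_nA = sf$mean_amp_nA,
      mean_amp_reverse_nA = sr$mean_amp_nA,
      mean_fwhm_forward_ms = sf$mean_fwhm_ms,
      mean_fwhm_reverse_ms = sr$mean_fwhm_ms,
      mean_speed_forward_mm_s = sf$mean_speed_mm_s,
      mean_speed_reverse_mm_s = sr$mean_speed_mm_s,
      empty_forward = nrow(fwd) == 0,
      empty_reverse = nrow(rev) == 0
    )
  })
}

#' False-alarm rate of the full pipeline versus detection threshold
#'
#' Runs preprocessing, detection and matching on a (presumed cell-free)
#' two-channel trace at each threshold and reports the single-fiber candidate
#' rate alongside the matched-event rate. On control data the matched rate is
#' the pipeline's false-alarm rate; coincidence rejection and the similarity
#' gate typically push it well below the single-fiber rate.
#'
#' @param trace Raw two-channel trace tibble.
#' @param thresholds Thresholds to sweep, nA.
#' @param pre_cfg,det_cfg,match_cfg Stage configurations.
#' @param preprocessed Set `TRUE` when `trace` is already preprocessed.
#' @return A tibble with `threshold_nA`, `single_rate_per_min` (candidate
#'   rate averaged over the two channels), `matched_rate_per_min`
#'   (forward + reverse events per minute), and the underlying counts.
#' @export
matched_far <- function(trace, thresholds,
                        pre_cfg = preprocess_config(),
                        det_cfg = detection_config(),
                        match_cfg = match_config(),
                        preprocessed = FALSE) {
  if (length(thresholds) == 0) stop("thresholds must be non-empty", call. = FALSE)
  check_trace(trace)
  sr <- trace_sample_rate(trace)
  duration_min <- nrow(trace) / sr / 60
  proc <- if (preprocessed) trace else {
    pre_cfg$normalize <- FALSE  # no pulses to normalize on in a control scan
    preprocess_scan(trace, pre_cfg)
  }
  purrr::map_dfr(sort(thresholds), function(th) {
    cfg_th <- det_cfg
    cfg_th$threshold <- th
    cand <- find_candidates(proc, cfg_th, sample_rate = sr)
    m <- match_candidates(cand, match_cfg, sample_rate = sr)
    tibble::tibble(
      threshold_nA = th,
      n_candidates_ch1 = sum(cand$channel == 1),
      n_candidates_ch2 = sum(cand$channel == 2),
      n_matched = nrow(m$events),
      single_rate_per_min = nrow(cand) / 2 / duration_min,
      matched_rate_per_min = nrow(m$events) / duration_min
    )
  })
}

#' Synthetic depth-to-field-of-view sensitivity profile
#'
#' A monotone table mapping tissue depth (mm) to the effective field-of-view
#' FWHM (mm) seen by the probe, for use with [depth_from_event()]. Diffuse
#' probes collect light from roughly the first 2 mm of tissue and the FOV
#' broadens with depth; this table is a synthetic linear approximation
#' anchored so that a 1.29 mm FOV corresponds to 1.1 mm depth. Replace it
#' with a Monte Carlo-derived table for quantitative work on a specific
#' probe geometry.
#'
#' @return A tibble with columns `depth_mm` (0 to 2) and `fov_fwhm_mm`,
#'   strictly increasing in both.
#' @export
difc_sensitivity_profile <- function() {
  depth <- seq(0, 2, by = 0.1)
  tibble::tibble(depth_mm = depth, fov_fwhm_mm = 0.6 + (0.69 / 1.1) * depth)
}

#' Estimate signal depth from mean peak width and speed
#'
#' The product of the mean temporal FWHM and the mean cell speed is the
#' effective field-of-view FWHM; inverting a monotone depth-to-FOV
#' sensitivity profile (by linear interpolation) yields the depth of origin
#' of the signals. A FOV outside the profile's range is clamped to the
#' nearest table endpoint with a warning.
#'
#' @param mean_fwhm Mean peak FWHM, seconds.
#' @param mean_speed Mean cell speed, mm/s.
#' @param profile Sensitivity table with columns `depth_mm`, `fov_fwhm_mm`
#'   (see [difc_sensitivity_profile()]).
#' @return Estimated depth, mm, with the implied FOV attached as the
#'   `fov_mm` attribute.
#' @examples
#' depth_from_event(0.0115, 112.3)  # ~1.1 mm
#' @export
depth_from_event <- function(mean_fwhm, mean_speed, profile = difc_sensitivity_profile()) {
  if (!all(c("depth_mm", "fov_fwhm_mm") %in% names(profile))) {
    stop("profile must have columns depth_mm and fov_fwhm_mm", call. = FALSE)
  }
  if (is.unsorted(profile$depth_mm, strictly = TRUE) ||
      is.unsorted(profile$fov_fwhm_mm, strictly = TRUE)) {
    stop("sensitivity profile must be strictly increasing", call. = FALSE)
  }
  fov <- mean_fwhm * mean_speed
  rng <- range(profile$fov_fwhm_mm)
  if (fov < rng[1] || fov > rng[2]) {
    warning("FOV ", signif(fov, 4), " mm outside the profile range [",
            signif(rng[1], 4), ", ", signif(rng[2], 4), "]; clamping")
    fov <- min(max(fov, rng[1]), rng[2])
  }
  depth <- stats::approx(profile$fov_fwhm_mm, profile$depth_mm, xout = fov)$y
  attr(depth, "fov_mm") <- fov
  depth
}

#' Linear calibration of count rate against known cell burden
#'
#' Ordinary least-squares fit of the per-animal count rate on the measured
#' blood concentration; the slope estimates the instrument's sampling rate
#' (mL/min) and r-squared is the squared Pearson correlation.
#'
#' @param data Data frame with one row per animal/sample.
#' @param concentration,count_rate Column names (unquoted) of the cell
#'   concentration (cells/mL) and count rate (counts/min).
#' @return An object of class `difc_calibration` with [tidy()] and
#'   [glance()] methods.
#' @export
calibration_regression <- function(data, concentration = concentration,
                                   count_rate = count_rate) {
  x <- dplyr::pull(data, {{ concentration }})
  y <- dplyr::pull(data, {{ count_rate }})
  if (length(x) < 3) stop("at least 3 points are required", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("degenerate input: zero variance in concentration or count rate", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  structure(
    list(fit = fit,
         slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r_squared = stats::cor(x, y)^2,
         n = length(x)),
    class = "difc_calibration"
  )
}

#' @export
print.difc_calibration <- function(x, ...) {
  cat("<difc_calibration> slope =", signif(x$slope, 4),
      "mL/min, intercept =", signif(x$intercept, 4),
      ", r^2 =", signif(x$r_squared, 3), ", n =", x$n, "\n")
  invisible(x)
}

#' Tidy a calibration regression
#'
#' @param x A [calibration_regression()] object.
#' @param ... Unused.
#' @return A tibble of coefficient estimates with standard errors.
#' @method tidy difc_calibration
#' @export
tidy.difc_calibration <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = unname(s[, "Estimate"]),
    std_error = unname(s[, "Std. Error"]),
    statistic = unname(s[, "t value"]),
    p_value = unname(s[, "Pr(>|t|)"])
  )
}

#' @rdname tidy.difc_calibration
#' @return `glance()`: a one-row tibble with `slope`, `intercept`,
#'   `r_squared`, `n`.
#' @method glance difc_calibration
#' @export
glance.difc_calibration <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 r_squared = x$r_squared, n = x$n)
}
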