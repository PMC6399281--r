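#' Detection configuration
#'
#' @param threshold Detection threshold on the preprocessed signal, nA
#'   (default 250, the calibrated counting threshold for CTFR-labeled cells).
#' @param prominence_fraction Minimum topographic prominence as a fraction of
#'   the threshold (default 0.5).
#' @param fov_fwhm Detector field-of-view FWHM, mm; divides the peak temporal
#'   FWHM to give the width-derived speed.
#' @param min_separation Minimum apex separation between candidates, samples.
#' @return A list of class `difc_detection_config`.
#' @export
detection_config <- function(threshold = 250,
                             prominence_fraction = 0.5,
                             fov_fwhm = 1.1,
                             min_separation = 3) {
  if (threshold <= 0) stop("threshold must be positive", call. = FALSE)
  if (prominence_fraction <= 0 || prominence_fraction > 1) {
    stop("prominence_fraction must lie in (0, 1]", call. = FALSE)
  }
  structure(
    list(threshold = threshold, prominence_fraction = prominence_fraction,
         fov_fwhm = fov_fwhm, min_separation = min_separation),
    class = "difc_detection_config"
  )
}

# Local maxima of x, plateau-aware: a run of equal values counts as one
# maximum with its apex at the middle sample. Returns integer indices.
local_maxima <- function(x) {
  r <- rle(x)
  nruns <- length(r$values)
  if (nruns < 3) return(integer(0))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  j <- 2:(nruns - 1)
  is_max <- r$values[j] > r$values[j - 1] & r$values[j] > r$values[j + 1]
  j <- j[is_max]
  as.integer(starts[j] + (r$lengths[j] - 1L) %/% 2L)
}

# Topographic prominence of the peak at index `apex`: walk outward on each
# side until a strictly higher sample (or the trace edge), tracking the
# minimum; prominence = peak - max(left min, right min). Chunked so the walk
# runs at vectorized speed.
peak_prominence <- function(x, apex, chunk = 4096L) {
  v <- x[apex]
  n <- length(x)
  side_min <- function(from, step) {
    m <- v
    i <- from
    while ((step > 0 && i <= n) || (step < 0 && i >= 1)) {
      j <- if (step > 0) min(n, i + chunk - 1L) else max(1L, i - chunk + 1L)
      seg <- if (step > 0) x[i:j] else x[j:i]
      if (step < 0) seg <- rev(seg)   # walk order: outward from the apex
      hit <- which(seg > v)
      if (length(hit) > 0) {
        if (hit[1] > 1) m <- min(m, seg[seq_len(hit[1] - 1L)])
        return(m)
      }
      m <- min(m, seg)
      i <- if (step > 0) j + 1L else j - 1L
    }
    m
  }
  left <- if (apex > 1) side_min(apex - 1L, -1L) else v
  right <- if (apex < n) side_min(apex + 1L, 1L) else v
  v - max(left, right)
}

# Enforce a minimum apex separation: process peaks from highest to lowest,
# dropping any peak within min_sep samples of an already-kept higher peak.
enforce_min_separation <- function(apexes, heights, min_sep) {
  if (length(apexes) <= 1 || min_sep <= 1) return(sort(apexes))
  ord <- order(heights, decreasing = TRUE)
  kept <- integer(0)
  for (i in ord) {
    if (length(kept) == 0 || all(abs(apexes[kept] - apexes[i]) >= min_sep)) {
      kept <- c(kept, i)
    }
  }
  sort(apexes[kept])
}

# Interpolated FWHM of the peak at `apex`, half-maximum relative to zero
# baseline. The crossing search on each side is bounded by the adjacent kept
# apex (or the trace edge). Returns list(fwhm, flagged): an unresolved side
# uses twice the resolved side and sets the flag; both unresolved gives NA.
peak_fwhm <- function(x, apex, left_bound, right_bound) {
  half <- x[apex] / 2
  cross <- function(idx_out) {
    # idx_out: indices walking outward from the apex (excluding it)
    if (length(idx_out) == 0) return(NA_real_)
    below <- which(x[idx_out] < half)
    if (length(below) == 0) return(NA_real_)
    b <- below[1]                      # first sample below half-max
    i_in <- if (b == 1) apex else idx_out[b - 1]
    i_out <- idx_out[b]
    # linear interpolation between the bracketing samples
    frac <- (x[i_in] - half) / (x[i_in] - x[i_out])
    abs(i_out - i_in) * frac + abs(i_in - apex)
  }
  left_idx <- if (apex - 1 >= left_bound) (apex - 1):left_bound else integer(0)
  right_idx <- if (apex + 1 <= right_bound) (apex + 1):right_bound else integer(0)
  wl <- cross(left_idx)
  wr <- cross(right_idx)
  if (is.na(wl) && is.na(wr)) return(list(fwhm = NA_real_, flagged = TRUE))
  if (is.na(wl)) return(list(fwhm = 2 * wr, flagged = TRUE))
  if (is.na(wr)) return(list(fwhm = 2 * wl, flagged = TRUE))
  list(fwhm = wl + wr, flagged = FALSE)
}

find_candidates_channel <- function(x, sample_rate, t0, channel, cfg) {
  apexes <- local_maxima(x)
  apexes <- apexes[x[apexes] >= cfg$threshold]
  if (length(apexes) > 0) {
    prom <- vapply(apexes, function(a) peak_prominence(x, a), numeric(1))
    apexes <- apexes[prom >= cfg$prominence_fraction * cfg$threshold]
  }
  apexes <- enforce_min_separation(apexes, x[apexes], cfg$min_separation)
  np <- length(apexes)
  if (np == 0) {
    return(tibble::tibble(channel = integer(), t_s = numeric(), amp_nA = numeric(),
                          fwhm_s = numeric(), v_mm_s = numeric(),
                          fwhm_flagged = logical()))
  }
  bounds_l <- c(1L, apexes[-np] + 1L)
  bounds_r <- c(apexes[-1] - 1L, length(x))
  fw <- lapply(seq_len(np), function(i) {
    peak_fwhm(x, apexes[i], bounds_l[i], bounds_r[i])
  })
  fwhm_s <- vapply(fw, function(z) z$fwhm, numeric(1)) / sample_rate
  tibble::tibble(
    channel = as.integer(channel),
    t_s = t0 + (apexes - 1) / sample_rate,
    amp_nA = x[apexes],
    fwhm_s = fwhm_s,
    v_mm_s = cfg$fov_fwhm / fwhm_s,
    fwhm_flagged = vapply(fw, function(z) z$flagged, logical(1))
  )
}

#' Find cell-candidate peaks on a preprocessed trace
#'
#' Searches each channel for local maxima with amplitude at or above the
#' detection threshold and topographic prominence of at least
#' `prominence_fraction * threshold`, separated by at least `min_separation`
#' samples (the higher peak wins). Each candidate's FWHM is measured by
#' linear interpolation of the half-maximum crossings on either side of the
#' apex (half-maximum relative to the zero baseline of the preprocessed
#' signal); the search for a crossing is bounded by the adjacent candidate
#' apex, and a side whose crossing cannot be resolved (merged shoulder) uses
#' twice the resolved side and sets `fwhm_flagged`. The width-derived speed
#' is `fov_fwhm / fwhm`.
#'
#' @param trace Preprocessed trace tibble (one or two channel columns).
#' @param cfg A [detection_config()].
#' @param sample_rate Hz; defaults to the trace attribute.
#' @return A tibble sorted by time with columns `channel`, `t_s`, `amp_nA`,
#'   `fwhm_s`, `v_mm_s`, `fwhm_flagged`, plus `sample_rate` and `duration`
#'   attributes.
#' @export
find_candidates <- function(trace, cfg = detection_config(), sample_rate = NULL) {
  check_trace(trace)
  sr <- sample_rate %||% trace_sample_rate(trace)
  chans <- trace_channels(trace)
  t0 <- trace$time_s[1]
  out <- purrr::map2_dfr(chans, seq_along(chans), function(col, id) {
    find_candidates_channel(trace[[col]], sr, t0, id, cfg)
  })
  out <- dplyr::arrange(out, .data$t_s, .data$channel)
  attr(out, "sample_rate") <- sr
  attr(out, "duration") <- nrow(trace) / sr
  out
}

#' Single-channel candidate rate versus detection threshold
#'
#' Counts peak candidates per channel on a (presumed cell-free) trace at each
#' threshold and divides by the scan duration, giving the single-fiber
#' false-alarm rate as a function of threshold. Rates are monotonically
#' non-increasing in the threshold.
#'
#' @param trace Preprocessed control trace tibble.
#' @param thresholds Numeric vector of thresholds, nA.
#' @param cfg Base [detection_config()]; its threshold is replaced by each
#'   element of `thresholds`.
#' @param sample_rate Hz; defaults to the trace attribute.
#' @return A tibble with columns `threshold_nA`, `channel`, `n_candidates`,
#'   `rate_per_min`.
#' @export
far_candidates <- function(trace, thresholds, cfg = detection_config(),
                           sample_rate = NULL) {
  if (length(thresholds) == 0) stop("thresholds must be non-empty", call. = FALSE)
  check_trace(trace)
  sr <- sample_rate %||% trace_sample_rate(trace)
  duration_min <- nrow(trace) / sr / 60
  purrr::map_dfr(sort(thresholds), function(th) {
    cfg_th <- cfg
    cfg_th$threshold <- th
    cand <- find_candidates(trace, cfg_th, sample_rate = sr)
    purrr::map_dfr(seq_along(trace_channels(trace)), function(id) {
      n <- sum(cand$channel == id)
      tibble::tibble(threshold_nA = th, channel = id, n_candidates = n,
                     rate_per_min = n / duration_min)
    })
  })
}
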