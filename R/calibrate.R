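#' Reference-microsphere calibration model
#'
#' Holds the bead-referenced intensities used to derive counting thresholds.
#' Brightness is normalized to FR4 reference microspheres measured in vitro;
#' the in vivo scale is set by CS microspheres, which circulate (FR4 beads
#' clear immediately) and are `cs_to_fr4_ratio` times brighter than FR4.
#' All intensities are in nA; use [uA()] to pass microamp values.
#'
#' @param fr4_mean Mean FR4 bead peak intensity measured in vitro, nA.
#' @param cell_to_fr4_ratio Mean labeled-cell brightness relative to FR4
#'   (4.4 for CTFR-labeled MM cells).
#' @param cs_to_fr4_ratio CS-to-FR4 brightness ratio (default 23).
#' @param cs_in_vivo_mean Mean in vivo CS bead signal, nA (default 11300,
#'   i.e. 11.3 uA).
#' @param threshold_fraction Counting threshold as a fraction of the FR4 mean
#'   (default 0.5).
#' @return A list of class `difc_calibration_model`.
#' @export
calibration_model <- function(fr4_mean = NULL,
                              cell_to_fr4_ratio = 4.4,
                              cs_to_fr4_ratio = 23,
                              cs_in_vivo_mean = 11300,
                              threshold_fraction = 0.5) {
  vals <- c(cell_to_fr4_ratio, cs_to_fr4_ratio, cs_in_vivo_mean, threshold_fraction)
  if (any(vals <= 0)) stop("calibration quantities must be positive", call. = FALSE)
  if (!is.null(fr4_mean) && fr4_mean <= 0) {
    stop("fr4_mean must be positive", call. = FALSE)
  }
  structure(
    list(fr4_mean = fr4_mean, cell_to_fr4_ratio = cell_to_fr4_ratio,
         cs_to_fr4_ratio = cs_to_fr4_ratio, cs_in_vivo_mean = cs_in_vivo_mean,
         threshold_fraction = threshold_fraction),
    class = "difc_calibration_model"
  )
}

#' Microamps to nanoamps
#'
#' Explicit unit tag for interfaces that quote microamp values (internally
#' everything is in nA).
#'
#' @param x Current in microamps.
#' @return Current in nanoamps.
#' @examples
#' uA(11.3)  # 11300 nA
#' @export
uA <- function(x) 1000 * x

#' In vitro counting threshold from the FR4 reference mean
#'
#' `threshold_fraction * fr4_mean`: peaks above half the FR4 bead mean (at
#' the default fraction) are counted as labeled cells.
#'
#' @param model A [calibration_model()] with `fr4_mean` set.
#' @return Threshold, nA.
#' @export
in_vitro_threshold <- function(model) {
  if (is.null(model$fr4_mean) || model$fr4_mean <= 0) {
    stop("fr4_mean must be set and positive", call. = FALSE)
  }
  model$threshold_fraction * model$fr4_mean
}

#' In vivo counting threshold from the circulating CS bead signal
#'
#' The in vivo FR4-equivalent intensity is the measured CS bead mean divided
#' by the CS:FR4 brightness ratio; the threshold is `threshold_fraction` of
#' that (at the defaults, 0.5 x 11300 / 23 = 245.7 nA, which the instrument
#' rounds to 250 nA — see [round_threshold()]).
#'
#' @param model A [calibration_model()].
#' @return Threshold, nA (unrounded).
#' @examples
#' in_vivo_threshold(calibration_model())  # ~246 nA
#' @export
in_vivo_threshold <- function(model) {
  if (model$cs_to_fr4_ratio <= 0) stop("cs_to_fr4_ratio must be positive", call. = FALSE)
  if (model$cs_in_vivo_mean <= 0) stop("cs_in_vivo_mean must be positive", call. = FALSE)
  model$threshold_fraction * model$cs_in_vivo_mean / model$cs_to_fr4_ratio
}

#' Round a threshold to the nearest step
#'
#' Kept separate from the threshold derivations so the exact value remains
#' available.
#'
#' @param threshold Threshold, nA.
#' @param to Rounding step, nA (default 10).
#' @return Rounded threshold, nA.
#' @examples
#' round_threshold(245.7)  # 250
#' @export
round_threshold <- function(threshold, to = 10) {
  round(threshold / to) * to
}

#' Count labeled cells in an extracted blood sample
#'
#' Blood samples run through tubing past a single probe are counted without
#' channel matching: the trace is preprocessed (background subtraction and
#' smoothing; no normalization), peaks above `threshold_fraction * fr4_mean`
#' are detected, and the count is divided by the sample volume.
#'
#' @param trace Single-channel trace tibble (`time_s` plus one channel
#'   column).
#' @param fr4_mean Mean FR4 bead intensity for the session, nA.
#' @param volume_ml Blood volume analyzed, mL (> 0).
#' @param pre_cfg,det_cfg Stage configurations; the detection threshold is
#'   replaced by the FR4-derived one.
#' @param threshold_fraction Fraction of the FR4 mean used as threshold.
#' @return Estimated concentration, cells/mL, with the peak count in the
#'   `n_peaks` attribute.
#' @export
count_blood_sample <- function(trace, fr4_mean, volume_ml,
                               pre_cfg = preprocess_config(normalize = FALSE),
                               det_cfg = detection_config(),
                               threshold_fraction = 0.5) {
  if (volume_ml <= 0) stop("volume_ml must be positive", call. = FALSE)
  if (fr4_mean <= 0) stop("fr4_mean must be positive", call. = FALSE)
  check_trace(trace)
  pre_cfg$normalize <- FALSE
  proc <- preprocess_scan(trace, pre_cfg)
  det_cfg$threshold <- threshold_fraction * fr4_mean
  cand <- find_candidates(proc, det_cfg)
  out <- nrow(cand) / volume_ml
  attr(out, "n_peaks") <- nrow(cand)
  out
}
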