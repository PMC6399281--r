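#' Run the full DiFC analysis pipeline on a raw two-channel trace
#'
#' Preprocessing (background subtraction, smoothing, channel normalization),
#' candidate detection, and forward/reverse coincidence matching in one call.
#'
#' @param trace Raw two-channel trace tibble (`time_s`, `ch1_nA`, `ch2_nA`).
#' @param pre_cfg,det_cfg,match_cfg Stage configurations.
#' @return A list of class `difc_result` with `processed` (trace tibble),
#'   `candidates` (tibble), and `match` (`difc_match`).
#' @examples
#' scan <- simulate_scan(sim_config(duration = 30, concentration = 100, seed = 7))
#' res <- difc_process(scan$trace)
#' glance(res$match)
#' @export
difc_process <- function(trace,
                         pre_cfg = preprocess_config(),
                         det_cfg = detection_config(),
                         match_cfg = match_config()) {
  proc <- preprocess_scan(trace, pre_cfg, provisional_threshold = det_cfg$threshold)
  cand <- find_candidates(proc, det_cfg)
  m <- match_candidates(cand, match_cfg)
  structure(list(processed = proc, candidates = cand, match = m),
            class = "difc_result")
}

#' @export
print.difc_result <- function(x, ...) {
  cat("<difc_result>", nrow(x$candidates), "candidates ->\n  ")
  print(x$match)
  invisible(x)
}
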