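#' Read and write DiFC trace files
#'
#' Traces are stored as delimited text with header `time_s,ch1_nA,ch2_nA`
#' (single-channel in-vitro traces may carry only `time_s,ch1_nA`), one row
#' per sample.
#'
#' @param trace A trace tibble.
#' @param path File path.
#' @return `read_trace()` returns a tibble with a `sample_rate` attribute;
#'   `write_trace()` returns `path` invisibly.
#' @export
write_trace <- function(trace, path) {
  check_trace(trace)
  readr::write_csv(trace, path)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  trace <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_trace(trace)
  for (col in names(trace)) {
    if (!is.numeric(trace[[col]])) {
      stop("parse error in ", path, ": column '", col, "' is not numeric", call. = FALSE)
    }
  }
  attr(trace, "sample_rate") <- trace_sample_rate(trace)
  trace
}

#' Read and write simulation ground truth
#'
#' Ground truth (cell transits and artifacts from [simulate_scan()]) is
#' stored as delimited text with header
#' `time_s,kind,direction,speed_mm_s,amp1_nA,amp2_nA`; cell transits have
#' `kind = "cell"`, artifacts use their artifact kind and leave direction and
#' speed empty. The round trip is lossless.
#'
#' @param truth A truth list (`events`, `artifacts`) as returned in
#'   `simulate_scan()$truth`.
#' @param path File path.
#' @return `read_truth()` returns a truth list; `write_truth()` returns
#'   `path` invisibly.
#' @export
write_truth <- function(truth, path) {
  ev <- truth$events
  ar <- truth$artifacts
  rows <- dplyr::bind_rows(
    tibble::tibble(time_s = ev$arrival_time_s, kind = "cell",
                   direction = ev$direction, speed_mm_s = ev$speed_mm_s,
                   amp1_nA = ev$amp1_nA, amp2_nA = ev$amp2_nA),
    tibble::tibble(time_s = ar$time_s, kind = ar$kind,
                   direction = NA_character_, speed_mm_s = NA_real_,
                   amp1_nA = ifelse(ar$kind != "single_ch2", ar$amplitude_nA, NA_real_),
                   amp2_nA = ifelse(ar$kind != "single_ch1", ar$amplitude_nA, NA_real_))
  )
  readr::write_csv(rows, path, na = "")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  expected <- c("time_s", "kind", "direction", "speed_mm_s", "amp1_nA", "amp2_nA")
  if (!identical(names(raw), expected)) {
    stop("parse error in ", path, ": expected header ",
         paste(expected, collapse = ","), call. = FALSE)
  }
  num <- function(col) {
    x <- raw[[col]]
    out <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & x != "" & is.na(out))
    if (length(bad) > 0) {
      stop("parse error in ", path, " at line ", bad[1] + 1L,
           ": non-numeric value '", x[bad[1]], "' in column '", col, "'",
           call. = FALSE)
    }
    out
  }
  time_s <- num("time_s")
  speed <- num("speed_mm_s")
  amp1 <- num("amp1_nA")
  amp2 <- num("amp2_nA")
  is_cell <- raw$kind == "cell"
  events <- tibble::tibble(
    arrival_time_s = time_s[is_cell],
    direction = raw$direction[is_cell],
    speed_mm_s = speed[is_cell],
    amp1_nA = amp1[is_cell],
    amp2_nA = amp2[is_cell]
  )
  amp <- ifelse(is.na(amp1[!is_cell]), amp2[!is_cell], amp1[!is_cell])
  artifacts <- tibble::tibble(
    time_s = time_s[!is_cell],
    kind = raw$kind[!is_cell],
    amplitude_nA = amp
  )
  if (nrow(events) == 0) events <- empty_truth_events()
  if (nrow(artifacts) == 0) artifacts <- empty_truth_artifacts()
  list(events = events, artifacts = artifacts)
}

#' Write detected peak candidates or matched events to delimited text
#'
#' @param x A candidates tibble from [find_candidates()] or the `events`
#'   tibble of a [match_candidates()] result (a `difc_match` object is
#'   accepted and its events written).
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_candidates <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}

#' @rdname write_candidates
#' @export
write_events <- function(x, path) {
  if (inherits(x, "difc_match")) x <- x$events
  readr::write_csv(x, path)
  invisible(path)
}
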