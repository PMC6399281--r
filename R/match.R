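#' Matching configuration
#'
#' Parameters of the dual-channel coincidence matcher.
#'
#' @param fiber_separation Physical separation `d` between the two collection
#'   fibers, mm (default 3).
#' @param v_max Assumed maximum possible cell speed, mm/s (default 400); sets
#'   the earliest admissible partner delay `d / v_max`.
#' @param similarity_factor A pair is accepted when its amplitudes and speed
#'   estimates agree within this factor on average (default 2.5).
#' @param coincidence_window Candidates whose apexes fall within this many
#'   samples on the two channels are discarded as movement artifacts
#'   (default 1).
#' @return A list of class `difc_match_config`.
#' @export
match_config <- function(fiber_separation = 3,
                         v_max = 400,
                         similarity_factor = 2.5,
                         coincidence_window = 1) {
  if (fiber_separation <= 0) stop("fiber_separation must be positive", call. = FALSE)
  if (v_max <= 0) stop("v_max must be positive", call. = FALSE)
  if (similarity_factor < 1) stop("similarity_factor must be >= 1", call. = FALSE)
  structure(
    list(fiber_separation = fiber_separation, v_max = v_max,
         similarity_factor = similarity_factor,
         coincidence_window = coincidence_window),
    class = "difc_match_config"
  )
}

ratio_max_min <- function(a, b) {
  pmax(a, b) / pmin(a, b)
}

# One directional greedy pass: for every seed candidate (leading channel),
# search the target channel in [t + d/v_max, t + 10 d/v_width] and accept the
# lowest-scoring partner with score <= similarity_factor (ties broken by
# smallest delay). A target consumed by an earlier seed is unavailable.
directional_pass <- function(seed, target, cfg) {
  out <- list()
  used <- logical(nrow(target))
  d <- cfg$fiber_separation
  for (i in seq_len(nrow(seed))) {
    v1 <- seed$v_mm_s[i]
    if (is.na(v1)) next
    t1 <- seed$t_s[i]
    lo <- t1 + d / cfg$v_max
    hi <- t1 + 10 * d / v1
    j <- which(!used & target$t_s >= lo & target$t_s <= hi & !is.na(target$v_mm_s))
    if (length(j) == 0) next
    vc3 <- d / (target$t_s[j] - t1)
    r_a <- ratio_max_min(seed$amp_nA[i], target$amp_nA[j])
    r_w <- ratio_max_min(v1, target$v_mm_s[j])
    r_d <- ratio_max_min((v1 + target$v_mm_s[j]) / 2, vc3)
    score <- (r_a + r_w + r_d) / 3
    ok <- which(score <= cfg$similarity_factor)
    if (length(ok) == 0) next
    dt <- target$t_s[j] - t1
    best <- ok[order(score[ok], dt[ok])][1]
    used[j[best]] <- TRUE
    out[[length(out) + 1L]] <- tibble::tibble(
      seed_row = seed$.row[i], target_row = target$.row[j[best]],
      t_seed = t1, t_target = target$t_s[j[best]],
      amp_seed = seed$amp_nA[i], amp_target = target$amp_nA[j[best]],
      fwhm_seed = seed$fwhm_s[i], fwhm_target = target$fwhm_s[j[best]],
      v_seed = v1, v_target = target$v_mm_s[j[best]],
      vc3 = vc3[best], score = score[best], dt = dt[best]
    )
  }
  dplyr::bind_rows(out)
}

empty_events <- function() {
  tibble::tibble(direction = character(), t1_s = numeric(), t2_s = numeric(),
                 amp1_nA = numeric(), amp2_nA = numeric(),
                 fwhm1_s = numeric(), fwhm2_s = numeric(),
                 vc1 = numeric(), vc2 = numeric(), vc3 = numeric(),
                 v_consensus = numeric(), score = numeric())
}

#' Match peak candidates across the two channels
#'
#' Implements the arterial/venous coincidence matcher. Candidate pairs whose
#' apexes coincide within `coincidence_window` samples are first discarded as
#' movement artifacts. A forward (channel 1 to 2, arterial) pass then pairs
#' each channel-1 candidate with the most similar channel-2 candidate in the
#' admissible delay window `[d/v_max, 10 d/v_c1]`; similarity is the average
#' of three max/min ratios — amplitudes, width-derived speeds, and the mean
#' width speed versus the delay speed `v_c3 = d / (t2 - t1)` — and a pair is
#' accepted when this score does not exceed `similarity_factor`. The pass is
#' repeated in the reverse (channel 2 to 1, venous) direction. A candidate
#' matched in both directions keeps only the lower-score event, so every
#' candidate ends in exactly one of: a forward event, a reverse event, the
#' unmatched list, or the coincident list.
#'
#' @param candidates Candidate tibble from [find_candidates()] containing
#'   both channels, sorted by time within each channel.
#' @param cfg A [match_config()].
#' @param sample_rate Hz, used to convert `coincidence_window` to seconds;
#'   defaults to the candidates' `sample_rate` attribute.
#' @return An object of class `difc_match`: a list with `events` (tibble
#'   `direction`, `t1_s`, `t2_s`, `amp1_nA`, `amp2_nA`, `vc1`, `vc2`, `vc3`,
#'   `v_consensus`, `score`), `unmatched` (candidate rows), `coincident`
#'   (discarded pairs), the configuration, and the scan duration when known.
#' @export
match_candidates <- function(candidates, cfg = match_config(), sample_rate = NULL) {
  sr <- sample_rate %||% attr(candidates, "sample_rate")
  if (is.null(sr)) stop("sample_rate is required (attribute missing)", call. = FALSE)
  cand <- tibble::as_tibble(candidates)
  cand$.row <- seq_len(nrow(cand))
  c1 <- cand[cand$channel == 1, ]
  c2 <- cand[cand$channel == 2, ]
  if (is.unsorted(c1$t_s) || is.unsorted(c2$t_s)) {
    stop("candidate lists must be sorted by time within each channel", call. = FALSE)
  }

  # (a) coincidence removal: one-to-one, nearest pairs first
  coincident <- tibble::tibble(row1 = integer(), row2 = integer(),
                               t1_s = numeric(), t2_s = numeric())
  if (nrow(c1) > 0 && nrow(c2) > 0) {
    win_s <- cfg$coincidence_window / sr + 1e-12
    # candidate pairs within the window, via interval search on the sorted ch2 times
    lo <- findInterval(c1$t_s - win_s, c2$t_s) + 1L
    hi <- findInterval(c1$t_s + win_s, c2$t_s)
    ii <- rep.int(seq_len(nrow(c1)), pmax(0L, hi - lo + 1L))
    jj <- unlist(lapply(seq_len(nrow(c1)), function(i) {
      if (lo[i] <= hi[i]) lo[i]:hi[i] else integer(0)
    }), use.names = FALSE)
    pairs <- tibble::tibble(i = ii, j = jj)
    pairs$dt <- abs(c1$t_s[pairs$i] - c2$t_s[pairs$j])
    pairs <- pairs[order(pairs$dt), ]
    used1 <- logical(nrow(c1)); used2 <- logical(nrow(c2))
    keep <- logical(nrow(pairs))
    for (k in seq_len(nrow(pairs))) {
      if (!used1[pairs$i[k]] && !used2[pairs$j[k]]) {
        keep[k] <- TRUE
        used1[pairs$i[k]] <- TRUE
        used2[pairs$j[k]] <- TRUE
      }
    }
    pairs <- pairs[keep, ]
    if (nrow(pairs) > 0) {
      coincident <- tibble::tibble(
        row1 = c1$.row[pairs$i], row2 = c2$.row[pairs$j],
        t1_s = c1$t_s[pairs$i], t2_s = c2$t_s[pairs$j]
      )
      c1 <- c1[!used1, ]
      c2 <- c2[!used2, ]
    }
  }

  # (b) forward and (c) reverse passes on the surviving candidates
  fwd <- directional_pass(c1, c2, cfg)
  rev <- directional_pass(c2, c1, cfg)

  # (d) joint resolution: lower score wins when a candidate is claimed by both
  all_ev <- dplyr::bind_rows(
    if (nrow(fwd) > 0) dplyr::mutate(fwd, direction = "forward") else NULL,
    if (nrow(rev) > 0) dplyr::mutate(rev, direction = "reverse") else NULL
  )
  events <- empty_events()
  used_rows <- integer(0)
  if (!is.null(all_ev) && nrow(all_ev) > 0) {
    all_ev <- all_ev[order(all_ev$score, abs(all_ev$dt)), ]
    kept <- logical(nrow(all_ev))
    taken <- integer(0)
    for (k in seq_len(nrow(all_ev))) {
      rows_k <- c(all_ev$seed_row[k], all_ev$target_row[k])
      if (!any(rows_k %in% taken)) {
        kept[k] <- TRUE
        taken <- c(taken, rows_k)
      }
    }
    all_ev <- all_ev[kept, ]
    used_rows <- c(all_ev$seed_row, all_ev$target_row)
    is_fwd <- all_ev$direction == "forward"
    events <- tibble::tibble(
      direction = all_ev$direction,
      t1_s = ifelse(is_fwd, all_ev$t_seed, all_ev$t_target),
      t2_s = ifelse(is_fwd, all_ev$t_target, all_ev$t_seed),
      amp1_nA = ifelse(is_fwd, all_ev$amp_seed, all_ev$amp_target),
      amp2_nA = ifelse(is_fwd, all_ev$amp_target, all_ev$amp_seed),
      fwhm1_s = ifelse(is_fwd, all_ev$fwhm_seed, all_ev$fwhm_target),
      fwhm2_s = ifelse(is_fwd, all_ev$fwhm_target, all_ev$fwhm_seed),
      vc1 = ifelse(is_fwd, all_ev$v_seed, all_ev$v_target),
      vc2 = ifelse(is_fwd, all_ev$v_target, all_ev$v_seed),
      vc3 = all_ev$vc3,
      v_consensus = (ifelse(is_fwd, all_ev$v_seed, all_ev$v_target) +
                       ifelse(is_fwd, all_ev$v_target, all_ev$v_seed) +
                       all_ev$vc3) / 3,
      score = all_ev$score
    )
    events <- dplyr::arrange(events, pmin(.data$t1_s, .data$t2_s))
  }

  unmatched <- cand[!cand$.row %in% c(used_rows, coincident$row1, coincident$row2), ]
  unmatched$.row <- NULL
  structure(
    list(events = events, unmatched = tibble::as_tibble(unmatched),
         coincident = coincident, config = cfg,
         duration = attr(candidates, "duration"),
         n_candidates = nrow(cand)),
    class = "difc_match"
  )
}

#' @export
print.difc_match <- function(x, ...) {
  cat("<difc_match>", sum(x$events$direction == "forward"), "forward,",
      sum(x$events$direction == "reverse"), "reverse events;",
      nrow(x$unmatched), "unmatched,", nrow(x$coincident), "coincident pairs\n")
  invisible(x)
}

#' Tidy the matched events of a `difc_match`
#'
#' @param x A [match_candidates()] result.
#' @param ... Unused.
#' @return The events tibble (one row per matched event).
#' @method tidy difc_match
#' @export
tidy.difc_match <- function(x, ...) x$events

#' One-row summary of a `difc_match`
#'
#' @param x A [match_candidates()] result.
#' @param ... Unused.
#' @return A one-row tibble with candidate and event counts, matched
#'   fractions, and (when the scan duration is known) per-minute rates.
#' @method glance difc_match
#' @export
glance.difc_match <- function(x, ...) {
  n_fwd <- sum(x$events$direction == "forward")
  n_rev <- sum(x$events$direction == "reverse")
  dur_min <- if (is.null(x$duration)) NA_real_ else x$duration / 60
  tibble::tibble(
    n_candidates = x$n_candidates,
    n_forward = n_fwd,
    n_reverse = n_rev,
    n_unmatched = nrow(x$unmatched),
    n_coincident_pairs = nrow(x$coincident),
    matched_fraction_forward = if (x$n_candidates > 0) 2 * n_fwd / x$n_candidates else NA_real_,
    matched_fraction_reverse = if (x$n_candidates > 0) 2 * n_rev / x$n_candidates else NA_real_,
    forward_rate_per_min = n_fwd / dur_min,
    reverse_rate_per_min = n_rev / dur_min
  )
}

#' Score a matching result against simulation ground truth
#'
#' Associates each matched event to the nearest ground-truth cell transit
#' within `tol` seconds (greedy, one-to-one, smallest time difference first;
#' the event time is the apex on the first fiber, i.e. `min(t1, t2)`), then
#' reports direction accuracy among associated events, sensitivity (fraction
#' of truth events with both channel amplitudes at or above `amp_threshold`
#' that were recovered), precision (fraction of events with a truth partner),
#' and the RMSE of the delay-derived speed `v_c3` against the true speed.
#' When a denominator is empty the metric is reported as 1 and the
#' `degenerate` flag is set.
#'
#' @param match A `difc_match` object.
#' @param truth Truth list from [simulate_scan()].
#' @param tol Association tolerance, seconds (must be positive).
#' @param amp_threshold Detection threshold used, nA (defines which truth
#'   events count as detectable).
#' @return A one-row tibble of metrics.
#' @export
evaluate_against_truth <- function(match, truth, tol = 0.05, amp_threshold = 250) {
  if (tol <= 0) stop("tol must be positive", call. = FALSE)
  ev <- match$events
  tr <- truth$events
  n_ev <- nrow(ev)
  detectable <- tr$amp1_nA >= amp_threshold & tr$amp2_nA >= amp_threshold
  ev_time <- pmin(ev$t1_s, ev$t2_s)

  assoc_ev <- integer(0)
  assoc_tr <- integer(0)
  if (n_ev > 0 && nrow(tr) > 0) {
    pairs <- tidyr::expand_grid(i = seq_len(n_ev), j = seq_len(nrow(tr)))
    pairs$dt <- abs(ev_time[pairs$i] - tr$arrival_time_s[pairs$j])
    pairs <- pairs[pairs$dt <= tol, ]
    pairs <- pairs[order(pairs$dt), ]
    for (k in seq_len(nrow(pairs))) {
      if (!pairs$i[k] %in% assoc_ev && !pairs$j[k] %in% assoc_tr) {
        assoc_ev <- c(assoc_ev, pairs$i[k])
        assoc_tr <- c(assoc_tr, pairs$j[k])
      }
    }
  }

  n_assoc <- length(assoc_ev)
  degenerate <- n_ev == 0 || sum(detectable) == 0 || n_assoc == 0
  direction_accuracy <- if (n_assoc > 0) {
    mean(ev$direction[assoc_ev] == tr$direction[assoc_tr])
  } else 1
  sensitivity <- if (sum(detectable) > 0) {
    sum(assoc_tr %in% which(detectable)) / sum(detectable)
  } else 1
  precision <- if (n_ev > 0) n_assoc / n_ev else 1
  speed_rmse <- if (n_assoc > 0) {
    sqrt(mean((ev$vc3[assoc_ev] - tr$speed_mm_s[assoc_tr])^2))
  } else NA_real_

  tibble::tibble(
    n_events = n_ev, n_truth = nrow(tr), n_truth_detectable = sum(detectable),
    n_associated = n_assoc,
    direction_accuracy = direction_accuracy,
    sensitivity = sensitivity,
    precision = precision,
    speed_rmse_mm_s = speed_rmse,
    degenerate = degenerate
  )
}
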