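test_that("a clean lagging pair is matched forward with the delay-derived speed", {
  cand <- make_candidates(channel = c(1, 2), t_s = c(1, 1.0267),
                          amp_nA = c(500, 500), v_mm_s = c(112.3, 112.3))
  m <- match_candidates(cand)
  expect_equal(nrow(m$events), 1)
  expect_equal(m$events$direction, "forward")
  expect_equal(m$events$vc3, 3 / 0.0267, tolerance = 1e-6)  # ~112.4 mm/s
  expect_equal(nrow(m$unmatched), 0)
  expect_equal(nrow(m$coincident), 0)
})

test_that("a lone candidate stays unmatched and reverse pairs are directed", {
  lone <- make_candidates(channel = 1, t_s = 2, amp_nA = 400, v_mm_s = 100)
  m <- match_candidates(lone)
  expect_equal(nrow(m$events), 0)
  expect_equal(nrow(m$unmatched), 1)

  rev_pair <- make_candidates(channel = c(2, 1), t_s = c(1, 1.039),
                              amp_nA = c(450, 440), v_mm_s = c(76.6, 76.6))
  m <- match_candidates(rev_pair)
  expect_equal(m$events$direction, "reverse")
  expect_equal(m$events$vc3, 3 / 0.039, tolerance = 1e-6)
})

test_that("same-sample apexes on both channels are discarded as coincident", {
  cand <- make_candidates(channel = c(1, 2), t_s = c(1, 1),
                          amp_nA = c(500, 480), v_mm_s = c(110, 108))
  m <- match_candidates(cand)
  expect_equal(nrow(m$events), 0)
  expect_equal(nrow(m$unmatched), 0)
  expect_equal(nrow(m$coincident), 1)
})

test_that("the similarity gate rejects dissimilar pairs at the stated score", {
  # amplitude ratio 10, other ratios ~1 -> score (10 + 1 + 1)/3 = 4 > 2.5
  v <- 3 / 0.0267
  cand <- make_candidates(channel = c(1, 2), t_s = c(1, 1.0267),
                          amp_nA = c(1000, 100), v_mm_s = c(v, v))
  m <- match_candidates(cand)
  expect_equal(nrow(m$events), 0)
  expect_equal(nrow(m$unmatched), 2)

  # amplitude ratio 2.5 exactly, others 1 -> score 1.5 <= 2.5: accepted
  cand2 <- make_candidates(channel = c(1, 2), t_s = c(1, 1.0267),
                           amp_nA = c(1000, 400), v_mm_s = c(v, v))
  m2 <- match_candidates(cand2)
  expect_equal(nrow(m2$events), 1)
  expect_equal(m2$events$score, (2.5 + 1 + 1) / 3, tolerance = 1e-9)
})

test_that("candidates outside the admissible delay window are not paired", {
  # delay shorter than d/v_max = 7.5 ms
  cand <- make_candidates(channel = c(1, 2), t_s = c(1, 1.004),
                          amp_nA = c(500, 500), v_mm_s = c(112, 112))
  expect_equal(nrow(match_candidates(cand)$events), 0)
  # delay beyond ten transit times (10 * 3 / 112 = 0.268 s)
  cand <- make_candidates(channel = c(1, 2), t_s = c(1, 1.3),
                          amp_nA = c(500, 500), v_mm_s = c(112, 112))
  expect_equal(nrow(match_candidates(cand)$events), 0)
})

test_that("unsorted candidate lists are rejected", {
  cand <- make_candidates(channel = c(1, 1), t_s = c(2, 1),
                          amp_nA = c(400, 400), v_mm_s = c(100, 100))
  cand <- cand[c(2, 1), ]  # break the sort
  attr(cand, "sample_rate") <- 1000
  expect_error(match_candidates(cand), "sorted")
})

test_that("every candidate lands in exactly one partition", {
  withr::with_seed(42, {
    for (rep in 1:20) {
      n1 <- rpois(1, 12); n2 <- rpois(1, 12)
      cand <- make_candidates(
        channel = c(rep(1, n1), rep(2, n2)),
        t_s = round(c(runif(n1, 0, 30), runif(n2, 0, 30)), 3),
        amp_nA = rlnorm(n1 + n2, log(500), 0.5),
        v_mm_s = rlnorm(n1 + n2, log(110), 0.3)
      )
      m <- match_candidates(cand)
      n_in_events <- 2 * nrow(m$events)
      n_total <- n_in_events + nrow(m$unmatched) + 2 * nrow(m$coincident)
      expect_equal(n_total, n1 + n2)
      expect_lte(nrow(m$events),
                 min(n1, n2))
    }
  })
})

test_that("time reversal swaps forward and reverse events one-to-one", {
  withr::with_seed(7, {
    for (rep in 1:10) {
      # well-separated synthetic pairs plus a few singletons
      n_pair <- 5
      base_t <- seq(1, by = 2, length.out = n_pair)
      v <- runif(n_pair, 60, 150)
      amp <- rlnorm(n_pair, log(500), 0.3)
      lead_ch <- sample(1:2, n_pair, replace = TRUE)
      cand <- make_candidates(
        channel = c(lead_ch, 3 - lead_ch, 1),
        t_s = c(base_t, base_t + 3 / v, 25.5),
        amp_nA = c(amp, amp * runif(n_pair, 0.8, 1.25), 300),
        v_mm_s = c(v, v * runif(n_pair, 0.9, 1.1), 100)
      )
      m <- match_candidates(cand)
      t_max <- 30
      mirrored <- cand
      mirrored$t_s <- t_max - mirrored$t_s
      mirrored <- mirrored[order(mirrored$t_s, mirrored$channel), ]
      attr(mirrored, "sample_rate") <- 1000
      m2 <- match_candidates(mirrored)
      expect_equal(sum(m2$events$direction == "forward"),
                   sum(m$events$direction == "reverse"))
      expect_equal(sum(m2$events$direction == "reverse"),
                   sum(m$events$direction == "forward"))
    }
  })
})

test_that("evaluation against truth handles perfect and degenerate cases", {
  scan <- simulate_scan(sim_config(duration = 240, concentration = 8,
                                   noise_sigma = 0, seed = 12))
  res <- difc_process(scan$trace, preprocess_config(normalize = FALSE))
  metrics <- evaluate_against_truth(res$match, scan$truth)
  expect_equal(metrics$direction_accuracy, 1)
  expect_equal(metrics$precision, 1)
  expect_gte(metrics$sensitivity, 0.95)  # edge-truncated transits may be lost
  expect_false(metrics$degenerate)

  empty_truth <- list(events = scan$truth$events[0, ],
                      artifacts = scan$truth$artifacts[0, ])
  empty_match <- match_candidates(make_candidates(channel = integer(0),
                                                  t_s = numeric(0),
                                                  amp_nA = numeric(0),
                                                  v_mm_s = numeric(0),
                                                  duration = 1))
  degen <- evaluate_against_truth(empty_match, empty_truth)
  expect_equal(degen$direction_accuracy, 1)
  expect_equal(degen$sensitivity, 1)
  expect_true(degen$degenerate)

  expect_error(evaluate_against_truth(res$match, scan$truth, tol = 0), "positive")
})

test_that("speed error from noisy scans stays below 10% of the mean true speed", {
  scan <- simulate_scan(sim_config(duration = 300, concentration = 20,
                                   noise_sigma = 40, amplitude_median = 800,
                                   amplitude_log_sd = 0.2, seed = 18))
  res <- difc_process(scan$trace)
  metrics <- evaluate_against_truth(res$match, scan$truth)
  expect_lt(metrics$speed_rmse_mm_s, 0.1 * mean(scan$truth$events$speed_mm_s))
})

test_that("tidy and glance summarize a match result", {
  cand <- make_candidates(channel = c(1, 2, 1), t_s = c(1, 1.0267, 5),
                          amp_nA = c(500, 500, 400), v_mm_s = c(112.3, 112.3, 90),
                          duration = 60)
  m <- match_candidates(cand)
  expect_equal(nrow(tidy(m)), 1)
  g <- glance(m)
  expect_equal(g$n_forward, 1)
  expect_equal(g$n_unmatched, 1)
  expect_equal(g$matched_fraction_forward, 2 / 3, tolerance = 1e-9)
  expect_equal(g$forward_rate_per_min, 1)
})
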