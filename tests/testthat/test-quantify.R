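test_that("SNR in dB follows 20 log10(I/sigma)", {
  expect_equal(snr_db(40, 40), 0)
  expect_equal(snr_db(400, 40), 20)
  expect_equal(round(snr_db(503, 40), 1), 22.0)
  expect_error(snr_db(-1, 40), "positive")
  expect_error(snr_db(500, 0), "positive")
})

test_that("rate/concentration conversions are exact inverses", {
  expect_equal(concentration_from_rate(10, 0.283), 35.3, tolerance = 0.01)
  expect_equal(concentration_from_rate(0, 0.284), 0)
  expect_equal(sampling_rate_from_count_interval(3.52), 0.284, tolerance = 0.001)
  for (x in c(0.01, 1, 7.3, 120)) {
    expect_equal(concentration_from_rate(rate_from_concentration(x)), x,
                 tolerance = 1e-12)
  }
  expect_error(concentration_from_rate(10, 0), "positive")
})

test_that("vessel flow rate uses the plug-flow cylinder formula", {
  expect_equal(vessel_flow_rate(112.3, 0.25), 5.5, tolerance = 0.02)
  expect_equal(vessel_flow_rate(100, 0.1), pi * 0.0025 * 100, tolerance = 1e-12)
  expect_error(vessel_flow_rate(0, 0.25), "positive")
})

test_that("depth inversion interpolates a monotone sensitivity profile", {
  # identity profile: depth == fov
  ident <- tibble::tibble(depth_mm = seq(0, 3, 0.5), fov_fwhm_mm = seq(0, 3, 0.5))
  expect_equal(as.numeric(depth_from_event(0.015, 100, ident)), 1.5,
               tolerance = 1e-9)
  # shipped profile anchors 11.5 ms x 112.3 mm/s (fov 1.29 mm) near 1.1 mm depth
  d <- depth_from_event(0.0115, 112.3)
  expect_equal(as.numeric(d), 1.1, tolerance = 0.01)
  expect_equal(attr(d, "fov_mm"), 0.0115 * 112.3, tolerance = 1e-9)
  # clamping and monotonicity errors
  expect_warning(d_lo <- depth_from_event(0.001, 100), "clamping")
  expect_equal(as.numeric(d_lo), 0)
  bad <- tibble::tibble(depth_mm = c(0, 1, 2), fov_fwhm_mm = c(1, 0.5, 2))
  expect_error(depth_from_event(0.01, 100, bad), "increasing")
})

test_that("scan summaries bin counts and flag empty bins", {
  cand <- make_candidates(channel = c(1, 2, 1, 2, 1),
                          t_s = c(1, 1.0267, 70, 70.03, 130),
                          amp_nA = c(500, 500, 450, 460, 400),
                          v_mm_s = c(112.3, 112.3, 100, 100, 90),
                          duration = 180)
  m <- match_candidates(cand)
  s <- summarize_scan(m, cand, interval = 60)
  expect_equal(nrow(s), 3)
  expect_equal(s$counts_forward, c(1, 1, 0))
  expect_equal(s$counts_ch1, c(1, 1, 1))
  expect_true(s$empty_forward[3])
  expect_true(is.na(s$mean_amp_forward_nA[3]))
  expect_error(summarize_scan(m, cand, interval = 0), "positive")

  none <- match_candidates(make_candidates(channel = integer(0), t_s = numeric(0),
                                           amp_nA = numeric(0), v_mm_s = numeric(0),
                                           duration = 120))
  s0 <- summarize_scan(none, make_candidates(channel = integer(0), t_s = numeric(0),
                                             amp_nA = numeric(0), v_mm_s = numeric(0),
                                             duration = 120),
                       interval = 60)
  expect_true(all(s0$counts_forward == 0))
  expect_true(all(s0$counts_ch1 == 0))
})

test_that("forward:reverse count ratio tracks the arterial fraction", {
  scan <- simulate_scan(sim_config(duration = 600, concentration = 100, seed = 23))
  res <- difc_process(scan$trace)
  g <- glance(res$match)
  frac_fwd <- g$n_forward / (g$n_forward + g$n_reverse)
  # arterial fraction 0.9; binomial 3-sigma band around it
  n <- g$n_forward + g$n_reverse
  expect_lt(abs(frac_fwd - 0.9), 3 * sqrt(0.9 * 0.1 / n) + 0.02)
})

test_that("per-bin counts recover an exponential concentration decay", {
  # piecewise-constant approximation of c(t) = c0 exp(-t/tau), tau = 100 s,
  # six 50 s segments; count matched events per segment and fit log-linearly
  tau <- 100
  c0 <- 1000
  mids <- seq(25, by = 50, length.out = 6)
  counts <- vapply(seq_along(mids), function(i) {
    scan <- simulate_scan(sim_config(duration = 50,
                                     concentration = c0 * exp(-mids[i] / tau),
                                     seed = 500 + i))
    nrow(difc_process(scan$trace)$match$events)
  }, numeric(1))
  fit <- lm(log(counts) ~ mids)
  tau_hat <- -1 / coef(fit)[2]
  expect_lt(abs(tau_hat - tau) / tau, 0.2)
})

test_that("matched false-alarm rate vanishes without coincident signal sources", {
  silent <- make_pulse_trace(10, 1000, baseline = 10000)
  far <- matched_far(silent, c(100, 250))
  expect_true(all(far$matched_rate_per_min == 0))
  expect_true(all(far$single_rate_per_min == 0))
  expect_error(matched_far(silent, numeric(0)), "non-empty")
})

test_that("matched FAR is monotone non-increasing in threshold", {
  scan <- simulate_scan(sim_config(duration = 600, concentration = 0,
                                   noise_sigma = 40,
                                   artifact_rate_single = c(4, 4),
                                   artifact_rate_coincident = 2, seed = 40))
  far <- matched_far(scan$trace, c(150, 300, 600, 1200))
  expect_true(all(diff(far$single_rate_per_min) <= 0))
  expect_true(all(diff(far$matched_rate_per_min) <= 1e-12))
})

test_that("calibration regression recovers a known line and rejects degenerate input", {
  df <- tibble::tibble(concentration = c(1, 5, 20, 100),
                       count_rate = 0.284 * c(1, 5, 20, 100))
  fit <- calibration_regression(df)
  expect_equal(fit$slope, 0.284, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(glance(fit)$slope, fit$slope)
  td <- suppressWarnings(tidy(fit))  # exact line: summary() warns
  expect_equal(td$estimate[td$term == "slope"], 0.284, tolerance = 1e-12)

  const <- tibble::tibble(concentration = rep(5, 4), count_rate = 1:4)
  expect_error(calibration_regression(const), "zero variance")
  expect_error(calibration_regression(df[1:2, ]), "at least 3")
})
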