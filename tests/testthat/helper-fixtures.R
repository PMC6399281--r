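# Programmatic fixtures: zero-baseline traces with analytic Gaussian pulses,
# built independently of the simulator.

gauss_pulse <- function(t, t_apex, amp, fwhm_s) {
  sd_s <- fwhm_s / (2 * sqrt(2 * log(2)))
  amp * exp(-(t - t_apex)^2 / (2 * sd_s^2))
}

# pulses: data.frame with columns channel (1/2), t_apex, amp, fwhm_s
make_pulse_trace <- function(duration, sample_rate = 1000, pulses = NULL,
                             baseline = 0, noise_sd = 0) {
  n <- round(duration * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  ch1 <- rep(baseline, n)
  ch2 <- rep(baseline, n)
  if (!is.null(pulses)) {
    for (i in seq_len(nrow(pulses))) {
      p <- gauss_pulse(t, pulses$t_apex[i], pulses$amp[i], pulses$fwhm_s[i])
      if (pulses$channel[i] == 1) ch1 <- ch1 + p else ch2 <- ch2 + p
    }
  }
  if (noise_sd > 0) {
    ch1 <- ch1 + stats::rnorm(n, 0, noise_sd)
    ch2 <- ch2 + stats::rnorm(n, 0, noise_sd)
  }
  trace <- tibble::tibble(time_s = t, ch1_nA = ch1, ch2_nA = ch2)
  attr(trace, "sample_rate") <- sample_rate
  trace
}

# Hand-built candidate rows for matcher unit tests.
make_candidates <- function(channel, t_s, amp_nA, v_mm_s, fov = 1.1,
                            sample_rate = 1000, duration = max(t_s) + 1) {
  cand <- tibble::tibble(
    channel = as.integer(channel), t_s = t_s, amp_nA = amp_nA,
    fwhm_s = fov / v_mm_s, v_mm_s = v_mm_s, fwhm_flagged = FALSE
  )
  cand <- cand[order(cand$t_s, cand$channel), ]
  attr(cand, "sample_rate") <- sample_rate
  attr(cand, "duration") <- duration
  cand
}
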