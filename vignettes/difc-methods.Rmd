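---
title: "Methods: dual-probe DiFC signal analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-probe DiFC signal analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(difc)
```

# The measurement and its signal model

Diffuse in vivo flow cytometry places two fiber-optic probes, separated by
`d` = 3 mm, on the skin above a major vascular bundle. Each probe collects
highly scattered fluorescence from roughly the first 2 mm of tissue over a
field of view (FOV) of about 1.1 mm FWHM along the vessel. A labeled cell
transiting a probe's FOV at speed `v` produces a fluorescence peak of
temporal width `FWHM_t = FOV / v` riding on a large (~10 µA), slowly varying
autofluorescence baseline with additive detector noise (σ ≈ 40 nA in the
calibrated system). A cell moving in the arterial direction passes probe 1
then probe 2, so its channel-2 apex lags by `d / v`; venous flow gives the
opposite order. Electronic or motion artifacts appear either on one channel
only, or on both channels at the same instant — never with a plausible
transit delay on both channels, which is what the matching stage exploits.

The analysis chain is:

1. background estimation and subtraction, smoothing, channel normalization
   (`preprocess_scan()`);
2. threshold-and-prominence peak detection with interpolated widths
   (`find_candidates()`);
3. forward/reverse cross-channel matching with coincidence rejection
   (`match_candidates()`);
4. quantification: count rates, false-alarm rates, SNR, speed, depth,
   concentration (`summarize_scan()`, `matched_far()`, `snr_db()`,
   `depth_from_event()`, `concentration_from_rate()`), and
   bead-referenced threshold calibration (`calibration_model()` and
   friends).

# Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `median_window` | 2.5 | s | running-median background window; must dwarf the ~10 ms transit pulses it must reject |
| `background_ma_points` | 7 | samples | smooths the staircase of the running median |
| `smooth_ma_points` | 3 | samples | 3 ms noise smoothing at 1 kHz; cuts white noise by √3 without distorting ≥ 5 ms pulses |
| `threshold` | 250 | nA | counting threshold; derived from the microsphere calibration (0.5 × 11300 / 23 ≈ 246, rounded to 250) |
| `prominence_fraction` | 0.5 | — | minimum topographic prominence as a fraction of the threshold; suppresses ripples on pulse flanks |
| `fov_fwhm` | 1.1 | mm | converts temporal FWHM to speed |
| `min_separation` | 3 | samples | minimum apex spacing; closer maxima are treated as one transit |
| `fiber_separation` (`d`) | 3 | mm | probe spacing; sets the delay-speed `v_c3 = d / Δt` |
| `v_max` | 400 | mm/s | fastest admissible cell; partner search starts at `d / v_max` after the seed apex |
| `similarity_factor` | 2.5 | — | acceptance gate on the mean of the three max/min ratios |
| `coincidence_window` | 1 | sample | apex-coincidence width treated as a movement artifact (configurable to 2–3 for jittery data) |

The sampling rate is a parameter throughout (default 1000 Hz), not a
constant, since acquisition hardware may run at other rates.

# The simulator: what it emulates, and what it does not

`simulate_scan()` is a first-class, tested module, not a fixture. It
generates, per scan:

* **Cell arrivals**: a homogeneous Poisson process with rate
  `concentration × sampled_flow_rate` (default 0.284 mL/min, the sampled
  blood volume per minute implied by the arterial flow calibration).
* **Direction and speed**: forward with probability `arterial_fraction`
  (default 0.9, reflecting the artery's larger flow); speeds from truncated
  normals (112.3 ± 25 mm/s arterial, 76.6 ± 20 mm/s venous — the calibrated
  system's mean values, with spreads chosen as realistic coefficients of
  variation since the source distributions are not published).
* **Pulses**: Gaussian in time with `FWHM = fov_fwhm / speed`. The true
  pulse shape is not published; observed peaks are smooth and unimodal, and
  a Gaussian is the simplest such shape consistent with a smooth sensitivity
  profile. Amplitudes are log-normal with median 530 nA (between the
  printed arterial/venous means of 532 and 503 nA) and log-sd 0.5, with
  independent per-channel log-normal jitter (sd 0.15) so matched pairs
  differ in amplitude as real probe couplings do while staying inside the
  factor-2.5 gate at defaults.
* **Baseline and noise**: a 10 µA constant (optionally a slow sinusoidal
  drift; default amplitude 0) plus white Gaussian noise, σ = 40 nA.
* **Artifacts**: spikes of uniform amplitude 250–2500 nA and width
  2–10 ms, rectangular or Gaussian at random; `single_ch1`/`single_ch2`
  kinds land on one channel, `coincident` artifacts share an identical apex
  sample on both channels so they exercise the coincidence-rejection rule.
  `artifact_rate_single` accepts per-channel rates, allowing
  one-channel-only control scans.

Everything drawn is recorded in the returned truth tables, and the same
seed reproduces a scan bitwise.

It does **not** emulate: photon transport (depth-dependent amplitude and
width coupling), cell clearance kinetics (concentration is constant within
a scan; decays are approximated piecewise), overlapping-transit pile-up
beyond what independent Poisson arrivals produce, detector saturation, or
slow physiological motion. Passing tests therefore demonstrate the
*algorithmic* correctness of the chain under the stated signal model, not
instrument performance on animals.

# Numerical choices

* **Edges**: every filter uses reflection padding (the edge sample is not
  repeated), so outputs keep the input length; behavior within half a
  window of the edges is approximate and documented as such.
* **Windows**: the median window in seconds is converted to an odd sample
  count by rounding (2.5 s at 1 kHz → 2501 samples); moving-average point
  counts must be odd.
* **Prominence** is topographic: walk outward from the apex on each side
  until a strictly higher sample (or the trace edge), take each side's
  minimum, and subtract the larger of the two minima from the apex.
* **FWHM** is measured at half the apex amplitude relative to the zero
  baseline of the preprocessed signal, by linear interpolation of the
  crossing on each side; the search is bounded by the adjacent candidate
  apex. If one side's crossing is unresolved (merged shoulder), twice the
  resolved side is used and the candidate is flagged; if neither resolves,
  the width is `NA` and the candidate cannot be matched.
* **Plateaus** (possible with rectangular artifacts on noiseless data)
  count as a single maximum with the apex at the plateau's middle sample.
* **Matching order**: coincidence removal first (nearest pairs first,
  one-to-one), then a greedy forward pass in time order, then a greedy
  reverse pass, then joint resolution in which events are accepted in
  ascending score order and any candidate already consumed invalidates the
  later event. Ties in score break by smaller delay. This guarantees the
  partition invariant: every candidate ends in exactly one of
  forward/reverse/unmatched/coincident.
* **Normalization scale**: the ratio of median provisional-candidate
  amplitudes, a robust statistic; with fewer than 5 candidates on either
  channel it falls back to the ratio of mean backgrounds. How the original
  instrument normalized is not published; this choice is stated as the
  package's own.

# Design decisions where the procedure was open

* **Partner-search window**: the published upper bound reads
  `t₁ + 10 v_c1 d`, which is not dimensionally a time; this package uses
  `t₁ + 10 · d / v_c1` — ten nominal transit delays — which grows for slow
  cells and shrinks for fast ones, the evidently intended adaptive
  behavior.
* **"Agreed within a factor 2.5 on average"** is implemented as the
  arithmetic mean of three max/min ratios: amplitudes, the two
  width-derived speeds, and the mean width-speed versus the delay speed
  `v_c3`. Whether `v_c3` should be compared to `v_c1`, `v_c2` or their mean
  is unstated; the mean is used.
* **"Closest match"** = lowest similarity score, tie-broken by smallest
  delay.
* **Consensus speed** of an event is the mean of `v_c1`, `v_c2`, `v_c3`.
* **Coincidence removal precedes matching** (order unstated in the source
  procedure); removal-first is simpler and strictly more conservative
  about movement artifacts.
* **FOV circularity**: the width-derived speed divides a *configured* FOV
  (1.1 mm), while the depth estimate inverts a depth→FOV profile using the
  *measured* width × speed product. The package treats the FOV as an input
  parameter and does not attempt to close the loop.
* **Sensitivity profile**: `difc_sensitivity_profile()` is a synthetic
  linear table anchored so a 1.29 mm FOV (11.5 ms × 112.3 mm/s) maps to
  1.1 mm depth, since the Monte Carlo photon-transport table it stands in
  for is out of scope. It is explicitly replaceable by a user-supplied
  table from an MC code.
* **Time-reversal symmetry**: reversing time maps forward events to
  reverse events one-to-one (the leading channel swaps); the test suite
  checks exactly this formulation.
* **Units**: all currents are nA internally; `uA()` converts interface
  values quoted in microamps. Threshold rounding to the nearest 10 nA is a
  separate helper so the exact derivation (245.7 nA) stays testable.

# Problem sizes used by the test and acceptance suites

Simulation-based properties run at sizes chosen to give stable statistics
in about a minute of CPU: false-alarm properties on two 60-minute control
scans at 1 kHz; direction accuracy and delay-speed quantization on three
noiseless 10-minute scans at 5 cells/mL; count-rate linearity on
10-minute scans at 1–1000 cells/mL; calibration-slope recovery on 100
replicates of 17 synthetic animals with Poisson counts; Poisson
arrival-law checks on 200–300 reduced-rate scans; oracle-equivalence
checks on traces of ≤ 10⁴ samples against naive O(N·W) reimplementations.

# Known limitations

* Overlapping transits are not deconvolved; a merged pair of cells counts
  once (flagged via the FWHM fallback when detectable). This biases counts
  low at very high concentrations.
* Matching is greedy and sequential, not a global assignment; pathological
  candidate bursts can be paired suboptimally.
* Transits whose apex falls off the trace edge are truncated and may be
  missed; sensitivity is therefore quoted on interior events.
* The depth estimate inherits whatever error the supplied sensitivity
  profile carries; the shipped profile is a documented synthetic stand-in.
* `r_squared` from `calibration_regression()` is reported without a
  confidence interval; at small n it is optimistic.
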