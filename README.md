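# difc

Signal analysis for **diffuse in vivo flow cytometry (DiFC)** — counting rare
fluorescently-labeled circulating cells (for example circulating tumor cells)
directly in the bloodstream of a living animal, without drawing blood. Two
fiber-optic probes rest on the skin above a major vascular bundle, a few
millimeters apart; each time a labeled cell transits a probe's field of view
it produces a short fluorescence peak in that probe's detector current. The
package is for researchers who need to turn those raw two-channel current
traces into cell counts, directions (arterial vs venous), speeds, depths and
circulating concentrations — and to validate every step against synthetic
traces with known ground truth.

## What it computes

Given two detector-current series sampled at ~1 kHz:

1. **Preprocess** — estimate the slowly varying autofluorescence background
   (~10 µA) with a 2.5 s running median + 7-point moving average, subtract
   it, smooth with a 3 ms moving average, and rescale channel 2 to channel 1
   to correct probe-coupling differences.
2. **Detect** — find cell candidates: local maxima with amplitude ≥ a
   calibrated threshold (250 nA for CTFR-labeled cells) and topographic
   prominence ≥ 50 % of the threshold. Each candidate *n* on channel *c*
   gets an apex time *t(c,n)*, amplitude *A(c,n)*, interpolated FWHM, and a
   width-derived speed *v(c,n) = FOV / FWHM* (FOV ≈ 1.1 mm).
3. **Match** — pair candidates across channels in the forward (1→2,
   arterial) and reverse (2→1, venous) directions. For a channel-1 candidate
   at *t₁*, partners are sought in *[t₁ + d/v_max, t₁ + 10·d/v₁]*
   (*d* = 3 mm, *v_max* = 400 mm/s) and accepted when amplitudes and the
   three speed estimates — two widths plus the delay speed
   *v_c3 = d/(t₂ − t₁)* — agree within a factor 2.5 on average. Same-sample
   coincident peaks are discarded as movement artifacts; unpaired candidates
   are dropped. This is what pushes the false-alarm rate an order of
   magnitude below a single fiber's.
4. **Quantify / calibrate** — count rates per direction and interval, SNR
   (`20·log10(I/σ)`), depth from mean width × speed via a sensitivity
   profile, concentration from count rate ÷ sampled volume rate
   (≈ 0.284 mL/min), reference-microsphere threshold derivation, and
   blood-sample counting.

A seeded **simulator** (`simulate_scan()`) generates both-channel traces with
Poisson cell arrivals, Gaussian transit pulses, log-normal amplitudes,
baseline + noise, and single-channel / coincident artifact spikes — with the
full ground truth returned for evaluation.

## Worked example

```r
library(difc)

scan <- simulate_scan(sim_config(duration = 600, concentration = 50, seed = 1))
res  <- difc_process(scan$trace)     # preprocess -> detect -> match
glance(res$match)
#>   n_candidates n_forward n_reverse n_unmatched n_coincident_pairs ...
#> 1          247       108        12           7                  0

evaluate_against_truth(res$match, scan$truth)
#>   n_events n_truth n_truth_detectable n_associated direction_accuracy ...
#> 1      120     134                120          120                  1
```

The 600 s scan at 50 cells/mL produced 134 true transits, of which 120 had
above-threshold pulses on both channels; all 120 were matched with the
correct flow direction (the remaining truth events fell below the 250 nA
threshold on at least one channel). Downstream quantities:

```r
g <- glance(res$match)
concentration_from_rate(g$forward_rate_per_min + g$reverse_rate_per_min)
#> 42.3  # cells/mL detected (of 50 simulated; sub-threshold transits are unseen)

ev <- tidy(res$match)
mean(ev$v_consensus[ev$direction == "forward"])
#> 111.3  # mm/s, arterial

snr_db(503, 40)          # 22.0 dB
in_vivo_threshold(calibration_model())   # 245.7 nA -> round_threshold() -> 250
vessel_flow_rate(112.3, 0.25)            # 5.5 uL/s
```

`plot_trace()`, `autoplot()` on a match, and `plot_far_sweep()` give the
standard diagnostic figures. A thin command-line wrapper lives at
`inst/cli/difc.R` (`simulate`, `process`, `far-sweep`, `calibrate`,
`count-sample`).

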