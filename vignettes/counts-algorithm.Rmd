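---
title: "From raw acceleration to activity counts: the algorithm and its validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From raw acceleration to activity counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epochcounts)
```

## The quantity being computed

Epoch-based activity counts are the oldest and most widely used summary of
wrist- and hip-worn accelerometer data: a unitless, device-defined number per
fixed time window ("epoch", typically 10-60 s) that accumulates band-pass
filtered, rectified, quantized acceleration. Counts are **not** a universal
unit — they are defined by a specific processing chain and its parameters —
and this package implements one specific, widely deployed chain: the one used
by ActiGraph's ActiLife and CentrePoint software for the wGT3X-BT, GT9X and
CentrePoint Insight Watch (CPIW) device generations. The chain descends from
the analog AM7164 watch, whose band-pass amplifier and 8-bit quantizer fixed
the counts scale everything since has replicated.

## The processing chain

Input is a 1- or 3-axis series of acceleration in g units at an admissible
sampling rate: 30-100 Hz in multiples of 10 Hz for the standard path, or
32/64/128/256 Hz for the CPIW path. Axes are processed fully independently.

1. **Resampling to 30 Hz.** CPIW recordings are resampled to 30 Hz (here by
   linear interpolation onto the exact 30 Hz grid — see *Numerical choices*).
   On the standard path, 30 Hz passes through; 60 and 90 Hz are decimated
   directly by keeping every 2nd or 3rd sample (phase 0); the remaining rates
   are first up-sampled by 3 via zero insertion followed by the first-order
   low-pass recursion
   $w_i = \tfrac{3\pi}{\pi+6}(v_i + v_{i-1}) + \tfrac{6-\pi}{\pi+6} w_{i-1}$
   (zero initial state), then decimated by `rate/10`. The recursion's DC gain
   is exactly 3, compensating the 1/3 duty cycle of zero insertion.
2. **Band-pass filtering.** A 7th-order IIR filter whose magnitude response
   at 30 Hz peaks at 0.759 Hz and falls to half gain (−6 dB) near 0.212 and
   2.15 Hz — the band compatible with human movement. Gravity/orientation
   (DC) and high-frequency artifact are rejected. The filter starts from the
   steady-state step-response initial condition computed from each axis'
   first sample, so a recording that begins at rest produces no startup
   transient.
3. **Rescale** by $a = \frac{3.0/4096.0}{2.6/256.0}\times 237.5 \approx
   17.127404$, mapping the filtered signal onto the legacy AM7164 range.
4. **Rectify** (absolute value).
5. **Threshold**: values above 128 clip to 128, values in $[4,128]$ are
   floored to integers, values below the deadband 4 become 0. From here on
   everything is exact integer arithmetic, so no float drift can reach the
   output.
6. **Decimate to 10 Hz** by non-overlapping three-sample averages, floored;
   a trailing remainder of 1-2 samples is dropped.
7. **Sum per epoch** over half-open blocks of $10\,l$ samples for epoch
   length $l$ seconds; an incomplete final epoch is dropped. Each per-axis
   epoch count is therefore an integer in $[0,\ 128\times 10\times l]$.

```{r example}
raw <- generate_white_noise(duration = 60, sample_rate = 40, n_axes = 3,
                            seed = 42)
counts <- activity_counts(raw, sample_rate = 40, epoch = 10)
counts
glance(counts)
```

`count_stages()` exposes every intermediate series for waveform-level
inspection, and `autoplot()` methods plot counts and the filter response.

## The band-pass coefficients

Two coefficient sets ship with the package and can be selected (or replaced
outright) via `count_filter()`:

* `"full"` — the default: the full-precision coefficient set used by the
  ActiLife software, as distributed in ActiGraph's open-source
  implementation of the algorithm.
* `"rounded"` — the same set rounded to 3 significant digits, the form in
  which the coefficients are usually quoted in print.

The choice of default is deliberate and matters. The filter's poles lie at
radii 0.96-0.99 inside the unit circle, so its response is extremely
sensitive to coefficient perturbation: rounding to 3 significant digits moves
the response peak from 0.759 Hz to about 0.99 Hz and turns the gentle
band-pass into a sharp resonance. The rounded set is therefore suitable for
display and provenance, but not for computing counts or characterizing the
band. Two facts tie the full set to the rounded one: `signif(full, 3)`
reproduces the rounded set coefficient-for-coefficient, and the full set
reproduces the published response landmarks (peak 0.759 Hz, half-gain 0.212
and ≈2.1 Hz). Both facts are asserted in the test suite.

```{r landmarks}
glance(count_filter())
```

## Steady-state initialization

The filter is realized in transposed direct-form II (7 delay registers).
`steady_state_init()` solves the linear fixed-point equations of that state
update under unit input and scales by the first sample, yielding the state
from which a constant input produces its steady-state output — here
essentially zero, since $H(1)\approx 0$ — from the very first sample. The
contract is behavioral (constant in, constant out from sample 0), so any
realization with identical input-output behavior is acceptable; the
independent reference implementation reaches the same initialization by a
different route, running a direct-form I difference equation whose
pre-history is the constant extension of the first sample.

## What the synthetic validation shows — and what it does not

`cross_validate()` replicates a four-case differential design: Gaussian
white noise at 30 or 40 Hz, summarized into 10 or 30 s epochs, computed both
by the vectorized pipeline (`activity_counts()`) and by an independent,
deliberately naive scalar-loop implementation (`oracle_counts()`) that
shares no stage code. The package's default design runs 100 simulations per
case of 60 s each; the acceptance suite requires exactly zero mismatched
epoch values. White noise is broad-band, so every branch of the filter,
quantizer and decimation logic is exercised; with the default 1 g noise
standard deviation the rescaled filtered signal straddles both the deadband
and the ceiling, so both thresholds are active. (The noise amplitude and
trial duration are package choices: 1 g places the signal across the
quantizer's full range, and 60 s gives at least two complete epochs in every
case. 100 simulations per case keeps the default validation run fast;
the design scales to more via `simulation_cases()`.)

Two caveats delimit what passing this validation demonstrates. First, it
shows self-consistency of two independent implementations of the same
specification, not agreement with the vendor's binaries — those are
proprietary, and bit-level agreement with them cannot be established from
public material alone. Second, synthetic white noise is not real wear data:
it has no gravity component, no posture changes, no autocorrelation and no
non-wear periods, so the validation says nothing about, e.g., wear-time
algorithms downstream.

## Numerical choices and edge-case policy

* **CPIW resampling** is linear interpolation onto the 30 Hz grid. The cloud
  service's exact resampler is not public; linear interpolation is the
  simplest method consistent with "resample to 30 Hz" and is preceded in the
  device by an anti-aliasing analog low-pass. It is a documented stand-in,
  injectable via the module boundary (`resample_cpiw_to_30()`), not a claim
  about vendor behavior.
* **Decimation phase** is 0: the first sample is always kept.
* **Epoch boundaries** are half-open: sample $j$ belongs to epoch
  $\lfloor j/(10 l)\rfloor$. Closed-on-both-ends boundaries would
  double-count the shared sample and could exceed the $128\times10\times l$
  ceiling.
* **Trailing partial blocks** (a 1-2 sample remainder at the 10 Hz stage, an
  incomplete final epoch) are dropped, not padded: padding would fabricate
  data, and epoch-complete reporting is the field's convention. This is a
  package decision; whether vendor software pads is not asserted.
* **Boundary values** of the quantizer: 4.0 maps to 4 (the middle branch is
  inclusive on both ends), values just below 4 map to 0, 128 maps to 128.
* **Non-finite samples** are rejected at input with the offending sample
  index; sub-second epoch lengths are rejected because the 10 Hz stage makes
  an epoch a whole number of 10-sample blocks.
* **Empty and length-1 inputs** are defined: empty in, empty out; a
  length-1 series filters to its steady-state output.
* **Half-gain landmarks** are located on the linear gain scale (−6 dB = half
  magnitude) by linear interpolation between the bracketing points of a
  0.001 Hz grid.

## Problem sizes used in the shipped checks

The test suite and acceptance script run entirely from generated data: the
differential validation uses 4 cases × 100 simulations × 60 s; the ceiling
and DC-rejection sweeps cover all twelve admissible rates with ~60 s
signals; response landmarks use a 15 000-point grid. These sizes keep the
whole suite under a minute on a laptop while leaving every code path
exercised.

## Known limitations

* No vector-magnitude counts, cut-point classification, non-wear detection,
  or alternative metrics (ENMO, Activity Index); counts are reported per
  axis in input order.
* No parsing of vendor binary formats (GT3X/AGD) or the vendor CSV header;
  input is plain CSV plus an explicit sampling rate (never inferred from
  timestamps).
* Idle-sleep-mode reconstruction and calibration/temperature correction are
  out of scope; the input is assumed to be calibrated acceleration in g.
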