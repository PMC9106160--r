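---
title: "Detecting gait events from shank angular velocity: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting gait events from shank angular velocity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitevents)
```

## The model

During walking, the shank (the segment between knee and ankle) swings
forward once per gait cycle. Projected onto the sagittal plane, its angular
velocity shows a stereotyped pattern: a small, low-amplitude oscillation
during stance, then a sharp reversal into a **negative minimum around
toe-off**, a **dominant positive peak at midswing** as the leg swings
through, and a second **negative minimum around heel strike** as the leg
decelerates into contact. The dual-minima rule turns this morphology into
an event detector:

1. find the dominant positive peaks — **midswing (MS)** anchors;
2. the nearest negative-valued minimum before each MS is **toe-off (TO)**;
3. the nearest one after it is **heel strike (HS)**.

The substrate is built from two markers on the tibia, proximal $(x_1, y_1)$
and distal $(x_2, y_2)$, projected onto the plane spanned by the direction
of progression ($x$) and the vertical ($y$):

$$\theta = \operatorname{atan2}(y_1 - y_2,\; x_1 - x_2), \qquad
\omega = \frac{d\theta}{dt}.$$

A four-quadrant arctangent plus unwrapping is used because a plain
arctangent is ambiguous across quadrants; a vertical shank reads
$\pi/2$ rad. The derivative is taken by central differences (one-sided at
the series ends) and low-pass filtered. All internal angles are radians and
rad/s; conversion to deg/s is left to presentation layers, which avoids a
class of unit bugs.

The method's appeal is that it needs no force platform: events come from
kinematics alone, and the force signal — where available — serves as the
reference to validate against, via a simple threshold (upward crossing =
HS, downward = TO).

### Assumptions

* The velocity waveform has exactly one dominant positive peak per cycle
  flanked by negative minima. Gait styles that violate this (shuffling
  without a swing peak, severe multi-peaked swing) will defeat the rule.
* The marker pair is roughly aligned with the bone axis; the projection
  treats the motion as planar. Strong circumduction mixes planes and
  degrades the orientation estimate.
* The lab frame is known. Because recording conventions differ, the axis
  map (which axis is vertical, which is the walking direction) is explicit
  input, and an auto-orientation step flips the velocity sign when its
  dominant peaks come out negative.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `fc` (cutoff) | 4 | Hz | low-pass for the velocity; walking kinematics live below ~6 Hz, soft-tissue noise above |
| `order` | 4 | — | effective zero-phase Butterworth order |
| `peak_frac` | 0.5 | — | relative height a positive peak needs to qualify as MS |
| `min_cycle_s` | 0.4 | s | minimum MS spacing; a cadence ceiling of 150 strides/min |
| `threshold_n` | 20 | N | GRF threshold for reference events, the common treadmill convention |
| `debounce_s` | 0.05 | s | shortest stance/swing episode accepted by the GRF detector |

Every detection criterion is *relative* (to the peak-height distribution,
or to spacing in time), so detection is invariant to uniform positive
scaling of the velocity — amplitude calibration does not matter.

## Numerical choices

**Filter realization.** A Butterworth design of order `order/2` run forward
and then backward: zero phase lag, and the stated `order` is the effective
combined order, the convention of the gait-analysis literature. Zero phase
matters because a causal filter would delay every event by the group
delay. Edges are padded with odd (point-symmetric) reflection. The
reflection pivots on the *median of the five outermost samples* rather than
the raw endpoint: the endpoint of a differentiated noisy series is itself a
one-sided difference with roughly twice the interior noise, and pivoting
the whole pad on one outlier can seed an edge transient comparable to the
signal. With the median pivot the transient stays at noise level.

**Differentiate, then filter.** For a linear zero-phase filter the order of
differentiation and filtering is interchangeable on band-limited signals
(the package tests this property explicitly, agreement within 1% RMS);
differentiating first was chosen so that the raw, unfiltered velocity
remains available for inspection.

**Qualifying MS peaks.** "Dominant positive peaks" is operationalised as:
positive local maxima with height at least `peak_frac` times the *median of
the tall-peak cluster* — the candidate heights within a factor of two of
the tallest — thinned to a minimum spacing of `min_cycle_s` keeping taller
peaks first. The cluster median (rather than the median of *all* positive
maxima) is deliberate: a realistic velocity trace contains several small
stance-phase maxima per cycle, and with noise their count can exceed the MS
count, dragging a global median below the stance-ripple height and letting
sub-cycle peaks qualify. The tall-cluster median keeps the criterion
relative (scaling-invariant) while anchoring it to the peaks that are
actually of MS stature.

**Auto-orientation.** The sign decision compares the 1% and 99% quantiles
of the filtered velocity rather than min/max, so a handful of edge or noise
samples cannot flip the signal.

**Tie-breaks and degenerate input.** Plateaus at a peak or minimum count
once, at their first sample. Coincident marker points are a
degenerate-geometry error, not NaN propagation. MS/TO/HS are reported at
sample resolution — a peak-picker's natural granularity — while the
zero-crossing estimate is linearly interpolated between its bracketing
samples, since a crossing genuinely lies between samples.

**Exact stance/swing/stride identity.** Stride time is computed as
`(to - hs_start) + (hs_end - to)`, which equals `hs_end - hs_start` to
rounding but makes `stance + swing == stride` hold *bit-exactly*, so
downstream consistency checks can use equality rather than tolerances.

**Event matching.** Predicted events are paired to reference events of the
same side and kind greedily by smallest gap, one-to-one, and never beyond
half the local reference stride — a prediction cannot be matched across a
cycle boundary. Greedy matching is validated in the test suite against an
exhaustive optimal-assignment oracle on small instances. The error sign
convention is `e = t_ref - t_pred`: positive means the prediction came
early. Summaries use the sample (n − 1) standard deviation; single-error
groups report SD as not available. The Bland–Altman coefficient of
variation is the SD of differences over the grand mean of the pair means,
×100 — one of several circulating definitions, chosen and documented here
because the quantity has no universal one.

## What the simulator emulates — and what it does not

`synthetic_config()` / `generate_trial()` produce bilateral trials with the
structure the detector assumes: per cycle, a small positive stance bump, a
negative minimum placed `to_min_lead_ms` *before* true toe-off, a dominant
midswing peak, and a negative minimum `hs_min_lag_ms` *after* true heel
strike; the orientation is the integral of this waveform; two tibia markers
per side ride on a 0.40 m segment about a gently translating ankle point,
with i.i.d. Gaussian positional noise; and the per-belt vertical GRF is a
smoothed trapezoid whose threshold crossings fall exactly on the true
events, so force-based reference extraction is exact by construction.

Defaults describe slow treadmill walking of a transfemoral-amputee-like
gait: stride 1.2 s (50 strides/min), stance fraction 0.62, midswing peak
5 rad/s, 2 mm marker noise, markers at 200 Hz, force at 1000 Hz, and —
crucially — *asymmetric* toe-off minimum leads: 80 ms on the left ("sound")
and 35 ms on the right ("prosthetic") leg, with small heel-strike lags of
5/13 ms. These offsets make the simulator exercise the method's known
failure signature: TO predicted early on essentially every step, more so on
the sound side, stance under- and swing over-estimated by the same amount,
while step and stride times stay nearly unbiased. The offsets are
configuration, not claims about any particular data set.

Waveform bump widths scale with the stride (σ of 5% of the stride for the
peak, 4% for the minima), balanced in area so the orientation does not
drift across cycles. These widths keep the landmarks sharp; they also put
some bump energy above 4 Hz, so the *filtered* velocity under-shoots the
analytic peak amplitude by design — tests therefore compare the raw
differentiated velocity against the analytic waveform, and the filtered
velocity against the analytic waveform passed through the same filter.

The simulator does **not** model: soft-tissue artifact correlation in time
or across markers (noise is i.i.d.), vaulting or circumduction kinematics
(timing offsets only), double-hump GRF shape (threshold crossings are all
that matter to a threshold detector), marker occlusion/gaps, or cadence
variability within a trial. Passing tests on synthetic data therefore show
that the *pipeline* is correct and that injected timing structure is
recovered faithfully — not that the detector achieves any particular
accuracy on real amputee data.

## Problem sizes

The test suite and the acceptance script run, by choice, on desk-scale
problems: single trials of 3–15 cycles for unit properties, 100 seeded
trials of 10 cycles for the asymmetry/noise study, and 20 trials of 25
cycles (≈ 1000 events per event type) for the summary statistics written by
`scripts/acceptance.R`. At these sizes the entire suite completes in well
under a minute.

## Known limitations

* The C3D layer supports the Intel-byte-order, floating-point storage
  subset; integer-scaled or DEC/MIPS files are rejected with a format
  error rather than mis-read.
* Classic C3D frame counters are 16-bit; the writer refuses trials longer
  than 32767 marker frames.
* Event times at sample resolution mean all timing errors are quantised to
  the marker period (5 ms at 200 Hz); sub-sample event localisation (e.g.
  parabolic interpolation of the minima) is deliberately out of scope.
* Step-time side attribution follows the common convention (a side's step
  runs from its own HS to the next contralateral HS); the mirrored
  convention only relabels sides.
* `detect_to_hs` requires a *negative-valued* minimum; a non-negative local
  minimum is never promoted to an event, and a cycle missing a flank at the
  trial boundary is reported incomplete rather than guessed.
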