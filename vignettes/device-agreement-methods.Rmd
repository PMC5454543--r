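---
title: "Methods: stabilometric parameters and balance-board/force-plate agreement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stabilometric parameters and balance-board/force-plate agreement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swayagree)
```

# The problem

Posturography summarizes quiet bipedal stance by the trajectory of the
center of pressure (CoP) under the feet. Laboratory force plates are the
reference instrument; consumer balance boards (four corner load cells, a
Bluetooth link, no calibration) are a tempting low-cost substitute. Before a
clinic swaps devices — or mixes several boards within one study — two
questions must be answered with measurement-agreement statistics rather
than correlations alone: does a board reproduce the plate's parameter
values, and do different board units behave alike (interchangeability)?

`swayagree` implements that analysis as a tested pipeline and, because raw
recordings from such studies are rarely deposited, pairs it with a
synthetic paired-device study generator so every stage can be validated
end to end.

# Signal model and conditioning

## CoP computation

A board reports four corner loads at positions `(±s_ml/2, ±s_ap/2)`. The
CoP is the load-weighted centroid (moment balance); the implementation and
its tests verify this against an independent torque-balance solution. Sensor
spans default to 433 mm (ML) x 238 mm (AP), published teardown values for
the common consumer board; they are configuration, not constants, because
the hardware geometry is not part of any data file.

Sign conventions are fixed once: AP positive toward anterior (top sensor
row), ML positive toward the subject's right. A force plate reports the
full wrench at its moment origin; the CoP in the contact plane a height
`dz` above that origin is `ml = (−My − Fx·dz)/Fz`, `ap = (Mx − Fy·dz)/Fz`
(floor-embedded plates use a z-down axis convention; the tests confirm the
formula against an explicit wrench-transport computation). When a board is
stacked on the plate, `dz` is the board height; the default 53 mm matches
the common board's published height. A configurable load floor (default
50 N on `ΣF` or `|Fz|`) distinguishes a mounted-but-unloaded device from a
standing subject and turns such samples into a typed error rather than a
wild CoP value.

## Resampling and filtering

Board samples arrive at a low, irregular rate; the pipeline linearly
interpolates onto a uniform 1000 Hz grid anchored at the first raw
timestamp (so board and plate grids align on the shared acquisition clock),
never extrapolating past the last sample. Both devices' CoP series are then
filtered with a 2nd-order Butterworth low-pass at 12 Hz applied forward and
backward (zero phase).

Two conditioning choices were genuinely open and are fixed as follows:

* **Filter the CoP, not the raw channels.** Every downstream parameter
  consumes the CoP; because the CoP is a smooth function of the channels
  and the filter is linear, the difference between the two orders is second
  order. Filtering the CoP keeps the pipeline identical for both device
  kinds.
* **Zero-phase handling.** The forward-backward pass squares the magnitude
  response, so the effective −6 dB point sits below the nominal 12 Hz
  cutoff; no cutoff compensation is applied, and the tests check the
  realized amplitude response against the analytic
  `|H(f)|² = (1 + (f/fc)^4)^{-1}` curve. Edges use odd-reflection padding of
  length 3 x order together with steady-state initial conditions, which
  makes a constant signal exactly invariant (the `signal` package's
  `filtfilt` zero-pads and fails that contract, so the forward-backward
  logic is implemented here, on top of `signal::butter` coefficients).

# The nine parameters

For a conditioned trajectory of `n` samples at rate `r` (duration
`(n−1)/r`):

| parameter | definition | unit |
|---|---|---|
| DOT | `Σ √(Δap² + Δml²)` | mm |
| Area | `π · c · √det S`, `S` = sample covariance of (ap, ml) | mm² |
| RMS_AP, RMS_ML | RMS deviation about the axis mean | mm |
| AdCP_AP, AdCP_ML | max − min per axis | mm |
| MV_AP, MV_ML | `Σ|Δx| / duration` | mm/s |
| TMV | DOT / duration | mm/s |

Two conventions must be made explicit because the field's usage varies:

* **Ellipse scale `c`.** The default is the large-sample 95% prediction
  ellipse, `c = χ²(2)` quantile at 0.95 ≈ 5.9915. At posturographic sample
  counts (30,001 points per 30 s trial) this is indistinguishable from the
  small-sample form `c = 2(n+1)(n−1)/(n(n−2)) · F(0.95; 2, n−2)`, which is
  available via configuration for short series.
* **Dispersion denominator.** Population form (`n`) by default, sample form
  (`n−1`) by configuration; at `n ≈ 30,000` the distinction is cosmetic,
  but naming it avoids the common SD-vs-RMS ambiguity.

Useful identities double as test oracles: `TMV · duration = DOT` exactly;
`max(MV_AP, MV_ML) ≤ TMV ≤ MV_AP + MV_ML`; `RMS ≤ AdCP` per axis; every
parameter is translation invariant; lengths scale linearly and the area
quadratically under spatial scaling.

# The agreement battery

All statistics operate on per-trial **force-plate − board differences**,
one per parameter, from simultaneous recordings (the board sits on the
plate, so both devices see the same physical trial).

* **ICC, two-way random (model 2).** Rows are targets, columns are the
  four devices; both the single-measure and average-measure forms are
  reported, each at two granularities: trial-level (subject x trial rows,
  18 x 4 in the reference design) and subject-mean (6 x 4, means over the
  three trials). The published description of this analysis mixes "average
  measures" with "single measurement", and mixes trial-level with
  subject-mean input, so the package computes all four and headlines
  ICC(2,1) on trial-level differences. Confidence bounds use the F-based
  construction (Satterthwaite df for the single form; the average-form
  interval is the Spearman–Brown transform). Negative lower bounds are
  reported as-is, never truncated; estimates are clamped to [−1, 1] only
  for display.
* **Friedman tests** across devices, tie-corrected midranks, chi-square
  reference with df = k−1, subject-mean granularity by default. An exact
  permutation mode (full `(k!)^n` enumeration) exists for small designs and
  anchors the tests.
* **Limits of agreement.** "95% confidence intervals" around the mean
  difference are implemented as mean ± 1.96 · SD of the differences (SD
  with n−1): with ~6–7% of observations falling outside in the motivating
  analysis, the band is clearly a limits-of-agreement band, not a
  standard-error band. Out-of-limit counting is strict (a value exactly on
  a limit is inside).
* **Contingency + chi-square.** Out-of-limit counts by parameter x device;
  Pearson chi-square of independence with df = (r−1)(c−1). A 9 x 4 table
  has df 24 (a published df of 43 for this layout is arithmetically
  inconsistent and is not reproduced). Parameters with zero exceedances
  carry no information about device association and are dropped from the
  chi-square (recorded in the report); no multiple-testing correction is
  applied, matching the marginal-testing convention of the field (a
  Bonferroni flag would be a one-line extension).
* **Spearman correlations** plate vs board per device (midrank-then-
  Pearson), with across-device mean and SD per parameter; trial-level
  pairing by default, subject-mean by configuration.

# What the generator emulates — and what it does not

`simulate_true_sway()` draws each axis from a stationary Ornstein–Uhlenbeck
process via its exact discretization. OU is the simplest process with
separately tunable amplitude (stationary SD `√(Dτ/2)`) and bandwidth
(relaxation time τ); defaults (τ = 1 s, SD = 3 mm per axis) give
realistic-looking quiet-stance stabilograms. It is *not* a biomechanical
claim: no inverted-pendulum dynamics, no neural feedback, no
open/closed-loop diffusion crossover, no AP/ML asymmetry by default.

`observe_with_board()` inverts the moment balance exactly (bilinear load
split), then applies per-channel gain and offset miscalibration, additive
noise, optional quantization, and jittered low-rate sampling.
`observe_with_forceplate()` builds the wrench at 1000 Hz with channel
noise. Subjects draw mass from Normal(81, 22) kg truncated at 40 kg (the
motivating cohort's moments), a stance-point offset, and a lognormal
sway-amplitude multiplier (healthy adults differ severalfold in sway
amplitude). Per-cell sub-seeds derive from a stable arithmetic hash of
(subject, device, trial), so corpora are pure functions of the master seed
and grow without perturbing existing cells. Board sampling defaults to
100 Hz with 1 ms timestamp jitter; the true raw rate of the consumer board
is undocumented, only the 1000 Hz interpolation target is fixed.

Passing tests on this generator therefore show that the *machinery* is
correct and calibrated — not that any particular physical board has these
noise figures, and not that the published cohort's numeric ICCs are
recovered (those depend on unreleased raw recordings).

## Two findings from scenario design worth knowing

Both emerged from closed-form analysis of the board model and shaped the
default and test scenarios:

* **Corner-gain errors are (almost) invisible.** Because the CoP is a
  load-weighted centroid normalized by total load, a gain error on any
  corner changes the recovered CoP, to first order, by a *translation*
  plus a small cross-axis coupling (~`(g−1)/4 · s_ml/s_ap` of AP sway into
  ML for a top-right gain `g`); the local scale stays exactly 1. Since all
  nine parameters are translation invariant, a 5% single-corner gain
  leaves a footprint of only ~0.1–1% in ML-derived parameters — far below
  trial-to-trial sway variability, so rank-based device comparisons have
  essentially no power against it at realistic study sizes. The
  deterministic direction of the effect (board ML dispersion/velocity read
  high) is tested instead.
* **Tare (net offset) errors are the agreement signal.** A net zero-error
  `Σo` inflates the measured total load and shrinks the recovered CoP by
  the factor `F/(F + Σo)` — an amplitude-proportional, subject-mass-
  dependent bias. This is the mechanism that makes plate−board differences
  consistent within subject (hence high ICCs across devices) while boards
  remain interchangeable; the default boards carry ~10 N per cell of tare
  accordingly.

# Numerical and test-design choices

* Tolerances: file round-trips at 1e-9 absolute (15 significant digits on
  disk); metric identities at 1e-12 relative; ICC against the ANOVA oracle
  at 1e-10; Friedman statistic against the sum-of-squares formulation at
  1e-12.
* Degenerate inputs are typed errors (low load, too-short series, zero
  rank variance, zero chi-square margins) except where a value is
  well-defined: an all-equal ICC matrix is 1 with a degenerate-interval
  flag, an all-tied Friedman matrix is statistic 0 with p 1, a zero-spread
  difference set has collapsed limits.
* Calibration checks use 500 replicate null studies (identical boards) at
  a reduced 10 s trial length and a fast-mixing sway (τ = 0.1 s) with
  strong subject heterogeneity (amplitude sdlog 0.7) and tare-offset
  boards at 250 Hz: chosen, before the checks were frozen, from the
  variance sizing above so that between-subject variance dominates device
  observation error (at 100 Hz, sampling-induced extreme-value jitter in
  the amplitude parameters would itself act as device noise). Under those
  conditions the trial-level Friedman false-positive rate is checked
  against its nominal 5% and trial-level ICC(2,1) medians against 0.9. The
  6-block subject-mean Friedman variant is known to be conservative at
  such small block counts (the chi-square reference overshoots the
  discrete rank distribution's tail) and is reported but not used as the
  calibration yardstick.
* Problem sizes in the test-suite (trial lengths of 3–10 s, truth rates of
  200–1000 Hz, 20–25 replicates for power-style checks) are the package's
  choice of smallest sizes at which each property is cleanly measurable.

# Known limitations

* The OU sway model underrepresents low-frequency drift and bounded-
  stationarity violations seen in long real recordings.
* No clock-synchronization or lag estimation between devices is modeled or
  corrected; simultaneity is assumed exact.
* The board model's load split is exactly bilinear; real boards add plate
  flexion and cross-talk nonlinearities, which is precisely where real
  ML-parameter disagreements likely originate.
* Quantization is uniform and per-channel; real ADCs may dither.
* The agreement battery treats the nine parameters marginally; no joint
  or multiplicity-adjusted inference is attempted.
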