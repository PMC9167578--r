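---
title: "Methods: freehand 3D ultrasound tendon morphology and mechanics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: freehand 3D ultrasound tendon morphology and mechanics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tendonmech)
```

`tendonmech` analyses acute loading effects on the free Achilles tendon:
geometry from tracked freehand 3D ultrasound sweeps, tendon force from
co-contraction-corrected plantarflexion torque, stiffness and Young's
modulus from staged contractions, and crossover-trial statistics. This
vignette records the models, the assumptions behind them, the numerical
choices, and what the synthetic-data generator does and does not emulate.
Units are fixed package-wide: mm, mm², ml (1 ml = 1000 mm³), N, N·m, s;
world coordinates are a right-handed frame in mm, pixels are (row, column)
from the top-left corner.

## Geometry from tracked sweeps

A sweep is an ordered sequence of frames, each holding a probe pose and a
segmented cross-section contour in sub-pixel image coordinates. Pixel
`(r, c)` maps to the image plane as `(c·sx, r·sy, 0)` mm, then through the
rigid calibration transform into the probe frame, then through the pose
into the world. Both transforms are rigid, so pairwise distances are
preserved up to the fixed pixel spacing; rotations must be orthonormal
within 1e-6 or the transform is rejected.

Free-tendon length is the straight chord between the two landmark points
(calcaneal notch, soleus muscle–tendon junction). The chord — rather than
a curved arclength — matches how a two-point landmark tool measures a
short, near-straight tendon; on curved specimens it is a lower bound.

Each contour's **station** is the projection of its centroid onto the
landmark chord. This ordering definition is a package choice: it is exact
for straight tendons and well behaved under small pose noise. After
ordering, stations must be strictly increasing; duplicates raise an error
rather than being merged silently. Contour areas are shoelace areas; 3D
contours are first checked for planarity (maximum out-of-plane deviation
0.5 mm, matching the imaging system's axial/lateral resolution) and
projected onto their best-fit plane. Self-intersecting polygons are
rejected, not "repaired".

Volume is the trapezoidal integral of the linearly interpolated area
profile over the slice span, divided by 1000; the mean CSA is the same
integral divided by the span, making `meanCSA × span ≡ volume` an exact
identity rather than an approximation. Linear area interpolation is a
deliberate, fully testable stand-in for proprietary surface-interpolation
reconstructions: for smooth profiles contoured at the practised 5–10 mm
intervals it reproduces any of our analytic phantoms well inside the
±0.5 ml accuracy reported for physical phantom scans of such systems. For
markedly non-convex slices a surface (shape) interpolation could differ;
we note this rather than guess at an unspecified algorithm.

## Force from torque

Surface EMG is conditioned with a 4th-order Butterworth 20–450 Hz bandpass
applied forward–backward (zero phase). The order is the surface-EMG
community default; zero-phase filtering matters because phase distortion
would misalign the envelope with torque in the regression below. The
signal is reflect-padded (about three low-frequency periods) before
`filtfilt` so edge transients do not leak into the envelope; DC rejection
of the realized filter exceeds 40 dB. One octave-free step above the upper
edge (500 Hz at 2 kHz sampling) the realized forward–backward response
retains about 21% amplitude — users needing a sharper cutoff can raise
`order`.

The envelope is a centred sliding-window RMS (default 200 samples at
1 kHz); at the edges the window shrinks to the available samples, so a
constant signal maps to its absolute value everywhere.

The antagonist model `torque = P1·envelope + P2` is fitted by ordinary
least squares on samples pooled across the (up to three) dorsiflexion
ramps. Pooling time-matched samples, rather than regressing trial peaks,
uses the whole ramp and gives standard errors for the recovery tests; a
per-trial alternative can be emulated by passing single-trial data frames.
A constant envelope leaves the slope unidentified and errors. The fitted
line converts the TA envelope observed during plantarflexion into an
antagonist torque added to the net torque; tendon force divides the true
torque by the moment arm `d1 − d2` (in metres), which requires
`d1 > d2 > 0`.

MVIC acceptance implements the two-highest-within-10% rule on per-trial
plateau peaks (moving-average maximum over a 0.5 s hold window — a
single-sample spike cannot set the MVIC). Staged trials extract the mean
torque over the central 50% of the hold phase; the hold boundaries come
from the known ramp duration. The central-50% window is a package choice —
holds are standardized at 8 s, but no averaging window is prescribed by
common protocols — and deviations beyond ±5% of the target raise a
re-trial flag rather than silently passing.

## Mechanics

Elongation is level length minus resting length, each the mean of two
repeat scans; repeat discrepancies beyond 1 mm warn. Small negative
elongations (resting noise exceeding the 35% level's stretch) are flagged,
never clamped, so downstream fits see the data as measured.

Stiffness is the OLS slope of force on elongation with a free intercept
(`force_through_origin = FALSE` by default): the force–elongation relation
over 35–75% MVIC is locally linear but does not pass through the origin
because the toe region is excluded. Stress (`F/CSA`, MPa) and strain
(`e/L0`, stored as a fraction; percent only in reports — keeping the
modulus in MPa without hidden factors of 100) are linear rescalings, so
`E = k·L0/CSA` holds to machine precision whenever both fits use the same
points; the test suite enforces 1e-9 relative. The slope is invariant to
the order of the levels, as it must be for a staged protocol performed in
random order.

## Crossover statistics

The 2 (time) × 3 (intervention) within-subject ANOVA is computed by
direct sums-of-squares decomposition over the subject, time, intervention
and time×intervention strata, each effect tested against its own
subject×effect stratum. The decomposition is algebraically identical to
`aov(y ~ time*intervention + Error(subject/(time*intervention)))` — the
test suite checks all three F statistics against `aov` — but runs an
order of magnitude faster, which matters for the 2000-replicate null
calibration. Sphericity is assumed (no correction) and pairwise contrasts
carry no multiplicity adjustment, matching how such trials conventionally
report uncorrected df and unadjusted p-values; with three intervention
levels the interaction stratum has only two numerator df, so sphericity
violations are mild. Period (week) effects are recorded in the dataset but
ignored by the primary model; the washout is treated as metadata, no
carryover model is fitted.

Contrasts and simple effects operate on per-subject change scores
(post − pre); the effect size is the difference of mean change scores over
the pooled (n−1-weighted) change-score SD. Normality checking uses the
Lilliefors-corrected one-sample KS test (parameters estimated from the
sample — the uncorrected KS null would be anti-conservative).

ICC: the label "ICC(3,1) with absolute agreement" mixes two classical
conventions (ICC(3,1) is the consistency form of the two-way mixed
model). Both forms are computed from the same mean squares; **absolute
agreement is the reported default**, following the stated intent of
agreement-based reliability, and `form = "consistency"` switches. CIs use
the McGraw–Wong F-distribution bounds. `SEM = SD·√(1−ICC)` and
`MDC = SEM·1.96·√2` are provided as explicit helpers so reliability
reports state their arithmetic.

The sample-size utility uses the paired normal approximation
`n = (z₁₋α/2 + z_power)² · 2(1−ρ)/ES²` and reports the formula alongside
the number. At ES = 0.5, α = 0.05, power = 80%, ρ = 0.2 it returns 51 —
published crossover trials in this area have reported substantially
smaller pilot-based numbers, which standard formulas do not reproduce;
the utility is deliberately transparent rather than tuned to any
particular published value.

## What the generator emulates — and what it does not

The generator produces every input with known ground truth:

* **Phantoms**: straight tubes with constant, linearly tapering or
  quadratic area profiles and closed-form volume. A straight centerline is
  the default because the free Achilles tendon is short and near-straight;
  the two-point length method presumes as much.
* **Sweeps**: frames every 0.1 mm (the slow-sweep acquisition spacing),
  circular cross-sections sampled as inscribed 64-gons, isotropic Gaussian
  translation jitter and small-angle rotation jitter. The default noise
  (0.2 mm SD translation) keeps ~95% of point-reconstruction errors within
  ±0.4 mm, the accuracy of a calibrated tracked probe. An inscribed 64-gon
  underestimates circle area by `1 − (n/2π)·sin(2π/n)` ≈ 0.16% — visible
  in the volume-recovery numbers as a constant, known bias.
* **EMG/torque trials**: 1 kHz sampling; dorsiflexion ramps whose torque
  starts at the passive level `P2` so every sample lies on the
  co-contraction line; staged ramp-and-hold plantarflexion at
  35/55/75% MVIC with a configurable ramp (default 2 s — the
  within-repetition ramp profile of loading protocols is rarely printed,
  so it is exposed as configuration rather than hard-coded); raw EMG as
  20–450 Hz band-limited noise amplitude-modulated so its RMS envelope
  tracks the programmed envelope, exercising the full filter+envelope
  chain. Antagonist activity during plantarflexion defaults to 8% of the
  dorsiflexion-maximum envelope.
* **Subjects**: MVIC torque ~100 N·m, moment arm 43.3 ± 3.9 mm, resting
  length ~50 mm, mean CSA ~44 mm² (≈2.2 ml), stiffness centred near
  330 N mm⁻¹ truncated to a 200–600 N mm⁻¹ physiologic band.
* **Crossover datasets**: subject baselines as a shared random effect
  (within-subject correlation 0.8) plus session noise; intervention
  changes drawn per cell. The default effects are calibrated to the
  acute-loading pattern the pipeline targets: volume changes of −0.3,
  −0.05 and −0.1 ml and stiffness changes of −67.35, +37.78 and
  −36.45 N mm⁻¹ for the long/high, short/high and long/low protocols, on
  baselines of 2.2 ml and 328 N mm⁻¹. Change-score SDs (0.12 ml,
  45 N mm⁻¹) are single realistic values; reported pairwise effect sizes
  in real cohorts arise from heterogeneous SDs that a single pair of SDs
  cannot simultaneously match, so the generator targets the sign and
  ordering of the group changes, not any specific effect-size triplet.

Not emulated: speckle-level B-mode image formation, automatic
segmentation, tracker hardware, tendon creep/viscoelasticity within a
session, and fatigue. Consequently, passing tests demonstrate that the
*analysis* chain is correct and unbiased under realistic noise — they do
not validate manual segmentation quality or probe-handling technique on
real tissue.

## Problem sizes and test design

The test suite runs the reconstruction oracles at 0.1 mm spacing with
64-point contours (the acquisition-fidelity configuration) and end-to-end
pipeline checks at 0.5 mm spacing with 32-point contours and 6 subjects —
sizes chosen so the full suite completes in well under a minute of compute
per file while leaving every numerical tolerance unchanged. Monte-Carlo
calibrations use 100 replicates for parameter recovery (co-contraction
coverage at 3 SE, stiffness bias < 2%), 2000 replicates for the
interaction test's type-I error (0.05 ± 0.02), and 50 replicates of
n = 200 for ICC bias (< 0.02). `scripts/acceptance.R` recomputes all of
these from scratch, plus one full 16-subject pipeline run at 0.1 mm
spacing, under a single command-line seed.

## Known limitations

* Linear area interpolation between contours; surface-based shape
  interpolation may differ on strongly non-convex slices.
* The chord-length definition underestimates arclength on curved tendons.
* Stations from centroid projection can fold back under extreme pose
  noise; the reconstruction then stops with an error instead of
  reordering silently.
* The ANOVA requires complete balanced data; subjects with missing cells
  must be dropped or imputed upstream.
* The co-contraction model is linear by construction; saturation of the
  EMG–torque relation near maximal effort is not modelled.
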