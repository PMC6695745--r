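---
title: "accelcal: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{accelcal: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(accelcal)
```

This vignette is the package's own account of its science: the models and
their assumptions, the parameters that matter, what the synthetic-data
generator emulates (and what it does not), the numerical choices, and the
known limitations. It states no empirical result that the test suite or the
acceptance script does not itself compute.

## 1. Why MET calibration is not age-equivalent

The MET normalizes activity oxygen uptake by *resting* oxygen uptake,
`MET = VO2gross / VO2rest`. Resting metabolism per kilogram roughly halves
between early childhood and adulthood, so a child walking beside an adult at
the same speed registers a *lower* MET while doing equal or greater relative
work. Calibrating accelerometer cut-points at fixed MET values (1.5, 3.0,
6.0, 9.0 for LPA/MPA/VPA/VVPA) therefore demands more acceleration of
children than of adults before crediting the same intensity level, and
free-living comparisons across ages inherit that bias.

The alternative criterion implemented here is the mass-specific net oxygen
cost of dynamic movement,

$$\mathrm{VO_{2net}} = \frac{\mathrm{VO_{2gross}} - \mathrm{VO_{2stand}}}{\text{weight}}
  \quad [\mathrm{mL\,min^{-1}\,kg^{-1}}],$$

which subtracts the *standing* rather than the resting baseline: it isolates
the energy requirement of movement itself, which is also what a body-worn
accelerometer senses. Its age-equivalence rests on the dimensionless
equivalent speed

$$\mathrm{Speed_{eq}} = \frac{V^2}{g\,h},$$

a Froude-type number: individuals of different stature moving at equal
`Speed_eq` move with kinematically equivalent gaits and — the empirical
claim this package's generator encodes as its ground truth — equal
`VO2net`. Five structural assumptions follow, and the generator reproduces
all of them:

1. hip accelerometer output vs absolute speed falls on one line for all age
   groups (the hip senses total mechanical work);
2. thigh output is inflated in shorter individuals (more internal work of
   limb movement), so thigh lines diverge;
3. `VO2net` vs `Speed_eq` is one common line across age groups;
4. MET vs `Speed_eq` separates by age group (resting metabolism differs);
5. `VO2net` vs accelerometer output separates by age group, ordered
   children < adolescents < adults in mg at fixed `VO2net`.

## 2. Processing and calibration procedure

**Signal chain** (in protocol order): resample to 30 Hz → truncate to
±6 g → band-pass 0.29–10 Hz, zero phase → per-epoch mean of the triaxial
Euclidean norm × 1000 (mg), 3-s epochs, trailing partial epochs dropped.
The band retains the frequency content informative of human movement while
rejecting the static gravity component and high-frequency noise; the 30 Hz /
±6 g envelope matches the device class used in free-living cohorts. ENMO
(`max(‖v‖ − 1, 0)` per sample, epoch mean) is provided for comparison only:
because it discards negative lobes it treats low-frequency/large-amplitude
(adult-like) and high-frequency/small-amplitude (child-like) movement
differently and is not age-equivalent.

**Criterion values**: resting VO2 is the minimum of a centered 2-min moving
average of the 20-min seated rest trace, computed on a regular 5-s grid
(linear interpolation); each stage contributes the mean of the steady-state
window, stage-relative time [165 s, 225 s). Sub-standing `VO2net` values are
flagged, never clamped.

**Calibration**: an ordinary least-squares regression of `VO2net` on MET
over the adult stage records (the stand record, a valid (MET ≈ 1.25,
VO2net = 0) point, is included; a config switch can drop it) maps the MET
cut-points to common `VO2net` cut-points. Per age group × placement,
criterion-vs-mg curves are fitted (Section 4), anchored at (0 mg → 0
VO2net) or (0 mg → 1 MET), and inverted: the cut-point is the smallest mg
on a 1-mg grid whose predicted response reaches the criterion value,
reported as an integer. Cut-points above the fitted range raise an
extrapolation error rather than extrapolating silently.

In adults, the `VO2net` cut-points are by definition the regression images
of the MET cut-points computed *from the same adult data*, so both methods
select the same adult operating points; the package encodes this identity
structurally (the adult MET-based cells are the VO2net-based cells) rather
than re-estimating it through a second spline, which would only add
estimation noise to an exact identity.

## 3. Parameters

| parameter | default | units | why |
|---|---|---|---|
| filter band | 0.29–10 | Hz | movement-information band |
| filter order | 4 (band-pass) | — | common accelerometry practice; zero-phase forward–backward application |
| working rate | 30 | Hz | target-device envelope |
| clip range | ±6 | g | target-device envelope |
| epoch length | 3 | s | captures children's intermittent bursts |
| MET cut-points | 1.5/3.0/6.0/9.0 | MET | conventional LPA/MPA/VPA/VVPA levels |
| REE window | 120 | s | published resting-energy rule |
| steady-state window | [165, 225) | s | avoids on-transient (τ ≈ 30 s) |
| anchor weight | 1000× | — | pseudo-observation enforcing the anchor |
| inversion grid | 1 | mg | integer cut-point reporting |
| non-wear rule | ≥60 min still, SD < 3 mg | — | idle-flag substitute for CSV input |
| night window | [23:00, 06:00) | — | age-dependent sleep wear habits |
| valid day | ≥720 | min wear | inclusion rule |
| g | 9.81 | m/s² | fixed exactly |

Speeds are stored in km/h as printed in protocol descriptions and converted
by ÷3.6 for all `Speed_eq` arithmetic.

## 4. Numerical choices in the curve fit

Treadmill calibration data cluster at the protocol speeds: for one group ×
placement there are ~70 points in only 8 mg clusters (anchor, stand, six
speeds) spread over 0–2600 mg. Three consequences drove the implementation:

* **Basis and smoothing.** An all-knots natural smoothing spline
  (`stats::smooth.spline`) with GCV is unstable on this design: GCV can
  overfit wiggles in the empty regions between clusters, and natural
  boundary conditions corrupt the two outer intervals. The package instead
  fits a cubic regression spline (mgcv) with basis dimension matched to the
  number of clusters (k ≤ 10) and GCV-chosen smoothing.
* **Heteroscedasticity.** VO2 scatter grows roughly proportionally with the
  response, so an unweighted fit lets the running stages dominate. A second
  pass re-weights by the inverse squared fitted level.
* **Monotonicity.** Intensity curves must be non-decreasing before
  inversion. Rather than isotonic *post-projection* of an unconstrained fit
  (which pools any wiggle into a flat stretch — exactly where a cut-point
  can land), the final fit re-estimates the spline coefficients under a
  monotonicity constraint (`mgcv::mono.con` + `mgcv::pcls`) at the
  GCV-chosen smoothing parameter. Isotonic projection remains as a safety
  net on the evaluation grid.
* **Anchor.** The anchor enters as a high-weight pseudo-observation and is
  additionally pinned exactly at 0 mg on the evaluation grid, so the
  documented invariant (curve through the anchor to 1e-6) holds by
  construction; a finite weight alone cannot guarantee it.
* **Exact-data path.** When the data determine the response exactly (≤10
  distinct mg values with zero within-cluster spread — the generator's
  noise-free limit), the fit is an exact interpolant built in log–log space
  of the increment above the anchor. Energy-cost curves are power-law-like,
  for which log–log interpolation is exact; a global cubic spline through
  the sharp anchor-to-stand kink instead rings far into the sparse upper
  intervals.
* **Ties and rounding.** Replicate mg values are collapsed to weighted
  cluster means for path selection; reported `VO2net` cut-points round half
  *up* to 1 decimal (base `round()` rounds half to even, and binary storage
  of x.x5 values would otherwise make the reported value representation-
  dependent); full precision is retained internally.

## 5. The synthetic world

No raw study data are deposited, so the generator *is* the package's data
world, with every group difference a config parameter (a "no difference"
null config is one override away).

**Physiology.** `VO2net = A·Speed_eq^p` with one shared (A, p) across
groups — assumption 3 encoded as truth, so pipeline recovery of
age-equivalence is a real test, not a tautology. `A` is set so that adults
(1.75 m, REE 3.5 mL/min/kg, standing = 1.25 × resting) walking at 5.6 km/h
sit at 5.0 MET; `p = 1.15` puts children near the published ~4.3 MET at the
same walk. MET follows as `(stand + VO2net)/ree` with group REE 5.5 / 4.3 /
3.5 mL/min/kg (children / adolescents / adults).

**Accelerometry.** Hip mg is one shared power curve of absolute speed
(`mg = m₁·v^{2.88}`), with `m₁` tuned analytically so the adult hip MPA
cut-point lands at 167 mg; thigh multiplies it by 1.89 / 1.75 / 1.63 per
group (children inflated most). Raw lab signals are band-limited (1–6 Hz)
Gaussian carriers scaled per stage so the expected post-filter epoch mg
equals the curve value — the signal stage is exercised, not bypassed. VO2
traces approach each stage plateau mono-exponentially (τ = 30 s).

**Dispersion** (chosen a priori to reproduce the published calibration fit
quality, R² ≈ 0.96–0.99): proportional VO2 point noise (CV 0.08 on
`VO2net`, CV 0.06 on 5-s trace bins), between-subject log-normal factors
(economy 0.04, mg level 0.03, resting metabolism 0.05), stage mg CV 0.03,
anthropometric SDs per group.

**Free living.** A semi-Markov chain over the five states (each day starts
sedentary; exponential dwell times with state-specific means; bout-state
probabilities derived from target occupancies — defaulting to the published
per-category activity splits) emits 3-s epochs whose mg is uniform within
the state's band of that group's ground-truth cut-points. Night
(23:00–06:00) is planted as device-off sleep and daytime non-wear bouts as
zero signal. Because state bands are defined by the exact analytic
cut-points, noise-free classification with the matched table recovers the
planted labels exactly — the end-to-end bookkeeping oracle.

**What the generator does not emulate** (so what a green test does *not*
establish): biomechanically realistic gait waveforms (only band-limited
stochastic carriers with matched epoch mg); walk–run economy discontinuity
(one smooth `Speed_eq` curve, which overstates VO2 at the fastest run);
device idiosyncrasies (idle-sleep firmware, timestamp drift, axis
miscalibration); population-representative activity profiles or
between-day habit structure; posture (the thigh placement's sit/stand
information is not modelled).

## 6. Recovery accuracy and its limits

With 10 subjects per group at the published dispersion, the sampling error
of a stage-cluster mean alone gives every recovered cut-point a ~3–4 %
standard deviation, and the realized resting physiology of the 10 adults
shifts *all* VO2net-based cells coherently by a further ±2.5 %. No
estimator can beat this floor from the data alone, so recovery quality is
assessed as the *mean* absolute relative error over the MPA/VPA cells of
the table (≤5 % in the acceptance suite); individual cells can and do
exceed 5 % in some seeds. In the noise-free limit recovery is exact to the
1-mg inversion grid. The raw-signal route carries one additional
systematic: the resting-VO2 rule (minimum of a 2-min moving average) is
biased low by ~2 % under trace noise — a property of the published rule
itself, inflating MET and deflating MET-based cut-points slightly.

## 7. Free-living conventions

Age maps to cut-point tables as <13 → children's, 13–16 → adolescents',
≥17 → adults'; reporting categories split adults at 50. Intensity intervals
are closed on the left (mg ≥ cut-point ⇒ that level). The night window is
half-open: an epoch starting 23:00:00 is excluded, 06:00:00 retained.
Non-wear (≥60 consecutive still minutes; an explicit idle column takes
precedence) is excluded from both numerator and denominator of wear time;
days are calendar-local; one valid day suffices for inclusion
(configurable). MVPA = MPA + VPA + VVPA.

## 8. Known limitations

* Cut-points derive from continuous treadmill walking and running only;
  intermittent and non-ambulatory activities are outside the calibration
  domain.
* The mg aggregation rule (mean post-filter vector norm per epoch) is one
  reasonable reading of a family of related intensity metrics; it is
  declared in configuration and logged in provenance so alternatives can be
  swapped.
* The published cut-point tables themselves are not reproducible at desk
  scale (the original 30-subject lab data are not deposited); parameter
  recovery on the synthetic world is the substitute, with the caveats of
  Section 6.
* `Speed_eq` equivalence is approximate at the extremes of stature, and a
  single smooth energy-cost curve blurs the walk–run transition.
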