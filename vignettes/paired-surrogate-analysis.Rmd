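---
title: "Comparing paired respiratory surrogates: models, methods and limits"
author: "resppair"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing paired respiratory surrogates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(resppair)
```

## The problem

Respiratory-correlated CT (4D CT) and gated radiotherapy both rely on an
external surrogate of breathing: an infrared marker block measuring
anterior-posterior abdominal displacement, or a pressure belt measuring
abdominal circumference change.  When the surrogate used to sort the 4D CT
is not the one monitoring treatment delivery, two systematic discrepancies
between the signals matter clinically:

* a **phase shift** -- one surrogate reaches end of inhalation (EOI) a
  fraction of a second before the other, reported both in seconds and as a
  percentage of the respiratory period; and
* a **trace-shape distortion** -- typically a steeper exhalation falloff on
  the pressure signal, with inhalation sometimes matching and sometimes not.

Both propagate through local-amplitude phase sorting into per-phase
differences in reconstructed anatomy (whole-lung volume, diaphragm apex
position) and into a mismatch between the gating window as planned and as
applied.  `resppair` implements this entire chain as testable code, with a
synthetic-data generator standing in for patient traces.

## The synthetic breathing world

`generate_internal_motion()` realizes a quasi-periodic cycle sequence.
Within a cycle of period $T_k$ and depth $d_k$ (both redrawn per cycle from
normal distributions), the amplitude over cycle fraction $u \in [0,1]$
(EOE to EOE) is

$$a(u) = d_k \, \sin^{2n}(\pi u),$$

a raised-sine power.  $n$ (`plateau_exponent`, default 1.5) controls the
end-of-exhalation dwell that free breathing shows; $n = 1$ is a pure raised
cosine.  A linear baseline drift and white Gaussian noise are added.  The
EOI sits exactly at $u = 1/2$.  Defaults: mean period 4 s (cohort draws
span 2.5-5.6 s), period SD 10% of the mean, depth 100 arbitrary units
(SD 10), 25 Hz sampling for the displacement-style stream and 40 Hz for the
pressure-style stream -- deliberately different so every two-trace operation
exercises resampling.  None of these rates or noise levels are reported for
the real systems; they are configurable stand-ins.

`distort_to_surrogate()` turns the internal motion into an imperfect
surrogate by, in order:

1. **lag** $\Delta$: the continuous model is evaluated at $t + \Delta$
   (positive $\Delta$ = the surrogate leads, i.e. reaches EOI earlier),
   never by rolling sample arrays, so lags are not quantized to the grid
   and compose additively;
2. **limb warps**: within each complete cycle, a strictly increasing
   bijection of the cycle interval onto itself remaps time on each limb.
   With exhale steepness $s \ge 1$ the fractional distance past EOI is
   mapped $x \mapsto x^{1/s}$ (steeper initial falloff); the inhale limb
   mirrors this with its own exponent.  Warps fix the EOE boundaries and
   the EOI time, so extrema counts, ordering and timing are preserved;
3. a pointwise power-law **response nonlinearity**, **gain/offset**, and
   extra Gaussian **sensor noise** (default 2 units on the 0-100 scale).

Because the input trace's own noise is carried through as an additive
residual, the identity distortion reproduces the input bit for bit -- the
fixed-point contract the tests rely on.

Partial cycles at the trace edges receive no warp (there is no flanking EOE
to anchor one); they do receive the lag.

What the generator does **not** emulate: baseline wander correlated with
posture, irregular apnea/cough events, hysteresis between the two
surrogates beyond a fixed lag, or any 3-D chest-wall mechanics.  A green
test therefore certifies the analysis chain on plausible quasi-periodic
input, not robustness to pathological breathing.

## Extrema, cycles, statistics

`detect_extrema()` is an exhaustive moving-window scan: a sample is a peak
candidate only if its full $\pm$`window`$/2$ neighborhood lies inside the
trace (a truncated window cannot certify an extremum -- this rule removes
spurious boundary extrema), no neighbor exceeds it, and no earlier neighbor
ties it (plateau ties keep the earliest sample).  Candidates are forced to
alternate EOI/EOE (same-type runs keep the more extreme member) and
adjacent pairs swinging less than `min_prominence` (default 10 on the 0-100
scale) are pruned, weakest first.  The default window is two-pass: a 1 s
conservative pass estimates the median inter-EOI gap, and the final window
is 0.4 of it, honoring the search-range-below-half-a-period rule.  The
test suite holds this whole definition equal to an independently written
brute-force loop on randomized traces.

The `override` argument -- `(time, label)` rows replacing the nearest
detected extremum -- is the programmatic analogue of dragging misplaced
peak markers by hand, and `true_extrema()` returns a synthetic trace's
ground-truth marks in the same shape.

Periods are EOI-to-EOI (`period_T`, the reported quantity) with the
EOE-to-EOE span (`period_eoe`) kept alongside for shape extraction; depth
is EOI amplitude minus the *preceding* EOE amplitude (the source text does
not disambiguate which flanking EOE; the preceding one is used and
documented).  Whole-trace renormalization to 0-100 of the global range can
enlarge apparent depth differences between two traces; this mirrors
standard practice and is deliberately not corrected.  Two-trace comparisons
pair cycles one-to-one by nearest EOI within half the local period and fail
if more than 20% stay unmatched.  Correlation interpolates both traces onto
the finer grid over the overlapping interval.

## Phase shift: latency and ellipse

`eoi_latency_shift()` pairs EOIs and reports
$\mathrm{lag}_i = t^{EOI}_{b,i} - t^{EOI}_{a,i}$: positive means the first
argument leads.  Percentages divide by the first trace's local EOI-to-EOI
period (the two traces' periods agree to within a few hundredths of a
second, so the choice is immaterial at reported precision).

`fit_ellipse()` is the direct least-squares conic fit with the
ellipse-specific constraint $4ac - b^2 = 1$, solved as a generalized
eigenproblem on the partitioned, mean-centered scatter matrix (the
numerically stable formulation).  For two equal-amplitude signals of the
same waveform lagged by phase $\varphi$, the simultaneous-amplitude scatter
is an ellipse whose axes lie on the $\pm 45^\circ$ diagonals with semi-axes
$\propto \cos(\varphi/2)$ and $\sin(\varphi/2)$, so
`ellipse_phase_shift()` reports
$\varphi = 2\,\mathrm{atan}(\text{antidiagonal}/\text{diagonal})$, the
diagonal axis being the fitted axis nearer $+45^\circ$; when the major axis
lies near $-45^\circ$ (anticorrelated signals) the supplementary angle in
$(\pi/2, \pi]$ is reported.  Identical traces collapse to a line: that is
flagged (`degenerate = TRUE`, $\varphi = 0$), not an error.  The closed
form assumes quasi-sinusoidal signals: at the default EOE dwell
(`plateau_exponent` 1.5) the waveform's harmonic content biases the ellipse
estimate upward by roughly 15% of the lag, so the estimator-agreement test
runs in the raised-cosine regime and the latency estimator is the primary
one.  The sign of the ellipse estimate is taken from the latency estimator
when available, else reported unsigned.

## Average cycle shape and limb verdicts

Each cycle between sequential EOEs is renormalized so its EOI maps to 100
and the lower flanking EOE to 0 (under drift the other endpoint stays
above 0), re-origined at the EOI, interpolated onto a 0.04 s grid and
averaged pointwise where at least `max(2, 20%)` of cycles contribute.

`compare_limbs()` scores each limb as the mean of
$\text{shape}_b - \text{shape}_a$ over the limb's overlapping grid
(exhalation: rel\_time > 0).  Both curves being pinned at 100 and falling
to 0, the steeper curve lies below, so positive scores mean A steeper.  The
default verdict threshold of 3.0 amplitude units stands in for the visual
three-group classification of practice; `calibrate_limb_threshold()` ships
the noise-only calibration showing scores stay within the threshold for
undistorted pairs at the default sensor noise.

**Known limitation -- alignment accuracy.**  Shape averaging is only as
good as the EOI placement it is given.  On a noisy trace the sample argmax
wanders over the peak dwell region, and *by more on whichever flank is
flatter*; since limb warps change flank flatness, automatically detected
extrema shift the warped trace's average curve slightly and bleed one
limb's distortion into the other's score.  With fully automatic detection
at the default noise level the warp-direction recovery rate is around 80%;
with corrected extrema (the `override` mechanism, or `true_extrema()` on
synthetic data -- the same role manual peak adjustment plays in the
clinical workflow) the test suite verifies recovery on the full warp grid.
Several automatic refinements (smoothed argmax, quadratic vertex fitting,
half-depth-midpoint landmarks, shift registration of the average curves)
were evaluated and each either reintroduces a warp-dependent bias or
degrades the noise-only calibration; accurate extrema are the honest
prerequisite, exactly as manual adjustment was in the original workflow.

## Local amplitude sorting

Samples between an EOI and the next EOE form the exhale limb (the EOI
sample opens it: phase 1, 100%Ex); between an EOE and the next EOI the
inhale limb (the EOE sample opens it: phase 6, 0%In).  The amplitude
fraction uses the limb's own EOE, handling baseline drift locally.  Phases
bin by *nearest nominal level* (1.0, 0.8, ... on exhale for phases 1-6;
0.0, 0.2, ... on inhale for phases 6-10) -- midpoint bins, because the
sorting diagram this mirrors draws phases *at* amplitude levels; the
bin-edge convention of the commercial sorter is unpublished, so the rule is
isolated in one function (`bin_fraction`) for a one-line swap.  Fractions
overshooting [0, 1] by up to 0.02 are clamped (noise overshoot); beyond
that, excluded with a warning.  Bin-midpoint ties go to the lower phase
index.

## The digital phantom

A cine (step-and-shoot) acquisition stands in for low-pitch helical
scanning: it poses the identical sorting question with none of the helical
interpolation details, which are not reproducible from the published
description.  Each couch position dwells at least one maximal breathing
period (the data sufficiency condition); the frame period defaults to
0.5 s, a typical source rotation time.  The anatomy model is linear:
diaphragm apex = base + excursion x (normalized internal amplitude), lung
volume = volume at EOE + 50 mL/mm x apex displacement; defaults 20 mm
excursion, 2 mm slices, 3000 mL, chosen fixed for reproducibility, not
realism.  Reconstruction selects, per couch position and phase, the frame
whose *surrogate* amplitude fraction is nearest the phase's nominal level
(ties to the earliest frame), takes the apex as the maximum over couch
positions, and quantizes to the slice thickness.

Two consequences the tests pin down: with identical surrogates the
per-phase differences vanish identically; with a lag of $T/10$ the
phase curves match after a circular shift of one phase index -- but only to
within one slice, never exactly, because amplitude-sorted phases are not
uniform in time (a worked example in the test file shows a phase-1 frame
landing midway between the reference's phase-10 and phase-1 anatomy).
The acceptance test uses 20 Hz frames: at the default 0.5 s frame period
the fraction grid is so coarse that max-over-couch selection alone biases
positions by up to a slice, which would test frame starvation rather than
sorting.

## Gating

`apply_gate()` supports amplitude windows (beam on while the normalized
signal is inside [lower, upper]) and phase windows (beam on for samples
sorted into listed phases); beam-on sets are unions of half-open
sample-grid intervals.  `gating_mismatch()` applies the planned window to
both the planning and the delivery surrogate and reports duty cycles, the
Jaccard overlap of the two beam-on time sets (closed form for a pure lag:
$(w-\Delta)/(w+\Delta)$ for per-cycle window width $w$), and the residual
internal motion -- the max-min range, matching margin thinking, not an SD
-- of the implied diaphragm position during beam-on.

## Determinism and numerics

Every stochastic step derives its seed from the user seed through a fixed
integer map (kept below $2^{31}$); identical configuration and seed give
byte-identical JSON reports.  Linear interpolation is used for all
resampling (`stats::approx`); the ellipse fit mean-centers and rescales
before solving; tie-breaks (plateau extrema, bin midpoints, frame
selection) are all "earliest wins" and documented at the definition site.
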