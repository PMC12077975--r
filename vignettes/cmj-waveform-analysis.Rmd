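---
title: "Countermovement-jump force-time analysis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Countermovement-jump force-time analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmjkit)
```

## Scope

`cmjkit` processes dual-force-plate countermovement jump (CMJ)
recordings — one vertical ground reaction force (vGRF) channel per limb
— into trial events, impulse-momentum kinetics, discrete per-limb
metrics with interlimb asymmetry indices, and 101-node time-normalized
force waveforms analysed by one-dimensional statistical parametric
mapping (SPM). The target design is a paired pre/post comparison: each
athlete is tested at a baseline session (T0) and a follow-up session
(T1), with one limb designated *involved* (e.g. a surgically
reconstructed knee) and the contralateral limb *uninvolved*.

Because real athlete monitoring data of this kind are usually
confidential, the package includes a first-class synthetic cohort
generator with exact analytic ground truth, so every stage of the
pipeline can be validated end to end.

## Trial-level processing

**Body weight.** BW is the mean total vGRF over a 1 s quiet-standing
window, with the window SD retained. The default window is the first
second of the recording; if it is not stationary (SD < 10 N and range
< 50 N) the window slides forward in 0.1 s steps, stopping before gross
movement (first drop below 75% of the initial mean), and the minimum-SD
window is used with a `no_stationary_baseline` QC flag. The 10 N / 50 N
limits are deliberately loose for quiet standing on commercial plates
(typical sway is a few newtons) while still catching drifting or
truncated baselines.

**Movement onset.** Two definitions are computed:

* *Method 1 (threshold)* — the first sample after the BW window at
  which total force drops below `BW - 5 SD`. Because it ignores small
  pre-movement fluctuations, it gives consistent start points across
  athletes and anchors the time-normalized waveforms (node 0).
* *Method 2 (backtracking)* — starting from the method-1 index, if the
  force exceeded `BW + 5 SD` anywhere in the preceding 100 ms, step
  back to the earliest such exceedance and repeat; return the last
  sample inside the `BW ± 5 SD` band before the excursion first left
  it. This captures a small centre-of-mass rise ("preload") before the
  unweighting dip, so that the assumption of zero initial velocity in
  the impulse-momentum integration is valid. Without an exceedance the
  two methods coincide.

The backward stopping rule is ambiguous between two readings — the
point where the band was *first departed* in the excursion chain, or
the last in-band sample before the final *downward* departure. We use
first-departure capture (it is the earlier, more conservative
stationary point) and expose the alternative via
`detect_onset_backtrack(rule = "band_reentry")` without claiming either
is canonical.

**Take-off** is the first sample after the propulsion peak at which
total force falls below 20 N. No sub-sample interpolation is used: at
1500 Hz the worst-case error is 0.67 ms.

**QC.** Trials are excluded when no stationary weighing window exists,
when the minimum force between onset and the propulsion peak drops
below 20 N (total unweighting — the integration start and the phase
landmarks become unreliable), or when no take-off is found.

## Kinetics and discrete metrics

Body mass is `BW / g` with `g = 9.81` m/s² exactly. Centre-of-mass
acceleration `a = F_total/m - g` is integrated by cumulative trapezoid
from the method-2 onset with `v = 0`. Phases follow the standard
convention: *unweighting* from onset to the velocity minimum, *braking*
to the zero-velocity upcrossing, *propulsion* to take-off; ties at the
velocity minimum break to the earliest index. Per-limb net impulse over
a phase is the trapezoidal integral of `F_limb - BW/2` divided by mass
(the even static split is the default baseline; no per-plate weighing
is assumed), and net peak force is the per-limb maximum of
`(F_limb - BW/2)/m` over the whole movement — peaks of the two limbs
are maximized independently. Trapezoidal integration makes the
decomposition exact: the six limb-phase impulses sum to the take-off
velocity to machine precision, which the tests assert at 1e-9.

Jump height is `v_TO² / 2g` (impulse-momentum method; flight-time
estimates are deliberately not implemented), contraction time is
method-2 onset to take-off, RSImod is jump height over contraction
time, and `F_TOTAL` is the sum of the two per-limb net peak forces.
The asymmetry index is

```
AI = (uninvolved - involved) / (uninvolved + involved) x 100
```

applied to signed metrics as-is, so a negative-valued unweighting
impulse yields the field's usual sign convention (positive AI =
uninvolved larger in signed value). Within each athlete and session the
QC-passing trial with the greatest jump height is carried into the
group analysis, ties to the earliest trial.

Two open points were decided as follows: peak force uses the whole
movement rather than the propulsion phase (both are computable; the
whole-movement reading matches listing peak force separately from the
phase impulses), and the kinetic metrics integrate from the method-2
onset, the definition tied to the stationary-start assumption.

## Waveforms and SPM

Per-limb force is divided by body mass (N/kg) and linearly interpolated
onto 101 equally spaced points from the method-1 onset to take-off.
Mass normalization keeps athletes of different size comparable; a
gravity-netted variant is available (`net = TRUE`) and changes each
athlete's curve by a constant only.

The paired SPM test computes the paired t statistic at each node,
estimates the field smoothness from the unit-normalized residual
gradients (`FWHM = sqrt(4 ln 2 / mean gradient variance)`, resels =
100/FWHM), and solves the expected-Euler-characteristic equation

```
alpha/2 = P(T >= t*) + resels * rho1(t*),
rho1(t) = sqrt(4 ln 2)/(2 pi) * (1 + t²/nu)^(-(nu-1)/2)
```

for the two-tailed critical threshold `t*`. Suprathreshold clusters are
maximal runs of nodes with `|t| > t*` (per sign), reported at integer
node resolution as percent of the movement. Cluster p-values use the
expected-cluster framework: with `E_m` the expected cluster count and
`E_n` the expected suprathreshold resel volume,
`p = 1 - exp(-E_m * exp(-beta k²))` for extent `k` in resels,
`beta = (Gamma(3/2) E_m / E_n)²`, doubled for two tails. At the
zero-extent limit this reproduces the set-level alpha.

A sign-flip permutation oracle provides a fully nonparametric reference:
all `2^n` row-wise sign flips when `2^n <= 4096`, otherwise 10,000
seeded resamples; the threshold is the `1 - alpha` quantile of the
max-|t| distribution and cluster p-values the tail fraction of max
cluster extents. On smooth null fields (FWHM 15 nodes, n = 10) the RFT
and permutation thresholds agree within a few percent (median |Δ|/t*
about 3%), and the measured family-wise error of the RFT threshold over
500 simulations is about 0.05; both checks run in the test suite. For
rough fields (estimated FWHM near the node scale) RFT thresholds drift
conservative relative to the permutation reference; the package reports
both rather than hiding the divergence. Nodes with zero variance but
nonzero mean difference get infinite t: they are excluded from
smoothness estimation and treated as suprathreshold.

Degrees of freedom are `n - 1` with no non-sphericity correction;
inference is two-tailed by default (one-tailed available).

## Group comparisons

The comparison matrix reproduces the paired design: (i) jump height,
contraction time, RSImod and F_TOTAL between sessions; (ii) each
per-limb, per-phase impulse and per-limb peak force within-limb between
sessions and between limbs within each session; (iii) the four
asymmetry indices between sessions; (iv) four SPM contrasts
(between-limb at T0, between-limb at T1, involved T0 vs T1, uninvolved
T0 vs T1). Normality of the paired differences is gated by Shapiro-Wilk
at 0.05 (the differences are what the paired test assumes normal);
failures fall through to the Wilcoxon signed-rank test — exact p for
n ≤ 25 without ties or zeros, Pratt's zero-handling otherwise. No
multiple-testing correction is applied; every row carries its gate
decision, group means ± SD, the statistic and p.

## The synthetic cohort generator

The generator works in velocity space: each trial's centre-of-mass
velocity is a piecewise cubic Hermite curve through the phase
landmarks — zero velocity and slope at onset, a negative minimum at the
unweighting/braking boundary, zero at the braking/propulsion boundary
with a prescribed positive slope, and the take-off velocity with end
slope `-g` so that force reaches exactly zero at take-off. Total force
is the exact analytic derivative `F = m(dv/dt + g)`, which makes the
impulse-momentum identity and all event times exact by construction:
ground truth is recorded at sample resolution (onset, velocity minimum,
zero crossing, 20 N take-off crossing, take-off velocity).

Default distributions encode the emulated cohort: mass 75.9 ± 11.5 kg,
jump height 0.37 ± 0.05 m, movement duration 0.84 ± 0.15 s (athlete
level), with 4% trial-to-trial jitter on height and duration, phase
fractions of roughly 35/25/40% of the movement, and an unweighting
depth coefficient keeping the force minimum near 30% of body weight.
Five trials per session mirrors typical testing practice; the recovery
experiments below use three to keep replicate counts high at fixed
compute.

The total force is split between limbs by a smooth athlete-specific
share function (baseline offset SD 0.02, plus a small smooth
oscillation). A *deficit* scales the involved limb's share by
`1 - delta` inside a window of normalized movement time with 1.5-node
raised-cosine edges, renormalizing so the total force — and hence all
total-body kinetics — is preserved.

Noise has two parts, added per limb after the split so between-limb
contrasts see exchangeable noise under the null: white sensor noise
(1.5 N per plate, always on) and a smooth motion-dependent component
(white noise convolved to FWHM 15 nodes, amplitude 0.3 N/kg) that ramps
in across movement initiation and scales with the instantaneous force
level, vanishing toward take-off and in flight. The two envelopes
encode that quiet standing is genuinely quiet (so the BW ± 5 SD
thresholds discriminate against the same variability they see in real
recordings) and that force variability cannot exceed the force itself —
without the level scaling, clipping at zero would distort both the
take-off crossing and the late-propulsion variance. An optional
"preload" prepends a small velocity hump (rise 20 ms, decay 75 ms,
force amplitude 30 N above BW) that exceeds `BW + 5 SD` within 100 ms
of the unweighting drop while its decay stays inside the band.

What the generator does *not* emulate: landing, arm-swing or technique
variation, plate cross-talk, soft-tissue artifacts, and any systematic
uninvolved-limb adaptation. Passing recovery tests therefore
demonstrates that the pipeline detects localized share deficits under
realistic noise — not that every physiological deficit presents this
way.

## Calibration of the recovery experiment

The recovery study conditions are: 10 athletes, 3 trials per session,
involved-limb share reduced by `delta = 0.20` over nodes 90–100 at T1.
The magnitude was calibrated once, on 40 replicate cohorts, so that the
mean within-window nodewise paired Cohen's d is ≈ 1.5 (measured
1.5–1.6 across replicate runs);
`nodewise_cohens_d()` recomputes this for any analyzed cohort. Under
these conditions the involved-limb T0-vs-T1 SPM contrast recovers a
cluster overlapping the injected window in ≈ 93% of 200 replicates,
and with `delta = 0` the rate falls to ≈ 3%.

A structural limitation is worth stating plainly: at this calibration
the *discrete* within-involved propulsion-impulse contrast rejects in
only ≈ 40–55% of replicates (seed-dependent across 200-replicate
runs). The injected deficit is share-proportional
and confined to the last tenth of the movement, where absolute force is
smallest (it vanishes at take-off), so its integral over the whole
propulsion phase is small relative to the paired impulse variability
implied by the smooth noise. This asymmetry — waveform-level inference
localizes a late deficit that phase-aggregated impulses dilute — is
precisely the methodological point the contrast design probes, but it
means the discrete contrast cannot reach the same power as the SPM
contrast at this effect size.

## Numerical choices and problem sizes

* Trapezoidal integration throughout (exact for the piecewise-linear
  sampled force of the generator's cubic velocity segments to within
  O(dt²), ≈ 2e-5 m/s at 1500 Hz).
* RFT threshold root-solving brackets adaptively up to t = 1e4 (the EC
  density tail is heavy at very low degrees of freedom).
* Permutation: exhaustive for `2^n ≤ 4096`, else 10,000 resamples.
* The generator's smooth time-domain noise is synthesized on a grid
  decimated to about a fifth of the kernel sigma and linearly
  interpolated back (the smoothed process has autocorrelation 0.99 at
  one coarse step, so the variance ripple is below 1%).
* Test-suite problem sizes: 500 simulations for FWER calibration, 200
  replicate cohorts each for the deficit and null recovery experiments,
  50 random matrices for the pointwise oracle.
* Reports round metrics to 2 decimals and p-values to 3 (below 0.001
  printed as "<0.001"); all underlying CSV/JSON artifacts keep full
  precision, and rendered tables contain no computation of their own.
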