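# cmjkit

Force-time analysis of the countermovement jump (CMJ) from dual force
plates, for sport scientists and clinicians monitoring neuromuscular
function — in particular paired pre/post designs where one limb is
*involved* (e.g. after knee surgery) and its contralateral counterpart
serves as the within-athlete reference.

The package covers the full chain from raw per-limb vertical ground
reaction force (vGRF) recordings to group inference:

* **Events** — body weight (BW) from a 1 s quiet-standing window;
  movement onset both as the first drop below `BW − 5·SD` (method 1,
  anchors waveform normalization) and by a 100 ms backward search for a
  `BW + 5·SD` "preload" exceedance (method 2, guarantees the
  stationary start the impulse-momentum method assumes); take-off at
  the first sub-20 N sample after the propulsion peak; QC flags for
  non-stationary baselines and total unweighting.
* **Kinetics** — centre-of-mass velocity by trapezoidal integration of
  `a = F/m − g`; unweighting / braking / propulsion phases split at the
  velocity minimum and zero crossing; per-limb, per-phase net impulse
  (N·s/kg) and net peak force (N/kg); jump height `v_TO²/2g`;
  contraction time; RSImod; F_TOTAL; and the interlimb asymmetry index

  ```
  AI = (uninvolved − involved) / (uninvolved + involved) × 100 .
  ```

* **SPM** — per-limb force curves normalized to 101 nodes from onset to
  take-off and compared with one-dimensional statistical parametric
  mapping: a paired t statistic at every node, field smoothness from
  residual gradients, the random-field-theory critical threshold
  solving `α/2 = P(T ≥ t*) + resels·ρ₁(t*)` with
  `ρ₁(t) = √(4 ln 2)/(2π) · (1 + t²/ν)^(−(ν−1)/2)`, suprathreshold
  clusters with extent p-values, and a sign-flip permutation oracle
  that cross-checks the parametric thresholds.
* **Synthetic cohorts** — a generator that builds trials in velocity
  space (piecewise cubic Hermite through the phase landmarks, force as
  its exact derivative), with configurable athlete distributions,
  smooth and white noise, optional preload bumps, QC violations, and an
  injectable involved-limb share deficit localized in normalized time —
  so the entire pipeline is testable against exact ground truth.

## Worked example

Simulate a 10-athlete, two-session cohort with a 20% involved-limb
share deficit injected over the last tenth of the movement at T1, and
run the full analysis:

```r
library(cmjkit)

cfg <- sim_config(n_athletes = 10, trials_per_session = 3,
                  deficit = list(window = c(90, 100), delta = 0.20,
                                 session = "T1"),
                  seed = 42)
coh <- simulate_cohort(cfg)
res <- analyze_cohort(coh, out_dir = "demo_out")
res
#> <cmj_cohort_analysis> 10 paired athletes, 20 best trials, alpha = 0.05 (rft SPM)
#> significant discrete contrasts:
#>             metric        contrast          p
#>  ai_imp_propulsion asymmetry_T0_T1 0.03845704

res$comparisons$spm$within_involved_T0_T1
#> <cmj_spm> paired t-field, n = 10 (nu = 9), FWHM = 8.5 nodes, rft t* = 4.609 (alpha 0.05, 2-tailed)
#>   cluster 91%-97% (extent 7), p = 0.0001337
```

Of the 24 discrete contrasts only the propulsion asymmetry index moves,
yet the SPM contrast of the involved limb against its own baseline
localizes the force loss to 91–97% of the movement, overlapping the
injected window (nodes 90–100) — a deficit confined to late propulsion
integrates to little over the whole phase, which is exactly why
waveform-level inference complements the discrete table. The
`demo_out/` bundle contains the per-session metric table, the two
formatted comparison tables, one JSON result and one two-panel figure
(mean ± SD waveforms above the thresholded t-field) per SPM contrast,
and a QC log.

Real data enter through the same front door: a manifest CSV
(`athlete_id,session,involved_side,path[,mass_kg]`) pointing at trial
CSVs with columns `time,fz_left,fz_right` (newtons), analyzed with
`analyze_cohort("manifest.csv", out_dir = "...")` or from the shell via
`inst/cli/cmjkit.R analyze --manifest manifest.csv --out results/`.

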