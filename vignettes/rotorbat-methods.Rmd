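---
title: "Models and methods behind rotorbat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind rotorbat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rotorbat)
```

`rotorbat` implements the computational chain used to study bat attraction
to wind turbines: acoustic classification of nacelle-height call
recordings, propagation modelling of recorder detection ranges and
bat-song active space, stereo-thermal 3D reconstruction with
distance-binned density estimation, and binomial mixed models of monthly
activity. This vignette documents the models, the tunable parameters, the
numerical choices, and the design decisions taken where the underlying
field methodology left the implementation open.

## Acoustic event classification

The package operates on *parameterised call events* — one row per
vocalisation with timing, duration, start/end/peak frequency, sweep rate
and category — not on raw audio. This mirrors the field workflow, where a
commercial recorder triggers 1.3 s files (0.3 s pre-trigger, 1 s
post-trigger) and call parameters are measured downstream; spectrogram
computation is deliberately out of scope.

**Trigger filter.** `apply_trigger_filter()` reproduces the deployed
recorder's bat-call criteria: FM calls of 1–30 ms with sweep rates of −9
to −1 kHz/ms, or CF calls of 2–30 ms with sweep rates of −2 to 1 kHz/ms,
within a 15–80 kHz trigger band (a 15–100 kHz "renebat" dialect is
selectable; the recording-time band is the default because it governs
which events enter the archive in the first place).

**Species identification.** Echolocation end frequency (F_end, kHz) is
the identification feature. Species bands are half-open exactly as
published: *N. noctula* < 22; Nyctaloid group (22, 29]; *P. nathusii*
(30, 42]; *P. pipistrellus* (42, 51]; *P. pygmaeus* > 51. Three decisions
were open and are resolved as follows:

* End frequencies in the published gap (29, 30] kHz are labelled
  `"Chiroptera"` (unidentified bat) rather than forced into a band.
* A sequence needs at least 2 search-phase calls for identification;
  sequences whose per-call assignments straddle adjacent *Pipistrellus*
  bands resolve to `"Pipistrellus spp."`, those mixing *N. noctula* with
  the Nyctaloid band resolve to `"Nyctaloid"` — the per-call values of all
  search calls are used, not a median, so a single out-of-band call
  demotes the assignment, which is the conservative reading of the
  ambiguity rule.
* The exact value 22 kHz is assigned to the Nyctaloid group (the
  published thresholds "< 22" and "> 22" leave the point itself
  unallocated; a measure-zero choice).

**Feeding buzzes.** A buzz is a maximal run of consecutive inter-call
intervals ≤ 10 ms (repetition rate ≥ 100 calls/s). The interval criterion
alone would fire on a single short interval, so `classifier_rules()`
additionally requires ≥ 3 consecutive qualifying intervals (≥ 4 calls) by
default; this is configurable. Buzzes are assigned from the search-phase
calls preceding the run; with fewer than 2 preceding calls the assignment
falls back to the recorder-level group band of the buzz calls themselves.

**Song.** Song elements are an input category (their recognition in
spectrograms was a manual step in the field and is emulated by the
synthetic generator). For Pipistrelloid species *and* *Plecotus* a
vocalisation counts as song only when ≥ 5 consecutive song elements occur
(single elements also occur in food-patch defence); Nyctaloid song
elements qualify with no minimum. Interleaved echolocation calls do not
break a run — songs are routinely interspersed with echolocation — but a
social call does. Song-eligible elements of the same assignment merge into
*song events* when inter-element gaps are ≤ 5 s. The merge threshold is a
design choice: triggered files end 1 s after the last trigger and observed
song events span consecutive files, so the threshold must exceed the
inter-file gap; 5 s is recorded in the run manifest and configurable.

## Sound propagation

`atmospheric_absorption()` implements the ISO 9613-1 pure-tone analytic
formulas (classical absorption plus O₂ and N₂ vibrational relaxation,
driven by the water-vapour molar concentration). Defaults are 20 °C, 60 %
relative humidity, 101.325 kPa — typical nacelle-height conditions. The
test suite checks the implementation against an independently coded second
implementation of the same standard.

`solve_max_distance()` solves the sonar equation by bisection on
[1 m, 10 km] to 0.01 m. Transmission loss is modelled as
`20 log10(r) + α r` over the full path r (the standard sonar-equation
convention; the alternative `r − 1 m` path changes results by far less
than the calibration uncertainty). The received level is strictly
decreasing in distance for α ≥ 0, so the root is unique. Sources at or
below the threshold return 0 m with a warning.

**Recorder detection range** is the one-way solve at the species' song
peak frequency and source level against the 37 dB SPL trigger.

**Active space** is the distance at which song falls to a conspecific's
20 dB SPL hearing threshold. The field methodology computed an
echolocation-style detection distance and *doubled* it because song
travels one way to a listener instead of returning as an echo. Two
readings of that procedure are implemented:

* `mirror_doubling` (default). For an extended, mirror-like reflector the
  echo level is `SL − 20 log10(2d) − 2αd`; doubling the detection distance
  `d` gives exactly the one-way audible range (substitute `A = 2d`). This
  mode is self-consistent for a one-way listener.
* `point_doubling`. Twice the point-target (zero target strength) two-way
  solve `SL − 40 log10(d) − 2αd = threshold`. Under absorption this
  understates the one-way range, increasingly so at high frequencies.

The default was chosen by calibration against the published results: with
source levels restricted to the published 72–108 dB peSPL range and song
peak frequencies to 14.0–26.4 kHz, the point-target reading cannot
reproduce the published *Plecotus* pair (25.1 m recorder range together
with a 42 m active space) for any parameter choice — the 25.1 m constraint
caps its active space near 27 m — whereas the mirror reading satisfies
both with a single parameter pair whose frequency falls essentially at the
top of the published song-frequency range. One published value resists
both readings: a species whose recorder detection range (at a 37 dB
trigger) *exceeds* its reported active space (at a 20 dB threshold) cannot
be reproduced by any single monotone propagation model, because a lower
threshold always yields a larger range; the package reports the
model-consistent value and the discrepancy is documented in the acceptance
suite rather than hidden.

**Species parameter table.** The deposited per-species song frequencies
and source levels were not available when the package was built, so the
packaged table (`species_parameters()`) was *calibrated*: frequencies and
source levels were solved, within the published ranges, so that the
propagation model reproduces the published anchor results (the 25.1 m and
114.3 m recorder-range extremes, the 42 m and 100 m active spaces, and the
82 m seven-species mean). The `provenance` column marks every calibrated
value; only the two published flight speeds (2.5 m/s *Plecotus*, 6.0 m/s
*N. noctula*) are literature-anchored, with the remaining speeds plausible
interpolations by body size and flight style. Users with measured
parameters should supply their own table — every propagation function
accepts one.

**Covered flight distance** multiplies song-event duration by the
species' commuting flight speed and flags events whose distance exceeds
the species' recorder detection range: a straight-flying bat would have
left the detection volume, so exceedance suggests circling flight.

## Stereo-thermal 3D reconstruction

The default `stereo_rig()` mirrors the field deployment: two 640 × 480
thermal cameras with 17.5° × 13.1° fields of view (50 mm lens, 11
frames/s), base distance 16 m, near ground level about 200 m from the
tower, both aimed at a shared convergence point at the nacelle
(~100 m up).

* **Projection model.** Angular pinhole mapping with per-pixel angle
  `fov/pixels`; pixels are 0-based, origin top-left, `u` rightward, `v`
  downward. Lens distortion and intrinsic matrices are ignored, matching
  the field system's own simplification; the systematic error this causes
  is largely removed by referencing all positions to the *triangulated*
  nacelle point (`normalize_to_nacelle()`), exactly as done in the field.
* **Triangulation.** Midpoint of the closest-approach segment between the
  two viewing rays, with the gap distance reported as a quality metric;
  rays closer than 10⁻⁴ rad to parallel raise a degeneracy error. Within a
  frame, left/right detections are paired greedily by smallest ray gap
  with a 3 m acceptance cap (twice the nominal distance resolution).
* **Resolution.** The analytic one-pixel-disparity resolution
  `r²·Δφ/b` is exposed via `range_resolution()`; at 200 m with the
  default rig it is ≈ 1.2 m, consistent with the deployed system's
  nominal 1.5 m.
* **Shell volumes.** Bat density is computed in 3 m spherical shells
  around the nacelle. Because the cameras see only part of each shell,
  densities divide counts by *clipped* volumes: shell ∩ both view
  frustums, estimated by per-shell Monte-Carlo (default 10⁵
  samples/shell, targeting < 1 % relative SE; seed fixed and recorded).
  The published description of "hemispherical" shells does not specify the
  hemisphere's orientation; the default uses full spherical shells clipped
  by the camera frustums — which is what physically restricts the observed
  volume — and a `hemisphere_normal` mask is available for sensitivity
  analyses (e.g. front vs rear half-spaces).
* **Counting unit.** Frame-level positions (detections), not tracks; all
  reconstructed trajectories are assumed to be bats, as in the field
  analysis (where 76 % of close approaches were acoustically confirmed).
* **Attraction model.** `fit_attraction_model()` fits
  `d(r) = a·exp(−r/λ) + c` — the minimal model consistent with an
  exponential decline toward a free-air-space floor — by weighted least
  squares (weights = shell counts), restricted to shells beyond 10 m
  because the nacelle body occupies much of the innermost volume. The
  decay length λ is profiled on a 0.5 m grid with (a, c) solved linearly
  at each λ to obtain start values, then refined by Levenberg–Marquardt;
  if the nonlinear step stalls (flat profiles make λ unidentifiable at
  a = 0) the deterministic grid-profile solution is returned.

## Activity statistics

`fit_activity_glmm()` models the per-cell proportion of bat recordings
containing feeding buzzes (or social vocalisations) with a binomial-logit
GLMM: fixed effects are species group, ordered-month orthonormal
polynomial contrasts up to degree 5, and their interaction (12
fixed-effect terms with 7 months); random intercepts for site and for an
observation-level unit (one level per cell) absorb between-site
heterogeneity and overdispersion. Fitting uses Laplace-approximated ML
with the bobyqa optimiser and a 10⁵-iteration cap. A year random intercept
is available by flag but off by default (in the motivating analysis it
explained no variability and was removed). Cells with zero recordings are
excluded during aggregation and reported. Marginal means and
Tukey-adjusted pairwise contrasts come from emmeans on the log-odds scale;
Spearman correlations between overall and behavioural activity use
tie-corrected ranks.

## Synthetic data: what it emulates and what it does not

The generators are pure functions of their configuration and seed.

* `simulate_night()` emulates the triggered-recording corpus at the
  event-parameter level: per-species search-phase pulse trains (end
  frequencies strictly inside the species band), planted feeding buzzes
  (intervals 6–9 ms), social calls, and song-element sequences
  (gamma-distributed inter-onset times, mean ≈ 0.4 s — a placeholder, as
  per-species inter-onset statistics live in the wider literature). Song
  events are planted with durations in the observed 2–98 s field range
  (default ceiling 30 s to keep test nights short). Background pulse
  intervals are truncated-lognormal bounded below at 30 ms, cleanly
  separated from the 10 ms buzz criterion so that classifier tests have an
  unambiguous ground truth; boundary behaviour (11–15 ms intervals) is a
  stress-test concern, not a default condition. Received levels follow the
  one-way propagation model at the simulated bat distance, closing the
  loop with the propagation module. Not emulated: waveforms, spectrogram
  measurement error, overlapping species within one recording, noise or
  test-signal triggers.
* `simulate_flight_scene()` draws positions by thinning a uniform point
  process inside the stereo visibility region with acceptance proportional
  to `d(r) = a·exp(−r/λ) + c` (defaults a = 0.01, λ = 15 m, c = 0.001:
  a ten-fold density elevation at the nacelle over the free-air floor,
  consistent with a strong attraction signal), then projects into both
  cameras with Gaussian pixel noise (default SD 0.5 px). Not emulated:
  rotor-blade clutter, track persistence across frames, weather-dependent
  insect dynamics, behaviourally mechanistic flight.
* `simulate_activity_dataset()` draws binomial counts from the
  logit-linear model on the field design (26 turbine-years over 6 sites,
  April–October, two groups, negative-binomial recording counts with mean
  310/cell). Default effect sizes are the published fixed-effect
  estimates; site and observation-level SDs default to 0.5 (the published
  analysis reports no variance components, so these are a realistic
  choice for nacelle-height monitoring data, made once). Note that the
  published social-activity parameters put some month × group cells at
  vanishing event probabilities, where simulated data can approach
  separation — null and recovery simulations therefore plant the group
  effect with month effects at zero.

Passing tests on these generators demonstrate the correctness of the
algorithms under the stated statistical structure; they cannot certify
performance on real recordings, where call-parameter measurement error,
species mixtures, and non-exponential density profiles occur.

## Numerical choices and problem sizes

Bisection tolerance 0.01 m on [1 m, 10 km]; Monte-Carlo shell volumes
10⁵ samples/shell; triangulation degeneracy threshold 10⁻⁴ rad; attraction
fit λ-grid 2–60 m in 0.5 m steps with Levenberg–Marquardt refinement
(max 200 iterations); GLMM via bobyqa with 10⁵-iteration cap. The
acceptance workflow uses 500-position triangulation Monte-Carlo runs,
density scenes of 800 (null) and 4000 (attracted) positions — the latter
matching the scale of the field position dataset — 3 × 60-recording
synthetic nights, and
hundreds of GLMM simulations at the full study design — sizes chosen so
the whole workflow runs in minutes on a single core while keeping
Monte-Carlo standard errors well inside the tolerances being tested.

## Known limitations

* The packaged species acoustic parameters are calibrated to published
  aggregate results, not measured; provenance is marked per value.
* One published active-space/detection-range pair is internally
  inconsistent under any single monotone propagation model (see above);
  the corresponding acceptance check documents the discrepancy.
* Emission directionality, tower acoustic shadowing and
  frequency-dependent receiver sensitivity are out of scope.
* Real-scene stereo ambiguity resolution beyond frame-synchronised
  nearest-gap matching (e.g. multi-target tracking) is out of scope.
* Residual diagnostics for the GLMM are limited to convergence/singularity
  flags and the simulation-based calibration checks in the test suite.
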