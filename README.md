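# rotorbat

Tools for analysing bat activity at wind-turbine nacelles: acoustic
classification of nacelle-height recordings, sound-propagation modelling of
recorder detection ranges and bat-song active space, stereo-thermal 3D
reconstruction of flight positions with distance-binned density estimation,
and binomial mixed models comparing feeding and social activity between
acoustic species groups.

## The scientific problem

Bats are killed at wind turbines in large numbers, and a central open
question is whether they are *attracted* to turbines — for feeding,
roosting, or mating opportunities — rather than colliding incidentally.
Acoustic detectors mounted in the nacelle record feeding buzzes (terminal
echolocation phases of prey capture, pulse intervals ≤ 10 ms), social
calls, and courtship song; stereo thermal cameras record 3D flight paths in
the rotor-swept zone. `rotorbat` implements the complete computational
chain needed to analyse such data, with seeded synthetic generators
standing in for raw field recordings, so every stage is testable end to
end:

1. **Acoustic events** (`classifier_rules()`, `apply_trigger_filter()`,
   `classify_sequence()`, `detect_feeding_buzzes()`,
   `detect_social_and_song_elements()`, `assemble_song_events()`) —
   rule-based classification of parameterised call-event streams.
   Species identification uses echolocation end frequencies
   (*N. noctula* F_end < 22 kHz, Nyctaloid group 22–29 kHz,
   *P. nathusii* 30–42 kHz, *P. pipistrellus* 42–51 kHz, *P. pygmaeus*
   > 51 kHz); a feeding buzz is a run of ≥ 3 consecutive inter-call
   intervals ≤ 10 ms; Pipistrelloid/*Plecotus* vocalisations count as song
   only with ≥ 5 consecutive song elements.
2. **Propagation** (`atmospheric_absorption()`, `solve_max_distance()`,
   `recorder_detection_range()`, `song_active_space()`,
   `covered_flight_distance()`) — ISO 9613-1 pure-tone atmospheric
   absorption and the sonar equation
   `SL − 20 log10(r) − α r = threshold` (one-way) /
   `SL − 40 log10(d) − 2 α d = threshold` (two-way), solved by bisection
   to 0.01 m.
3. **Stereo 3D** (`stereo_rig()`, `pixel_to_ray()`, `triangulate()`,
   `shell_volumes()`, `density_profile()`, `fit_attraction_model()`) —
   angular pinhole projection, closest-approach triangulation, Monte-Carlo
   volumes of camera-clipped 3 m spherical shells around the nacelle, and a
   weighted fit of the attraction model `d(r) = a·exp(−r/λ) + c`.
4. **Activity statistics** (`aggregate_activity()`, `fit_activity_glmm()`,
   `marginal_means_and_contrasts()`, `activity_correlation()`) —
   binomial-logit GLMM with species group × ordered-month polynomial
   contrasts (degree 5) as fixed effects and site plus observation-level
   random intercepts (lme4), marginal means with Tukey-adjusted contrasts
   (emmeans), Spearman correlations.
5. **Synthetic data** (`simulate_night()`, `simulate_flight_scene()`,
   `simulate_activity_dataset()`) — seeded generators with ground-truth
   ledgers that make classifier precision/recall, triangulation error,
   density-model recovery and GLMM calibration exactly scoreable.

## Worked example

```r
library(rotorbat)

## species-specific detection ranges and song active space at 20 °C / 60 % RH
s <- propagation_summary()
s[, c("species", "song_peak_freq_khz", "detection_range_m", "active_space_m")]
#>                     species song_peak_freq_khz detection_range_m active_space_m
#> 1          Nyctalus noctula               15.0              48.0           89.0
#> 2         Nyctalus leisleri               16.5              37.3           71.2
#> 3       Vespertilio murinus               14.0             114.3          168.7
#> 4             Plecotus spp.               26.4              25.1           42.1
#> 5     Pipistrellus nathusii               17.5              64.6          100.0
#> 6 Pipistrellus pipistrellus               20.0              30.3           55.4
#> 7     Pipistrellus pygmaeus               21.5              25.6           47.6
mean(s$active_space_m)
#> [1] 82.00176
```

A recorder triggering at 37 dB SPL hears *Plecotus* song out to ~25 m but
*V. murinus* song out to ~114 m; at a conspecific hearing threshold of
20 dB SPL the songs carry 42–169 m (mean 82 m), i.e. singing males are
audible to other bats over much larger ranges than echolocation calls.

```r
## classify a synthetic night and score against the planted ground truth
night <- simulate_night(seed = 42, n_recordings = 40)
res <- classify_night(night$events)
res$manifest[c("n_buzzes", "n_song_elements", "n_song_events")]
#> $n_buzzes       [1] 7
#> $n_song_elements[1] 168
#> $n_song_events  [1] 5
head(res$buzzes[, c("recording_id", "n_calls", "assignment")], 3)
#>   recording_id n_calls assignment
#> 1      rec0002       9  Nyctaloid
#> 2      rec0010       7  Nyctaloid
#> 3      rec0013      11  Nyctaloid
```

All 7 planted buzzes and all 5 planted song events are recovered; the
assignments match the end-frequency bands of the planted species.

```r
## 3D density around the nacelle from a simulated stereo-thermal scene
rig <- stereo_rig()                        # 16 m base, ~200 m stand-off
sc  <- simulate_flight_scene(rig, seed = 7, n_positions = 900,
                             a = 0.01, lambda_m = 15, c_floor = 0.001)
pos <- normalize_to_nacelle(triangulate_detections(rig, sc$detections),
                            rig$convergence_point)
vol <- shell_volumes(rig, shell_edges = seq(0, 60, 3), seed = 1)
fit <- fit_attraction_model(density_profile(pos, vol))
c(lambda_m = fit$lambda_m)   # true decay length: 15 m
```

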