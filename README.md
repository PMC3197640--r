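# ehtforce

Video-optical contractility analysis for engineered heart tissue (EHT),
with a fully synthetic validation world.

EHTs are three-dimensional cardiac muscle strips cast between two elastic
silicone posts. Each spontaneous contraction bends the posts toward each
other; automated video recording of markers at the post tips turns that
deflection into a force signal via cantilever beam mechanics,

    F = 3 π E R⁴ δ / (4 L³),

with elastic modulus *E*, post radius *R*, post length *L* and tip
deflection *δ*. From the force trace the assay derives the parameters used
in stem-cell cardiology and proarrhythmia screening: force of contraction
(mN), beating frequency (bpm), maximal contraction/relaxation velocity
(dF/dt), beat-to-beat interval scatter (interdecile range, IDR), threshold
concentrations at which a compound significantly slows relaxation or
induces irregular beating, and a sarcomere alignment score
(90°/IQR of orientation angles).

`ehtforce` implements that entire chain for R:

* **mechanics** — deflection ↔ force conversion and cross-sectional stress
  (`force_from_deflection()`, `deflection_from_force()`,
  `cross_sectional_stress()`);
* **trace analysis** — prominence-based twitch detection, per-twitch
  amplitude/kinetics, per-recording summaries (`detect_peaks()`,
  `measure_twitches()`, `summarize_recording()`, `analyze_trace()`);
* **rhythm statistics** — IDR, Poincaré pairs, exact (enumerated)
  Mann-Whitney U for n = 4 replicate groups (`interdecile_range()`,
  `poincare_pairs()`, `mann_whitney_u()`);
* **dose-response** — baseline normalisation, paired t and Mann-Whitney
  threshold procedures, concentration-response tables
  (`normalize_to_baseline()`, `threshold_concentration()`,
  `threshold_table()`, `build_concentration_response()`);
* **alignment** — axial angle dispersion and the inverse-dispersion score
  (`angle_dispersion()`, `alignment_score()`, `aggregate_alignment()`);
* **synthetic data** — ground-truth-annotated twitch traces with calcium,
  chronotropic and proarrhythmic drug effect models (`generate_trace()`,
  `calcium_scale()`, `apply_drug_effect()`, `simulate_dose_response()`);
* **synthetic video** — rendering and tracking of post-tip markers
  (`render_frames()`, `detect_markers()`, `track_deflection()`);
* **pipeline/IO** — CSV traces, JSON manifests and reproducible reports
  (`read_trace()`, `run_pipeline()`, `write_report()`).

No laboratory recordings are publicly available for this assay, so the
synthetic module is first-class, tested code: its defaults encode the
reported preparation (61 µN twitches, 0.5 Hz regular beating, 60 s
recordings) and every analysis stage is validated against traces whose
ground truth is known by construction. See
`vignettes/eht-contractility-methods.Rmd` for the models, assumptions and
numerical choices.

## Worked example

```r
library(ehtforce)

preset <- eht_preset("spontaneous_heht")   # 61 uN, 0.5 Hz, 60 s
geom   <- default_post_geometry()          # E = 1 MPa, R = 0.5 mm, L = 10 mm

# simulate one recording, push it through the deflection/force loop
rec  <- generate_trace(preset$schedule, preset$params, seed = 1)
defl <- trace_to_deflection(rec$trace, geom)
res  <- analyze_trace(defl, geom = geom)
res$summary
#> Recording summary (60 s): 30 twitches
#>   mean force            61.095 uN
#>   frequency              0.497 Hz (29.8 bpm)
#>   contraction velocity 476.730 uN/s
#>   relaxation velocity  330.944 uN/s
```

The recording recovers the preset: ~61 µN mean twitch force (0.061 mN)
and ~0.5 Hz spontaneous frequency. Rhythm scatter of the same recording:

```r
interdecile_range(res$summary$beat_intervals)$idr   # seconds of RR-scatter
```

A full screening experiment — four wells, cumulative concentrations of an
E-4031-like hERG blocker, thresholds for relaxation slowing (paired t)
and interval scatter (exact Mann-Whitney on per-well IDR):

```r
cp <- eht_compound_preset("e4031_like")
ex <- simulate_dose_response(cp$model, cp$ladder, n_wells = 4, seed = 3)
threshold_table(ex)
#>     compound threshold_relaxation threshold_scatter
#> 1 e4031_like                    1                30
```

And the alignment score: a sample whose angle dispersion is 9° (10% of
90°) scores exactly 10:

```r
alignment_score(angle_dispersion(c(80, 85.5, 90, 94.5, 100)))
#> [1] 10
```

## Acceptance script

`scripts/acceptance.R` recomputes the package's headline quantities from
scratch by running the pipeline on freshly generated inputs: the
alignment worked example, mean force and frequency recovered from four
synthetic 60 s default-preset recordings routed through the inverse beam
formula, and the percent force drop between 0.2 mM and 1.8 mM
extracellular calcium under the constrained Hill model. Run it from the
repository root against the installed package:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
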