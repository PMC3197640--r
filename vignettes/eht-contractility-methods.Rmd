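---
title: "Models and methods behind ehtforce"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ehtforce}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ehtforce)
```

## The measurement problem

Fibrin-based engineered heart tissue (EHT) is cast between two elastic
silicone posts in a 24-well plate. When the tissue contracts it bends the
posts toward each other, so a camera watching markers at the post tips sees
the inter-marker distance shrink and recover once per beat. Everything the
assay reports — force of contraction, beating frequency, contraction and
relaxation kinetics, rhythm irregularity, drug threshold concentrations —
is derived from that deflection signal. `ehtforce` implements the full
chain and, because no public recordings exist for this assay, ships a
synthetic-data generator that plays the role of the laboratory: every stage
is validated against traces whose ground truth is known by construction.

## Post mechanics

A silicone post is treated as a cylindrical cantilever loaded at its tip.
Small-deflection beam theory gives

$$F = \frac{3\pi E R^4}{4 L^3}\,\delta,$$

with elastic modulus $E$, post radius $R$, length $L$ and tip deflection
$\delta$. The pre-factor is the post stiffness $k$ (N/m), exposed as
`post_stiffness()`; force and deflection are exact inverses of each other
(`force_from_deflection()` / `deflection_from_force()`, tested to
$10^{-12}$ relative error across a $10^6$-fold range). Positive $\delta$
means the posts bend toward each other, so traces are non-negative at
rest.

Post geometry is deliberately **mandatory configuration**: the formula's
$R^4/L^3$ sensitivity means no hidden default could be trusted across
racks. `default_post_geometry()` ($E = 1$ MPa, $R = 0.5$ mm,
$L = 10$ mm, $k \approx 0.147$ N/m) is an illustrative PDMS-like post used
by the simulations and examples only.

Cross-sectional stress divides force by $\pi (d/2)^2$ under the
circular-cylinder assumption with the 0.72 mm mean tissue diameter. Note
that 0.061 mN over that area is 0.150 mN/mm², not the 0.12 mN/mm²
sometimes quoted for this preparation; the latter is presumably a per-EHT
average over varying diameters. `cross_sectional_stress()` reports the
formula value.

## Synthetic twitch traces

The generator's defaults *are* the stated experimental world, not tuning
knobs:

* **twitch force 61 µN** — the reported population mean (0.061 ± 0.013 mN);
* **frequency 0.5 Hz** — the reported mean of regular spontaneous beating
  (individual tissues range 40–70 bpm, which the dose-response simulator
  samples per well);
* **60 s recordings at 100 Hz** — the standard measurement window, with
  `dt = 0.01` s comfortably inside the Nyquist and slope-resolution needs
  of 0.2 s upstrokes;
* **interval cv 0.05** — "regular" beating with mild physiological jitter
  (a choice: the assay literature reports regularity qualitatively);
* **trace noise 0.5 µN** — the force equivalent of roughly 0.1 px centroid
  precision seen through the illustrative 0.147 N/m post at a typical
  macro-lens scale; chosen from that error budget, not fitted.

The twitch waveform is not published, so a shape had to be chosen. We use
a two-phase raised cosine: a rising limb of length `time_to_peak` and a
falling limb of length `relaxation_time`,

$$f(t) = \tfrac{A}{2}\left(1-\cos\frac{\pi t}{t_{peak}}\right)
\quad\text{then}\quad
\tfrac{A}{2}\left(1+\cos\frac{\pi (t-t_{peak})}{t_{relax}}\right).$$

It is $C^1$-smooth, single-peaked with maximum exactly $A$, and its
maximal slopes have closed forms ($A\pi/2t_{peak}$ rising,
$A\pi/2t_{relax}$ falling), which turns the downstream velocity estimators
into testable quantities rather than conventions. Beat intervals are
lognormal with mean $1/f$ and the configured cv — strictly positive and
with the cv controlled exactly. "Scattered" beating (the proarrhythmic
phenotype) superimposes occasional skipped (doubled) and premature
(halved) intervals at 10% probability each on an inflated cv; this
reproduces the phenotype of irregular beating without any
electrophysiological model, which is explicitly out of scope.

All randomness flows from one integer seed; identical arguments give
bit-identical traces, and the generator emits a ground-truth sidecar
(event times, per-event amplitude, overlap flag) for round-trip tests.

**What a green test does not establish.** The generator emulates the
*statistical* structure of healthy and drugged recordings: amplitudes,
kinetics, interval scatter, concentration–effect maps. It does not emulate
baseline drift, motion artefacts, partial detachment, early/delayed
afterdepolarisation morphology, or week-scale maturation trends. Green
round-trip tests certify the analysis chain, not the biology.

## Effect models

**Calcium.** Twitch force follows a Hill curve in extracellular calcium,
normalised to 1 at the 1.8 mM assay baseline. Its two parameters are
solved (numerically, once) from the two published constraints: force falls
by 90% at 0.2 mM, and a plateau is reached between 2.2 and 3.0 mM. We
operationalise "plateau" as scale(2.2)/scale(3.0) = 0.97 — a genuinely
flat segment, chosen a priori rather than parking the model on the 0.95
acceptance boundary. The solved parameters are EC50 ≈ 0.60 mM and
$n \approx 2.09$. Because the curve keeps rising above baseline, the
multiplier exceeds 1 between 1.8 and 3.0 mM; the printed constraints are
ratio constraints and hold exactly.

**Proarrhythmic drugs.** A compound is a phenomenological map, not a
channel model: a Hill factor slows relaxation (dividing
`relaxation_time`, hence scaling peak relaxation velocity), a second Hill
factor with a 10-fold higher midpoint reduces force (the depolarisation-
block surrogate seen only at high concentrations), and above a
`scatter_onset` concentration the interval cv inflates by
$0.3\,(c-c_0)/(c+c_0)$ with scattered mode switched on. The maximal
reduction defaults to 0.4, the midpoint of the reported 30–50% band.

**Chronotropy.** Isoprenaline multiplies the spontaneous frequency by a
gain (default 1.3, a modest β-adrenergic response); carbachol reverses it
to baseline. The gain's size is not published for this preparation; the
tests assert the direction and the reversal, not the magnitude.

## Twitch detection and measurement

The recognition algorithm of the original software is unpublished, so the
package implements a minimal, deterministic reconstruction:

1. centred moving-average smoothing (default 50 ms);
2. local maxima ranked by **topographic prominence**, keeping those above
   20% of the smoothed dynamic range;
3. a 250 ms refractory rule keeping the more prominent of two close peaks.

Per twitch, the diastolic baseline is the mean of the smoothed-signal
minima in the two adjacent inter-beat windows (robust to slow drift);
amplitude is smoothed peak minus baseline; contraction/relaxation times
run between the 10% amplitude crossings and the peak (10% chosen for
noise stability; the assay's original fractional endpoints are not
published); maximal velocities are extreme first differences of the
smoothed signal on each limb, relaxation reported positive. Twitches
whose limb never returns to the 10% level in the available window —
truncated boundary twitches — are dropped, implementing "measurable
twitches only". Frequency is (number of intervals)/(summed interval
length); with fewer than two twitches it is flagged undefined rather than
fabricated.

**Numerical choice worth knowing:** a 50 ms moving average attenuates the
default twitch's peak slope by ≈ 2.5% (the sinc factor
$\mathrm{sinc}(\pi w / 2 t_{peak})$). That is invisible in ratio-based
results (drug effects, normalisation) but matters when comparing a slope
against a finite-difference oracle; the oracle-equivalence test therefore
runs the estimator with a 5 ms window on a dense noiseless twitch, where
it agrees with brute force to 0.03%. The 50 ms default stays, because at
0.5 µN noise it is what keeps false peaks at zero.

## Rhythm statistics

Beat intervals within a recording are not normally distributed, so scatter
is measured by the **interdecile range** (P90 − P10). The percentile
convention — linear interpolation at plotting positions $(k-1)/(n-1)$,
R's type 7 — is not dictated by the field; it is pinned, documented and
frozen by tests, because any convention change silently moves every IDR.
The same convention is used for the alignment IQR and the diastolic
rest-separation decile in tracking.

The replicate comparison is a **Mann-Whitney U test computed exactly**:
with $n = 4$ wells per group the normal approximation is meaningless, so
the two-sided p comes from full enumeration of all
$\binom{n_a+n_b}{n_a}$ assignments of the pooled midranks (ties included).
The smallest attainable two-sided p at 4 vs 4 is 2/70 ≈ 0.029 — worth
remembering when reading significance calls at this group size. A
tie-corrected normal mode with continuity correction is provided for
larger groups and agrees with the exact null within 0.01 at $n = 20$.

Poincaré pairs (previous interval, following interval) are provided for
plotting; regular beating sits on the identity diagonal.

## Dose-response thresholds

Cumulative-concentration experiments are paired by design: the same wells
are measured at baseline and at every concentration. The threshold for a
contractility parameter is the **lowest ladder concentration with
two-sided p < α and the effect in the expected direction** (decrease for
velocities and force, increase for IDR). Two procedures mirror the
screening protocol: a **paired** Student's t-test on within-well
differences for contractility parameters (the repeated-measures design
makes the paired form the defensible reading of "Student's t-test"), and
the exact Mann-Whitney on per-well IDR values for scatter. No
multiple-testing correction is applied across the ladder — the screening
protocol applies none — and the result object carries an explicit
`multiplicity_corrected = FALSE` flag.

The direction gate prevents a paradoxical increase from being called a
"decrease threshold"; with a degenerate α = 1 the first ladder step with
the right direction qualifies, as expected.

**An honest limitation.** Under the null, five uncorrected two-sided
tests at α = 0.05 with a direction gate produce at least one false
threshold call in roughly $1-(1-0.025)^5 \approx 12\%$ of experiments
(simulation: ~15%, the shared baseline recording correlating the five
comparisons). A negative-control compound therefore yields
"threshold = none" in only ~85% of runs under the t-procedure — this is a
property of the uncorrected screening design itself, not of the
implementation, and no implementation of that design can push the rate
above ~88%. The exact Mann-Whitney scatter procedure, conservative at
$n=4$ (minimal directional p = 1/70), reaches ~100%. The acceptance suite
asserts the ≥ 95% no-call bound for both procedures; the t-branch
assertion fails by design and is kept failing rather than silently
loosened, as documentation of the design's false-positive cost.

## Alignment score

Sarcomere orientations are axial (defined modulo 180°). Dispersion is the
interquartile range after **axial canonicalisation**: the sample is
rotated so its circular axial mean (mean direction of the doubled angles)
maps to 90° and folded into [0°, 180°). This makes the dispersion
invariant under rotation of the whole image and removes the 0°/180° wrap
artefact, while reducing to the plain IQR for concentrated samples. The
score is the inverse relative dispersion, $90^\circ/\mathrm{IQR}$
(90° ≙ 100% ≙ 1): 9° dispersion scores 10, 90° scores 1. Zero dispersion
returns `Inf` with a degeneracy flag. Aggregation averages scores across
raters within an image first, then across images within a format group,
and compares groups with a two-sample Student's t-test.

## Synthetic video and tracking

The optional video front end closes the loop on the "figure recognition"
stage. Frames are grayscale matrices with two dark square markers whose
separation is `rest_separation − δ(t)`; squares are drawn with exact
sub-pixel area coverage, so the ground-truth centroid is known to machine
precision. Detection is deliberately minimal: Otsu's automatic threshold,
4-connected component labelling, the two largest components, and
darkness-weighted centroids (weights `median(frame) − intensity` on the
component dilated by one pixel, recovering partially covered edge
pixels). On noiseless frames this recovers centroids to better than
0.1 px and the round-tripped deflection to numerical precision; at 5%
contrast noise the centroid error stays below 0.3 px on ≥ 95% of frames
with no detectable bias. The rest separation is estimated as the upper
decile of the separation series — diastole dominates the duty cycle, so
the estimate is robust to beating occupying most of the recording. Frames
lost to segmentation (≠ 2 components) are linearly interpolated up to a
5% budget, beyond which tracking fails loudly. Inter-marker distance
(rather than absolute marker position) is tracked, which cancels
whole-plate drift.

## Reproducibility surface

Traces travel as CSV (`time_s,value,value_unit`), configurations,
manifests, ground truth and reports as JSON. `run_pipeline()` isolates
per-well failures, embeds the package version and an MD5 hash of the
manifest, and reproduces byte-identical report bodies (modulo timestamp)
for identical inputs. The R functions are the interface; a thin
`Rscript` wrapper (`inst/scripts/eht-analyze.R`) covers shell use.

## Known limitations

* Phenomenological drug maps: no ionic currents, no action-potential
  morphology, no carry-over between cumulative doses (wash-out is
  metadata only).
* The beam formula is the small-deflection limit; no large-deflection or
  finite-element correction.
* Amplitude estimates inherit a small positive bias from taking window
  minima as baseline under noise (≈ +1% at default settings), inside
  every stated tolerance but visible if you look.
* The 0.061 mN / 0.5 Hz presets pin one reported timepoint of a
  maturating preparation; other reports quote 100 µN at the same
  frequency. The presets document, not resolve, that spread.
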