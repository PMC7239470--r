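---
title: "Quantifying temperature-plastic structural coloration: metrics, models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying temperature-plastic structural coloration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromaplast)
```

## The problem

Structural colour patches — such as the blue-green throat and abdominal
badges of male fence lizards — arise from light interference in iridophore
nanostructures, and the reflected hue can shift with body temperature: the
same ornament looks green on a cold animal and blue on a warm one.
Saturation (colour purity) is conventionally measured as the reflectance
inside a focal wavelength band relative to total reflectance, which is
problematic when the focal hue itself moves with temperature, differs
between individuals, or — in weakly ornamented animals — is dominated by
long-wavelength background (skin) reflectance rather than the ornament.

`chromaplast` implements a complete workflow for this situation:
reflectance-spectrum processing, a family of saturation metrics over fixed
and peak-tracking bands, a tetrachromatic visual-sensitivity model, and the
mixed-model machinery needed to ask the two questions that matter for a
plastic ornament: *do individuals change at the same rate across
environments?* and *which metric best preserves individuals' relative
colour ranks across environments?*

## Spectral processing

Spectra enter as percent reflectance relative to a white standard, in wide
(spectrometer-export) or long CSV/TSV. Processing is deliberately minimal
and fully logged:

* **Regridding** — linear interpolation onto the inclusive integer grid
  300–700 nm (401 points). Extrapolation is refused: a spectrum that does
  not cover the range is an error, not a guess.
* **Smoothing** — classic loess (locally weighted quadratic regression
  with tricube weights) with a span of 2/3 of the points, the conventional
  setting for reflectance spectra. A span this wide reproduces constants
  and low-degree polynomials essentially exactly but attenuates narrow
  features; spectral structure narrower than roughly 30 nm should not be
  interpreted after smoothing.
* **Negative reflectance** — smoothing and instrument noise can push
  reflectance slightly below zero. The default is to *retain* negatives
  (no silent data alteration) and record how many there are; zero-clipping
  is an explicit opt-in (`handle_negatives(mode = "zero")`), and is
  required before the visual model, which is undefined for negative
  stimuli.
* **Replicates** — the statistical models consume replicate measurements
  directly (the replicate structure is what makes repeatability and the
  mixed models identifiable); `average_replicates()` exists but is an
  explicit choice, never a default.

Every step appends to a processing log that suffices to replay the
pipeline; `write_processing_log()` serializes it to JSON.

## The saturation metrics

All metrics share one denominator, total brightness: the trapezoidal
integral of reflectance over 300–700 nm. Integrals are trapezoidal on the
1 nm grid throughout; a raw point-sum convention would differ at the 1/400
level, and the edge half-segments of discontinuous test spectra are
visible at that level in exact expectations.

| metric | band | rationale |
|---|---|---|
| `S1B` | fixed 400–510 nm | the conventional "blue" band |
| `S1Sc` | fixed 450–550 nm | "turquoise", centred on the badge hue |
| `S1ScFull` | fixed 400–600 nm | spans the whole blue-to-green plastic range |
| `S3` | peak ± 50 nm | tracks the expressed hue |
| `S3Sc` | peak ± 50 nm, centre capped at 600 nm | as `S3`, but background-proof |
| `S8` | max − min over total | amplitude contrast |

Hue `H1` is the wavelength of maximal reflectance (ties broken toward the
lowest wavelength, deterministically), and mean brightness `B2` is the
average reflectance over the grid.

Two conventions needed a decision the definitions leave open:

* **S3 edge handling** — the ±50 nm window is *truncated* at 300/700 nm
  rather than shifted, so the window centre remains the peak wavelength.
* **S8 dimensionality** — the printed contrast formula divides percent by
  percent·nm; it is implemented exactly as printed (both parts scale
  linearly, so scale invariance still holds), and a mean-brightness
  variant is provided separately as `saturation_contrast_mean()`, never
  substituted silently.

The capped metric `S3Sc` is the interesting one. In weakly ornamented
animals the reflectance peak can sit beyond 600 nm, on the rising
background, so `S3` scores the *skin*, not the ornament. Capping the
window centre at 600 nm makes the metric fall back to the long edge of the
ornament range, so background-dominated spectra receive low, stable scores
while ornamented spectra (peak ≤ 600 nm) are scored identically to `S3`.
Band presets can be overridden or extended from YAML
(`read_band_config()`), since the right fixed band is system-specific.

## The visual model

Cone spectral sensitivities are built from the standard A1 visual-pigment
alpha+beta template (Govardovskii et al. 2000) at the four iguanid peak
wavelengths 359, 459, 481 and 558 nm; cone ratios are carried as data (the
default is even) but do not enter the noiseless relative-catch
computation, and the illuminant is flat unless supplied. Each sensitivity
is normalized to unit area so a spectrally flat stimulus excites all four
cones equally and maps to the achromatic origin — the property that makes
distance from the origin behave as saturation.

Relative quantum catches (u, s, m, l, summing to one) are projected into a
regular tetrahedron with the UV vertex on the vertical axis and all
vertices at distance 0.75 from the origin. Because the tetrahedron is not
a sphere, the attainable distance depends on hue direction (0.25 at face
centres to 0.75 at vertices); the hue-independent saturation is
`r_achieved = r / r_max`, where `r_max` comes from casting a ray from the
origin through the colour point to the first face. The ray cast is checked
against an independent half-space bisection oracle to 1e-6 over a thousand
random catch vectors. `visual_saturation_panel()` emits the catches,
coordinates and `r_achieved` per spectrum; `visual_panel_to_metric()`
feeds `r_achieved` into the statistical framework like any spectral
metric.

## The statistical framework

Saturation values are natural-log transformed and temperature is centred
on the grand mean, so intercepts are the phenotype at the mean
temperature. Five linear mixed models (lme4) form a ladder:

1. `value ~ temperature * sex + (temperature | individual)`
2. `value ~ temperature + sex + (temperature | individual)`
3. `value ~ temperature + (1 | individual)`
4. `value ~ temperature + (temperature | individual)`
5. `value ~ temperature + (temperature || individual)`

The 1 vs 2 likelihood-ratio test (maximum likelihood, 1 df) asks whether
the sexes differ in reaction norms; if so, the data are split by sex and
the random-structure comparisons run per sex: 3 vs 4 (REML, 2 df) for
individual slope variation, 4 vs 5 (REML, 1 df) for the slope–intercept
correlation. Likelihood ratios are referred to a plain chi-square with df
equal to the parameter-count difference. At a variance boundary this is
conservative; an equal-mixture chi-square reference is available
(`boundary_mixture = TRUE`) but off by default, favouring the conventional
reporting style for these tests. Confidence intervals for the
slope–intercept correlation come from profile likelihood by default, with
a parametric bootstrap alternative; estimates pinned at ±1 are flagged as
boundary cases rather than hidden.

Repeatability is the intraclass correlation from a Gaussian
random-intercept model per treatment, `R = var_ID / (var_ID + var_res)`,
with a 95% interval from parametric-bootstrap refits (default 1000, with
an explicit seed). Rank preservation is Spearman's rank correlation
between per-individual means in the two environments, with average ranks
for ties, exact p-values for n ≤ 9 without ties and the t approximation
otherwise — the software convention is stated because it is not universal.
`metric_comparison_report()` assembles the whole picture, one row per
metric × sex, sorted by rank preservation; non-converged fits keep their
row with flags rather than disappearing.

## The synthetic cohort generator

No spectral data ship with the package, so the generator is first-class:
it produces cohorts with the full structure the analysis assumes, plus the
ground truth needed for recovery tests. Each spectrum is

> background sigmoid (rising toward 700 nm) + Gaussian ornament peak +
> smooth replicate noise,

with the ornament centre shifting linearly with temperature (green when
cold, blue when warm), log ornament amplitude following a random
intercept/slope process whose positive coupling makes brighter-baseline
individuals brighten faster with warmth, and three tiers: ornamented males,
weakly ornamented females (hue offsets ≥ 0, i.e. skewed toward the
background side), and unornamented females, whose faint ornament at cold
temperature loses to their dark, strongly red-rising background
(reflectance peak beyond 600 nm — up to the grid edge) but is expressed
enough when warm for the peak to return below 600 nm.

Replicate noise is smooth (white noise on 25 nm knots, spline
interpolated) rather than white, to exercise the loess smoother the way
probe-replacement noise does, and a per-replicate log-amplitude jitter
models the probe sampling slightly different patches of the badge.

### Calibration

The packaged preset (`preset_paper_emulation()`) encodes the study
conditions: 17 ornamented males, 15 females (a fifth unornamented), 23 and
33 °C treatments, triplicate measurements, positive amplitude coupling.
The free parameters were calibrated once, jointly, so that under the full
pipeline (simulate → regrid → smooth → metrics):

* the population mean peak wavelength lands near 600 nm when cold and
  near 500 nm when warm (the hue anchors of the system being emulated);
  the ornament-centre shift itself is −9 nm/°C — slightly less than the
  anchor separation implies — because background pull on female peaks and
  background-dominated individuals add asymmetrically to the cold mean;
* every female's cold spectrum peaks beyond 600 nm (weak ornaments sit on
  the long edge; unornamented backgrounds peak near the grid edge), while
  warm peaks return below 600 nm;
* the capped metric `S3Sc` preserves female cross-temperature ranks at
  least as well as `S3` in most simulated cohorts (median rank-correlation
  advantage ≈ 0.26 across seeds): the unornamented females' dark bases
  make their background-derived `S3` scores spuriously large and unstable,
  scrambling `S3` ranks, while the capped window scores them low and
  stably. This is a tendency, not an identity — in a minority of cohorts
  the two metrics tie or `S3` edges ahead by a few hundredths;
* the male slope–intercept correlation is positive for every spectral
  metric. For females no sign is guaranteed (nor should it be): bounded
  metrics compress gains for bright individuals and fixed bands respond to
  hue offsets, and background-dominated individuals have reaction norms
  that track the background — the system being emulated likewise shows a
  negative female correlation for one peak-tracking metric.

What the generator does **not** emulate: iridescence and measurement-angle
effects, within-individual body-temperature spread around the treatment
set-points (a jitter parameter exists but defaults to off), instrument
dark/white calibration error, and any biophysical (photonic) model of why
hue shifts — the generator is phenomenological. Passing tests on synthetic
cohorts therefore validate the *machinery* (metric definitions, geometry,
estimators, decision ladder) and the qualitative phenomena the generator
encodes, not the biological magnitudes of any real population.

### Direct metric simulation

`simulate_metric_panel()` bypasses spectra and draws log-metric values
straight from the random-intercept/slope process the ladder assumes. It
exists because type-I-error, power and coverage studies need hundreds of
refits; the packaged studies use 200–500 simulations per claim, sizes
chosen to keep the full test suite comfortably inside a coffee break while
leaving the binomial noise on estimated rates well inside the asserted
bands.

## Numerical choices and degenerate inputs

* Integrals: trapezoid on the 1 nm grid everywhere; the same-grid
  convention is what makes a flat spectrum's 400–600 nm fraction exactly
  one half.
* Hue ties: lowest wavelength, so flat or noisy spectra are deterministic.
* Zero total reflectance: an error (`not NaN`) for every ratio metric.
* All-zero spectra: refused by `hue_H1` and `quantum_catch`.
* `r_achieved` at the origin is 0 by definition; points outside the
  tetrahedron (invalid catch vectors) are errors.
* lme4 convergence messages are captured per model and propagated as
  flags; singular fits mark the correlation as a boundary case.
* Every stochastic routine takes an explicit seed; simulation without one
  is an error rather than an irreproducible run.

## Known limitations

* The loess span is a fraction of points, so the effective bandwidth is
  tied to the 401-point grid; other grids change the smoothing strength.
* Variance-component likelihood-ratio tests at the boundary are
  conservative under the plain chi-square reference (the default); the
  mixture option trades convention for calibration.
* With only two temperatures, individual "slopes" are differences in
  disguise; the random-slope models are identifiable thanks to replicates,
  but extrapolation beyond the measured range is meaningless.
* The visual model is noiseless: no receptor-noise discrimination
  modelling, no chromatic adaptation beyond the flat illuminant.
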