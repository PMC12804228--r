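---
title: "Friction, acoustic emission and tactile perception: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Friction, acoustic emission and tactile perception: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tactileAE)
```

## The measurement problem

When a finger slides over a surface, two synchronized signals carry
complementary information about the contact: the **friction force** measured
by a force plate under the sample, and the **acoustic emission (AE)** — high
frequency (here 100–900 kHz) elastic stress waves released by asperity
contact and material deformation, picked up by a piezoelectric sensor on the
substrate. Friction coefficients separate hard, smooth substrates well but
struggle to discriminate fabrics, whose coefficients cluster below 0.5; the
AE energy in a 120–160 kHz band of interest discriminates fabric
constructions (terry, knit, woven) where friction cannot. A sensory panel
rating the same surfaces on six attributes (slippery, soft, rough, thick,
greasy, pleasant; 1–10 interval scale) provides the perceptual layer that
both instrumental channels are meant to explain.

This package implements the full analysis chain — per-stroke friction
statistics, AE spectral and RMS features, and the statistical layer (PCA
with concentration ellipsoids, Tukey–Kramer comparisons, a combined
tribology–sensory PCA) — together with a synthetic-data generator that
plants known ground truth, so every stage is testable without human-subject
recordings.

## Friction model

The instantaneous coefficient of friction is

$$\mathrm{COF}(t) = \frac{|F_\mathrm{lateral}(t)|}{F_\mathrm{normal}(t)},$$

masked wherever the normal force falls below `min_normal` (default 0.2 N)
to prevent blow-up at finger lift-off. The absolute value makes the series
invariant to sliding direction; the sign of the lateral force is kept
separately as the direction tag.

**Stroke segmentation.** One stroke is one sliding movement between
direction reversals. Strokes are maximal runs of consistent lateral-force
sign after hysteresis debouncing (band ±0.05 N, minimum duration 0.25 s =
10 samples at 40 Hz); the hysteresis suppresses zero-crossing chatter at
reversals, and sub-minimum runs are merged into their predecessor and
counted in the segmentation log.

**Static/dynamic split.** Within a stroke, static friction manifests as the
initial force peak and kinetic friction as the following plateau. The
static region runs from the stroke start to the *first sample attaining the
stroke's maximum COF*; the dynamic region is the remainder minus a trailing
5% trim that excludes the deceleration into the reversal. The boundary rule
is a declared convention of this package: where exactly the static region
ends is not observable from the force trace alone, and the first-maximum
rule is the one consistent with the classic peak-then-plateau morphology.
Strokes with fewer than 4 valid samples are flagged unusable and excluded
(with a log entry), never silently filled.

**Stroke statistics.** Static COF = 95th percentile over the static region;
dynamic COF = median over the dynamic region. *One percentile convention is
used everywhere in the package*: linear interpolation between the closest
order statistics (`stats::quantile` type 7), exposed as `pctl()` and tested
against an independent sort-and-interpolate oracle. Indices are 1-based and
inclusive throughout, the natural R convention.

No COF values are discarded as outliers: box-plot summaries
(`summarize_features()`) report medians, quartiles, 1.5 × IQR whiskers and
retained outlier counts.

## Acoustic-emission features

Two feature families are extracted from each AE waveform.

**Spectral band percentile.** A full-record one-sided FFT amplitude
spectrum (a pure sinusoid of amplitude A gives magnitude A at its bin) is
optionally cleaned by `smooth_spectrum()` and summarized by the 90th
percentile of the magnitudes in the closed 120–160 kHz band. Welch-style
segment averaging (Hann window, 50% overlap) is available for
memory-bounded runs and flagged in the output.

**Spectrum smoothing.** Isolated narrow peaks caused by
direction-reversal transients are removed when all three criteria hold:
peak-normalized prominence in [0.01, 0.1], height above 0.015, and no other
significant peak within the minimum distance. The published thresholds
presuppose a magnitude scale that is never stated; this package normalizes
each record's spectrum to a maximum of 1 before applying them (and returns
the result on the raw scale), which makes the thresholds meaningful across
record lengths. Likewise the quoted distance of 50,000 frequency bins is
tied to 30 s records at 2 MSa/s (bin ≈ 0.033 Hz), i.e. about 1.67 kHz; the
package stores the distance in Hz (default 1670 Hz) and converts per
record, with `min_distance_bins` available for literal fidelity. Removed
peaks are filled by linear interpolation between their base bins; retained
bins are never altered, and no magnitude ever increases.

**RMS envelope.** The AE energy envelope is the windowed root mean square
$x_\mathrm{RMS} = \sqrt{\sum_1^n x^2 / n}$ over consecutive non-overlapping
windows aligned to the first sample — 20,000 samples = 0.01 s at 2 MSa/s,
the study convention; the package parametrizes the window in samples and
derives seconds from the rate. A trailing partial window is dropped and
logged. The RMS profile of a fabric trial looks like the friction profile
(rise, plateau, collapse at reversal), so the same static/dynamic split and
statistics are applied to it (95th percentile / median per stroke).

**RMS stroke segmentation** runs in two modes. `transfer` rescales the
force-domain stroke boundaries into RMS-window indices (both streams start
at trial t = 0; no cross-correlation alignment is attempted because no
synchronization procedure beyond a common start is defined). `self` finds
strokes from the envelope alone: stretches of the moving-average-smoothed
profile below a valley threshold (20% of the envelope's 95th percentile)
delimit sliding movements. Profiles without valley structure — constant
envelopes, as planar materials produce — raise an explicit not-segmentable
error rather than returning arbitrary spans. The moving average spans 3
windows by default: with 0.01 s windows and sub-second strokes the
reversal valleys are only about two windows wide, and a wider average
(e.g. 5 windows) erases them; for multi-second strokes any small width
works, and the parameter is exposed.

## Statistical layer

**PCA.** `run_pca()` performs covariance-mode PCA (center, no scaling) by
default. The choice is deliberate: applied to raw 1–10 ratings it yields
eigenvalues on the rating-variance scale of published sensory
variance-contribution tables (six eigenvalues summing to far more than 6,
which correlation-mode PCA cannot produce). Correlation mode is available
and is the default for the combined tribology PCA, whose four active
variables live on unrelated physical scales. Components are sign-fixed so
the largest-magnitude loading of each component is positive, making output
deterministic; eigenvalues, variance percentages and cumulative percentages
are reported in the layout of the published table, and the package ships an
independently published variance/loadings table as a plain-text fixture
against which the same invariants (variance normalization, orthonormal
loadings) are checked.

**Concentration ellipsoids.** Per-group 95% regions in score space use the
chi-square scaling of the group sample covariance: radii
$r_k = \sqrt{\lambda_k \, \chi^2_{d,0.95}}$ along the covariance
eigenvectors. This is the *data ellipse* convention (the region containing
about 95% of the distribution), matching the description of ellipses around
the averaged point of each material's responses; the F-based confidence
region for the group *mean* is implemented as an alternative
(`scaling = "f"`). Groups with fewer points than dimensions + 1, or with
zero scatter, are flagged degenerate instead of erroring.

**Tukey–Kramer.** All-pairs comparisons use
$q = |\bar y_i - \bar y_j| / \sqrt{(\mathrm{MSE}/2)(1/n_i + 1/n_j)}$
with the pooled within-group mean square and N − k error degrees of
freedom, and p-values from the studentized range distribution
(`stats::ptukey`, which performs the required numerical integration at
better than 10⁻⁶). With equal group sizes this reduces exactly to the
classical Tukey HSD, which the tests verify against an independent
computation and against `stats::TukeyHSD`. The family-wise error is
controlled at α = 0.05 *within* one feature (COF, AE RMS, or band
percentile); no additional correction is applied across features, matching
the separate per-panel comparisons of the original analysis. Degenerate
inputs: identical groups give q = 0, p = 1; zero within-group variance with
unequal means reports p at the numerical floor rather than failing.

**Combined PCA.** The four tribology variables (per-material mean
static/dynamic COF and static/dynamic AE RMS) are the active variables;
sensory attribute means are overlaid as supplementary vectors — the
correlation of each attribute with each component's scores — without
influencing the decomposition. `correlation_signs()` reads signed
attribute–feature relationships (positive / negative / near-zero at
|r| < 0.2) off the model.

## The synthetic-data generator

The generator is first-class, tested code that plants known ground truth
with the statistical structure the analysis assumes.

* **Protocol constants** mirror the study: target loads 2/3/4 N, 30 s
  recordings, 3 repeats, force at 40 Hz, AE at 2 MSa/s, six materials,
  eight panellists. The stroke count per recording is not part of the
  protocol; 10 strokes per 30 s (3 s per sliding movement, a comfortable
  reciprocating pace) is the default.
* **Force model.** The normal channel tracks the target load with Gaussian
  error (sd 5% of load) plus a 0.1 Hz sinusoidal drift of 5% amplitude with
  a random phase per trial — an experimenter holding a prompted load. The
  lateral channel per stroke is a linear ramp over the first 20% of the
  stroke to the static peak $\mu_s L$, a plateau at $\mu_d L$, and a 5%
  terminal decay, signed by direction, plus Gaussian noise (sd 2% of load).
  Ramp and decay start/end at 5% of their level so the lateral sign equals
  the stroke direction everywhere. Smooth planar substrates additionally
  get an 8 Hz stick-slip modulation of the plateau. `noise = FALSE` zeroes
  every stochastic term, making the planted coefficients exactly
  recoverable — the basis of the closed-loop recovery tests.
* **AE model.** White noise is masked in the frequency domain to
  120–160 kHz (giving analytically predictable band statistics), scaled by
  the material's in-band level, added to an unfiltered broadband floor, and
  multiplied by the stroke friction envelope so the waveform is near-zero
  at reversals.
* **Questionnaires.** Ratings are the material's planted attribute profile
  plus Gaussian panellist noise (sd 0.8 rating units, a realistic scatter
  for untrained panellists), then monotonically rescaled per panellist and
  attribute so grades 1 and 10 are each used — the anchoring instruction
  given to the panel — and clipped to the scale. The rescaling preserves
  rank order, so zero-noise panels rank materials identically.
* **Presets.** The six material presets order dynamic COF as
  PET > enamel > PTFE ≳ terry > knit ≈ woven (all fabrics < 0.5) and the
  AE band levels inversely; knit and woven are given nearly identical
  friction (0.334 vs 0.330) but clearly distinct AE levels, so the COF
  comparison cannot separate them while the AE features can. Sensory
  profiles carry an inverse association between AE level and perceived
  pleasantness/slipperiness. All preset numbers are simulator fixtures, not
  measurements.
* **Randomness.** One integer seed per trial drives a single stream
  (`simulate_trial()`); identical seeds give bit-identical output. In
  `run_report()`, the corresponding (load, repeat) cell of *every* material
  shares one stream — common random numbers, emulating the paired
  within-participant design in which each subject strokes all materials
  under the same session conditions. This pairing is what makes
  between-material contrasts stable at realistic noise levels, exactly as
  within-subject designs do in real panels.

**What the generator does not emulate** — and therefore what passing tests
do not show about real data: participant-to-participant differences in skin
condition, contact area or stroke velocity; load dependence of the friction
coefficient (synthetic COF obeys Amontons' law, real skin does not);
acoustic propagation, attenuation and sensor coupling; non-stationary AE
bursts within a stroke; panellist idiosyncrasies beyond additive noise.
Recovery tests demonstrate that the *algorithms* are correct and
well-calibrated, not that the physical assumptions hold.

## Problem sizes and numerical choices

The package's simulated-study defaults (`pipeline_config()`) use 6 s
recordings with 8 strokes and AE at 500 kSa/s — sizes chosen so a full
three-fabric study (3 loads × 3 repeats × 3 materials, with full-record
FFTs of 3 × 10⁶ samples each) runs in about a minute on one CPU while
leaving every rate-dependent constant (0.01 s RMS windows, 120–160 kHz
band, Nyquist margin) intact. The generator's own `trial_plan()` defaults
stay at the full protocol scale (30 s, 2 MSa/s). Monte-Carlo calibrations
in the tests use 2000 replicates (Tukey family-wise error; ellipsoid
coverage at n = 2000/20000).

Other numerical conventions: spectra are computed in double precision with
R's mixed-radix FFT; RMS windows align to sample 0 and drop the trailing
remainder; percentiles interpolate linearly (type 7) everywhere; PCA signs
follow the largest-loading-positive rule; ties in the stroke-maximum rule
resolve to the *first* maximal sample; all validation failures name the
offending record.

## Known limitations

* Self-mode RMS segmentation needs visible valley structure; heavily
  overlapping strokes or very low in-band levels fall back to an explicit
  error, and transfer mode (from the synchronized force trace) is the
  robust default whenever force data exist.
* The smoothing rule removes only *isolated* narrow peaks; a reversal
  transient sitting inside dense spectral structure is deliberately left
  untouched.
* `combined_pca()` aggregates to whatever keys the two tables share; with
  only a handful of materials the PCA is low-rank and the supplementary
  correlations are correspondingly coarse.
* The studentized-range p-value floor is machine precision; exact
  permutation p-values are out of scope.
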