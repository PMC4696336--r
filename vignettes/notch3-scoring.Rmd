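---
title: "Quantifying vascular NOTCH3 accumulation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying vascular NOTCH3 accumulation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(notch3score)
```

## The biomarker

CADASIL, the most common hereditary cerebral small-vessel disease, is caused
by mutations in *NOTCH3* and characterised by progressive accumulation of
the NOTCH3 extracellular domain in the walls of small arteries. In
transgenic mouse strains expressing mutant human *NOTCH3* at different
levels, granular NOTCH3-immunopositive deposits appear in brain vessel
walls at an age that decreases with expression level, and grow in number
and size thereafter. The **NOTCH3 score** turns this staining pattern into
a number suitable for group comparison and for powering preclinical
treatment studies: the total area of small, round, strongly stained
particles in a standardised field.

This package implements the score twice, for the two tissue contexts in
which it is used:

* **Mouse brain sections** (DAB single staining): convert to 8-bit,
  sharpen with an unsharp mask (sigma 1 px, weight 0.60), threshold at
  intensity 150 (dark-positive), extract connected particles, keep those
  with area 0–30 px² and circularity 0.50–1.00, and report the total
  retained area ([`notch3Score()`]).
* **Human brain sections** (NOTCH3/CD31 double staining): within a
  manually drawn CD31-positive vessel mask, count pixels at or below
  intensity 100 and report them as a percentage of the vessel area
  ([`vesselMaskedScore()`]). No sharpening and no particle filter are
  applied by default, and both can be enabled for sensitivity analyses.

## Pipeline definitions and numerical choices

**Grayscale conversion.** Colour micrographs are collapsed by a weighted
channel mean (default: unweighted mean, the standard 8-bit conversion of an
RGB image), rounded half-up and clipped to [0, 255]. The scanner's own
colour pathway is unknowable from the outside; the weights are exposed so a
user can match a different convention (e.g. luma weights 0.30/0.59/0.11).

**Unsharp mask.** The filter computes `(I − w·G_σ(I)) / (1 − w)` per pixel
in real arithmetic, where `G_σ` is Gaussian smoothing with σ = radius.
Three numerical decisions make results bit-stable across runs and
platforms: the kernel is truncated at 3σ (minimum half-width 1 px) and
normalised; edges are handled by replicate padding, which avoids the dark
border halos that zero padding would push across the threshold; and the
result is rounded half-up, then clipped to [0, 255]. Whether the original
ImageJ analysis rounded or truncated is not recoverable; rounding is the
recorded choice and the test suite allows ±1 intensity unit against a dense
convolution oracle to absorb exactly this ambiguity.

**Threshold polarity.** DAB-positive staining is dark on a light
background, so "threshold 150" is interpreted as *member iff intensity ≤
150*. The direction is exposed (`polarity = "bright"`) because a published
threshold number alone does not fix it.

**Connectivity and label order.** Particles are 8-connected by default
(4-connectivity available). Labels are assigned 1..K in raster-scan order
of each component's first pixel, so every downstream table is reproducible
byte-for-byte.

**Perimeter and circularity.** The perimeter is the *crack boundary*: the
count of unit pixel edges adjacent to a non-member pixel or the image
border, hole boundaries included; holes are not filled and do not count
toward area. Circularity is `min(1, 4π·area/perimeter²)`. The crack
boundary was chosen because it is exactly defined and oracle-testable;
ImageJ's particle analyser uses a weighted boundary approximation that
yields systematically higher circularities for small digital shapes (its
perimeter is shorter), so circularity windows are not directly transferable
between the two conventions. This is why `circMin` is an explicit
parameter rather than a constant. Concretely, under the crack convention a
single pixel and a 3×3 square both have circularity 0.785, the digital disc
of radius 2.5 (area 21) has 0.659, but the radius-2 disc (area 13,
perimeter 20) has 0.408 and falls *below* the 0.50 default — a purely
discrete effect with no biological meaning.

**Filter bounds.** Both the size and the circularity windows are inclusive
on both ends; a particle of exactly area 30 or circularity 0.50 is
retained. Size is in uncalibrated pixel²; no physical pixel size enters the
score. Particles touching the image border are included.

## The synthetic generator

No stained slides are distributed with this package; every claim about the
pipeline is instead validated against synthetic fields with exact ground
truth ([`renderField()`], [`simulateCohort()`]). A field is a light tissue
background (intensity 235), a vessel-wall annulus (intensity 215, inner
radius 80 px, outer 96 px in a 256×256 frame), and dark granular deposits
placed uniformly on the wall with a minimum edge-to-edge gap of 2 px,
followed by additive Gaussian pixel noise (default SD 8) and clipping.

Three generator choices are deliberate and load-bearing:

* **Deposit radii are drawn from {1.5, 2.5} px.** These rasterise (with
  centres snapped to pixel centres) to fixed digital shapes of area 9 and
  21 px² with crack-boundary circularities 0.785 and 0.659 — inside both
  default filter windows. A naive "radius 1–3 px" rule would emit the
  radius-2 disc, which the circularity filter rejects (see above), and
  truth recovery would silently become approximate. With this choice,
  noise-free recovery is *exact*: pipeline score = total true deposit area,
  bit-for-bit.
* **Intensity margins are engineered around the unsharp overshoot.**
  Deposit intensities are N(90, 8) clamped to [60, 120]. The unsharp mask
  amplifies local contrast by up to 1/(1−w) = 2.5×; with background 235 and
  wall 215, no background or wall pixel can undershoot to 150 in the
  noise-free case, and no deposit pixel can overshoot above it, so the
  thresholded set equals the deposit mask exactly. With noise SD 8
  (amplified to ≈ 2.2 × 8 by the filter) the wall sits ≈ 3–4 amplified SDs
  above threshold, keeping false-positive pixels rare; per-mouse mean
  scores stay within 10 % of truth (typically under 1 %).
* **Cohort load model.** The expected deposit count per field is
  `L(age, e) = rate · e · max(0, age − onset(e))` with expression
  multipliers e ∈ {1.0, 1.5, 2.0, 3.5} and onsets 52/22/13/6 weeks — the
  published ordering: higher expression, earlier onset. Per-field counts
  are Poisson(L). The rate (0.15 deposits/week) is a scale choice that
  keeps the heaviest cell (~40 deposits/field) placeable on the wall; the
  model is meant to reproduce the qualitative structure (onset ordering,
  monotone growth), not any absolute score, which depends on staining and
  optics that are not modelled. Deposit *size* growth with age, which is
  reported qualitatively in the source material, is not modelled — counts
  carry the progression here.

The default cohort mirrors the study design: ages 6/24/52/82 weeks, 3 mice
per strain × age, 10 fields per mouse. What passing tests on these fields
show is that the *measurement machinery* is exact and well-calibrated; they
say nothing about staining variability, section thickness, illumination
gradients, vessel segmentation or field selection in real material, none of
which the generator emulates. Field selection in particular is manual in
the original procedure and explicitly out of scope: the pipeline takes the
field list as given.

## Statistical layer

* `tTestFromSummary()` is the pooled-variance Student t-test (df =
  n₁+n₂−2), computable from (mean, SD, n) alone; with the published
  20-month summaries (659 ± 51 vs 1150 ± 107, n = 3) it gives t = 7.17,
  df = 4, p = 0.0020. Pooled (not Welch) is the default because it is the
  conventional "unpaired Student's t-test" and reproduces that printed
  p-value; Welch is one argument away.
* `anovaLSD()` wraps a one-way ANOVA and reports Fisher's LSD pairwise
  table with *unadjusted* p-values — that is the definition of the LSD
  procedure; the output documents the multiplicity rather than adjusting
  away from the published method.
* `fitProgression()` / `compareSlopes()`: OLS score-on-age fits; slope
  equality is tested through the age × group interaction of a pooled
  model, the standard ANCOVA formulation. Published "slope ± x" values are
  not reproduced numerically because whether their dispersion is SE or SD
  is not stated; only the procedure is fixed here.
* `sampleSizeProgression()` returns the smallest integer group size whose
  exact (noncentral-t) two-sample power reaches the target, seeded by the
  normal-approximation formula. α = 0.05 and power = 0.80 are flagged
  defaults, not published values; the variance source and endpoint behind
  any published animal-count claim are parameters, not assumptions.

## Degenerate inputs and error contracts

Empty vessel masks, single-observation groups, all-identical ages and
empty cohort designs raise immediate, specific errors. An unreadable image
inside a cohort run is recorded as a failure while the run continues, and
the CLI exits nonzero if any failure occurred. Images deeper than 8
bits/channel are rejected outright: silently rescaling them would change
the meaning of the fixed thresholds 150/100.

## Problem sizes used in the test suite

Oracle-equivalence checks run 200 random masks up to 64×64 against a
brute-force flood-fill/edge-count implementation; unsharp filtering is
checked against dense convolution on images up to 32×32; recovery checks
use 3 noise-free and 30 noisy 256×256 fields; the progression check
simulates the full 4 × 4 × 3 × 10 default cohort at noise SD 2 (a low-noise
setting that keeps the zero-load cells exactly zero, so rank agreement with
the programmed loads can be required to be exactly 1); calibration checks
use 10,000 null replicates (n = 3 per group) and 20,000 Monte-Carlo power
replicates. These sizes were chosen so each property is tested at
convincing resolution while the whole suite stays fast enough to run on
every change.

## Known limitations

* Circularity values are convention-dependent (crack boundary vs weighted
  boundary); windows tuned in ImageJ must be re-tuned here.
* The human score's published absolute values cannot be reproduced without
  the original slides, and their units are not recoverable; the package
  fixes the procedure and reports both percentage and raw positive area.
* No stain separation: the human variant relies on an externally supplied
  CD31 vessel mask rather than unmixing DAB from Vector Blue.
* Scores are in uncalibrated pixel²; cross-magnification comparisons
  require the user to hold imaging conditions fixed, as the original
  procedure does.
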