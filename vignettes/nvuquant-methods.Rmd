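---
title: "Methods: automated neurovascular histomorphometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated neurovascular histomorphometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its methods: the model behind
each measurement, the tunable parameters and why their defaults are what
they are, what the synthetic generator does and does not emulate, and
the numerical conventions. It states no empirical results beyond what
the test suite itself computes.

## 1. The vessel segmentation stack and its 8-bit semantics

Vessel area is measured by a filter stack of the kind written as ImageJ
macros for fluorescent vascular stains:

1. linear rescale to 8-bit (min → 0, max → 255);
2. Gaussian blur, σ = 2 px — suppresses shot noise at a scale below the
   thinnest vessel (~3 px);
3. Sobel gradient magnitude ("find edges") — vessels become bright
   double contours;
4. local variance, radius 5 px — fills the space between the two
   contours of a vessel, turning contours into solid bands;
5. local median, radius 3 px — removes isolated high-variance speckle;
6. subtract σ, where σ is the standard deviation of the current image —
   an adaptive background floor that keeps the *rule* identical across
   images while tracking per-image noise level;
7. multiply by 255 — saturating multiplication of an 8-bit integer
   image is a binarization: 0 stays 0, everything ≥ 1 becomes 255;
8. invert; foreground is the pixels equal to 0 after inversion;
9. connected-component ("particle") analysis, 8-connectivity, particles
   smaller than `min_area = 25` px² discarded (noise specks), no
   circularity filter.

**8-bit emulation.** After every stage the result is rounded half-up
(`floor(x + 0.5)`, deterministic across platforms, unlike banker's
rounding) and clamped to [0, 255], exactly as a macro operating on an
8-bit image would behave. A float mode (`eight_bit = FALSE` per filter,
`eight_bit_mode` in `filter_params()`) exists to study precision loss;
8-bit is the default because step 7's binarization only makes sense on
integers. Rank-filter neighbourhoods are the Euclidean disk
{offsets : dx² + dy² ≤ r²}; ImageJ's rasterized kernels differ by at
most a rim pixel, and the disk definition is exactly checkable against
brute-force enumeration (which the test suite does). All filters use
replicate edge padding, which avoids spurious border particles.

**Estimator bias — read before interpreting absolute fractions.** The
edge → variance cascade widens each vessel by roughly the variance
radius per side: a 6 px tube produces a mask band of about 17 px, i.e.
an area fraction ~3× the true one. This is intrinsic to the operator
order, not noise. The measurement is therefore a *relative* area index:
across scenes spanning 2–15% true vessel fraction it is strongly linear
in the truth (the acceptance suite requires R² ≥ 0.6 and positive
slope; observed R² ≈ 0.98 with slope ≈ 2.9), so group ratios,
relative-to-control means and correlations — the quantities the
downstream statistics consume — are preserved. Absolute fractions
should not be compared across different filter parameter sets.

## 2. Morphometry

**Percent area** is the fraction of pixels strictly above a fixed
threshold. The threshold must be frozen once per experiment; the
package operationalizes "identical threshold criteria for all the
pictures" as Otsu's threshold computed on the pooled control-group
histogram (`pooled_otsu()`), then applied unchanged to every group
(`run_pipeline()` does this automatically). A fixed a-priori value is
equally valid and supported.

**Skeleton length** replaces manual centerline tracing (NeuronJ-style)
with Zhang–Suen thinning to a 1-px, 8-connected skeleton. Length is the
sum over adjacent skeleton pixel pairs — 1 px orthogonal, √2 px
diagonal — times the pixel size. Each unordered pair counts once; an
isolated pixel contributes 0. Thinning erodes roughly 2 px at each
blunt end, so a 3×20 px bar reads as 16–19 steps; this constant
per-endpoint bias cancels in group comparisons. The automated
surrogate is validated against the
generator's exact centerline truth rather than against human tracing.

**Pericyte coverage** is length-based (the tracing-length quote in the
source protocol decides the open question of length- vs area-based
coverage): a vessel-centerline pixel is covered when any
pericyte-positive pixel lies within `tolerance_radius` (default 2 px,
modelling soma/process apposition to the vessel wall across the
basement membrane); covered length uses the same step weights with both
step endpoints required to be covered. Coverage of an empty vessel
skeleton is an error, not 0 — there is no estimand.

## 3. Cell detection and colocalization

Manual click-counting is replaced by multi-scale Laplacian-of-Gaussian
detection. The image is rescaled to [0, 1]; at each scale σ on a
geometric ladder (ratio ~1.3) from `min_scale` (3 px) to `max_scale`
(8 px) the scale-normalized response σ²·(−∇²G∗I) is computed; 3×3
spatial maxima that also dominate adjacent scales and exceed
`score_threshold` become candidates; greedy non-maximum suppression
(best score first, ties broken by row then column) enforces
`min_distance` (6 px).

Two hardening steps proved necessary on realistic scenes:

* **Hessian ridge rejection** (`edge_ratio`, default 10): candidates
  whose smoothed-image Hessian satisfies tr²/det > (r+1)²/r are
  elongated (ridge-like) responses along vessels or pericyte process
  bands, not somata — the same edge-rejection criterion SIFT uses.
* **Border exclusion**: maxima within one scale radius of the border
  are replicate-padding artifacts and are dropped.

A soma of amplitude A (on the [0, 1] scale) at the matched scale yields
a LoG response ≈ A/2. The default `score_threshold = 0.05` suits clean
soma channels; when counting somata sitting on bright process bands
(the pericyte channel) the threshold should be ≈ A/2 — the package's
cohort analyses use 0.3 for somata of amplitude ≈ 0.63.

**Double positives** use greedy one-to-one matching in ascending
distance with `pairing_radius` 5 px (deterministic tie-break by
distance, row, column). One-to-one matching caps the double-positive
count at min(count_a, count_b) and prevents one nucleus claiming
several partners; a maximum bipartite matching would differ only in
contrived geometries.

## 4. Group statistics and ΔΔCt

The animal, not the image, is the unit of inference (group sizes in the
motivating study are mice, each contributing 4 or 6 fields): per-animal
values are means over that animal's images, so unbalanced image counts
do not reweight animals. Relative-to-control normalization divides all
animal values by the control-group mean (control relative mean = 1 by
construction); SEM = SD/√n on the normalized values.

Two groups are compared with the unpaired Student t (pooled variance —
the period-typical Prism default for "unpaired t test"; Welch via
`var_equal = FALSE`); three or more with one-way ANOVA followed by
Tukey HSD using the studentized-range distribution at the error df
(Tukey–Kramer standard errors for unbalanced groups). Tukey runs on raw
values by default; ANOVA is location-invariant so normalization does
not change it. Degenerate zero-variance inputs return p = 1 (equal
means) or p = 0 with a warning (unequal).

The qPCR pipeline follows the quoted protocol exactly, including its
two idiosyncrasies: ΔCt subtracts the **geometric mean of the
normalizer Cts on the Ct scale** (not the more common arithmetic mean —
the protocol's wording wins), and fold changes use the **signed
convention** 2^(−ΔΔCt) for up-regulation, −2^(ΔΔCt) for
down-regulation; an unsigned 2^(−ΔΔCt) column is emitted alongside to
avoid ambiguity. A sample is flagged differentially expressed when its
signed fold lies more than 2 control-group SDs from the control-group
mean fold. With a single normalizer gene (the motivating study used
β-Actin alone) a global Ct shift cancels exactly — checked to 1e-12 by
the test suite. With several normalizers the geometric mean on the Ct
scale is not translation-equivariant, so the cancellation is only
approximate (~0.2% on realistic tables); the arithmetic mean would
restore exactness but the protocol's wording wins.

## 5. The synthetic generator: what a green test establishes

No imaging data from the motivating study are deposited, so validation
runs against a seeded simulator that emulates the *structures being
measured*, with exact pre-noise ground truth (the estimand is the
noiseless scene):

* vessels: unit-step random-walk centerlines (heading noise SD 0.08
  rad) rendered as constant-width tubes, width uniform in 3–10 px;
  recorded length is exactly (n−1)·pixel_size per polyline;
* pericytes: process bands (tube of width vessel+2 px) along a
  contiguous fraction of each vessel's centerline, somata (Gaussian
  blobs, σ 3 px) placed on covered stretches at a rate per 100 µm of
  vessel; coverage truth is the exact covered/total centerline ratio;
* cells: Gaussian somata (σ 4 px ≈ a 10 µm soma at 0.6 µm/px), counts
  Poisson-drawn, centres ≥ 3σ apart; a C1qa-like channel marks a
  specified fraction of the IBA1-like population (pairing truth
  recorded);
* fibrin-like puncta: 2–4 px discs, half on vessels;
* background 20 + linear gradient of amplitude 10 at random
  orientation; Poisson shot noise then Gaussian read noise (SD 5);
  output rounded/clamped to 8-bit.

Defaults approximate a 20× cortical field: 512×512 px at 0.6 µm/px,
vessel intensity 180, soma amplitude 160, band 110 — soma
peak-to-background SNR ≈ 20. Cohorts add a per-animal lognormal
biological effect (CV 0.1) and per-group effect multipliers whose
defaults are the magnitudes reported for aged mouse cortex (fibrin ×3,
pericyte count ×0.8, coverage ×0.5, microglia/C1qa ×3, running ×0.65 on
C1qa⁺ cells; the four-group young/aging/aged-sedentary/aged-runner
template interpolates the aging group at roughly half effect). Scene
seeds derive deterministically from the cohort seed, so results are
independent of generation order; the RNG kind is pinned
(Mersenne-Twister / inversion / rejection sampling).

What the simulator does **not** emulate: optics (no PSF model beyond a
1 px edge blur), 3D sectioning, staining variability between channels
of one cell, vessel branching topology, or spatially correlated
background structures. A green planted-effect test therefore
establishes that the measurement pipeline recovers known effects under
realistic noise and geometry — not that it would do so on any given
microscope's output.

## 6. Numerical conventions and degenerate inputs

* Rounding: half-up on non-negative values, everywhere.
* Constant images: normalize to all-0 (degenerate range convention);
  variance/Sobel of a constant are 0; blur/median leave it unchanged.
* Featureless (structure-free) fields are outside the segmentation
  algorithm's domain: the 8-bit rescale stretches pure noise to full
  contrast and the variance stage then saturates, marking most of the
  image foreground. Such fields announce themselves by an absurd area
  fraction (> 0.5); they are not silently zeroed.
* `subtract_saturate(c = "auto")` resolves to the sample SD of the
  image as passed in (post-rounding in 8-bit mode); the resolved value
  is recorded in `params_used$sigma_used` for audit.
* Connectivity is 8 throughout (particle analysis, skeleton steps).
* Empty masks: `skeleton_length` returns 0; `pericyte_coverage` with an
  empty vessel skeleton errors; `analyze_particles` returns an empty
  table with `percent_area = 0`.
* Determinism: identical inputs and parameters give bit-identical
  outputs; the full pipeline rerun under one seed writes byte-identical
  CSVs (checked by the acceptance suite).

## 7. Known limitations

* The segmentation area index is biased upward by design (section 1);
  it supports relative comparisons only.
* TIFF I/O is not provided in this build (no TIFF reader available in
  the target environment); PNG and plain PGM are.
* Skeleton length underestimates tortuous vessels slightly (thinning
  end effects) and merges vessels that the segmentation mask merges.
* The ΔΔCt DE rule inherits the fragility of the signed fold scale:
  with control folds straddling ±1 the control SD is inflated; the
  unsigned column is provided for sensitivity analyses.
* No mixed-effects modelling of image-within-animal nesting; the
  simple per-animal-mean scheme is reproduced deliberately.
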