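---
title: "Models and methods: thermal-dose analysis of homologous recombination readouts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermhr)
```

# The experimental system

Hyperthermia in the 40–44 °C range degrades BRCA2 and thereby attenuates
DNA double-strand-break repair by homologous recombination (HR). The
package analyses the three readouts such studies rely on — RAD51 focus
morphology in S-phase nuclei, clonogenic survival after irradiation, and
immunoblot band intensities — across a fixed design grid of thermal doses
(`thermal_design()`): 40 and 41 °C for up to 240 min, 42 °C for up to
120 min, and 43/43.5/44 °C for up to 60 min, each with a 0-minute (37 °C)
control arm.

No public raw data exist for this assay class, so the package treats the
*synthetic-data generators as first-class citizens*: they encode the study
conditions (sample sizes, noise levels, effect sizes) as defaults, produce
ground truth alongside every dataset, and the analysis pipeline is
validated by parameter recovery against that truth.

# Clonogenic survival model

Colonies on a plate seeded with $n$ cells are modelled as
$\mathrm{Poisson}(n \cdot \mathrm{PE} \cdot \mathrm{SF}(D))$, where the
plating efficiency PE combines the baseline efficiency at 37 °C with a
heat-kill multiplier per thermal dose, and the surviving fraction follows
the linear-quadratic law
$$\mathrm{SF}(D) = \exp\left(-(\alpha D + \beta D^2)\right),
\qquad \alpha, \beta \ge 0.$$
Seeded cell numbers double for every 2 Gy of dose (200 cells at 0 Gy for
fast-growing lines, 300 for slower ones), mirroring standard practice so
that colony counts stay countable at high dose.

## Fitting and the normalization intercept

`fit_lq()` fits $\log \mathrm{SF} = c - (\alpha D + \beta D^2)$ by least
squares with the non-negativity constraint enforced exactly (the active
sets of the two constrained parameters are enumerated; the two-parameter
problem makes this trivial and free of iterative-solver tolerance).

The free constant $c$ deserves explanation, since surviving fractions are
already normalized to 0 Gy and the textbook curve passes through
$\mathrm{SF}(0) = 1$. The normalization divides every plate in a condition
by the *estimated* 0 Gy plating efficiency — a quantity with its own
sampling error that is then shared by all points of that condition. If the
fit is forced through the origin, that shared error has nowhere to go: in
simulation under the package's default conditions the nominal 95%
confidence intervals cover the truth only ~89% of the time, and the
shared-versus-separate F-test rejects a true shared curve ~20% of the time
at the 5% level. Estimating one free log-scale normalization constant per
dataset absorbs exactly this error; coverage returns to ~95–96% and the
F-test's type-I error to ~5–6%. On exactly normalized (noise-free) data
$c = 0$ and $(\alpha, \beta)$ are recovered to machine precision.
`intercept = FALSE` restores the strict through-origin fit for users who
want the textbook parameterization.

Fits are unweighted on the log scale by default (a `weights` argument is
exposed); replicates enter as individual points to preserve degrees of
freedom.

## Shared-versus-separate curves

Whether several thermal doses share one survival curve is decided by the
extra-sum-of-squares F-test on nested least-squares models:
$$F = \frac{(\mathrm{RSS}_{\mathrm{pooled}} - \mathrm{RSS}_{\mathrm{sep}})
            / (\mathrm{df}_{\mathrm{pooled}} - \mathrm{df}_{\mathrm{sep}})}
           {\mathrm{RSS}_{\mathrm{sep}} / \mathrm{df}_{\mathrm{sep}}}.$$
For the LQ model the pooled fit shares $(\alpha, \beta)$ across groups
while keeping one normalization constant per group, so the test compares
the *curve parameters*, not the normalizations. The same machinery serves
the linear plating-efficiency-versus-time regressions and, with a
quadratic-in-time polynomial, the fractionation time courses of the blot
module. The decision level `alpha_level` defaults to 0.05 and propagates
from the pipeline configuration.

# Focus-counting pipeline

The pipeline mirrors a standard particle-analysis macro:

1. **Maximum projection** of each channel (`max_project()`).
2. **Nucleus segmentation** on the EdU channel (`segment_edu_nuclei()`).
   The default global threshold is `median + 6 × 1.4826 × MAD` of the
   projected image: most of a field is background, so the median and MAD
   estimate background level and noise robustly. A maximum-entropy
   threshold is deliberately *not* used here — it splits the two most
   entropic pixel populations, which on a field containing both bright and
   dim nuclei separates nucleus classes rather than background, and dim
   S-phase-compromised nuclei must still be segmented. Components smaller
   than `min_nucleus_area_um2` (default 20 µm²) are discarded.
3. **EdU gating**: a nucleus is EdU-positive when its mean EdU signal
   exceeds the background mean by `edu_positive_k` (default 3) background
   standard deviations. Only EdU-positive nuclei are analysed by default
   (HR requires S phase).
4. **Per-nucleus RAD51 thresholding** with the Kapur maximum-entropy
   algorithm (`max_entropy_threshold()`): the threshold maximizes the sum
   of Shannon entropies of the normalized background and foreground
   histograms, computed on a 256-bin histogram over the full gray range of
   the in-mask pixels; ties break toward the lowest level, and a
   degenerate (single-bin) histogram yields zero foci with a warning.
5. **Particle analysis** (`detect_foci()`): connected supra-threshold
   components with area in `[0.05, 5]` µm² are kept. The size filter is
   interpreted in square micrometres of projected area — with the default
   82 µm / 1024 px geometry, 0.05 µm² is about 8 pixels, the conventional
   scale for a focus-size floor.
6. **Per-nucleus statistics** (`profile_nuclei()`): focus count, mean
   area, mean intensity, and the *mean integrated density per focus*,
   defined as the mean over foci of each focus's area × mean intensity
   (not the product of the means; the per-focus product weights bright
   large foci correctly). Zero-focus nuclei report count 0 with `NA`
   morphology statistics and are unclassifiable.

Coordinates are pixel-centred and 0-based; all areas are converted to µm²
through the configured pixel size.

## Morphology classification

Three focus morphologies occur: category 1, many bright foci of normal
size (intact HR); category 2, few large foci (attenuated HR, typical of
41–43 °C doses); category 3, many very small dim foci with reduced EdU
signal (stalled replication forks, typical above 43 °C).
`classify_category()` operationalizes the visual calls as rules in the
(count, mean integrated density) plane against a reference distribution of
control-condition nuclei: category 3 if density falls below the
low-density cutoff (evaluated first), else category 2 if the count falls
below the low-count cutoff, else category 1.

The cutoffs are low quantiles of the control reference. The default
quantile is 0.01: since the reference *is* the category-1 distribution, a
cutoff at its 10th percentile would by construction misclassify ~10% of
category-1 nuclei per margin (~19% for the two rules combined), while the
1st percentile keeps the false-reassignment rate at the percent level —
category-2 counts (2–6 foci) and category-3 densities (hundreds versus
thousands of µm²·a.u.) sit far beyond either cutoff. Because an extreme
quantile is estimated from data, the reference should contain on the order
of 100 control nuclei for a stable cutoff (the function enforces a minimum
of 20). Both quantiles are arguments.

# Densitometry

`quantify_band()` integrates a lane profile over a peak window above a
straight baseline joining the window endpoints (trapezoidal rule; negative
net areas floor at 0 with a warning) — the convention of profile-based gel
tools. `normalize_levels()` divides each band by its lane's loading
control *first*, then expresses it as a percentage of the
control-normalized 37 °C reference of the same blot, cell line and
fraction; the order matters under unequal loading, and the result is
invariant to rescaling all signals of a blot. `anova_tukey()` wraps
one-way ANOVA with Tukey HSD (Tukey–Kramer for unbalanced groups);
`fractionation_analysis()` applies the quadratic-in-time curve comparison
and per-time Welch t-tests to whole/supernatant/pellet series.

# Synthetic-data generators

* **Images** (`gen_image_dataset()`): non-overlapping elliptical nuclei
  with jittered axes (overlap is forbidden to keep truth matching exact);
  per-nucleus category drawn from `category_mix`; foci planted as 3-D
  Gaussian blobs (XY sigma per category, axial sigma 1 µm) strictly inside
  the nucleus, with a minimum centre separation proportional to the
  category's focus size; EdU drawn per category (category 3 at half the
  category-1 level). Camera noise is Poisson shot noise (gain 1) plus
  Gaussian read noise (SD 50) on a 16-bit scale; both can be disabled for
  exact-recovery tests. Default geometry: 1024 × 1024 px over 82 × 82 µm,
  14 slices at 1 µm. Default morphologies: category 1 ≈ 20 foci of
  σ 0.25 µm at peak 10000; category 2 ≈ 4 foci of σ 0.45 µm at peak 12000;
  category 3 ≈ 30 foci of σ 0.16 µm at peak 3500. The three printed focus
  patterns constrain these only qualitatively; the numbers are generator
  defaults chosen to look like confocal RAD51 data, not measured claims.
* **Colony counts** (`gen_colony_counts()`): the Poisson model above, with
  default truth α = 0.3 /Gy, β = 0.03 /Gy², PE₃₇ = 0.7 and a heat-kill
  profile that declines roughly linearly in time with a
  temperature-dependent slope.
* **Blots** (`gen_blot_table()`): band = loading control × true relative
  level × mean-one lognormal noise (CV 0.15 by default, four cell lines).
  The default dose–response profile (`default_brca2_profile()`) is
  anchored at the landmark values 22% at 43 °C/60 min, 64% at
  40 °C/240 min and ~60% at 41 °C/60 min, interpolating the rest of the
  grid with depletion saturating above 43 °C.

All generators are deterministic given their integer seed (fields use
fixed-offset substreams so partial runs reproduce), and identical seeds
give bit-identical outputs.

## What the generators do and do not emulate

The images contain no optical point-spread function, chromatic shift,
uneven illumination, autofluorescence, cell-cycle structure, or touching
nuclei; blots have no smile, saturation or spatially correlated
background; colony counts have no plate-to-plate overdispersion beyond
Poisson. Passing tests therefore demonstrate that the *algorithms* are
correct and calibrated under the stated noise model — not that the
pipeline is robust to every artefact of real microscopes and gels. The
module boundaries (per-ROI thresholding, quantile cutoffs, baseline
choice) are exactly the places where such robustness would be tuned on
real data.

# Numerical choices and degenerate inputs

* Histograms for thresholding use 256 bins over the full gray range;
  threshold ties break toward the lowest level; single-bin histograms are
  an error at the API level and a warned zero-focus outcome inside the
  pipeline.
* The constrained LQ solution enumerates active sets exactly; `boundary`
  flags fits pinned at α = 0 or β = 0.
* Welch's t-test is the default two-sample test; two zero-variance groups
  with equal means return t = 0, p = 1 by convention.
* SF ≤ 0 points (zero colonies) cannot be log-transformed and are dropped
  with a warning; fewer than three usable distinct doses is an error.
* Surviving fractions normalize per condition by the mean 0 Gy plating
  efficiency, so the condition-mean SF at 0 Gy is exactly 1.
* The studentized-range distribution is evaluated numerically via R's
  `ptukey`.

# Problem sizes

The test suite and the demo pipeline run on reduced geometries chosen as a
deliberate design point: 512 × 512 px fields with 3–5 slices and ~5 nuclei
per field (≈150 treated plus ≈120 control nuclei for the classification
checks), 500 null simulations for F-test calibration, 100 simulations for
confidence-interval coverage, and 100 simulated four-cell-line blot
experiments for the recovery summaries. These sizes keep every
Monte-Carlo estimate's error well inside the tolerance it is compared
against while remaining quick on a laptop; the full-size defaults
(1024 × 1024 × 14) remain the generator's defaults for realistic use.

# Known limitations

* Focus detection is 2-D (post-projection); overlapping foci along Z merge.
* The classifier is a fixed rule in two features; it reports `NA` for
  zero-focus nuclei rather than guessing.
* The LQ machinery assumes homoscedastic log-scale errors; Poisson noise
  makes high-dose points noisier, which mildly inflates the F-test's
  type-I error (measured ~6% at nominal 5% under default conditions).
* Lane profiles are assumed already extracted; the package does not locate
  lanes on arbitrary scanned gels.
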