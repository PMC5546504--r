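# thermhr

Quantitative analysis of hyperthermia experiments that probe DNA repair by
homologous recombination (HR).

Mild heat (40–44 °C) degrades the BRCA2 protein, which in turn prevents
loading of RAD51 onto DNA double-strand breaks and so attenuates HR — the
basis for combining hyperthermia with radiotherapy or PARP inhibitors. A
thermal dose is a (temperature, duration) pair; the question the package
addresses is how HR readouts respond across a grid of such doses. It is
aimed at radiobiology and DNA-repair labs analysing three standard assay
types:

* **RAD51 focus counting** in fluorescence Z-stacks: maximum-intensity
  projection, segmentation of EdU-positive (S-phase) nuclei, per-nucleus
  maximum-entropy (Kapur) thresholding of the RAD51 channel, particle
  analysis with an area filter, per-nucleus statistics (focus count and
  mean integrated density per focus = mean over foci of area × mean
  intensity), and rule-based classification of the three focus
  morphologies (normal / few-large / many-small-dim).
* **Clonogenic survival**: plating efficiency (PE), surviving fractions
  normalized to 0 Gy, linear-quadratic fits
  `SF(D) = exp(−(αD + βD²))` with `α, β ≥ 0`, and shared-versus-separate
  curve decisions via the extra-sum-of-squares F-test
  `F = ((RSS_pooled − RSS_sep) / (df_pooled − df_sep)) / (RSS_sep / df_sep)`.
* **Immunoblot densitometry**: baseline-subtracted band quantification
  from lane profiles, loading-control and 37 °C-reference normalization,
  one-way ANOVA with Tukey HSD, and solubility-fractionation
  (whole/supernatant/pellet) time-course comparisons.

Because no raw images or blots are deposited for this kind of study, the
package ships seeded synthetic-data generators with known ground truth for
all three assays (`gen_image_dataset()`, `gen_colony_counts()`,
`gen_blot_table()`); every analysis function is exercised against that
truth in the test suite.

## Worked example

Simulate a clonogenic experiment over the thermal-dose design grid, fit a
survival curve, and ask whether the 42 °C durations need separate curves:

```r
library(thermhr)
library(dplyr)

obs <- gen_colony_counts(survival_gen_config(seed = 2))
sf  <- surviving_fraction(obs)

fit <- fit_lq(filter(sf, temperature_C == 40, duration_min == 60))
fit
#> Linear-quadratic fit: alpha = 0.3563 /Gy, beta = 0.01854 /Gy^2 (n = 12, rss = 0.1863, df = 9)
tidy(fit)
#> # A tibble: 2 × 5
#>   term  estimate std.error conf.low conf.high
#> 1 alpha   0.356     0.0650  0.209      0.503
#> 2 beta    0.0185    0.0104 -0.00495    0.0420
```

The generator's default truth is `α = 0.3 /Gy`, `β = 0.03 /Gy²`; both fall
inside the intervals. The same generator uses identical survival parameters
for every duration, so the curve comparison correctly keeps one curve:

```r
compare_curves(filter(sf, temperature_C == 42),
               group = "duration_min", x = "dose_Gy", y = "sf", model = "lq")
#> Extra-sum-of-squares comparison (lq model, 4 groups): F(6, 36) = 0.5246, p = 0.7858
#> -> one shared curve explains the data
```

Simulate immunoblots and recover the thermal dose–response of the BRCA2
level (percent of the 37 °C control, mean ± SEM over four cell lines):

```r
bands <- gen_blot_table(blot_gen_config(seed = 2))
normalize_levels(bands) |>
  filter(temperature_C == 43) |>
  group_by(duration_min) |>
  summarise(mean_level = mean(level), sem = sd(level) / sqrt(n()))
#>   duration_min mean_level   sem
#> 1            0      100    0
#> 2           15       53.7 10.1
#> 3           30       40.6  4.03
#> 4           60       23.0  4.41
```

The generator truth at 43 °C/60 min is 22%: heat-induced BRCA2 degradation
deepens with treatment time, and an hour at 43 °C leaves less than a
quarter of the protein.

`run_pipeline(run_config(...))` chains synthetic-data generation, the
focus pipeline, survival analytics and blot statistics into one seeded,
fully reproducible run that writes all result tables under one directory.

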