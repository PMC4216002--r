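# lungtrack

Stochastic tracking of mucus obstruction in branching airway trees, for
researchers modeling cystic fibrosis (CF) and other obstructive lung
disease. Clinical monitoring sees a CF lung through two keyholes:
spirometry — FEV1 (the volume forcibly exhaled in one second) and FVC (the
forced vital capacity) — and occasional MRI/CT imaging that localizes
mucus "pockets" at ~1 cm resolution. One centimeter voxel, however, hides
the last ten generations of the bronchial tree. `lungtrack` estimates that
hidden micro-distribution of mucus, and forecasts its spirometric
consequences, by Metropolis–Hastings sampling over the space of mucus
configurations consistent with the measurements.

## The model in brief

* **Airway tree** — a complete symmetric binary (Weibel-type) tree over
  generations 0–23 with fractal geometry: diameter and length scale by
  $2^{-1/3}$ per generation from a 1.8 cm × 12 cm trachea. Each imaging
  voxel is one generation-13 subtree (10 bifurcations, 1024 terminal
  bronchioles). Mucus is quantized in units of the smallest bronchiole's
  lumen volume.
* **Flow** — per-segment Poiseuille resistance with an annular mucus
  lining, $R = R_0/(1-f)^2$ for fill fraction $f$; series/parallel
  recursion over the tree; AA% = percent of alveolar-level segments not
  sealed off. FVC scales with AA% (anchored to NHANES III reference
  values); FEV1 follows one-compartment emptying calibrated so a healthy
  lung has FEV1/FVC = 0.8.
* **Sampling** — a constant-temperature Metropolis chain whose proposal
  moves one mucus unit between two uniformly drawn segments (an exactly
  symmetric kernel), with energy
  $E = w_1\big(\tfrac{\Delta \mathrm{FEV1}}{\mathrm{FEV1}^*}\big)^2 +
  w_2\big(\tfrac{\Delta \mathrm{FVC}}{\mathrm{FVC}^*}\big)^2$
  (or the analogous per-voxel form on resistance ratio and AA%), accepted
  by the Boltzmann rule $\min(1, e^{-\Delta E/T})$.
* **PDFE-2D** — offline per-mucus-fraction 2D probability tables of
  (airflow resistance ratio, AA%), built once by flat-energy sampling and
  interpolated in real time; the inverse problem and the forecast both run
  against these tables instead of re-simulating subtrees.

The pipeline: `build_pdfe_table()` (offline) → `fit_lung()` /
`fit_lung_spirometry()` (inverse problem) → `drilldown()` (per-generation
mucus inside one voxel) → `grow_mucus()` + `predict_spirometry()`
(forecast). `generate_patient()` produces synthetic patients with known
ground truth so the whole chain is testable without clinical data. See
`vignettes/mucus-tracking.Rmd` for the full methods account.

## Worked example

A reduced lung (64 voxels of 5-level subtrees) keeps everything inside a
minute; the full-scale objects are the same code with other parameters.

```r
library(lungtrack)

lung <- lung_model(n_voxels = 64, voxel_levels = 5)
tab <- build_pdfe_table(lung$voxel_tree, fractions = seq(0, 1, by = 0.1),
                        chain_settings(n_steps = 20000, thin = 10, seed = 42))
pdfe_mode_curve(tab)
#> # A tibble: 11 × 6
#>   fraction blocked resistance_ratio log10_ratio aa_percent density
#>      <dbl> <lgl>              <dbl>       <dbl>      <dbl>   <dbl>
#> 1      0   FALSE               1           0         100     1
#> 2      0.1 FALSE               1.23        0.09       75.5   0.257
#> 3      0.2 FALSE               1.62        0.21       62.5   0.1
#> # i 8 more rows
```

The mode curve is the most probable (resistance ratio, AA%) pair per mucus
fraction: already at 10% mucus the most likely voxel has lost a quarter of
its alveoli and gained 23% resistance.

```r
sp <- generate_patient(lung, n_pockets = 2, seed = 7)
sp
#> <synthetic_patient> 64 voxels, 2 pockets, total mucus 17504.7 mm^3
#>   ground truth FEV1 2.96 L, FVC 3.91 L

fit <- fit_lung(sp$voxels, sp$patient, tab, lung,
                chain_settings(n_steps = 30000, thin = 10,
                               temperature = 5e-4, seed = 5))
glance(fit)
#> # A tibble: 1 × 9
#>   mode    n_retained acceptance_rate  min_energy fev1_best fvc_best fev1_target
#>   <chr>        <int>           <dbl>       <dbl>     <dbl>    <dbl>       <dbl>
#> 1 imaging       2700           0.943 0.000000102      2.96     3.91        2.96
```

The chain recovers the forward-simulated spirometry (best retained sample
2.96 / 3.91 L against targets 2.96 / 3.91 L; `min_energy` ~1e-7 means ~0.03%
relative mismatch). Drilling into the first pocket voxel gives its
per-generation mucus distribution (normalized mucus = a generation's share
of the voxel's mucus over its share of the voxel's air; 1 = proportional):

```r
pocket <- which(sp$voxels$mucus_mm3 > 0)[1]
drilldown(fit, pocket, chain_settings(n_steps = 10000, thin = 10,
                                      temperature = 5e-4, seed = 3))
#> # A tibble: 5 × 5
#>   generation mucus_mm3 sd_mm3 air_mm3 normalized
#> 1          6     155.   112.     477.      0.962
#> 2          7      56.0   44.0    477.      0.348
#> 3          8     157.    42.4    477.      0.977
#> 4          9     227.    61.6    477.      1.41
#> 5         10     210.    64.6    477.      1.31
```

Finally, forecast spirometry two years ahead under a 150 mm³/year pocket
growth rate:

```r
grown <- grow_mucus(sp$voxels, lung, rate_mm3_yr = 150, horizon_yr = 2)
predict_spirometry(grown, tab, lung, sp$patient, n_draws = 500, seed = 11)
#> <spiro_forecast> 500 draws
#>   mean FEV1 1.94 L, mean FVC 2.83 L (healthy FVC 5.08 L)
```

The patient's FEV1 is predicted to fall from 2.96 L to about 1.9 L.

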