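# cardiatlas

Automated left-ventricular (LV) phenotyping from 3D cine cardiac MR, and the
statistical machinery to plan wall-thickness studies with it.

Regional myocardial hypertrophy is poorly captured by a single global LV
mass number, but mapping wall thickness point-by-point across a population
requires (i) automatic segmentation of many hearts, (ii) anatomical
correspondence so that "point j" means the same place in every subject, and
(iii) honest per-point power calculations that respect the multiple-testing
burden. `cardiatlas` implements that chain for high-resolution (thin-slice)
versus conventional thick-slice short-axis imaging:

* **Synthetic phantoms** — truncated-ellipsoid LV shells with b-SSFP-like
  contrast, Gaussian noise, seeded shape/pose variation and *analytic*
  ground truth (cavity volume, myocardial volume, wall thickness at any
  surface point), so every downstream stage is testable without scans.
* **Multi-atlas patch-based segmentation** — each target voxel is labelled
  by a weighted vote of similar image patches from a pool of labelled
  atlases, after landmark-based similarity alignment. The candidate weight
  is `exp(-SSD/(h²n))·exp(-|offset|²/s²)`.
* **Surface mapping** — isosurface extraction of the endo- and epicardium,
  a mean-shape template with a fixed point count `P`, ICP-projected
  correspondence, and wall thickness measured along the midwall normal.
* **Evaluation & reliability** — Dice overlap, point-to-surface distances,
  contrast ratio `CR = (SI₁−SI₂)/√(SD₁²+SD₂²)`, Bland-Altman agreement and
  ICC(2,1) (two-way random, absolute agreement).
* **Power mapping** — the per-point sample size needed to detect a wall
  thickness change δ at point j with power p and familywise level α over P
  points:

  ```
  N_j = 2 f(α/P, p) σ²_j / δ²,   f(γ, p) = (u_γ + u_{2(1−p)})²
  ```

  where `σ²_j` is the variance of paired test-retest thickness differences
  at point j and `u_γ` the two-sided standard-normal critical value. With
  α = 0.05, p = 0.9 and P = 16386, `f = 35.3892` and `N_j = 70.7784·σ²_j`.
  Voxelwise 2D-vs-3D comparisons use the paired Wilcoxon signed-rank test,
  mapped as −ln(p) with Bonferroni threshold `−ln(α/P) ≈ 12.70`.

## Worked example

```r
library(cardiatlas)

# an atlas pool, a correspondence template, and one test-retest subject
base <- phantom_spec()                      # 25x25x45 mm endo, 8 mm wall
pool <- generate_atlas_pool(base, 3, shape_variation_sd = 1.5,
                            rng_seed = 11, spacing = c(1.8, 1.8, 2))
tmpl <- build_template(pool, template_spacing = c(3.5, 3.5, 3.5))
tmpl
#> <template_model> P = 3294 correspondence points

pair <- generate_retest_pair(base, rng_seed = 5, spacing = c(1.8, 1.8, 2))
surf <- extract_surfaces(pair$acq1$labels)
reg  <- register_template(tmpl, surf$endo, surf$epi,
                          target_landmarks = pair$acq1$landmarks)
tm   <- measure_thickness(reg$endo, reg$epi, subject_id = "s1")
tm
#> <thickness_map> 3294 points, mean 7.9 mm (subject s1, acquisition NA)
```

The mean recovered thickness (7.9 mm) sits within ~1% of the phantom's
8 mm prescription; per-point values feed `difference_field()` →
`sample_size_map()` → `percent_reduction()` to reproduce the thin-slice
power advantage:

```r
power_constant(0.05, 0.9, 16386)
#> [1] 35.3892
set.seed(1)
glance(sample_size_map(difference_field(matrix(rnorm(20 * 100, 0, 1), 20), modality = "3D")))[, 1:3]
#> # A tibble: 1 x 3
#>   median_n q25_n q75_n
#> 1     45.4  38.0  59.3
# (median N = 2 f(a/P, p) x median per-point variance; with P = 16386
#  points the factor is 70.78 per unit variance)
```

A thin CLI over the same functions lives at `inst/cli/cardiatlas.R`
(`phantom | segment | thickness | evaluate | reliability | power | run`).

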