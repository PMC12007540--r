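# tractlife

White matter pathways change over the whole human lifespan: they grow
rapidly in infancy, mature through adolescence, plateau in adulthood and
decline in aging. `tractlife` is an R package for the post-processing side
of such studies. Starting from streamline tractograms (TRK/TCK) and scalar
maps (NIfTI) produced by upstream tools, it derives per-bundle features,
stitches multi-cohort data into continuous lifespan trajectories, and asks
how features, pathways and life phases relate to one another. It is aimed
at neuroimaging researchers analysing bundle-level measures across wide
age ranges — and, because restricted multi-site data cannot ship with
code, every stage is exercised end-to-end on synthetic inputs with known
ground truth.

## What it computes

**Bundle features.** The ten macrostructural shape metrics of a bundle —
volume, endpoint volume, length, span, curl, diameter, elongation, total
and head/tail surface areas — from streamline geometry and voxel
occupancy, where curl = length/span (1 for a straight bundle), diameter
treats the bundle as a cylinder (d = 2√(V/πL)) and elongation = L/d. Plus
tract-averaged microstructure (FA, MD, NODDI scalars, ...) and cortical
features probed at streamline endpoints.

**Lifespan trajectories.** Each (pathway, feature) is modelled by
covariate-adjusted restricted cubic spline regression (C-RCS):

y = β₀ + β₁·age + Σⱼ γⱼ sⱼ(age) + δ·sex + ε,

with knots at 2, 4, 22, 35, 75 and 90 years and the standard restricted
basis (linear beyond the boundary knots). A case-resampling bootstrap
gives percentile bands, peak/minimum ages with 95% intervals, and
cohort-averaged cross-sectional rates (difference per year, percent
difference per year) over the infant (0–5), development (5–21), young
adult (22–35) and aging (36+) windows. A continuity-based adjustment
removes the between-cohort acquisition offset that age-overlap-based
harmonization methods cannot handle.

**Associations.** Cross-feature correlation matrices (plain and partial,
controlling age and sex), cross-pathway correlations of per-year rates,
the development-versus-aging "gain predicts loss" test, and
anterior-posterior gradient regressions — all with Benjamini–Hochberg FDR
control at 0.05.

## Worked example

```r
library(tractlife)

# A solid synthetic cylinder (r = 5 mm, L = 100 mm) on a 0.5 mm grid
g <- reference_grid(diag(c(0.5, 0.5, 0.5, 1)) +
                      cbind(matrix(0, 4, 3), c(-2, -7, -7, 0)),
                    c(220, 56, 56))
cyl <- make_bundle("cylinder_fill", params = list(radius = 5, length = 100),
                   grid = g, seed = 1)
compute_shape_features(cyl)
#> Bundle shape features:
#>   volume_mm3             7965
#>   endpoint_volume_mm3    79.25
#>   length_mm              100
#>   span_mm                100
#>   curl                   1
#>   diameter_mm            10.07
#>   elongation             9.93
#>   surface_area_mm2       4380
#>   head_surface_area_mm2  179.5
#>   tail_surface_area_mm2  179.5
```

The analytic volume is πr²L ≈ 7854 mm³; the voxel count lands within 2%,
and diameter/elongation within 1% of the true 10. Next, a four-cohort
lifespan table with a known bump trajectory, a +0.5 acquisition offset in
the young-adult cohort, and noise:

```r
sim <- simulate_lifespan_table(
  trajectory_spec("peaked_bump",
                  list(baseline = 1, amplitude = 1, peak_age = 25, width = 18),
                  noise_sd = 0.2, cohort_offsets = c(young_adult = 0.5),
                  n_per_cohort = 700),
  pathways = "AF_left", features = "FA", seed = 7)

off <- estimate_offsets(sim$table)      # continuity-based harmonization
subset(off, cohort == "young_adult")
#>   pathway feature      cohort    offset     mode
#> 3 AF_left      FA young_adult 0.5354627 additive

fit <- bootstrap_fit(apply_offsets(sim$table, off), "AF_left", "FA",
                     B = 500, seed = 7)
find_extremum(fit, "max")
#> peak at age 23.5 years (95% CI 23.1-23.9)
cohort_mean_rate(fit)
#>   pathway feature      cohort diff_per_year pct_diff_per_year
#> 1 AF_left      FA      infant    0.02681428         1.8079250
#> 2 AF_left      FA development    0.02691119         1.5459845
#> 3 AF_left      FA young_adult   -0.01311773        -0.6954570
#> 4 AF_left      FA       aging   -0.01168708        -0.8418241
```

The injected 0.5 offset is recovered to 0.035; the feature rises through
development and declines after the young-adult window, and the fitted
peak sits near (slightly before) the generating bump's peak — the
out-of-span bump's maximum is displaced by the spline approximation, a
point discussed in the vignette. `plot(fit)` draws the data, curve and
bootstrap band; `summary(fit)`, `coef(fit)`, `predict(fit)`,
`residuals(fit)` and `simulate(fit)` behave like any R model object.
`run_pipeline()` chains every stage (simulate → harmonize → fit →
summarize → correlate) deterministically from one seed and writes CSVs
plus a JSON manifest.

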