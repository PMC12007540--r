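---
title: "Modelling white matter bundle features across the lifespan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling white matter bundle features across the lifespan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tractlife)
```

## The problem

Diffusion MRI tractography reconstructs white matter pathways as bundles of
streamlines. Across a lifespan cohort (ages 0 to 100), each bundle can be
described by three families of features: *microstructure* (DTI scalars such
as FA and MD, NODDI scalars such as ICVF, averaged over the voxels the
bundle occupies), *macrostructure* (ten shape metrics derived from
streamline geometry and voxel occupancy), and *connected cortex* (cortical
measures probed at streamline endpoints). `tractlife` implements the
post-segmentation stages of such an analysis: feature extraction from
tractograms and scalar maps, cross-cohort harmonization, spline-based
trajectory modelling with bootstrap inference, and the correlation analyses
that relate features, pathways, and life phases to each other. Bundle
segmentation, diffusion model fitting and surface reconstruction are
upstream tools whose outputs this package consumes.

## Coordinate conventions

All streamlines live in world RAS millimetres. Voxel indices are 0-based
and voxel centers sit at integer voxel coordinates, so a world point maps
to the voxel `floor(v + 0.5)` of its continuous voxel coordinate `v`; the
same rule is shared by voxelization, map sampling and endpoint probing.
TRK files store voxel-scaled coordinates with a half-voxel corner offset;
they are converted to world mm at load so every downstream computation
sees one convention.

## The ten shape metrics

For a bundle with streamlines \(s_1,\dots,s_m\):

* **length** is the mean streamline arc length, **span** the mean distance
  between each streamline's endpoints, and **curl** = length / span
  (1 for a straight bundle, growing with curvature).
* **volume** is the count of voxels visited by any resampled streamline
  point times the voxel volume. Streamlines are resampled to a step of
  0.2 times the smallest voxel size first, so no crossed voxel is skipped
  at realistic curvature; halving the step changes the cylinder fixture's
  count by well under half a percent.
* **diameter** treats the bundle as a cylinder,
  \(d = 2\sqrt{V/(\pi L)}\), and **elongation** is \(L/d\).
* **surface area** counts exposed voxel faces under 6-connectivity (a face
  is exposed when its neighbour is unset or outside the grid), weighting
  each face by the two voxel sizes that span it.
* **endpoint volume** and the **head/tail surface areas** use the voxels
  containing streamline first/last points after a consistent
  reorientation; the head is the end whose centroid is lower on the axis
  of largest head-tail separation (more left, posterior or inferior in
  RAS), with ties broken in x, y, z order.

Because span is described in the field simply as the distance between a
bundle's two ends, both readings are available: the default is the mean
per-streamline endpoint distance, and `span_mode = "centroid"` instead
uses the distance between the head and tail centroids. Endpoint volume
uses the union of the head and tail masks where they overlap.

## Sampling microstructure and cortex

Tract averages are plain unweighted means over occupied voxels — no
streamline-density weighting — with missing-coded voxels ignored.
Cortical features are probed at both endpoints of every streamline,
averaged within a streamline (a missing end is dropped) and then across
streamlines. Endpoint lookup is nearest-voxel with a 2 mm fallback to the
nearest valid voxel, because termini often sit at the white/gray
interface just off the voxelized ribbon; the fallback choice is ours, is
deterministic, and radius 0 disables it. Pathways with no cortical
endpoint coverage propagate `NA` rather than erroring, since several
mid-brain pathways have no associated cortex.

## Cross-cohort harmonization by continuity

Lifespan studies stitched from several acquisition protocols show a step
offset in one cohort (typically the young adults, scanned at different
resolution). Covariate-matched harmonization methods need overlapping
ages between batches, which lifespan cohorts do not have. We therefore
rely on the continuity of biological trajectories: fit the age model to
the reference cohorts only, predict at the target cohort's ages, and take
the mean observed-minus-predicted residual (or the mean ratio in
multiplicative mode) as a constant offset — an acquisition effect, not a
biological one, hence constant in age. The estimate is refused when the
target's age range is not bracketed by at least 20 reference observations
per side, because the reference fit would extrapolate. On simulated data
with a known injected offset of 0.5 at 1000 sessions per cohort and noise
SD 0.2, the estimate lands within 0.05 and the residual discontinuity
after correction is below 0.05 (see the test suite); the residual bias is
the spline's interpolation error across the covariate gap, which shrinks
as the true trajectory approaches the spline span.

## The C-RCS trajectory model

Each (pathway, feature) is modelled by ordinary least squares on a
restricted cubic spline in age plus covariates:

\[
y = \beta_0 + \beta_1\,\mathrm{age} + \sum_{j=1}^{k-2}\gamma_j s_j(\mathrm{age})
  + \delta^\top z + \varepsilon,
\]

where the \(s_j\) form the standard restricted truncated-power basis,
linear beyond the boundary knots, normalised by \((t_k-t_1)^2\) for
conditioning (this rescales coefficients, never the curve). Default knots
are 2, 4, 22, 35, 75 and 90 years — placed at expected developmental
shifts in brain volumetry, five to six knots being the usual compromise
between flexibility and overfitting — and the default covariate is sex.
Quadratic fits constrain the two sides of a peak to be mirror images and
Poisson-style growth curves still miss the strongly nonlinear infant
period, which is why the spline family is used. Predictions are reported
at the covariate reference (sex averaged over the fitted sample).

Uncertainty comes from a case-resampling bootstrap over sessions (the
production default is 10000 replicates; tests use a few hundred with
fixed seeds, and every replicate set is reproducible from its seed).
Sessions are resampled as independent rows, mirroring a cross-sectional
treatment of the data — repeated sessions of one infant are treated as
independent, a deliberate simplification. From a fit we derive:

* the **difference per year** — the analytic first derivative of the
  fitted curve, a cross-sectional rate, not a longitudinal one (a
  one-year central difference mode is available and agrees to first
  order);
* the **percent difference per year** — 100 × derivative / fitted value,
  which errors when the fitted value is numerically zero;
* **peak/minimum ages** by dense 0.1-year grid search, with 2.5/97.5
  bootstrap percentiles of the replicate extremum ages as the 95%
  interval and a `boundary` flag when the extremum sits at the range
  edge;
* **cohort-averaged rates** over integer ages in the four windows:
  infant 0–5, development 5–21, young adult 22–35, aging 36 up to the
  fitted maximum.

## Correlation analyses

Three questions, all with Pearson correlation (the linear correlation
coefficient; Spearman is an option) and Benjamini–Hochberg FDR at 0.05:

1. *Across sessions*: which features covary within a pathway, with and
   without partialling out age and sex (residualise both features on the
   covariates, correlate the residuals, t-test on
   \(n - 2 - \#\mathrm{covariates}\) degrees of freedom)?
2. *Across pathways*: do pathways with steep rates in one feature have
   steep rates in another (per-cohort rate vectors across pathways)?
3. *Development versus aging*: does the per-pathway developmental rate of
   a feature predict its aging rate ("gain predicts loss")?

The FDR family is per correlation matrix (its upper triangle), and per
feature set for the gain-loss test; missing data are handled
pairwise-complete with n reported per pair. Anterior-posterior gradients
regress per-pathway rates on the bundle centroid's y coordinate in
standard space with both a linear and a quadratic model; both models'
coefficients and p values are reported since either trend may be of
interest.

## What the synthetic generators emulate

All tests and the demo pipeline run on synthetic data carrying its own
ground truth:

* `make_bundle()` builds straight, arc, helix and filled-cylinder bundles
  with analytic length, span and curl attached. The cylinder is filled on
  a deterministic square cross-section lattice (default 0.5 mm) rather
  than by random disk sampling, so digitised volume converges to
  \(\pi r^2 L\) without coupon-collector gaps; align the lattice with
  voxel centers for the cleanest convergence.
* `make_scalar_volume()` evaluates constant, linear-gradient and
  two-region fields at voxel centers.
* `simulate_lifespan_table()` draws ages uniformly within each cohort
  window (true lifespan age distributions are not uniform; this is a
  deliberate simplification, and densities are configurable), applies a
  smooth trajectory, a sex shift, a per-cohort acquisition offset and
  Gaussian noise. The default of 700 sessions per cohort (~2800 total)
  matches the scale of a large four-cohort lifespan study. Trajectory
  forms include curves lying exactly in the spline span — used whenever a
  test must separate estimator error from approximation error — plus
  Gaussian bumps and piecewise-linear slopes that do not, which probe the
  approximation itself.
* `simulate_pathway_slopes()` draws per-pathway (development, aging) rate
  pairs from a multivariate normal with chosen cross-cohort correlation
  \(\rho\) and optional between-feature correlation; 63 pathways by
  default, a whole-brain pathway set.

What passing these tests does *not* show: the generators contain no
tractography failure modes (spurious or truncated streamlines), no
heteroscedastic or age-dependent noise, no non-uniform age sampling, and
no real acquisition physics — performance on real multi-site data can be
worse in all of those directions.

## Numerical and design choices

* Peak-location checks use an in-span inverted-U whose exact maximum is
  at age 25: for a truth outside the spline span the fitted curve's peak
  is systematically displaced (for a Gaussian bump of width 15 the
  displacement is about 1.6 years with the default knots), and the
  bootstrap interval correctly tracks the fitted model's peak rather than
  the out-of-span function's. The same consideration applies to any real
  feature: peak ages are peaks of the fitted spline.
* Bootstrap band calibration is checked over 200 simulated datasets of
  n = 400 with 500 replicates each — enough for the Monte-Carlo error of
  the empirical coverage to be about 1.5 percentage points while keeping
  the whole check under half a minute on one CPU; observed coverage sits
  a point or two below the nominal 95%, the usual mild undercoverage of
  percentile intervals at moderate n.
* Degenerate inputs error early and descriptively: empty bundles,
  closed-loop streamlines (span 0, curl undefined, the offending
  streamline is named), points outside the grid at voxelization time,
  rank-deficient designs, unbracketed harmonization targets, p values
  outside [0, 1].
* Ties in the head/tail axis choice are broken x before y before z;
  which.max makes this deterministic.
* All generators restore the caller's RNG state; every random operation
  takes an explicit seed, and the pipeline derives stage seeds from one
  root seed so a run is reproducible byte for byte.

## Known limitations

Bundle volumes are voxel counts, so they carry digitisation bias of order
(surface area × voxel size); surface areas are exposed-face counts, which
overestimate smooth-surface area (a cylinder's digitised lateral surface
approaches 4/π times the true value as voxels shrink) — both match the
definitions in common use for these descriptors, and comparisons across
subjects on a fixed grid are unaffected. Harmonization assumes the offset
is constant in age and that the underlying trajectory is smooth through
the covariate gap. The bootstrap treats sessions as independent. None of
the analyses here are longitudinal: every rate is a cross-sectional
association with age.
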