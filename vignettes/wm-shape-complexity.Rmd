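---
title: "Quantifying white-matter shape complexity by 3D box-counting fractal dimension"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying white-matter shape complexity by 3D box-counting fractal dimension}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wmfractal)
```

## The measurement

Degenerative disease changes not only how much white matter (WM) a brain
has, but how intricately it is shaped. `wmfractal` quantifies that shape
with the box-counting fractal dimension (FD). Given a voxel set, cover
it with meshes of cubic cells of edge $r$ and count the occupied cells
$N(r)$. For a set with power-law scaling $N(r) \propto r^{-\mathrm{FD}}$,
so an ordinary least-squares fit of

$$\log N(r) = -\,\mathrm{FD}\,\log r + k$$

over the self-similar range of $r$ estimates FD; the intercept $k$ is a
nuisance parameter. FD is dimensionless: a filled volume approaches 3, a
smooth sheet 2, a curve 1, and WM structures land in between, higher
values meaning more space-filling complexity.

The pipeline evaluates FD for three shape representations of a WM
segmentation, each probing a different aspect of morphometry:

* **general structure** — all WM voxels; volume-like complexity;
* **surface** — WM voxels with a face-adjacent background neighbor, the
  WM/GM interface; gyral/sulcal boundary shape;
* **skeleton** — the one-voxel-wide medial line set left by
  topology-preserving 3D thinning; the interior fiber-network
  complexity (bundle crossings, bifurcations).

Each representation is computed for the whole brain and, after a
midline split, for the left and right hemispheres, giving nine FD
outcomes per subject (`fdOutcomeNames()`).

## Subject-level processing and its assumptions

Input is a WM probability map (values in $[0,1]$, NIfTI), the typical
product of tissue segmentation. Processing assumes cubic voxels; the
`resampleIsotropic()` step (trilinear, default target 1 mm, matching
typical T1 slice thickness) is available for anisotropic inputs and is
off by default because near-isotropic acquisitions are common. Linear
interpolation is used rather than nearest-neighbor because binarization
happens *after* resampling and linear interpolation preserves the 0.5
level set far better.

Binarization uses threshold 0.5 with the inclusive convention
$p \ge 0.5$, so plateau values behave deterministically. The whole-brain
mask is skeletonized *before* hemisphere splitting, and hemisphere
skeletons/surfaces are restrictions of the whole-brain sets; splitting
first would create artificial cut faces that inflate both the surface
and the skeleton near the midline.

### Thinning

The skeleton is produced by six-directional thinning with sequential
simple-point deletion. A foreground voxel (26-connectivity) is *simple*
when its deletion changes no topology, characterized by two local
numbers: exactly one 26-connected foreground component in its
3×3×3 neighborhood, and exactly one 6-connected background component in
its 18-neighborhood touching a face neighbor. Each pass visits the six
border directions in a fixed order (−x, +x, −y, +y, −z, +z) and deletes
candidates sequentially in raster order, re-checking simplicity at
deletion time; curve endpoints (voxels with a single foreground
neighbor) are protected. Consequences, asserted by the test suite on a
randomized phantom suite: the skeleton is a subset of the input,
thinning is idempotent, 26-component counts and Euler characteristic
are preserved, and no 2×2×2 solid block survives. The fixed order makes
results bit-reproducible; its price is that the skeleton of a perfectly
mirror-symmetric object need not be perfectly mirror-symmetric, which
is irrelevant at the scale of FD estimation.

### Hemisphere midline

With `midline = "auto"` the cut plane is searched over the central 20%
of the left–right axis (restricting the search avoids degenerate cuts
on skewed masks) and placed where the number of foreground voxel pairs
straddling the plane is minimal — in a brain-like mask, the
interhemispheric fissure. Ties resolve toward the grid center, then the
smaller index. The left piece takes the slices up to the cut, so the
two pieces always partition the input exactly.

## Box counting choices

* **Scale ladder.** Geometric ladders are standard; the default adapts
  the base to the lattice. If the largest grid dimension is an exact
  power of 3, scales are $3^0,3^1,\dots$ up to the full dimension: every
  mesh tiles the grid exactly, which is the natural ladder for triadic
  constructions such as the Menger sponge (a powers-of-2 ladder on a
  $27^3$ sponge is lattice-mismatched and underestimates FD by roughly
  0.24 — a genuine finite-size artifact, not an estimator bug).
  Otherwise the grid is padded to the next power of 2 and scales run
  from 1 to half the padded dimension, giving at least five points on
  inputs of $128^3$ and above.
* **Offsets.** `nOffsets = 1` (the zero offset) by default, for exact
  integer counts and bit-reproducibility. Optional deterministic
  offsets (corners of the $r$-cell) average out grid-placement bias.
* **Scaling window.** The self-similar range is selected by scanning
  all contiguous windows of at least `minPoints = 4` scales and keeping
  the one with the highest $R^2$, subject to $R^2 \ge 0.98$; ties go to
  the wider window, then the smaller $r_{\min}$. Degenerate inputs that
  reach the floor nowhere are an error, deliberately loud. Flat curves
  (a single occupied cell at every scale) have zero total variance and
  are treated as perfect fits with slope 0.
* **Regression.** Unweighted OLS on $(\log r, \log N)$. The fit is
  exact to machine precision on collinear input; a positive slope is
  impossible for a valid curve and raises an error rather than being
  clamped. FD is reported as the slope magnitude with its window,
  $R^2$, and point count, so every estimate is auditable.

Finite-size behavior worth knowing: a voxelized solid ball of radius 60
on a $128^3$ grid reads FD ≈ 2.87 rather than 3, because boundary cells
inflate counts at coarse scales; at radius 120 on $256^3$ the estimate
is within 0.1 of 3. The analytic-recovery tests therefore use exact
tilings (cube, plane, line, sponge) at modest sizes and push smooth
curved bodies to $256^3$.

## Cohort statistics

The nine FD outcomes are compared across five clinical groups
(neurological controls and four ALS phenotypes: with frontotemporal
dementia, with and without corticospinal-tract hyperintensity, and
classic) with a linear mixed-effects model fitted by REML:

$$\mathrm{FD}_{ij} = \beta_0 + \beta_1\,\mathrm{age}_{ij} +
\gamma_{g(i,j)} + u_{\mathrm{gender}(i)} + \varepsilon_{ij},
\qquad u \sim N(0, \sigma_u^2).$$

Age is a fixed covariate because FD declines with age and group ages
differ; gender enters as a random intercept to absorb heterogeneity.
With only two gender levels the variance estimate routinely lands on
the boundary $\hat\sigma_u^2 = 0$; the implementation reports the
boundary fit (in which case fixed effects coincide with OLS — a tested
limit) instead of failing. Marginal age and group tests are
Satterthwaite type-III F tests; covariate-adjusted group means are
estimated marginal means at the covariate grand mean; all pairwise
contrasts use the Tukey HSD adjustment on the model's error degrees of
freedom. A sensitivity variant re-fits on patients only with ALSFRS-R
(the revised ALS functional rating scale, 0–48, lower = worse) as an
additional fixed covariate.

Supporting procedures: outlier screening by externally studentized
residual > 3 or leverage > $3p/n$ in the fixed-effects design
(deterministic, reported, remove-and-refit is the caller's choice);
Spearman rank correlations of each FD outcome with ALSFRS-R,
log-duration and log-progression-rate, with Benjamini–Hochberg control
across the nine outcomes per clinical measure; Kruskal–Wallis
comparison across El Escorial diagnostic-certainty strata (encoded
1–4) with Bonferroni-adjusted pairwise rank tests. The progression
rate is $(48 - \mathrm{ALSFRS\text{-}R})/\mathrm{duration}$ in points
per month, the standard construction in the ALS literature; duration
and rate are natural-log transformed before parametric use, with
non-positive values excluded per subject rather than fudged.

## What the synthetic generators emulate

Because clinical scans cannot ship with a package, every stage is
exercised on synthetic inputs whose ground truth is known.

**Phantoms** (`makePhantom()`): Menger sponges
($\mathrm{FD} = \log 20/\log 3 \approx 2.7268$), fractal percolation
(subdivision 2, retention $p$, FD $= 3 + \log_2 p$, conditioned on
survival), solid blocks (3), sheets (2), lines (1), rods, tori, and a
branching tube tree (`makeWMTreePhantom()`) that emulates the gross
geometry of a WM probability map: connected, tubular, bilaterally
lobed with randomized branch angles. `phantomProbability()` converts
any binary phantom into a segmentation-like map (mild blur plus
bounded noise) constructed so that binarization at 0.5 recovers the
phantom exactly.

**Cohorts** (`makeCohort()`): one row per subject under exactly the
structural model the mixed model assumes — group mean plus a linear age
effect ($-0.0005$ FD/yr by default, the order of magnitude reported in
WM aging studies), a gender-specific effect (SD 0.005, small relative
to residual SDs of 0.013–0.054), and Gaussian noise. Default group
sizes (11/20/20/24/22), per-group age distributions, gender ratios,
ALSFRS-R moments, duration medians/quartiles (matched by a log-normal,
consistent with the field's practice of log-transforming duration), EES
frequencies, and all 45 FD means/SDs are embedded as a versioned
constants table (`referenceCohortParams()`) encoding a published ALS
morphometry cohort's reported values; they are the generating
conditions, not tuning knobs. ALSFRS-R is coupled to whole-brain
skeleton FD through a Gaussian copula whose latent correlation
$2\sin(\pi\rho_s/6)$ yields a requested Spearman $\rho_s$ (default
0.431). Each component draws from a named seed substream, so adding a
generator never perturbs existing streams.

What the generators deliberately do **not** emulate: MRI physics (bias
fields, Rician noise), partial-volume effects, registration error,
cortical folding geometry, or longitudinal structure. Passing tests
therefore demonstrate correctness of the algorithms and calibration of
the statistics under the assumed generating model — not robustness to
scanner artifacts.

## Problem sizes and verification

The test suite (and the bundled `scripts/acceptance.R`) verifies, among
other properties: exact equality of `boxCount()` with a brute-force
cell scan on 50 random masks up to $32^3$; machine-precision slope
recovery on collinear curves; analytic FD recovery within 0.05 for the
level-3 sponge, a $64^3$ cube, a sheet and a line; the thinning
contract on a 50-seed phantom suite; mean percolation FD within 0.15 of
$3+\log_2 p$ over 30 seeds at $p \in \{0.6, 0.8\}$; null calibration of
the group test (rejection rate in $[0.03, 0.07]$ at $\alpha = 0.05$)
and of the Tukey family (FWER $\le 0.07$) over 500 simulated cohorts;
recovery of the generating age slope within 20%; and at five groups of
$n = 20$ with the embedded whole-brain skeleton parameters
(ALS-FTD $2.469 \pm 0.020$ vs ALS-CST+ $2.501 \pm 0.024$), a
significant Tukey-adjusted FTD vs CST+ contrast in well over 90% of 200
replicates. These sizes keep the full suite under a few minutes on one
CPU while leaving the Monte-Carlo standard errors small relative to the
asserted bands.

## Known limitations

* Box counting on voxel data underestimates the dimension of smooth
  curved bodies at small grid sizes (boundary-cell inflation at coarse
  scales); estimates are comparable across subjects processed at the
  same resolution, which is what the group analysis uses.
* The thinning's fixed subiteration order trades exact mirror symmetry
  for bit-reproducibility.
* The auto-midline is a planar cut; strongly curved interhemispheric
  geometry would need an explicit midline or a pre-computed hemisphere
  labeling.
* The gender random effect has two levels; its variance is weakly
  identified and often estimated at the boundary. This mirrors the
  modeling choice it reproduces and is reported, not hidden.
* FD reference values for the simulated cohorts come from one published
  cohort; they parameterize the generator and say nothing about other
  populations or scanners.
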