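---
title: "Radial-distance shape morphometry from manual contour stacks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radial-distance shape morphometry from manual contour stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hippomorph)
```

## The problem and the model

Manual delineation of an elongated subcortical structure — here the
hippocampus — produces, per subject and hemisphere, an ordered stack of
closed planar contours traced on coronal slices. Two questions are asked
of such data: *is the structure smaller overall* (volumetry), and *where
on its surface is it deformed* (shape analysis). hippomorph implements
both ends of that pipeline and a synthetic-cohort generator that makes
every stage testable without imaging data.

**Volumetry.** The planimetric estimator sums the traced cross-sectional
areas (shoelace formula on the polygon vertices) times the slice
thickness:
$$\hat V \;=\; \sum_{i} A_i \,\Delta z .$$
Volumes are adjusted for head size by the covariance method: with
$\alpha$ the OLS slope of volume on total intracranial volume (TIV)
*estimated in controls only*,
$$\mathrm{HV}_{\mathrm{adj}} \;=\; \mathrm{HV} - \alpha\,
  (\mathrm{TIV} - \overline{\mathrm{TIV}}_{\mathrm{controls}}).$$
Two identities pin this down: a subject at the control mean TIV is
unchanged, and the adjusted control volumes have exactly zero residual
slope on TIV. Group differences in adjusted volume are tested with a
fixed-effects linear model (`group + age`), with significance flagged at
a Bonferroni-adjusted $\alpha = 0.025$ (two hemispheres); associations
with clinical scores use Spearman rank correlation.

**Shape.** Each contour stack is interpolated onto a fixed parametric
grid of $C = 100$ circumferential points $\times$ $L = 150$ longitudinal
levels (15{,}000 vertices), giving every subject the same vertex lattice.
A medial curve — the per-level centroid of the equally spaced boundary
points — runs along the anterior–posterior axis, and the *radial
distance* from the medial point to each surface vertex is the dependent
variable of all vertex-wise statistics. At each vertex an ordinary
least-squares model
$$r_{v} \;\sim\; \mathrm{group} + \mathrm{age} + \mathrm{TIV}$$
yields a $t$ statistic for the group contrast (patient $-$ control, so
negative $t$ = inward deformation, i.e. surface shrinkage in patients)
and a two-sided $p$ from the $t_{n-p}$ distribution.

**Multiple comparisons.** Vertices with uncorrected $p$ below the
cluster-forming threshold (default $0.05$, two-sided) form sign-segregated
masks; their connected components under 4-neighbour connectivity with
circumferential wrap are the clusters. Family-wise error is controlled by
permutation of the *maximum cluster size*: each observed cluster of size
$s$ gets
$$p_{\mathrm{corr}} \;=\; \frac{1 + \#\{b : \max_b \ge s\}}{B + 1},$$
which cannot be zero and is monotone in $s$. Threshold-free cluster
enhancement (TFCE) is available as an alternative enhancer,
$\mathrm{TFCE}(v) = \sum_{h} e(h)^{E} h^{H} \,\mathrm{d}h$ with defaults
$E = 0.5$, $H = 2$, $\mathrm{d}h = \max|t|/100$. Note that this integral
is homogeneous of degree $H + 1$ when the map and $\mathrm{d}h$ are
scaled together.

## Assumptions

* Contours arrive rigidly pre-aligned in a common space (registration is
  upstream and out of scope); coordinates are millimetres, slices are
  parallel planes.
* One simple (non-self-intersecting) closed contour per slice; tracing
  direction is arbitrary and normalized to counter-clockwise on read.
* Cross-sections are star-shaped enough that the per-level centroid lies
  inside the contour, making the point-to-medial distance equal to the
  ray distance.

## Correspondence: the part the grid quietly decides

Vertex-wise statistics are only meaningful if vertex $(l, c)$ means the
same anatomical location in every subject. Three choices fix this:

1. **Circumferential origin.** Point 1 of each resampled contour is where
   the ray from the area centroid in the $+x$ direction crosses the
   boundary. The crossing snaps to an existing vertex when it lands
   within `perimeter / (100 C)` of one.
2. **Minimal twist.** Between adjacent slices the origin is re-anchored
   to the cyclic rotation minimizing the summed squared point-to-point
   distance to the previous slice (equivalently, maximizing the circular
   cross-correlation). Without this, arc-length origins drift around the
   tube and create twist artifacts.
3. **Longitudinal registration.** $L$ levels are placed at uniform
   normalized positions along the slice ordering with piecewise-linear
   interpolation between adjacent resampled slices.

Equal-arc resampling itself is solved as a fixed point: the sample is
refined until the points are uniform in the arc length of the polyline
through the samples themselves. The refinement contracts by roughly three
orders of magnitude per pass, so it converges in a handful of iterations
and moves points by far less than tracing precision; in exchange,
resampling an already-resampled contour is exactly idempotent, which
makes correspondence reproducible across runs and tools.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `L`, `C` | 150, 100 | levels, points | longitudinal extent carries more anatomy than the circumference; 15,000 vertices total |
| `min_area` | 0.5 | mm² | freehand tracing produces tiny terminal slices that destabilize resampling; smaller slices are dropped with a warning |
| `cluster_forming_p` | 0.05 | – | two-sided vertex threshold; the cluster statistic is sensitive to it, so it is exposed, not hidden |
| `n_perm` | 10,000 | – | permutation resolution; the seed is mandatory, and tiny cohorts fall back to exhaustive enumeration with a warning |
| scheme | Freedman–Lane | – | permutes reduced-model residuals so age/TIV are respected under the null; plain label permutation available for transparency |
| ROI fractions | 1/3, 1/3, 1/3 | – | head/body/tail boundaries are a convention, not a measurement; configurable |
| TFCE `E`, `H`, `dh` | 0.5, 2, $\max|t|/100$ | – | the standard published parameterization |
| connectivity | 4-neighbour + wrap | – | the grid is a tube; column $C$ is adjacent to column 1; 8-neighbour available |

## The synthetic cohort generator

`generate_cohort()` builds two-group cohorts of hippocampus-like tubes:
a curved medial arc (~40 mm) with an enlarged anterior head bulge and a
mildly elliptical cross-section, radii within 2–8 mm; 40 coronal slices
at 1 mm spacing. Per subject, a log-normal global scale (sd of log scale
0.05, giving realistic volume variability), TIV proportional to
scale³ around 1.5·10⁶ mm³ with 5% multiplicative noise (so TIV is a
genuine, imperfect head-size covariate), group-specific Gaussian age
distributions (patients 62.8 ± 13.0, controls 61.8 ± 5.9 years, sizes
31/29 by default), and clinical scores for patients only. Patients
additionally receive a localized inward deformation: radii inside a patch
defined *in grid coordinates* are multiplied by $1 - \delta$ (default
$\delta = 0.15$ over an anterior-head patch), so ground truth aligns
exactly with analysis space and Dice overlap against recovered clusters
is well defined. Boundary vertices get independent Gaussian radial noise
($\sigma = 0.3$ mm, about a third of a voxel); because the boundary
points sit at sorted angles around the slice center, the noisy polygons
are star-shaped and always simple. All randomness derives from one master
seed: covariates are drawn first, then one sub-seed per subject, so
cohorts are byte-identical across reruns.

`simulate_radial_maps()` is the map-level counterpart (same covariate
stream, deformation and noise applied directly on the grid). It is useful
for quick statistical experiments, but note that white *vertex* noise
produces an extremely discrete null of the maximum cluster size (clusters
of a few vertices), which makes the permutation test markedly
conservative there; the contour-level generator, whose slice-to-level
interpolation induces the longitudinal smoothness real extractions have,
is what the calibration studies use.

**What the generator does not emulate:** anatomically realistic
subfields, correlated tracing error along the boundary (an optional
smoothed-noise mode is a natural extension), rater bias, partial-volume
or segmentation-protocol effects, and any registration error — contours
are generated pre-aligned. Passing tests therefore validate the
*computational pipeline under its stated assumptions*, not robustness to
real-world segmentation variability.

**Attenuation worth knowing about.** The deformation is exact at
construction: deformed boundary radii are exactly $(1-\delta)$ times the
template's. But the *measured* radial-distance deficit is attenuated
(roughly $0.91$ rather than $0.85$ at $\delta = 0.15$ over a 30%-of-
circumference patch), because the medial centroid shifts with the
deformed boundary and equal-arc resampling redistributes points around
the rim. This is a property of centroid-referenced radial distance in
general, not of this implementation; localization (Dice against the true
patch) is unaffected.

## Numerical choices

* Degenerate vertices (zero residual variance) saturate at $t = \pm 10^8$
  for a real effect and exactly 0 for coefficients at rounding level;
  $p$ values are floored at the smallest positive double so $p \in (0, 1]$.
* The permutation engine avoids refitting the GLM per permutation: by the
  Frisch–Waugh–Lovell identity the contrast $t$ needs only the permuted
  residuals' projections onto the residualized regressor and onto an
  orthonormal design basis, which are batched into one matrix product per
  block of permutations (C++/Armadillo). The R-level fit and a naive
  per-permutation `lm()` refit serve as oracles in the tests.
* Permutation indices are drawn in R under the caller's seed and passed
  to C++, so results are reproducible across platforms and the RNG state
  of the session is restored afterwards.
* Ties and discreteness: cluster sizes are integers, so the achievable
  significance levels of the max-cluster test are discrete; with the
  contour-level noise structure the null is spread widely enough that the
  test is close to nominal (see the calibration study below).

## Validation studies (what the tests compute)

* Geometry: a 40-slice cylinder of radius 5 mm reproduces $\pi r^2 h$
  within 1%; the analytic elliptical tube's radius profile is recovered
  within 2% at the default grid; rigid translation leaves radial maps
  unchanged to $10^{-9}$.
* Statistics: vertex $t$ maps match a normal-equations oracle to
  $10^{-8}$; connected components match brute-force DFS labelling on 200
  random wrap grids; TFCE of a single-vertex map equals its hand-summed
  discrete integral (0.385 for height 1, $E=0.5$, $H=2$,
  $\mathrm{d}h=0.1$).
* Calibration: 500 null cohorts (δ = 0, 30/group, σ = 0.3 mm) through
  the full contour pipeline at a reduced 50 × 40 grid with 500
  permutations each; the family-wise false-positive count must lie in the
  central 95% binomial band around 0.05. The reduced grid and permutation
  count keep this study at desk scale while leaving the statistic's
  behaviour intact.
* Recovery: 50 cohorts with the default head patch at δ = 0.15; the
  significant inward cluster must overlap the true patch (Dice ≥ 0.5) in
  at least 80% of cohorts, with the head ROI significant and the tail ROI
  quiet.
* Determinism: `simulate → extract → stats` reruns are byte-identical
  under fixed seeds.

## A worked example

```{r, eval = FALSE}
cfg <- cohort_config(n_patients = 30, n_controls = 30, L = 50, C = 40,
                     delta = 0.15, sigma = 0.3, seed = 7)
coh  <- generate_cohort(cfg)
maps <- lapply(coh$stacks, function(s) radial_map(parameterize(s, 50, 40)))
fit  <- shape_lm(~ group + age + tiv, coh$covariates, maps)
res  <- permutation_cluster_test(fit, n_perm = 1000, seed = 11)
res
plot(fit, clusters = res)
rois <- roi_cluster_test(fit, roi_partition(50, 40),
                         n_perm = 1000, seed = 11)
cluster_table(rois)
```

## Known limitations

* The medial curve is the per-level centroid — deterministic and exact
  for symmetric cross-sections, but not an intrinsic (Blum) medial axis,
  and it attenuates focal deficits as described above.
* Radial distance uses the matching level index, not ray casting; on
  strongly non-star-shaped cross-sections the two differ.
* Correspondence is anchor-plus-minimal-twist, not a group-wise
  optimization; systematic shape differences between groups could in
  principle bias correspondence.
* The volume group test assumes independent subjects and a common error
  variance; no mixed or longitudinal models are provided.
* One contour per slice: structures that split into multiple components
  on a slice are rejected rather than merged.
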