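---
title: "Methods: VAT overlay analysis and its synthetic validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: VAT overlay analysis and its synthetic validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stimtract)
```

This vignette documents the models, conventions and design choices behind
`stimtract`, in the spirit of a statistical-methods appendix: what is
computed, under which assumptions, and what the synthetic experiments do and
do not demonstrate.

## The volume of activated tissue

The electric field of a current point source in a homogeneous, isotropic
medium falls off with the square of distance (Coulomb's law). Tissue around
a DBS contact is taken as activated where the field exceeds a threshold
`E`, which gives a spherical activated volume with radius

$$ r = \sqrt{\frac{I}{4 \pi \sigma E}} $$

for stimulation current $I$. Defaults are $\sigma = 0.1$ S/m and
$E = 0.2$ V/mm, standard constants for this family of models. The current
column of contact tables is in mA and the threshold in V/mm; all unit
conversion to SI happens inside `activation_radius()` and nowhere else, so
there is exactly one place where a unit bug could live. The sphere is
deliberately simple: no electrode geometry, pulse-width or anisotropy
effects. This matches the model class the analysis is built around — for
correlating stimulation sites with structures at millimetre scale, more
elaborate field simulations add parameters without adding identifiable
information. When several contacts on a lead are active, the site is their
arithmetic mean ("geometric center").

Useful identities, both tested: $r(4I) = 2\,r(I)$, and
$r^2 \cdot 4\pi\sigma E = I$ to machine precision.

## Density mapping

Streamline bundles are rendered to isotropic scalar volumes in one fixed
convention: world millimetres, RAS+, voxel *centers* (the world coordinate
of voxel index $(0,0,0)$ is the grid origin; indices are 0-based
internally). TRK's corner-origin voxel-mm dialect is converted on read.
Only isotropic, axis-aligned grids are supported; anything else raises an
error rather than silently resampling.

Rasterization resamples each streamline at half-voxel arc-length steps and
deposits one count per sample in its containing voxel (visitation
counting). The deposition rule is not segment-length weighting; for the
ratio statistics computed downstream the constant factor between the two
conventions cancels, and visitation counting is the simplest rule
consistent with a streamline-count interpretation. Consequences, both
tested: density is additive over streamlines, and total unsmoothed mass
scales like $1/\text{step}$, so absolute density units are
resolution-dependent. Scores are therefore comparable only *within* one
structure across patients — which is all the per-structure regressions
need — and are never normalized across bundles.

Smoothing is separable convolution with a normalized discrete Gaussian
(SD in voxels = $\sigma_{mm}$ / voxel size), truncated at 4 SD, zero-padded
at the boundary. $\sigma = 0$ is an exact identity; mass is conserved to
better than $10^{-6}$ for support at least 4 SD inside the boundary. The
reference settings are 0.22 mm voxels with $\sigma = 2$ mm for bundle
densities, and 1 mm voxels with a 3 mm kernel for terminal (endpoint)
densities. A kernel "width" of 3 mm is ambiguous; it is read as
$\sigma = 3$ mm to parallel the explicit sigma phrasing of the 2 mm kernel,
with a FWHM interpretation selectable (`kernel_units = "fwhm"`). Tests and
the demo pipeline run at 0.5–1 mm voxels on small bounding boxes: the
mathematics is identical, only the constant resolution factor changes, and
the suite verifies grid-size invariances explicitly. Problem sizes
throughout (300 streamlines per bundle, grids of roughly $130^3$ voxel
equivalents, 20 replicates) were chosen as the smallest sizes at which all
statistical claims are stable.

## Activation scoring and regression

A structure's activation at a site is the mean of its density image over
all voxels whose centers lie within the activation radius — voxel centers,
not partial-volume weights, consistently with the grid convention (the
brute-force oracle in the tests enumerates exactly the same set). Spheres
that catch no voxel center raise a resolution error instead of returning a
fabricated value.

Outcome improvement is the relative reduction of the Y-BOCS score,
$(\text{baseline} - \text{follow-up}) / \text{baseline}$, so 1 means
symptom-free and negative values mean deterioration. Left and right
hemispheres enter the regression as separate observations carrying their
patient's improvement. This pooling doubles the nominal sample size while
the outcome is shared within a patient; the resulting non-independence is a
property of the replicated design, kept deliberately, and its footprint is
visible in the synthetic experiments (see below). No multiple-testing
correction is applied across structures; raw p-values are reported.

Leave-one-out validation refits the univariate model $n$ times (via the
closed-form OLS leave-one-out residual $e_i / (1 - h_{ii})$; the test
oracle does the $n$ explicit refits) and reports
$1 - R^2 = \overline{(y_i - \hat y_{(i)})^2} / \mathrm{Var}(y)$ with the
*population* variance (divide by $n$) of the whole group as normalizer —
the same normalizer for every fold. The convention is configurable
(`variance = "sample"`); only the population choice makes $1-R^2$ an exact
mean-squared-error ratio. Out-of-sample $R^2$ can be negative, and the
suite demonstrates that it routinely is on noise-only data at $n = 10$.

## Streamline selection, fingerprints and conjugations

Streamlines are selected from a normative tractogram when any point
(after resampling to 0.5 mm, so sparse polylines cannot slip through a
small ROI) lies within a sphere of 2 mm *diameter* around a stimulation
coordinate — diameter semantics, radius 1 mm. Group fingerprints take the
union of per-site selections (each streamline once) and render terminal
densities. Peaks are voxels strictly greater than all 26 neighbors, above a
minimum value, with closer-than-`min_separation` peaks suppressed keeping
the larger (ties break toward the lexicographically smallest index).
Conjugation thresholds each fingerprint at its own quantile (default 0.95 —
a free parameter, since no canonical threshold exists for "supra-threshold
penetration"), intersects the masks, and pairs peaks of the two sources
within a pairing distance that touch the mask's 26-neighborhood. Surface
projection is plain trilinear sampling at mesh vertices (OFF-format ASCII
meshes; out-of-grid vertices get 0 with a warning).

The peak-detection neighborhood, separation and threshold have no
authoritative published values; the defaults here are recorded design
choices, and every one is a function argument.

## The synthetic study

The generator exists because the patient cohorts this analysis class is
applied to cannot be deposited. It emulates the *statistical* structure the
pipeline assumes, not anatomy:

- **Bundles** are smooth perturbations of a polyline centerline: offsets
  drawn i.i.d. per control point, linearly interpolated along arc length
  and variance-normalized so every point's marginal lateral SD equals
  `lateral_sd` exactly (a stationary piecewise-linear Gaussian field). They
  are abstract test anatomy and make no attempt to mimic real bundle
  geometry.
- **Cohorts**: two bilateral cohorts, n = 12 (baseline Y-BOCS
  $34.3 \pm 4.4$, improvement $0.44 \pm 0.25$) and n = 14 ($33.4 \pm 3.7$,
  $0.46 \pm 0.29$), targeting spatially disjunct clusters along the true
  bundle; contact placement jitter 1.5 mm SD. Baselines are truncated to
  [8, 40] and rounded; follow-up scores are rounded to the clinician
  integer scale and the reported improvement recomputed from rounded
  scores. Stimulation currents are not published for such cohorts; the
  default is a truncated Gaussian with mean 3 mA, SD 0.5 mA — a free
  choice, exposed in the spec of every cohort.
- **Outcomes** are linear in the true bundle's per-patient mean bilateral
  activation plus Gaussian noise. The slope is calibrated so the activation
  signal's SD equals the cohorts' stated improvement SD divided by
  $\sqrt 2$, and the noise SD matches it: improvements land at
  $\approx 0.45 \pm 0.27$ on the clinical scale *and* the true-model
  patient-level $R^2$ is about 0.5. `simulate_outcomes()` keeps the
  improvement continuous by default so that a noiseless simulation is
  exactly linear in activation; integer rounding is available via
  `round_scores = TRUE`.

**Decoy geometry.** The demo study includes two decoy bundles that carry no
effect. Designing a *fair* decoy is the subtle part: any structure whose
density decays steeply across the stimulation sites acquires a spurious
correlation with the outcome, because the convexity of a steep falloff
couples its activation to the even (radial) moments of the placement jitter
— the same moments that drive the true bundle's activation. The decoys are
therefore broad (8 mm lateral SD) bundles flanking the target 12 mm
laterally: at the sites their density varies smoothly and almost linearly
in the lateral coordinate, which is symmetric-mean-zero with respect to the
outcome, so their activation is statistically unrelated to improvement.
Under this design the recovery experiment (`recovery_experiment()`: fixed
anatomy, 20 re-seeded 26-patient cohorts) ranks the true bundle first by
joint adjusted $R^2$ in essentially every replicate while decoy p-values
stay non-significant. Decoy p-values still run slightly hot relative to the
nominal 5% — the visible footprint of pooling two hemispheres per patient —
which is reported, not corrected, because the pooled design is the point.

**What passing does not show.** The generator produces Gaussian jitter,
Gaussian bundles and a linear effect; real cohorts have correlated
placement errors, registration error, non-Gaussian anatomy and effects that
need not be linear in mean density. The synthetic experiments validate the
*implementation* (formulas, conventions, invariances, ranking behaviour at
realistic signal-to-noise), not the clinical model itself.

## Numerical and degenerate-input policy

Structured error conditions, not sentinel values: empty streamlines,
anisotropic grids, spheres outside the grid, spheres catching no voxel
center, constant predictors (overall or after removing one observation),
and sites without outcomes each raise a typed error naming the offending
record. Per-streamline correlations that are undefined (zero overlap or
outcome variance) are flagged `defined = FALSE`, never reported as 0. In
the structure screen, a failing structure/partition lands in an `error`
column without aborting the remaining fits. All generators and the full
pipeline are bit-reproducible for a fixed seed; stage seeds are derived
from one master seed.
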