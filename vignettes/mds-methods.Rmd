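---
title: "The marginal diffusion slope: model, assumptions and validation apparatus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The marginal diffusion slope: model, assumptions and validation apparatus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdslope)
```

## The biomarker

Gliomas infiltrate the brain beyond their contrast-enhancing rim. Water
diffusivity, measured per voxel as the apparent diffusion coefficient
(ADC, mm²/s), falls where cellularity is high, so the *shape* of the ADC
transition across the macroscopic tumour boundary carries information
about how diffusely the margin is infiltrated: a sharp rise from the
hypercellular core to normal parenchyma suggests a circumscribed edge,
a shallow rise suggests occult infiltration.

The marginal diffusion slope (MDS) quantifies this. For each voxel of the
refined enhancing-tumour boundary, a unit outward normal is estimated and
the ADC map is sampled along it centrifugally over a fixed window, −2 mm
inside to +6 mm outside the boundary, at 2 samples/mm (17 samples). Each
valid profile contributes the slope of an ordinary least-squares fit of
ADC against distance; regression is done against the sample index and
converted to per-mm units by the sampling frequency (2 points/mm), which
is algebraically identical to regressing on millimetres. The patient-level
MDS is the unweighted mean of the valid per-profile slopes, in
(mm²/s)/mm. Higher MDS (steeper rise) is the favourable phenotype.

A linear fit is used deliberately: the underlying transition is plausibly
sigmoidal, but sigmoid fits are unstable on noisy 17-point profiles, and
the linear slope is a robust monotone summary. Where the truly linear
portion is narrower than the fitted run the slope underestimates the
transition steepness; the consequences are quantified below.

## Geometry

All geometry is metric. Volumes carry a voxel-to-world affine (0-based
voxel indices, world millimetres); boundary normals, sampling windows and
slopes are computed in world mm, so anisotropic grids are handled
correctly. The same code path serves 3D clinical volumes and 2D
preclinical maps.

* **ROI refinement** (`refineROI`): morphological closing (Euclidean
  ball, default radius 1 voxel), hole filling, then retention of every
  face-connected component of at least 5 voxels — multifocal disease
  contributes all its foci.
* **Boundary** (`extractBoundary`): mask voxels with a face-adjacent
  background neighbour (4-/6-connectivity); the outside of the grid
  counts as background.
* **Normals** (`estimateNormals`): per boundary voxel, the boundary
  points inside a centred 5×5(×5) kernel are taken to world mm and the
  eigen-decomposition of their scatter about the centroid separates
  tangential directions (leading eigenvalues) from the surface normal
  (smallest eigenvalue). Orientation is made outward by the gradient of a
  Gaussian-smoothed (σ = 1 voxel) mask indicator; where that gradient
  vanishes the vector points away from the component centroid.
  Neighbourhoods with fewer than 3 boundary points are skipped and
  counted.
* **Sampling** (`sampleProfiles`): bi-/trilinear interpolation at each
  window position; positions outside the volume are missing, never
  zero-filled, and missingness breaks contiguity.

## Validity rules

A sample is *measurable* when its containing voxel lies in the combined
tumour-abnormality region: enhancing tumour, non-enhancing core, or FLAIR
abnormality. The FLAIR class alone would wrongly exclude the inner −2 mm
of the window, which lies in enhancing tumour. Per profile, the
contiguous run is the longest consecutive stretch of measurable,
non-missing samples containing the boundary crossing (arc = 0); the
profile is valid iff the run *spans* strictly more than 4 mm (at 2
samples/mm, at least 10 samples). Span, `(n−1)/rate`, rather than sample
count times the interval, is the implemented convention: a run from −2 mm
to +3 mm measures 5 mm. Slopes are fitted over the run only.

The strict 4 mm rule interacts with the window in one important way: a
valid run spans at least 4.5 mm, so no transition narrower than 4.5 mm
can ever be measured without off-transition samples entering the fit.
For a linear ramp of width 4 mm the best possible OLS recovery is 94.55%
in exact arithmetic (one clamped sample at maximal leverage), and voxel
discretization costs a further ~5% at 1 mm spacing. This is a property of
the estimator under its own validity rules, not an implementation defect;
the synthetic-patient tests document it, and recovery to within 5% is
demonstrated whenever the imposed transition covers the fitted run (e.g.
a 9 mm ramp, recovered to 1%).

## The simulator

`makeGaussianTumour` builds the in-silico apparatus: cellularity
ρ(x) = ρ_peak·exp(−r²/2σ²) on a 2D grid (default 256² at 0.5 mm), and
diffusivity through Graham's relation D ∝ 1/√ρ. A background floor
(default 10⁻⁵·ρ_peak) keeps the far field finite; raw values
1/√(ρ+floor) are mapped affinely onto [`d_core`, `d_plateau`] so the map
plateaus at parenchymal diffusivity (8×10⁻⁴ mm²/s) far from the tumour
and bottoms at a dense-tumour value (3×10⁻⁴ mm²/s) at peak cellularity.
With this floor the plateau is met to 0.08% at 6σ and to machine
precision beyond ~15σ. The simulated core is the level set
ρ ≥ 0.5·ρ_peak (radius 1.18σ); a 0.9 threshold was rejected because at
σ = 1 mm on 0.5 mm voxels it yields a sub-voxel core that the ≥5-voxel
component policy removes. σ controls infiltrativeness: `runInfiltrationSweep`
shows mean MDS strictly decreasing in σ, the mechanism behind the
biomarker hypothesis.

```{r sweep, eval = FALSE}
runInfiltrationSweep(c(1, 2, 4, 8))
```

## Synthetic fixtures

Every analysis stage is testable without external data; each generator
returns its ground truth.

* **Patient** (`makeSyntheticPatient`): ellipsoidal enhancing core
  (default spherical, 8 mm radius, 48³ grid at 1 mm — the clinical
  resampling grid), ADC ramping linearly across the boundary over
  `transition_width_mm` (slope = (plateau − core)/width along the
  analytic surface normal; the signed ellipsoid distance is first-order
  exact and exact for spheres), plateau 8×10⁻⁴, core 6×10⁻⁴ mm²/s,
  optional seeded Gaussian noise, and a FLAIR shell of configurable
  thickness. Specs whose ramp extends past the FLAIR shell are refused —
  the truth would be truncated.
* **Rodent** (`makeSyntheticRodent`): a 2D Gaussian cell-density blob
  (σ = 1.5 mm, a few-mm lesion as in glioblastoma xenografts) on a
  160² grid at 0.2 mm, with noiseless ADC a monotone decreasing function
  of the density *seen at imaging resolution* — the density is blurred by
  a fixed 0.4 mm point spread before the relation is applied, reflecting
  that MRI resolves far coarser structure than histology. Because the
  blur is fixed in mm while the lesion scales with σ, the
  histology-to-imaging footprint ratio (infiltration index) increases
  with σ; pure Gaussian level sets would scale proportionally and make
  the ratio uninformative. The default relation is affine decreasing;
  validation of the band analyses uses a negative exponential, which is
  steeper near the ROI edge.
* **Cohort** (`makeSyntheticCohort`): MDS ~ N(5×10⁻⁵, 2×10⁻⁵), survival
  exponential with hazard `baseline_rate·exp(β·z)` on standardized MDS,
  all events observed; β = ln(0.5) mimics a halved hazard per SD.

What the fixtures do *not* emulate: Rician MR noise, spatially
correlated noise, EPI distortion, lesion texture, irregular margins,
partial-volume label errors, registration error. Passing tests therefore
demonstrate correctness of the estimator under its stated model, not
clinical performance.

## Cohort statistics

`fitCox` standardizes MDS before fitting so the exponentiated coefficient
is the hazard ratio per 1 SD; ties use the Efron likelihood
(day-resolution survival makes ties likely), and the Schoenfeld global
test checks proportional hazards. `survivalSummary` reports the
Kaplan–Meier median with log-log CI, which with no censoring reduces to
the sample median (even n: midpoint of the central order statistics).
The repeated-measures coefficient of variation is
sd(x₁−x₂)/mean((x₁+x₂)/2) with the sample (n−1) standard deviation —
the denominator choice is configurable since conventions differ. ICC is
the two-way random-effects single-measure form ICC(2,1), assembled from
the ANOVA mean squares; Bland–Altman limits are bias ± 1.96·sd of the
differences. No multiplicity correction is applied anywhere.

## Numerical choices and scaling

* Grid agreement is enforced to 10⁻⁴ mm on affines; 4D inputs are
  rejected rather than squeezed.
* Trilinear interpolation is exact on affine fields, which the test
  suite exploits as an oracle.
* An undefined patient MDS (no valid profiles) is an explicit NA
  sentinel, never 0 — zero is a meaningful slope.
* Problem sizes in the tests — 40–48³ clinical grids, 256² simulator
  grids, cohorts of 100–2000 — were chosen so the whole validation runs
  in about a minute while keeping every boundary ≥ 10 voxels in radius,
  where the normal-field error is below 5° and the skipped-vector
  fraction below 1%.
* Determinism: all randomness flows through explicit seeds; repeated
  runs are bit-identical.

## Known limitations

The slope underestimates steep sub-resolution transitions (see the 4 mm
analysis above). Normal estimation assumes locally curve-like topology
inside the kernel; at kissing surfaces or very thin structures the
smallest-eigenvalue direction can be ambiguous and such vectors are only
partially filtered by the degeneracy rule. The infiltration index
depends on the mask thresholds of both modalities; only its ordering, not
its absolute value, is validated. Registration between ADC, structural
volumes and histology is assumed perfect — errors there propagate
directly into profile mixing.
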