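---
title: "Measuring glymphatic function with the DTI-ALPS index: model, simulator, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring glymphatic function with the DTI-ALPS index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtialps)
```

## The measurement and its geometry

The glymphatic system clears interstitial waste from the brain along
perivascular channels. DTI-ALPS ("diffusion tensor image analysis along the
perivascular space") quantifies this non-invasively from an ordinary
diffusion tensor acquisition by exploiting a geometric accident at the level
of the lateral ventricle body: there, medullary veins — and the perivascular
spaces around them — run along the image x-axis (right–left), perpendicular
to both the projection fibers (which run along z, inferior–superior) and the
association fibers (along y, anterior–posterior).

Water mobility along the perivascular axis therefore shows up as the Dxx
component of the diffusion tensor inside either tract, while the tensor's
other diagonal components in those tracts reflect ordinary
across-fiber diffusion. The index is

$$
\mathrm{ALPS} \;=\;
\frac{\mathrm{mean}\!\left(D_{xx}^{\mathrm{proj}},\, D_{xx}^{\mathrm{assoc}}\right)}
     {\mathrm{mean}\!\left(D_{yy}^{\mathrm{proj}},\, D_{zz}^{\mathrm{assoc}}\right)} ,
$$

where all four quantities are means of raw diagonal tensor components (in
image coordinates, **not** eigenvalues) over a 5 mm disk ROI in each tract.
An isotropic medium gives ALPS = 1 exactly; healthy perivascular flow pushes
it above 1; a lower value indicates reduced perivascular diffusivity, read
as impaired glymphatic transport. The ratio is invariant to a common scaling
of all four diffusivities, strictly increasing in either Dxx and strictly
decreasing in either denominator component — properties the test suite
asserts directly.

In the clinical study this package models, the index was compared between 42
children with childhood absence epilepsy (CAE) and 50 age- and
gender-matched healthy controls (HC), and correlated with age, disease
duration, and seizure frequency within groups. Because no raw imaging data
are publicly deposited, the package validates every stage of the measurement
chain by *parameter recovery on synthetic data*: a generator with exactly
known ground truth stands in for the patients.

## The forward model

**Phantom.** `phantom_spec()` defines a voxel grid (default 48 × 48 × 24 at
1.72 × 1.72 × 3 mm — a reduced-field-of-view analog of a 128 × 128 in-plane
matrix with 3 mm slices, chosen so a 92-subject cohort simulates in a few
minutes) containing three disjoint cuboid tracts in an isotropic background.
Tensors are axis-aligned (diagonal) because the measurement itself reads
diffusivities along image axes; no rotation machinery is needed or wanted.
Literature-typical white-matter magnitudes are used where the clinical
report gives none: axial diffusivity 1.4 × 10⁻³ mm²/s, radial
0.4 × 10⁻³ mm²/s, background 0.8 × 10⁻³ mm²/s, all configurable.

**Encoding a known truth.** Both ALPS-relevant tracts share a perivascular
x-axis diffusivity d. Since the denominator components equal the radial
diffusivity, the index inverts analytically:
`solve_perivascular_dxx(target, dyy, dzz) = target × mean(dyy, dzz)`.
`make_phantom()` applies this so the region-mean ALPS equals the requested
target to machine precision — the round-trip identity is a standing test.
Targets requiring d ≥ the axial diffusivity are rejected (the fiber axis
would stop being the principal axis; with the defaults this caps targets at
3.5, far above the physiological range ~0.8–2.5).

**Signal.** `simulate_dwi()` evaluates the mono-exponential Stejskal–Tanner
model S = S₀·exp(−b·gᵀDg) for each entry of a gradient table — by default 30
directions at b = 1000 s/mm² plus one b = 0 volume, the clinical protocol.
Directions come from a deterministic Fibonacci half-shell
(`build_gradient_table()`): reproducibility is preferred over mimicking any
vendor table, and the resulting second moment is within a few percent of the
uniform value I/3. Noise is Rician — the magnitude of a complex
Gaussian-corrupted signal, the correct model for magnitude MRI — with
σ = S₀/SNR and a default SNR of 30, typical of 3 T DTI. Noiseless simulation
(`snr = NULL`) is exact, which is what makes the fit's exactness testable.

**Inverse.** `fit_tensor()` uses ordinary log-linear least squares on the
six-component design b·(gx², gy², gz², 2gxgy, 2gxgz, 2gygz). On noiseless
positive signals this solves the forward model exactly (the suite requires
relative error < 1e-8 on every voxel); under Rician noise at SNR 30 the
voxelwise median |Dxx| error is ~2.6 × 10⁻⁵ mm²/s, and 9-voxel ROI averaging
reduces the effect on ALPS to a per-subject SD of ~0.04 with bias below
0.02 — small against the between-subject SDs of 0.30–0.36. Signals are
floored at 10⁻⁶·S₀ before the log; eigendecomposition clamps negative
eigenvalues to zero (counting them) rather than rejecting voxels, mirroring
common tool behavior and keeping the index computable. FA uses the standard
normalized eigenvalue-dispersion formula with FA(0-tensor) ≡ 0, and the
directionally-encoded color map (red = x, green = y, blue = z) reproduces
the conventional tract colors on the phantom.

**ROIs.** `place_rois_auto()` puts a 5 mm disk at each tract's in-plane
centroid on a single axial slice — a 2-D disk, not a sphere, because the
clinical procedure draws ROIs on one axial FA slice; slice thickness is
carried by the single-slice convention. A voxel belongs to the disk iff its
center lies within the radius (half-in voxels excluded; the center voxel is
always included). At 1.72 mm voxels the 5 mm disk is a 3 × 3 block of 9
voxels, a fact the tests derive by enumerating voxel-center distances rather
than asserting as a constant. Manual `roi_spec()` coordinates are accepted
for non-phantom data. Only one (left-hemisphere-analog) tract pair is
measured — no bilateral averaging, matching the clinical procedure.

## The cohort generator

`sample_cohort()` draws, per group, (ALPS, age, duration, frequency) from a
Gaussian copula whose normal scores carry the target correlation matrix,
then maps each coordinate through the inverse CDF of its marginal. Defaults
are the study conditions: true ALPS ~ N(1.45, 0.36) in CAE and N(1.66, 0.30)
in HC; age 8.31 ± 2.12 vs 8.44 ± 1.94 years truncated to [4, 12] (the CAE
onset range); duration 10.71 ± 4.97 months and frequency 7.71 ± 2.00 per day
in CAE only, truncated at 0; correlations ALPS–age 0.766 (CAE) / 0.651 (HC),
ALPS–duration −0.48, ALPS–frequency 0. Covariate pairs the study does not
report default to correlation 0; the implied matrix is checked for positive
semi-definiteness with an error naming the offending pair.

Two design choices deserve a note:

* **Truncation via the quantile transform, not clipping.** Mapping copula
  uniforms through the truncated-normal quantile keeps the marginal a proper
  truncated normal; clipping would pile probability mass on the bounds and
  shift the moments. The tests compare empirical means/SDs at n = 5000
  against the *analytic truncated-normal* moments (e.g. age's effective SD
  is 1.79, not the 2.12 parameter).
* **Attenuation is accepted, not compensated.** Monotone marginal transforms
  shrink Pearson correlations slightly below the normal-score targets
  (~0.01 here). The generator imposes the target matrix on the scores, as
  its contract states, and the recovery tolerances absorb the attenuation.

## What the validation does and does not show

The seeded experiments (see `analysis/` and `scripts/acceptance.R`)
demonstrate that the pipeline recovers group means within ±0.03 at the
clinical sample sizes, preserves the imposed correlation structure, and that
the statistical battery (pooled-variance t-tests — chosen because that form
reproduces the published age p-value 0.76 from summary statistics alone —
two-tailed throughout, Pearson correlations, plain chi-square without
continuity correction, no multiplicity adjustment, matching the clinical
analysis) is calibrated: the group test's type-I error sits in (0.03, 0.07)
over 1000 null replicates.

A caveat the numbers force on us: a single cohort at n = 42–50 yields a
Pearson r whose sampling SD is 0.07–0.13, so any one seed's recovered r can
sit over 0.1 from its target even with a perfect generator and pipeline.
The analysis therefore always pairs the clinical-n measurement with an
n = 2000 generator-level check, and recovered correlations should be read
with that scatter in mind.

The phantom is deliberately idealized: axis-aligned single-tensor voxels, no
crossing fibers, no partial-volume mixing at tract borders (ROIs sit well
inside tracts), no motion or eddy-current artifacts (the clinical pipeline
corrects these; synthetic data are artifact-free by construction), no
susceptibility distortion, and manual-ROI variability — the dominant
real-world nuisance — is absent because placement is deterministic. Passing
recovery tests therefore certifies the *computational chain* (simulation →
fit → ROI → index → statistics), not the robustness of ALPS to anatomy,
artifacts, or rater variability in real patients. Between-subject imaging
claims of the underlying study remain unreproducible at desk scale without
its raw data.

## Numerical conventions

* Component order everywhere: (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz); mm²/s.
* NIfTI-1 with an RAS-positive affine; FSL-style `bval`/`bvec` text files;
  non-unit weighted b-vectors are renormalized with a warning.
* All stochastic stages (noise, cohorts) are seeded; two runs from the same
  configuration and seed agree bitwise, including written CSVs.
* Perfect correlations report the smallest representable positive p rather
  than 0; degenerate inputs (empty masks, zero variance, rank-deficient
  gradient designs, non-PSD correlation targets) raise errors naming the
  failing stage.

## Problem sizes used in the shipped experiments

Group recovery images 92 subjects (42 + 50) on the default 48 × 48 × 24
grid at SNR 30; correlation recovery images one 42-subject CAE cohort and
one 50-subject HC cohort and cross-checks the generator at n = 2000 on true
values; calibration uses 1000 null replicates of the group test and 50
repeated measurements of one phantom. These sizes were chosen to mirror the
study's own ns where the claim is about the study, and to make Monte-Carlo
standard errors small where the claim is about the method.
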