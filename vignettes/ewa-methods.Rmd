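---
title: "Automatic infarct quantification in LGE CMR: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automatic infarct quantification in LGE CMR: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ewamri)
```

## The problem

Late gadolinium enhancement (LGE) cardiovascular MR is the reference
standard for visualizing myocardial infarction: infarcted myocardium
retains contrast agent and appears hyperenhanced, while viable myocardium
is nulled by the inversion pulse.  Turning that picture into an infarct
size in percent of left-ventricular mass (%LVM) is notoriously
method-dependent: fixed thresholds at n standard deviations above remote
myocardium, full-width-at-half-maximum (FWHM) rules, and Otsu's criterion
all give systematically different answers, and several are biased in
opposite directions on magnitude inversion-recovery (IR) versus
phase-sensitive inversion-recovery (PSIR) reconstructions.

`ewamri` implements the EWA approach — **E**xpectation-maximization
intensity classification, **w**eighted summation, and **a**-priori
perfusion-territory information — as a six-step automatic pipeline:

1. surface-coil intensity correction,
2. constrained two-Gaussian EM classification of myocardial intensities
   and derivation of the optimal threshold,
3. level-set growth of the infarct core from supra-threshold seeds,
4. slice-wise detection of microvascular obstruction (MVO),
5. post-processing (culprit-territory filter, small-region removal),
6. partial-volume weighted summation of infarct size.

Inputs are a short-axis image stack with voxel geometry, manually traced
endocardial/epicardial contours (papillary muscles excluded by the
contourer), and — when the a-priori model is used — the culprit artery and
the anterior/inferior right-ventricular insertion points.

## The model, step by step

### Constrained EM classification (step 2)

Myocardial intensities are modelled as a two-component Gaussian mixture,

$$p(I) = \pi_n\,\mathcal N(I;\mu_n,\sigma_n^2) +
          \pi_i\,\mathcal N(I;\mu_i,\sigma_i^2),$$

normal myocardium (subscript *n*) and infarct (*i*, the larger mean).  The
fit is initialized by labelling the top decile of the intensity histogram
as infarct (a deliberately small 10% seed at the 90th percentile,
ties broken toward normal) and is *constrained* each E-step: intensities
below the 5th percentile keep infarct-responsibility 0, intensities above
the 95th keep responsibility 1.  The clamps stabilize the fit and prevent
the two components from collapsing onto each other.  Percentiles use the
linear-interpolation estimator (`quantile` type 7); the constraint
boundaries inherit that choice.

The working threshold $t^\*$ is the intensity at which a voxel is equally
likely to be normal or infarcted, i.e. the posterior-equality point
$\pi_n \mathcal N(t;\mu_n,\sigma_n) = \pi_i \mathcal N(t;\mu_i,\sigma_i)$
— a quadratic in $t$ solved in closed form, taking the root inside
$(\mu_n, \mu_i)$.  We read "equal probability of being representative of
either class" as posterior (mixture-weighted) equality because the
question is about the class given the intensity; the unweighted
class-conditional variant is available via
`optimal_threshold(pair, weighted = FALSE)`.

Numerical choices worth knowing:

* Intensities are standardized internally and parameters mapped back, so
  the fit and $t^\*$ are exactly equivariant under affine intensity
  rescaling ($aI + b$, $a > 0$) — a property the test suite asserts.
* Convergence: maximum absolute parameter change below $10^{-6}$ on the
  standardized scale, cap 500 iterations.
* Component SDs are floored at $10^{-6}$ of the standardized range rather
  than treated as fatal, so quantized or noise-free inputs (where a
  component can sit on one repeated value) remain fittable; a component
  whose *weight* collapses below $10^{-6}$ is still an error.
* With a mass of tied values at the maximum the strict 90th-percentile
  initial cut would be empty; it then falls back to `>=`.
* The per-iteration `objective` recorded by `em_fit()` is the EM lower
  bound on the observed-data log-likelihood (expected complete-data
  log-likelihood plus responsibility entropy).  With the clamp sets
  fixed, neither the E- nor the M-step can decrease it, and the tests
  assert the trace is non-decreasing.  The expected complete-data term
  alone is *not* monotone — it omits the entropy — which is why the bound
  is what we track.
* Whether the original formulation clamps responsibilities every E-step
  or only at initialization is not documented; we clamp every E-step
  (the stronger, more stable reading) and note the alternative here.

### Level-set core growth (step 3)

The core is grown from all supra-threshold voxels with a discrete
narrow-band level set whose speed is linear in intensity,

$$S(I) = \frac{I - t^\*}{I_{\max} - t^\*},$$

zero at the threshold, one at the maximal myocardial intensity, negative
below threshold.  Each sweep, the front moves outward where
$S - \alpha\kappa > 0$ (candidates 6-adjacent in 3D) and inward where
$S - \alpha\kappa < 0$; $\kappa$ is an in-slice discrete curvature proxy
($1 - 2p$, with $p$ the in-region fraction of the 8-neighbourhood,
non-myocardial neighbours counting one half).  Additions and removals are
computed simultaneously from the current region, so the evolution is
deterministic; it stops at stability or after `levelset_max_iter = 200`
sweeps.  A voxel with $S = 0$ exactly is excluded (strict inequality).

The smoothing weight of the original implementation is not published; we
default to $\alpha = 0.1$ (speed units per curvature unit), declared, not
claimed faithful, and CLI-configurable.  Two exact limits anchor the
scheme: with $\alpha = 0$ the output equals direct thresholding
$\{S > 0\}$, and a large $\alpha$ collapses an isolated single-voxel
front.  Curvature flow is not monotone in $\alpha$, so no nesting is
asserted; on smooth-bordered phantoms the default-$\alpha$ core differs
from the $\alpha = 0$ core by at most 20% of its size.

### MVO detection (step 4)

MVO — contrast-free hypointense cores inside acute infarcts — is missed
by any intensity threshold and is recovered geometrically, slice by
slice: 4-connected non-core myocardial components are holes (MVO) when
every boundary contact is infarct core or the endocardial border, with at
least one core contact; any contact with the epicardial side or remote
myocardium lets the flood fill escape and disqualifies the component.
A morphological closing (dilate with the 3x3 cross kernel, re-run the
hole search on the dilated core, then erode) additionally seals leaks of
up to two pixels.  The erosion is applied to the closed core while holes
found at the dilated stage are kept; the alternative reading (eroding the
hole set) is noted but not used.  Core components use 8-connectivity,
holes 4-connectivity — the standard complementary pairing that avoids
topological paradoxes.  MVO voxels are fully infarcted tissue and join
the infarct mask with weight 1.

The extra "at least one core contact" requirement is our reading of
"totally surrounded by infarct or connected to the endocardial border":
without it a dark component bounded only by blood would qualify.

### Post-processing (step 5)

With a culprit artery supplied, infarct voxels outside the artery's
maximal-extent territory are removed (bright artifacts elsewhere in the
myocardium cannot be infarct of that artery).  Then isolated regions
smaller than 1.5 cm^3 are discarded unless they comprise more than 1% of
LV mass or are the only region.  Components use 26-connectivity in 3D so
a transmural infarct spanning slices is never fragmented; percentages are
component volume over myocardial volume (density cancels).  If the rule
would remove every region of a non-empty mask, the largest is retained —
the only-region clause generalized so the filter never empties a
segmentation.  Filtering runs culprit-first, size-second, and is
idempotent.  Size filtering is binary-volume based: weighting is step 6
and follows this step.

### Weighted quantification (step 6)

Each infarct voxel contributes its estimated infarcted-tissue fraction,

$$w = \mathrm{clamp}\!\left(\frac{I - \mu_r}{P_{90,\mathrm{MI}} - \mu_r},\,0,\,1\right),$$

anchored at 0 at the remote-myocardium mean and at 1 at the 90th
percentile of the core infarct intensities; MVO voxels count as 1.
Infarct size is $100 \sum w \, / \, N_{\mathrm{myo}}$ %LVM.  Both anchors
transform identically under affine rescaling, so the weighted size is
scale-invariant.  The P90 anchor (rather than the maximum) is robust to
single bright voxels; its price is that the bulk of fully infarcted
voxels sits slightly below the anchor under noise, a small negative bias
visible in the phantom study below.  P90 is computed over core (non-MVO)
voxels, before the MVO merge; at a *fixed* anchor the weight is monotone
in intensity, while recomputing the anchor after brightening a
supra-P90 voxel can slightly deflate the other weights — the monotonicity
property holds anchor-wise, not anchor-recomputed.

$\mu_r$ is the mean over the extent-model remote mask when a culprit is
given.  In no-model mode (the experimental configuration, used e.g. for
animal data where human perfusion territories do not apply) coil
correction is skipped and $\mu_r$ falls back to the EM normal-component
mean $\mu_n$ — the natural model-free estimate of nulled-myocardium
intensity.

### Coil correction (step 1) and the sector model

Surface-coil drop-off is modelled as a smooth multiplicative field,
second-order in in-plane position (six monomials $1, x, y, x^2, xy, y^2$
— "second order" capturing a gradient proportional to squared coil
distance, "linear" in its parameters).  Samples are blood-pool voxels
(endocardial interior eroded one pixel, avoiding boundary partial volume)
and remote-myocardium voxels; each contributes its intensity divided by
its tissue-class mean, and the field is the per-slice least-squares
surface through these relative intensities, normalized to mean 1 over the
samples.  Slices with fewer than 6 samples share a pooled surface;
rank-deficient designs drop to first order with a warning.  Whether the
original fits per slice or in 3D, additively or multiplicatively, is
unstated; per-slice multiplicative least squares was chosen for
closed-form solvability, with the pooled fallback for sparse slices.
Corrected images divide by the field, which must be strictly positive
over the myocardium (sign-preserving for PSIR).

The a-priori model lives on an extended bulls-eye: 9 rings (3 basal, 3
mid, 3 apical; slices map to rings by a proportional midpoint rule,
`ring = floor((s - 0.5) * 9 / S) + 1`, identity for 9 slices) by 24
half-open 15-degree sectors per slice.  Sector 1 starts at the anterior
RV insertion angle and indices increase through the septum toward the
inferior insertion (the shorter arc), per-slice LV centers, one insertion
pair per stack.  Voxels on an exact bin edge are snapped to it within
float tolerance so assignment is consistent under rigid rotations of the
whole geometry.  The bundled LAD / LCx / RCA territories reproduce the
qualitative layout (LAD anterior + anteroseptal + apex, RCA inferior +
inferoseptal, LCx lateral) with genuine gaps between territories; the LM
model is their union.  The exact published sector sets exist only
graphically, so the defaults are replaceable YAML configuration —
validated for schema and the LM-union invariant, not asserted as truth.

## Comparator thresholds

For benchmarking on identical inputs the package ships the classical
methods, all unweighted binary cuts by definition: n-SD from remote
(`threshold_nsd`; on purely Gaussian remote intensities 2SD and 3SD flag
the theoretical upper-tail ~2% and ~0.1% of voxels), FWHM from the
myocardial minimum and from the remote mean (`threshold_fwhm_min`,
`threshold_fwhm_remote`, the latter warning when applied to IR images, as
it was designed for PSIR), Otsu's 256-bin between-class-variance
threshold (`threshold_otsu`, ties across an empty inter-class gap broken
mid-gap), and the plain EM cut (`threshold_em_pure`).  The FWHM variants
use global myocardial extrema; the original region-growing
formulations are approximated by `from_region = TRUE`, which anchors the
maximum inside the largest connected hyperenhanced region.
`run_compare()` tabulates %LVM, thresholds, and Dice agreement against a
reference mask.

## The synthetic phantom

`generate_phantom()` builds a short-axis LGE-like stack with voxel-level
ground truth: an annular myocardium (default endo/epi radii 24/33 mm) on
a 64 x 64 x 9 grid at 1.5 x 1.5 x 8.0 mm with no slice gap — the typical
clinical acquisition — containing a transmural wedge of infarct.  The
wedge indicator is rasterized at pixel centers and convolved with a
normalized Gaussian PSF (default SD 1.5 mm, reflected boundaries, mass
conserving), which *is* the partial-volume model: the blurred map is the
per-voxel infarcted-tissue fraction that step 6 claims to estimate, and
its integral over the myocardium is the true %LVM.  Intensity composes as
`remote + fraction * (infarct - remote)` over the myocardium, with bright
blood pool and dim background; an optional MVO sub-wedge hugging the
endocardium is carved down to remote intensity (intensity only — the
truth keeps those voxels fully infarcted); an optional multiplicative
second-order coil field and Gaussian noise follow.  IR mode takes the
magnitude, so nulled remote myocardium shows folded noise; PSIR keeps
signed values.  That folding is the one mode-specific difference — no
Rician model in this version, and no Bloch simulation, motion, or k-space
effects.

Contrast defaults are remote mean 20, infarct mean 120, noise SD 10 —
contrast-to-noise 10 between infarct and nulled myocardium, a mid-range
operating point for 1.5 T LGE.  The coil field defaults to flat; the
coil-correction tests switch on a known gradient and require recovery
within 2% RMS.  `generate_paired()` emulates a paired IR/PSIR acquisition
of one heart: shared geometry and truth, independent noise draws from
sub-seeds.  A fixed seed makes every phantom bit-identical.

What passing on phantoms does *not* show: real LGE has Rician noise
statistics off the nulled region, through-plane partial volume,
papillary and trabecular structure, motion, and contours drawn by humans.
The phantom isolates the estimation problem the algorithm is built for —
recovering a blurred, noisy fraction field — so phantom accuracy is a
necessary, not a sufficient, indication of clinical accuracy.

## Problem sizes and study conditions

The test-suite and acceptance studies use the package's chosen problem
sizes: the default 64 x 64 x 9 phantom; 20 seeded phantoms with spans
60-120 degrees, transmurality 0.5-1 and contrast-to-noise 10 for the
recovery study (and the same for the paired IR/PSIR study); 50 phantoms
for the zero-smoothing level-set identity; one million simulated voxels
for the n-SD tail check; 100 random mixture pairs against a $10^{-4}$
grid for the threshold closed form.  Under those conditions the weighted
estimate runs at a bias of about $-1$ %LVM (SD well under 1 %LVM) against
voxel-level truth, beats the binary core count on essentially every
phantom, and IR/PSIR pairs agree to a few tenths of a %LVM — numbers
recomputed from scratch by `scripts/acceptance.R`, not quoted from
anywhere.

## Known limitations

* The level-set smoothing parameters and the exact published perfusion
  territories are declared defaults, not reproductions.
* FWHM comparators default to global extrema rather than the original
  region-growing definitions (option provided).
* MVO is detected strictly 2D per slice; no 3D bridging, and no
  distinction from intramyocardial hemorrhage.
* No automatic contouring: endo/epi borders and insertion points are
  inputs.
* The EM model is strictly two Gaussians; images whose nulled myocardium
  is better described by a Rayleigh distribution are fit with the generic
  Gaussian pair by design.
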