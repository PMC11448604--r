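---
title: "OPTrecon: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{OPTrecon: models, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of the science it implements: the
imaging model, the reconstruction algorithms, the tunable parameters and
their defaults, what the synthetic-data generator does and does not
emulate, and the numerical decisions taken where the design was open.

# Imaging model and conventions

Optical projection tomography records wide-field images of a rotating,
approximately transparent sample. When the depth of field covers the
sample, each camera pixel approximates a line integral of the
fluorophore distribution along a straight, axis-parallel ray, so each
detector row v builds an independent sinogram and each slice of the
volume can be reconstructed on its own.

Conventions fixed package-wide (the literature states none of them
consistently, so they are pinned here and asserted by tests):

* Angles are degrees, counter-clockwise viewed down the rotation axis;
  projection p (1-based) is at `theta_p = (p-1) * angularRange / P`, with
  the first frame at 0.
* The rotation axis is vertical in the frame: detector rows index z.
* A slice image is a square matrix `img[row = y, col = x]`; the detector
  column grid coincides with the image x grid; the axis projects to the
  detector column `rotationCenter` (fractional, default `(U+1)/2`). A
  unit point at `(centre + r, centre)` traces
  `u(theta) = rotationCenter + r cos(theta)`.
* `ProjectionStack` frames are indexed `(p, v, u)`;
  `ReconstructionVolume` voxels `(z, y, x)`.

# Discrete Radon transform and its adjoint

`forwardProject()` samples the image along rotated rays with bilinear
interpolation. Bilinear quasi-interpolation on a rotated lattice carries
a small phase-dependent mass error set by the lattice spacing in *both*
directions, so each detector bin is modelled by two sub-rays offset
±0.25 px (a detector-footprint average) and rays are sampled at 0.5 px
steps. This keeps the per-angle mass-conservation error below 0.1% even
for white-noise images while remaining cheap; the trade-off is a mild
detector-aperture smoothing that slightly improves, rather than harms,
filtered reconstructions.

The iterative solver's backprojection is the *exact transpose* of this
gather (bilinear scatter over the identical sub-ray lattice), so the
dot-product identity `<Ax, y> = <x, A'y>` holds to machine precision
(`adjointConsistencyCheck()` reports ~1e-16). This matters: TwIST's
convergence theory assumes the gradient `A'(y - Ax)` uses the true
adjoint, and approximate adjoint pairs are a classic source of
spurious non-convergence in iterative CT. The kernels are implemented in
C++ (Rcpp) since they dominate the run time.

# Filtered back projection

`fbpSlice()` implements the standard frequency-domain route: projections
are zero-padded to the next power of two at least twice the detector
width (avoiding circular-convolution bias), multiplied by the DFT of the
band-limited spatial-domain ramp (`h[0] = 1/4`,
`h[n] = -1/(pi^2 n^2)` for odd n; this discretization avoids the DC bias
of sampling `|f|` directly), apodized per the configured window, and
back-projected pixel-wise with linear detector interpolation.

Normalization follows from the Riemann sum of the inverse Radon
integral: `pi / P` for P angles spanning either 180 or 360 degrees (for
360-degree data conjugate rays are counted twice and the halved angular
weight averages them). The absolute scale is verified on the analytic
disc phantom, whose interior must reconstruct to its true value 1.0;
the acceptance script recomputes this (`disc_interior_mean`).

Parameters:

* `filter` (default `ram-lak`): apodization; softer windows (`hamming`,
  `hann`) trade resolution for noise suppression. `none` is an
  unfiltered laminogram, kept for diagnostics.
* `frequencyCutoff` (fraction of Nyquist, default 1): band limit.
* `angularUsage`: `full360` (default) back-projects every projection;
  `fold360to180` averages opposed projections first — equivalent in the
  parallel limit, halving filtering cost; `native180` for 180-degree
  acquisitions.
* Voxels outside the inscribed circle are zeroed (they are not supported
  by every view).

`fbpVolume()` processes detector rows in chunks sized to `maxRamBytes`;
chunking is a pure scheduling choice and the output is bit-identical for
any chunk size (asserted by test).

# TwIST compressive-sensing reconstruction

Sparse angular sampling accelerates OPT and lowers light dose, but FBP
from few views is streak-dominated. `twistReconstruct()` minimizes

    1/2 ||y - A x||^2 + lambda TV(x)

by the two-step iterative shrinkage/thresholding scheme

    x_{t+1} = (1 - alpha) x_{t-1} + (alpha - beta) x_t
              + beta Psi_lambda(x_t + A'(y - A x_t))

where `Psi_lambda` is an isotropic total-variation proximal denoiser
(Chambolle dual projection with a fixed inner iteration count, default
10) followed by a nonnegativity clamp (fluorescence is nonnegative;
disable via `nonnegativity = FALSE`).

Design choices, made where the method leaves them open:

* **Operator normalization.** A is scaled by its largest singular value,
  estimated by 20 seeded power iterations, so the relaxation parameters
  can be derived from an assumed spectral interval `[xi1, 1]` of `A'A`:
  `rho = (1 - sqrt(xi1)) / (1 + sqrt(xi1))`, `alpha = rho^2 + 1`,
  `beta = 2 alpha / (1 + xi1)`, with `xi1 = 1e-3`. These are the
  two-step parameters appropriate for a moderately ill-conditioned
  operator; they are exposed in `twistConfig()`.
* **Default `lambda = 0.01 * max|A'y|`** (computed after normalization):
  scale-invariant, so the same default works across intensity units.
* **Monotone variant.** A step whose objective increases is retried as a
  plain IST step (`alpha = beta = 1`); if even that fails to descend —
  possible only within the accuracy of the inexact TV prox — the
  previous iterate is kept and iteration stops. The objective trace
  (attribute `objective`) is therefore non-increasing after the first
  two iterates. Non-finite objectives abort with a diagnostic.
* **Warm start**: Hamming-filtered FBP by default (deterministic and
  several times faster than a zero start); `init` overrides.
* **Stopping**: relative objective decrease below `tol` (default 1e-4)
  or `maxIters` (default 200).
* The TV dual ascent uses step `tau = 0.248` on the gradient of `u /
  lambda`, keeping the update stable for arbitrarily large `lambda`.

# Fan-beam reconstruction for focal scanning

Focal scanning sweeps a shallow, higher-NA focal plane through the
sample during each exposure to beat the DOF/resolution trade-off, but
the scanning lens is not perfectly telecentric: magnification varies
approximately linearly with axial position. A linear magnification
trend `m(z) = m0 (1 + g z)` is exactly the first-order behaviour of a
fan of rays diverging from a vertex at distance `D = 1/g` on the optical
axis, so the package models the acquisition as flat-detector fan-beam
geometry with the virtual detector at the rotation axis.

* `calibrateMagnification()` fits apparent size vs axial position by
  least squares. Only *relative* magnification is needed:
  `g = slope/intercept` per mm and `D = intercept/slope` mm (an exact
  line `size = 100 + 2 z` gives D = 50 mm). Gradients below `1e-6` of
  the axis value are treated as telecentric (`D = Inf`). An optional
  true object size yields the absolute `m0`.
* `fanbeamReconstruct()` is the standard flat-detector fan FBP: weight
  by `D / sqrt(D^2 + u^2)`, ramp-filter as in the parallel case,
  back-project along the fan rays with the `1/U^2` distance weight,
  `U = (D + b)/D` for a voxel at signed axial distance b. The full
  acquired range is used with unit redundancy weights (a documented,
  slightly biased simplification at exactly 180 degrees). As D grows
  the result converges to `fbpSlice()`, and `D = Inf` delegates to it.
* `estimateFanOrigin()` automates the empirical choice of D: the slice
  is reconstructed over a candidate grid and the radially weighted mean
  fitted bead FWHM is minimized (off-axis tangential smearing is the
  signature artifact of assuming parallel geometry). Ties break toward
  larger D, the weaker correction. A visual, manual version of this
  choice is what an instrument operator would otherwise do.

Fan-beam validity is restricted to the central plane of the lens;
reconstructing rows far from it with the in-plane fan degrades
off-axis points. That limitation is inherited from the geometry, not
fixable in 2-D, and full 3-D cone-beam reconstruction is out of scope.

# Focal-sweep PSF and deconvolution

The conventional fixed-focus trade-off is quantified by
`conventionalResolutionLimit()`: setting the DOF equal to the sample
radius with `DOF = lambda / NA^2` fixes `NA = sqrt(lambda / DOF)` and
the Rayleigh resolution `0.61 lambda / NA`; 7 mm DOF at 550 nm gives
about 38 µm. The DOF convention and Rayleigh criterion are package
choices (several conventions differ by small constant factors); this
pair is standard and internally consistent.

`modelPsf()` uses a Gaussian-beam approximation — lateral
`sigma(z) = sigma0 sqrt(1 + (z/zR)^2)`, `sigma0 = 0.21 lambda / NA`,
`zR = n lambda / (pi NA^2)` — each plane normalized to unit integral and
weighted uniformly in z (a triangle-wave sweep cycling many times per
exposure gives uniform dwell). This is a deliberately parametric stand-in
for a full diffraction PSF: adequate for the deconvolution role and
fully testable. `projectPsf()` sums the planes and renormalizes;
`deconvolveProjections()` applies per-frame Richardson–Lucy (flux-
preserving and nonnegative, with a boundary normalization term for the
zero-padded edges) or Wiener deconvolution before reconstruction.

# Preprocessing decisions

* **Flat field**: `(frame - offset) / (background - offset)` rescaled by
  the mean gain so corrected frames keep their intensity scale; negative
  results clamp to 0; more than 1% of nonpositive gain pixels is an
  error.
* **Hot pixels**: replace only pixels deviating from their window median
  by more than `thresholdSigmas` robust sigmas. The robust sigma is the
  per-frame global `MAD * 1.4826` of the median residuals — the
  per-window alternative is unstable for 3x3 windows, and defects are
  sparse so a global scale is appropriate.
* **Bleaching**: monoexponential in projection index (a proxy for
  cumulative exposure), fitted on log frame totals above a background
  percentile; `s_p = exp(k (p-1))`, with R^2 stored so a poor fit is
  visible. Simplest physical default; the model object keeps the
  diagnostics needed to judge it.
* **Alignment**: for 360-degree data the projection at theta and the
  column-mirrored projection at theta + 180 are identical up to a shift
  of twice the axis offset. The offset comes from the peak of their
  cross-correlation averaged over opposed pairs (sub-pixel via 16x
  frequency-domain correlation upsampling plus a parabolic refinement —
  a plain three-point parabola is biased on broad peaks); the tilt from
  the linear trend of per-row-band offsets. Because a tilt mixes
  detector rows between the opposed frames, one pass carries a small
  multiplicative bias; up to three estimate-correct-re-estimate passes
  remove it. 180-degree data have no opposed pairs and require manual
  parameters, by design.

# The phantom generator: what it does and does not emulate

`phantomSpec()`/`makePhantom()`/`simulateProjections()` generate all
test data. Defaults mirror a typical mesoscopic fluorescence OPT
acquisition: a 14 mm field, 400 projections over 360 degrees. Beads are
rendered by an integrated-Gaussian footprint of the stated diameter with
a 0.7-voxel floor: 1 µm beads are far sub-voxel at a 14 mm / 128 grid
(109 µm voxels), and the floor keeps them band-limited on the grid
rather than aliased into single voxels. The simulator applies, in
order: forward projection (parallel, or central-plane fan at distance
D), optional focal-sweep blur, bleaching `exp(-k (p-1))`, rigid
misalignment, and seeded noise (Gaussian or Poisson) — noise last, so
bleach estimation sees realistic totals. All randomness flows from the
single spec seed; two runs are bit-identical.

Not emulated: refraction and scattering in the sample, depth-dependent
PSF variation across detector rows, camera fixed-pattern and read noise
beyond the two stated noise models, mechanical wobble of the rotation
stage, and out-of-plane (cone-beam) rays — fan simulation uses the same
in-plane fan for every row, matching the central-plane validity of the
fan reconstruction. Passing tests therefore demonstrate correctness of
the reconstruction mathematics and parameter recovery under the stated
acquisition physics, not robustness to every instrument imperfection of
real data.

# Problem sizes and numerical tolerances

The test-suite and acceptance problem sizes were chosen as the smallest
that keep each phenomenon in its proper regime: 256-px slices at 400
angles for absolute-intensity FBP self-consistency; 128-px slices for
the sparse-view SSIM table and the fan-beam contrast (D = 50 mm on a
14 mm field, bead rings at radii up to 0.8 field radius); 96-px,
48-row stacks for alignment recovery; 64-px stacks elsewhere. SSIM uses
the canonical constants `K1 = 0.01`, `K2 = 0.03` and a Gaussian window
`sigma = 1.5` (radius 5), the window shrinking only for images too small
to hold it. Bead fitting reports `FWHM = 2 sqrt(2 ln 2) sigma` from a
symmetric 2-D Gaussian + offset least-squares fit in a window of four
expected FWHM, with overlapping windows merged to the brighter peak and
a relative-amplitude floor (10% of the brightest excursion) suppressing
reconstruction-noise maxima on near-flat backgrounds.

One scaled-down comparison deserves a caveat: at a 128-px grid the
angular Nyquist bound is about `pi * 64 = 201` projections, so a
200-projection subset of a 400-projection acquisition is *fully
sampled*, not 2x undersampled as it would be on a full-resolution
camera. The sparse-view table therefore shows TwIST dominating FBP at
every genuinely sparse sampling (20, 40, 80), while the 200-projection
FBP — which differs from its own 400-projection reference only by
angular discretization and shares its systematic artifacts — sits near
SSIM 1 and is not a meaningful undersampling benchmark at this scale.

# Known limitations

* Fan-beam reconstruction and simulation are exact only in the central
  plane; no cone-beam (FDK) path is provided.
* The bleaching model is monoexponential; fluorophores with
  multi-component decay will show a sloped residual (visible in the
  stored R^2).
* Automatic alignment requires 360-degree coverage and features with
  detectable structure in most row bands.
* Volume output formats are OME-TIFF (32-bit float, affine-rescaled
  with the scaling recorded in the companion OME-XML; bit-exact for
  16-bit integer data) and per-slice TIFF directories. OME metadata are
  written as a companion XML file; embedded ImageDescription OME-XML is
  read but not written.
* Richardson–Lucy flux conservation is exact up to the zero-padded
  boundary correction; content touching the frame edge conserves less
  precisely.
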