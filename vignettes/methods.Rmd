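---
title: "Convex 3D deconvolution for low-photon-count widefield stacks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Convex 3D deconvolution for low-photon-count widefield stacks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(fhdeconv)
```

## The problem

A widefield fluorescence microscope records a focal stack: a sequence of 2D
images at successive focus positions. Every plane collects light from the
whole specimen, so raw stacks have poor axial contrast, and at the
exposure levels used for live-cell work (tens of photoelectrons per voxel at
the peak) photon shot noise and camera read noise are both prominent.
`fhdeconv` reconstructs the underlying 3D intensity distribution from such a
stack by minimizing a convex objective,

$$\min_{x \ge 0}\; \ell(Ax) + \nu\, \mathcal R(x),$$

where $A$ is 3D convolution with the microscope point spread function (PSF),
$\ell$ is a negative log-likelihood matched to the camera noise, and
$\mathcal R$ is the Frobenius norm of the discrete Hessian field. Convexity
matters: the solver (ADMM) reaches the global optimum of the stated model,
so reconstructions are reproducible and artifacts are attributable to the
model, not to local minima.

## PSF model

The in-focus amplitude PSF of an aberration-free, Abbe-sine-corrected
high-NA objective is the Debye diffraction integral

$$h_A(r) = \int_0^{\alpha}\sqrt{\cos\varphi}\;
J_0\!\bigl(2\pi k \sin\varphi\, r\bigr)\,\sin\varphi \, d\varphi,
\qquad \alpha = \arcsin(\mathrm{NA}/n),\; k = n/\lambda,$$

evaluated by composite trapezoid quadrature (default 256 nodes, exposed as
`n_phi`; the integrand is smooth, and 256 nodes already give ~6 significant
digits). The amplitude transfer function (ATF) is its 2D Fourier dual on
the pupil plane; defocus by $z$ multiplies the ATF by the non-paraxial
phase factor

$$D(u, v, z) = \exp\!\left\{-i 2\pi z \sqrt{k^2 -
(\mathrm{NA}/\lambda)^2 (u^2+v^2)}\right\},$$

with $(u,v)$ pupil coordinates normalized so the aperture edge is the unit
circle (the physical frequency is $(\mathrm{NA}/\lambda)\,u$; with that
reading the square root is real across the whole pupil of an immersion
objective and no paraxial approximation is involved). The intensity PSF is
the squared modulus of the defocused field. Two discretization choices
matter:

* **Pixel integration.** The field is rendered on an `oversample`-times
  finer lateral grid whose subsamples are centered within each sensor pixel,
  then block-averaged. Doubling the default `oversample = 4` changes the
  binned PSF by well under 1%.
* **Band limiting.** The numerically transformed ATF is masked to its
  analytically known support, the disk of radius $\mathrm{NA}/\lambda$. The
  raw discrete transform of a finite-window amplitude PSF inevitably leaks
  a little outside this disk (the Airy-type tails are truncated by the
  window); the mask restores the exact support.

Each xy-slice of the final PSF is normalized to sum to one. This is the
unit convention of the whole package: it makes the reconstruction's voxel
values photoelectrons collected per exposure, because a point emitter then
contributes its full flux to every focal plane.

The model PSF is depth-invariant, which is adequate for thin samples;
depth-varying and aberrated PSFs are out of scope (a measured PSF stack can
be supplied instead of the theoretical one).

## Noise model and its estimation

Scientific cameras are shot-noise plus read-noise limited. A raw value in
digital units (DN) is modeled as
$y = \gamma\,\mathrm{Pois}(\theta) + \mathcal N(0, \sigma^2)$
with gain $\gamma$ (DN per photoelectron) and read noise $\sigma$ (DN).
Dividing by $\gamma$ gives photoelectron units with normalized read noise
$\tilde\sigma = \sigma/\gamma$. The exact Poisson-Gaussian likelihood has no
closed form, so the package uses the shifted-Poisson surrogate
$\tilde y \approx \mathrm{Pois}(\theta + \tilde\sigma^2) - \tilde\sigma^2$,
which matches the mixed model's mean and variance at every photon count and
has a tractable negative log-likelihood

$$\ell(v) = \sum_{j \in C} v_j - (\tilde y_j + \tilde\sigma^2)
\log(v_j + \tilde\sigma^2).$$

Effective counts $\tilde y + \tilde\sigma^2$ can dip below zero at dark
voxels (read noise); they are clamped to zero, since the surrogate count
cannot be negative.

$\gamma$ and $\sigma$ are estimated from the focal stack itself via the
affine variance law $\operatorname{Var}(y) = \gamma\,\mathbb E[y] + \sigma^2$
that the mixed model implies. `estimate_noise_params()` collects local
mean-variance pairs over 8x8 blocks of every slice and fits the law by
iteratively reweighted least squares (weights $\propto$ 1/predicted
variance squared, the sampling variance of a local variance estimate). Two
details keep the fit unbiased, and both deviate deliberately from the most
obvious implementation:

* The local noise variance is estimated from second-difference
  pseudo-residuals $(y_{i-1} - 2y_i + y_{i+1})/\sqrt 6$ along both lateral
  axes rather than the plain block variance, which is inflated by any
  smooth signal ramp through the block.
* Textured blocks are discarded by thresholding the gradient energy of a
  3x3-smoothed copy of the slice at its 75th percentile *within intensity
  strata*. A global threshold would discard essentially every bright block
  (gradients scale with brightness) and censor the top of the mean-variance
  cloud; measuring texture on the smoothed slice stops the selection from
  keying on the block's own noise realization. With the global variant the
  fitted gain was biased about 5% low on blob-phantom stacks; the
  stratified variant recovers it to ~1-2%.

Blocks touching the saturation ceiling (99.5th percentile by default) are
dropped. If the intensity range is too narrow to identify the slope, the
estimate is flagged, the slope is reported as zero and the variance is read
directly from the residuals — on a pure-read-noise stack this returns
$\sigma^2$ instead of an arbitrary extrapolated intercept.

## Regularization

The default regularizer is the Frobenius-Hessian (FH) penalty
$\mathcal R(x) = \sum_j \lVert H_j x\rVert_F$: the voxelwise Frobenius norm
of the 3x3 matrix of second differences (pure terms as twice-applied
forward differences, mixed terms as forward differences along both axes,
replicate boundaries). It is convex and 1-homogeneous, and — unlike total
variation — vanishes on affine intensity ramps, so it promotes piecewise
*smooth* rather than piecewise constant structure and avoids TV's staircase
artifacts on biological images. The mixed components carry a factor
$\sqrt 2$ inside the operator so the plain 6-vector norm equals the matrix
Frobenius norm; no anisotropic weighting is applied even though the axial
pitch differs from the lateral pitch. For comparison studies the package
also provides Tikhonov (`l2`), squared Laplacian, lasso (`l1`), and
isotropic 3D TV, behind the same interface.

## ADMM solver

The objective is split three ways: the fidelity acts on $z_1 = Ax$, the
regularizer on $z_2 = Hx$, non-negativity on $z_3 = x$. All three proximal
updates are closed-form (shifted-Poisson: the stable positive root of a
voxelwise quadratic; FH/TV: group soft-thresholding; non-negativity:
clipping), and the x-update solves Fourier-diagonal normal equations, so an
iteration costs a fixed small number of 3D FFTs — $O(N \log N)$ per
iteration. Convergence follows from convexity; iterations stop when the
relative change $\lVert x^{k+1}-x^k\rVert_2 / \lVert x^k\rVert_2$ (over the
full reconstruction grid, margins included) drops below $10^{-3}$, or at
150 iterations.

Numerical choices:

* **Penalty parameter.** A single fixed $\rho$ couples all three splits
  (deterministic, no adaptive schedule). Its scale matters: the curvature
  of the Poisson-family likelihoods is roughly 1/counts, so a penalty that
  ignores the photon scale makes progress per iteration vanish at high
  counts. The default is $\rho = 0.2 / \overline{(\tilde y)_+ +
  \tilde\sigma^2}$, i.e. matched to the mean effective count; it is a
  configuration value, not adapted during the run.
* **Boundary handling.** The difference operators use replicate (Neumann)
  boundaries while the x-update uses the periodic transfer functions
  $|\hat A|^2$, $\sum |\hat H|^2$. The mismatch is confined to the volume
  edge and absorbed by the splitting together with the expanded boundary.
* **Initialization.** $x^0$ is the measured stack (clamped at zero,
  converted to photoelectrons) replicate-padded into the reconstruction
  grid and then flux-matched: scaled so $\sum (Ax^0)$ over the measured
  region equals the observed flux. A widefield stack carries roughly $n_z$
  times the specimen flux (every plane collects the full emission), and
  starting that heavy costs hundreds of iterations of mass shedding. The
  problem is convex, so initialization affects speed only. Because this
  initialization makes the first x-update an exact fixed point, the
  stopping rule is armed from the second iteration.
* **Diagnostics.** The per-iteration history records the objective, the
  primal residual, the dual-residual surrogate $\rho\lVert z^{k+1}-z^k\rVert$
  (the cheap standard proxy; the adjoint-mapped residual would cost two
  extra FFTs per iteration), and the relative change. The objective is not
  strictly monotone under ADMM; windowed decrease is the meaningful check.
* **Output.** The returned volume is clamped at zero so the non-negativity
  invariant holds even when the run stops short of full convergence, and is
  reported both on the full grid and cropped to the measured region.

## Undetermined boundary

FFT convolution silently assumes the volume is periodic; real stacks are
not, and the resulting wrap-around errors show up as ringing. Instead of
apodizing or padding the data, the reconstruction grid is expanded beyond
the measured region and the fidelity term simply ignores the margin. The
margin voxels then absorb whatever intensity is needed to explain edge
light. Default margins are about half the PSF extent per axis, rounded up
so each expanded dimension is a product of small primes (fast FFT sizes).
The margin content itself is not interpretable and is discarded by the
measured-region crop.

## Synthetic data generator

The simulation study uses three phantom classes that stand in for the
morphologies of typical stained structures: a **hollow shell** (membrane
stain on a 6 um microsphere; exact indicator of a spherical annulus, 300 nm
thick by default so the core is resolvable at 65 nm pitch), **filaments**
(actin-like: smoothed random curvilinear tubes with slowly turning
directions), and **blobs** (nucleus-like: soft-edged random ellipsoids).
Volumes are normalized so the maximum equals the requested peak
photoelectron count; the study photon levels follow the usual ladder from
1000 down to 10 peak photoelectrons, with camera gain 2.0 DN/e- and read
noise 3.0 DN throughout, at 65 nm lateral and 150 nm axial pitch with an
NA 1.4, n 1.51 objective at 525 nm emission.

A subtlety discovered while validating the end-to-end pipeline: if the
generator blurs the phantom by plain circular convolution on the
measurement grid, out-of-focus light wraps back into the field of view —
light that a real microscope (and the solver's expanded-boundary model)
would lose off the edges. On a 6 um shell that fills most of the field this
mismatch pushed the bulk of the reconstructed mass into the margins.
`simulate_focal_stack(pad = ...)` therefore zero-embeds the truth in an
expanded grid, blurs there, and crops the measured region, which is the
physically faithful protocol; study runs use margins matched to the
solver's.

What the phantoms deliberately do not emulate: real cellular texture,
depth-varying aberrations, pixel-to-pixel gain variation, hot pixels, and
sample motion. Tests passing on these phantoms validate the estimator and
solver contracts, not performance on any particular real specimen.

## Evaluation metrics

* `snr_db(x_hat, x_true)` $= 10\log_{10}(\lVert x_{\mathrm{true}}\rVert_2^2
  / \mathrm{MSE})$ with MSE the mean squared error. Numerator is a sum and
  denominator a mean, so the value carries a $10\log_{10} n$ offset
  relative to a pure power ratio; the convention follows the simulation
  study this package reproduces and orders methods identically.
* `nmse_affine(x_hat, ref)` fits $a\,x + b$ to the reference by Nelder-Mead
  (started at the closed-form least-squares solution) and reports the
  residual sum of squares over $\lVert \mathrm{ref}\rVert_2^2$; used when
  intensity scales are not comparable across methods. NMSE is computed on a
  representative slice rather than whole volumes; the slice index is a
  parameter defaulting to the in-focus plane.
* `tune_nu_golden()` tunes the regularization weight by golden-section
  search until the bracket gap is below $10^{-5}$, over $\log_{10}\nu$ by
  default (weights act multiplicatively; reported parameter grids are
  geometric).

## Problem sizes used in the shipped studies

The package's own acceptance studies run at sizes chosen to keep the full
suite tractable on a single CPU: noise-parameter recovery on a
256x256x22 blob stack, bead-geometry recovery on the full 128x128x57 shell
stack (reconstruction grid 160x160x75), and the noise-model/regularizer
ordering study on 48x48x12 volumes with ten noise realizations per phantom
class. The ordering claims are scale-free; absolute SNR values are not
comparable to other problem sizes.

## Known limitations

* Depth-invariant PSF only; refractive-index mismatch and aberrations are
  not modeled.
* Uniform gain and read noise across the sensor (CMOS per-pixel variation
  should be handled upstream by flat-field correction).
* The exact Poisson-Gaussian likelihood is approximated by the
  shifted-Poisson surrogate (moment-matched; the approximation is weakest
  at very low counts with large read noise).
* The ADMM penalty is fixed per run; extreme photon levels far outside the
  calibrated range may need a manual `rho`.
* The dual-residual history is a surrogate; stopping is governed by the
  relative-change rule, as stated.
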