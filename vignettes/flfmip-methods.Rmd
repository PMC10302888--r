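---
title: "Models and methods in flfmip"
author: "flfmip authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in flfmip}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flfmip)
```

# The measurement this package models

Fluorescence-detected mid-infrared photothermal Fourier light-field
(FMIP-FLF) microscopy combines two ideas:

1. **Fourier light-field (FLF) imaging.** A lenslet array at a pupil-conjugate
   plane splits the fluorescence into a small grid of *elemental images* —
   perspective views recorded side by side on one camera frame. Because each
   lenslet looks through a different patch of the objective pupil, an emitter
   that moves axially translates *laterally* in each elemental image
   (parallax), at a rate and direction set by that lenslet's pupil offset.
   One 2D snapshot therefore encodes a 3D volume.
2. **Mid-infrared photothermal (MIP) readout.** A pulsed mid-IR pump heats
   wherever the specimen absorbs at the pump wavenumber. Thermosensitive
   fluorescent dyes lose roughly 1% of their brightness per Kelvin, so the
   IR-on frame is dimmer than the IR-off frame exactly where the targeted
   vibrational band (e.g. the lipid ester C=O stretch at 1744 cm^-1^)
   absorbs. The IR-off minus IR-on difference is a chemical image.

Each FMIP volume consumes exactly two camera frames (one IR-on, one IR-off),
so the volume rate is half the frame rate — a 16 fps camera yields 8
volumes per second.

# Forward model

A camera frame is modeled as the axial sum of 2D convolutions between each
object slice and the depth-matched light-field PSF:

$$ y \;=\; H x \;=\; \sum_z x_z \circledast h_z . $$

`project()` implements $H$ with zero-padded (linear, never circular) FFT
convolutions; `adjointProject()` implements $H^\top$ as per-depth valid
cross-correlation. Two conventions matter:

* **Full-support canvas.** The output frame is the full linear-convolution
  support (object + PSF − 1 per axis). With this choice forward and adjoint
  are exact matrix transposes, which the inner-product test verifies to
  machine precision and every ADMM step relies on.
* **One composite canvas.** All elemental images live on a single canvas and
  a single 2D convolution per depth handles them all. This presumes the
  lateral object support does not exceed one elemental-image pitch —
  physically, the instrument's iris at the native image plane enforces
  exactly this. If a synthetic object is made wider than the elemental
  pitch, elemental images overlap and the inverse problem acquires
  translation ghosts at multiples of the pitch; the default canvas sizing in
  `simulatePsfStack()` (lenslet grid × field of view) respects the
  constraint.

Under per-slice-sum-one PSF normalization (the default), projection
conserves total flux, which makes adjoint and linearity tests clean.
Operators run in 64-bit floats; FFT lengths are rounded up to 2/3/5-smooth
sizes.

# PSF model and calibration

The real instrument measures its PSF once, by scanning a single
sub-resolution bead axially in 100 nm steps. The simulator reproduces the
two behaviors that measurement shows, without a wave-optics integral:

* **Parallax:** the elemental spot of the lenslet at normalized pupil offset
  $p$ (fraction of the pupil radius; for a 2 × 2 array with occupancy
  $N = 2$, $p = \pm 1/2$ per axis) translates by $\mathrm{NA} \cdot p$
  micrometers laterally per micrometer of depth — the sine-condition
  marginal-ray slope scaled to that pupil position.
* **Defocus:** each spot is a Gaussian (or Airy) profile with
  $\sigma(z) = \sqrt{\sigma_0^2 + (\mathrm{NA}_{\rm eff}\, z / 2)^2}$, where
  $\mathrm{NA}_{\rm eff} = \mathrm{NA}/N$ is the sub-aperture NA seen
  through one lenslet and $\sigma_0$ comes from the diffraction-limited
  in-focus width $\mathrm{FWHM}_0 = 0.51\,\lambda_{\rm em}/\mathrm{NA}_{\rm eff}$
  (≈ 0.60 µm at 560 nm, NA 0.95, N 2).

This is deliberately a *geometric* model: no aberrations, no diffraction
integral, no depth-dependent magnification. Conclusions that depend on fine
PSF structure (side lobes, spherical aberration) are outside what passing
tests demonstrate about real hardware.

`calibratePsfFromBeads()` mirrors the experimental calibration on a bead
z-stack: a per-slice percentile background floor (default 10th percentile)
is subtracted, negatives are clipped, the stack is normalized, and the bead
image centroid is recorded per slice. The stack must contain one bead; at
the best-focus slice each elemental image is checked for a single connected
bright region, and a second region raises an ambiguity error. On a noiseless
simulated stack calibration inverts simulation to better than 1e-6 relative
L2 — the background floor only removes far-tail values that are numerically
negligible.

# Reconstruction

`reconstruct()` solves

$$ \hat x = \arg\min_{x \ge 0}\; \tfrac12 \lVert Hx - y\rVert_2^2
   + \lambda_{\ell_1} \lVert x\rVert_1 + \lambda_{\rm TV}\,\mathrm{TV}_{3D}(x) $$

by consensus ADMM with three splits: an $\ell_1$ copy (soft-thresholding), a
gradient-field copy (isotropic-TV group shrinkage), and a nonnegativity copy
(projection). The quadratic x-update is solved by warm-started conjugate
gradients on the normal equations in operator form (8 inner iterations by
default); $H$ is never materialized.

Choices the problem statement leaves open, and what this package does:

* **TV flavor and boundary:** isotropic TV over forward differences with
  replicate boundary (the last difference along each axis is zero; axes of
  length one contribute nothing). `tv3d()` exposes the regularizer and is
  tested against a brute-force reference.
* **Nonnegativity** is enforced by default even though the objective alone
  does not require it: fluorophore density is physically nonnegative.
  Photothermal *difference* volumes may carry either sign; there the
  difference frame is flipped to its dominant sign before the constrained
  solve and flipped back (see below).
* **Penalty parameter:** fixed $\rho = 1$, no adaptive scheme. Keeping
  $\rho$ fixed makes every update positively homogeneous, so scaling the
  measurement and both $\lambda$s by $c > 0$ scales the entire iterate
  sequence by $c$ — the scaling-equivariance property tested to 1e-6.
* **Defaults** ($\lambda_{\ell_1} = 10^{-3}$, $\lambda_{\rm TV} =
  2\times10^{-4}$, 60 iterations) were tuned once on the single-bead
  phantom, for measurements normalized to unit peak. They are config
  values, not constants of nature: rescale them with your data.
* **Stopping:** relative iterate change below `relTol` (1e-6) or
  `maxIters`; the convergence flag, objective trace and primal/dual
  residual norms are always returned.
* **Depth clipping:** reconstruction content far outside the PSF's axial
  support is unreliable and shows up as edge artifacts, so slices farther
  than `depthClipAxialFwhmMultiplier` (default 2) times the PSF's axial
  FWHM from its best-focus plane are zeroed post hoc. Set 0 to disable.

The reported objective is the merged value
$\tfrac12\lVert Hx-y\rVert^2 + \lambda_{\ell_1}\lVert x\rVert_1 +
\lambda_{\rm TV}\mathrm{TV}(x)$ at the (projected) iterate; it is checked to
be non-increasing after a 5-iteration burn-in. With all regularizers off and
no constraint the solver falls back to plain CG on the normal equations,
whose quadratic objective is monotone by construction.

# Photothermal signal extraction

The sign convention is **off − on**: thermosensitive dyes dim when heated,
so positive FMIP means absorption. `fmipDifference()` never clips negative
pixels (clipping is a display decision); it also logs — but does not correct
— the integer cross-correlation drift between the two frames, since a
snapshot instrument should hold registration to well under a pixel.

`fmipRatio()` divides the difference by the IR-off baseline,
$(I_{\rm off}-I_{\rm on})/\max(I_{\rm off}, \text{floor})$, masking pixels
below the floor (default: 1% of the frame's 99th-percentile intensity).
The ratio is the detector-gain-invariant quantity proportional to local
absorption; on a uniformly modulated object it equals the modulation depth
exactly.

`reconstructFmipVolume()` defaults to *diff-then-recon* — deconvolve the
difference frame directly, which is what makes one volume cost two frames —
with *recon-then-diff* available for comparison; unregularized and noiseless
the two agree by linearity. Because the difference is ~1% of the raw
signal, each frame handed to the solver is normalized to unit peak and the
result rescaled, so the default regularization weights keep their meaning
at any gain or modulation depth.

# Spectra and isotope ratios

An FMIP spectrum is the ROI-mean FMIP volume value at each pump wavenumber;
replicates (e.g. N = 3 cells) contribute mean and standard deviation per
point. Photobleaching limits a sweep to about six wavenumbers, which drives
several choices in `fitLorentzian()`:

* the line model is a Lorentzian plus a **constant baseline** (attributed to
  water absorption inside cells; no functional form is established, so a
  constant is the least-committal choice, with a linear option available);
* a **single component** is the default — six points cannot support two
  free Lorentzians (8+ points required for `nComponents = 2`);
* initialization is **multistart** over 5 candidate centers spanning the
  sampled range, keeping the best converged fit by RSS, because sparse
  sampling makes single-start NLS prone to local minima;
* a fitted amplitude that does not clear 3× the residual noise flags the
  center as unreliable (a flat spectrum has no meaningful center).

`peakRatio()` computes the 1704/1744 cm^-1^ ROI-mean intensity ratio — the
fraction of lipid built from ^13^C-labeled fatty-acid uptake relative to de
novo synthesis — plus per-droplet ratios with box-plot summaries. Droplets
are segmented on the 1744 volume by Otsu threshold and 6-connected
components of at least 4 voxels; both routines are implemented in-package
(no installed package labels 3D connectivity) and tested against
hand-computed cases.

# The synthetic phantom: what it emulates, and what it does not

`generateVolume()` builds three scene types with full ground truth:
sub-voxel **beads** (resolution studies; a 175 nm bead is well below the
0.3 µm voxel, so it grids to one voxel), **rods on a tilted substrate**
(bacteria dried on tilted silicon, spreading depth across the axial range),
and a **cell with lipid droplets** (spherical droplets in an ellipsoidal
cytoplasm, nucleus excluded, a configurable fraction carrying the
isotope-shifted band).

Spectral ground truth per object class is a set of Lorentzian bands,
defaulting to 1744 cm^-1^ (endogenous lipid C=O), 1704 cm^-1^ (the
^13^C-shifted carbonyl — the in-cell FMIP peak position; note the *neat*
fatty-acid FTIR shift is ~30 cm^-1^, a separate printed fact kept as a
separate parameter), and 1650 cm^-1^ (protein amide-I), each with 10-15
cm^-1^ HWHM.

The photothermal physics in `generateFramePair()`:
$m(\mathbf r) = (\text{modulation/K}) \cdot \Delta T \cdot
\sum_b L_b(\nu)\, A_b(\mathbf r)$, each band's Lorentzian normalized to 1
at its center. Modulation is applied **multiplicatively to the fluorescence
before projection** — heating happens at the object, not on the camera.
The temperature field is taken proportional to local absorption with no
diffusion blur: the thermal diffusion length for a 50 ns pulse in water,
$\sqrt{4 D \tau} \approx 165$ nm, is sub-voxel at 0.3 µm sampling.
Defaults: 1%/K modulation, a 1 K peak temperature rise (the real rise is
not established; 1 K is a conservative, physically plausible scene scalar).

Noise is Poisson shot noise at a photon budget (default 10 000 expected
photons at the brightest IR-off pixel — a realistic CMOS well depth) plus
additive Gaussian read noise (default 2 photons RMS), drawn independently
for the on and off frames. All randomness flows from the single `seed`
(frame pairs fold in the rounded wavenumber so a sweep gets independent
noise; `noiseSeed` overrides this for replicate acquisitions), and a fixed
seed reproduces output byte for byte.

When a target SNR for the photothermal channel is needed, the package's
convention is the **peak-pixel difference SNR**: the difference signal at
the brightest pixel, $m \cdot B$, over its shot noise $\sqrt{2B}$, so a
budget $B = 2\,(\mathrm{SNR}/m)^2$ realizes a given SNR at modulation depth
$m$ (SNR 10 at 1% modulation needs $2\times10^6$ photons — achievable with
the long exposures the photothermal protocol already uses). Spectral-sweep
benchmarks run at this SNR with N = 3 replicate acquisitions averaged per
wavenumber, mirroring the real protocol's per-point replication.

What the phantom does **not** model — and therefore what passing tests do
not show about real data: photobleaching kinetics (the six-wavenumber cap
stands in for it), heat diffusion and thermal decay between pulses,
mechanical drift between frames, aberrations, autofluorescence background,
and depth-dependent magnification.

# Resolution metrics

`fwhmGaussian()` fits amplitude, center, width and constant offset by
nonlinear least squares and reports
$\mathrm{FWHM} = 2\sqrt{2\ln 2}\,\sigma$; it is exact on model profiles,
invariant to intensity scale and offset, errors on flat profiles and warns
on multimodal ones. `resolutionReport()` locates each bead's reconstructed
maximum (quadratic sub-voxel peak interpolation), extracts x/y/z line
profiles through it, fits each, and excludes beads closer than 3× an
expected FWHM to a neighbor. `thermalDiffusionLength()` is
$\sqrt{4 D \tau}$ with water's diffusivity $D = 1.38\times10^{-7}$ m²/s as
the documented, overridable default; any water-like $D$ (1.3-1.5 ×
10^-7^ m²/s) reproduces ~165 nm for a 50 ns pulse within a few percent.

# Problem sizes and runtimes

The package's own test and benchmark sizes, chosen to exercise every code
path at interactive cost: operator identities on 16 × 16 × 4 volumes with
8 × 8 PSFs; ADMM behavior on 12 × 12 × (3-5) grids; the end-to-end
resolution benchmark on the full instrument configuration at 64 × 64 × 16
voxels (0.3 × 0.3 × 0.35 µm, 128 × 128 PSF canvas, ~1 min on one core);
and six-wavenumber spectral sweeps at 32 × 32 × 7 (a few seconds per
reconstruction). Larger grids scale as (FFT size × depths × iterations).

# Known limitations

* The PSF is geometric; quantitative agreement with a measured PSF beyond
  its parallax slopes and width trends is not claimed.
* Composite-canvas deconvolution assumes the iris constraint; objects wider
  than one elemental pitch produce pitch-translation ghosts.
* ADMM with fixed ρ can converge slowly on poorly scaled inputs; normalize
  measurements to unit peak (the FMIP path does this internally).
* With six points, the Lorentzian center's confidence interval from `vcov`
  is approximate at best; treat `seCenter` as indicative.
* No absolute concentration calibration is attempted: FMIP intensity is
  proportional to absorption only up to dye response and thermal factors.
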