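# flfmip

Simulation and reconstruction for **fluorescence-detected mid-infrared
photothermal Fourier light-field (FMIP-FLF) microscopy** — high-speed 3D
chemical imaging that reads mid-IR absorption through the temperature
sensitivity of fluorescent dyes.

## Who this is for

FMIP-FLF acquires an entire 3D chemical volume from two camera snapshots:
a lenslet array at a pupil-conjugate (Fourier) plane splits the fluorescence
into a 2 × 2 grid of perspective *elemental images* on one frame, and a
pulsed mid-IR pump modulates the fluorescence (~1% per Kelvin of
photothermal heating) wherever the specimen absorbs at the pump wavenumber.
This package is for people building, simulating, or analyzing data from such
instruments: it implements the full computational pipeline — PSF simulation
and bead-stack calibration, the light-field forward operator, regularized
3D deconvolution, photothermal signal extraction, vibrational spectroscopy,
and resolution metrics — exercisable end to end on ground-truthed synthetic
phantoms, with no hardware required.

## The model

A camera frame is the axial sum of 2D convolutions between the object
slices and depth-dependent light-field PSFs:

```
y = H x = Σ_z  x_z ⊛ h_z
```

Volumes are recovered by ADMM-solved regularized least squares,

```
x̂ = argmin_{x ≥ 0}  ½‖Hx − y‖² + λ₁‖x‖₁ + λ_TV · TV₃D(x) ,
```

with soft-thresholding (ℓ1), isotropic-TV group shrinkage, nonnegativity
projection, and a conjugate-gradient quadratic step in operator form.
The photothermal (FMIP) signal is the IR-off minus IR-on difference,
normalized by the IR-off baseline:

```
FMIP ratio = (I_off − I_on) / I_off   ∝  local mid-IR absorption at ν
```

Sweeping the pump over ~six wavenumbers (1690–1745 cm⁻¹ for lipid work)
and fitting a Lorentzian `A·γ² / ((ν − ν₀)² + γ²) + b` locates vibrational
bands; the 1704/1744 cm⁻¹ intensity ratio separates lipids built from
¹³C-labeled fatty-acid uptake from de novo synthesized lipid. See the
methods vignette (`vignettes/flfmip-methods.Rmd`) for every model
assumption and default.

## Worked example

A single lipid droplet in a cell phantom, imaged through the simulated
2 × 2 light-field optics with the pump at the 1744 cm⁻¹ ester C=O band.
The photon budget of 2 × 10⁶ gives the photothermal difference signal a
peak-pixel SNR of 10 (signal 0.01·B against shot noise √(2B)):

```r
library(flfmip)

cfg <- opticalConfig(fovUm = c(9.6, 9.6), zRangeUm = c(-1.05, 1.05))
psf <- simulatePsfStack(cfg)
psf
#> PSFStack: 64 x 64 canvas, 7 depths [-1.05, 1.05] um (per-slice-sum-one)

spec <- phantomSpec(kind = "cell-with-droplets",
                    geometry = list(cellRadiusUm = 3, nucleusRadiusUm = 0.5,
                                    nDroplets = 1,
                                    dropletRadiusRangeUm = c(0.8, 0.8)),
                    photonBudget = 2e6, seed = 1)
vols <- generateVolume(spec, cfg)
pair <- generateFramePair(vols, psf, 1744, spec)   # IR-on / IR-off snapshot
r <- fmipRatio(pair)
median(r[imageData(pair@irOff) > 0.5 * max(imageData(pair@irOff))], na.rm = TRUE)
#> [1] 0.0101
```

The ratio on the droplet image is ~0.01: the 1%/K modulation at 1 K,
recovered from the frame pair. Reconstructing the FMIP volume at six pump
wavenumbers and fitting the spectrum over the droplet voxels:

```r
fmip <- reconstructFmipVolume(pair, psf, reconSettings(maxIters = 25L))
fmip
#> Volume: 32 x 32 x 7 voxels (0.3 x 0.3 x 0.35 um), signed

nus <- seq(1690, 1745, length.out = 6)
volumes <- lapply(nus, function(nu)
  reconstructFmipVolume(generateFramePair(vols, psf, nu, spec), psf,
                        reconSettings(maxIters = 25L)))
fit <- fitLorentzian(extractSpectrum(nus, volumes,
                                     imageData(vols$fluorescence) > 0))
fit[, c("centerCm1", "hwhmCm1")]
#>   centerCm1  hwhmCm1
#> 1  1743.915 10.44169

thermalDiffusionLength(50e-9) * 1e9   # nm heat spreads during one IR pulse
#> [1] 166.1325
```

The fitted band center lands within 0.1 cm⁻¹ of the generator's 1744 cm⁻¹
ground truth (with its 10 cm⁻¹ half width recovered), and the 50 ns pump
pulse confines heating to ~166 nm — below the optical resolution, so the
photothermal effect does not blur the image.

## Command-line interface

A thin CLI over the same functions is installed at `exec/flfmip`
(subcommands `psf-simulate`, `psf-calibrate`, `recon`, `mip`, `phantom`,
`metrics-resolution`); image stacks travel as 32-bit float multi-page TIFF
with YAML sidecars for grid metadata.
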