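---
title: "Models and methods behind spiralpam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind spiralpam}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spiralpam)
```

spiralpam is a desk-scale simulator of a handheld spiral-scanning
photoacoustic microscope built around a resonant fiber cantilever and a
transparent ultrasound transducer (TUT). This vignette records the models the
package implements, the parameters that matter, and the design choices made
where the instrument's description left the design open. Every number quoted
here is computed by the package's own tests or the acceptance script; nothing
is asserted that the code does not reproduce.

## Resonant fiber scanner

A single-mode fiber glued to the tip of a piezo tube is a clamped-free
Euler-Bernoulli beam. Its flexural resonance is

$$\omega = \beta \sqrt{E/\rho}\; R / L^2,$$

with Young's modulus $E$, density $\rho$, fiber radius $R$ and free length
$L$. For a circular cross-section the radius of gyration is $R/2$, so the
first-mode constant is $\beta = \lambda_1^2/2$ with
$\lambda_1 = 1.8751$ the first root of $\cos\lambda\cosh\lambda = -1$.
`resonant_frequency()` evaluates this closed form; the test suite checks it
against an independent finite-difference eigenvalue solve of the beam
operator to 0.5 % across random specifications. A silica fiber
($E = 73$ GPa, $\rho = 2200$ kg/m³, $R = 62.5$ µm) at $L = 18$ mm gives
310.9 Hz, consistent with the 327-335 Hz resonance band observed on the real
probe and its 333 Hz operating point.

One scan cycle is 1 s of imaging, 0.2 s of active braking and 0.3 s of free
decay — 1.5 s per volume. Design choices where the hardware description is
silent:

* **Ramp shape.** The drive amplitude "gradually increases"; we use a linear
  0→1 ramp over the imaging phase, which gives uniform radial pitch between
  spiral turns (the premise of the stepped-PRF density design).
* **Chirality and axes.** $x = A\sin\omega t$, $y = A\cos\omega t$: the $y$
  channel leads by a quarter period and the spiral is counter-clockwise in a
  right-handed probe frame. The hardware does not specify handedness.
* **Braking.** Modeled as the same quadrature drive, 180° phase-opposed, with
  amplitude falling linearly to zero over the braking phase. No braking gain
  is documented; the kinematic tip amplitude is taken to follow the drive.
* **Free decay.** Exponential envelope with time constant
  `decay_time_constant`, default `decay_duration / 3` so the residual
  amplitude is below 5 % at the cycle end. The measured decay constant is not
  documented, so it is a configuration parameter.
* **Dynamic model.** `simulate_trajectory(model = "dynamic")` integrates a
  driven damped oscillator per axis with natural frequency from the beam
  formula and quality factor $Q = \pi f \tau$ — tying the only observable
  (the free-decay envelope $\tau$) to the oscillator — then rescales so the
  imaging phase ends exactly at `max_radius`. The analytic Lorentzian gain
  predicts that scale to within 1 %, which the tests assert.
* **Trajectory sampling.** Default 500 kHz, equal to the highest laser PRF,
  so trigger positions are linear interpolations between samples 2 µs apart
  and never extrapolations.

## Stepped-PRF triggering and illumination density

An outward spiral with constant angular rate covers area at a rate that grows
linearly in time, so a constant laser PRF concentrates pulses at the center.
The canonical five-step schedule (20 kHz at 0.05-0.1 s, 100 kHz, 200 kHz,
250 kHz, then 500 kHz from 0.4-1 s; laser off before 0.05 s while the beam
still dwells near the center) equalizes the areal density. Generating the
full train yields 356,000 triggers; per-step counts use
`floor(duration * prf)` with a $10^{-9}$ guard because, e.g.,
$0.6 \times 5\times10^5$ is fractionally below 300,000 in binary floating
point.

`density_map()` interpolates beam positions at fire times, bins them with the
same pixel-assignment rule as the reconstruction module (a shared routine, so
the two stages can never disagree), and records which pixels the beam
traversed during laser-on time. On the 512 × 512 grid over the 2.6 mm field
of view the simulation yields between 0 and 6 shots per traversed pixel
(mean 1.74, fill factor 0.993 over the field of view). The idealized design
band of 1-5 shots per pixel follows the analytic density-versus-time curve;
exhaustive binning cannot reach a minimum of 1, by counting alone: the
20 kHz step delivers 1,000 shots into an annulus of roughly 1,540 pixels.
The handful of 6-shot pixels sits just outside the 0.4 s jump to 500 kHz
where the analytic density peaks. `fill_factor()` and `frequency_sweep()`
reproduce the aliasing behavior: coverage rises with scan frequency until
the pulse train phase-locks to the spiral (integer PRF/frequency ratios
leave radial spoke gaps).

## KLM transducer model

`klm_two_way_response()` implements the KLM equivalent circuit: the piezo
layer is an acoustic transmission line tapped at its midpoint by the
electrical branch through a frequency-dependent transformer, with matching
and backing layers as transmission-line two-ports into semi-infinite loads.
Rather than quoting one of several textbook variants, the element values are
derived from the exact piezo three-port:
$\phi(\omega) = \omega Z_c / (2 h \sin(\gamma/2))$ and
$X_1 = h^2 \sin\gamma / (\omega^2 Z_c)$, with $\gamma$ the acoustic phase
across the piezo and $h = k_t\sqrt{\rho v^2/\varepsilon^S}$. The test suite
holds this against an independent Mason impedance-matrix solver; the two
agree to machine precision on a bare plate, and to 1 % peak / 3 % shape on
random plates (the acceptance property).

The printed stack is 94 µm lithium niobate, a 30 µm 0-3 ceramic-epoxy
composite first matching layer, 19 µm epoxy second matching and a 1 mm epoxy
backing on a 6 × 6 mm element into water at 50 Ω. Material constants are not
part of the printed design, so the package ships an editable table
(`pam_materials()`):

* LNO 36° rotated Y-cut: $v = 7340$ m/s, $\rho = 4640$ kg/m³, $k_t = 0.49$,
  clamped relative permittivity 39 — standard thickness-mode values.
* Composite: $v = 4000$ m/s — the quarter-wave velocity implied by the
  printed 30 µm at 33.5 MHz ($4 f t = 4020$ m/s) — and
  $\rho = 2400$ kg/m³, i.e. $Z = 9.6$ MRayl, close to the DeSilets two-layer
  optimum $Z_p^{4/7} Z_w^{3/7} \approx 8.9$ MRayl for LNO into water.
* Epoxy (EPO-TEK-301 class): $v = 2650$ m/s, $\rho = 1150$ kg/m³.

Two further choices: the 1 mm backing is treated as a semi-infinite epoxy
load, because a lossless 1 mm layer terminated in air would ring with a
1.3 MHz comb that the real, lossy backing suppresses (per-layer loss hooks
exist but default off, since no loss values are documented); and the
sub-micron ITO/gold electrodes are acoustically ignored. With these
defaults the simulated two-way response has a center frequency of 35.0 MHz
and a −6 dB fractional bandwidth of 73.6 %, against design values of
33.5 MHz and 68.3 % — both inside the ±10 % band that device-to-device
fabrication tolerance already implies. Band metrics interpolate the
outermost −6 dB crossings linearly on the 4096-point, 0-150 MHz default
grid; the time-domain pulse is the Hermitian inverse FFT with zero-phase
reference at the grid origin.

## Phantoms

`make_vessel_phantom()` grows biased random-walk tubes: per-step Gaussian
direction perturbation (the `tortuosity` parameter, radians), confined depth
drift, branching with fixed probability at 70 % of the parent diameter, and
sphere-stencil rasterization at absorption 1. Ground-truth centerlines and
diameters ride along in metadata so reconstruction and morphometry can be
scored without segmentation in the loop. Edge, grid and point targets are
exact geometric primitives (the edge sits precisely at the grid midline).
All generators are deterministic under their seed.

What the generator emulates: tortuous, branching, depth-banded absorbing
tubes with controllable diameter statistics — enough to give the vessel
metrics non-trivial ground truth. What it does not emulate: optical fluence
and scattering in tissue, acoustic heterogeneity and attenuation, flow, or
physiological contrast. Passing tests therefore validate the geometry and
signal chain, not tissue realism.

## Synthetic acquisition

The forward model for one A-scan: the initial pressure line is the
absorption volume weighted by a separable lateral Gaussian around the beam
axis; depth maps to time by **one-way** flight $t = z/c$ (photoacoustic
reception — unlike the transducer characterization, which is pulse-echo);
the line is convolved with the transducer's two-way impulse waveform,
sampled at 250 MHz, and seeded white Gaussian noise is added. Receive
sensitivity is flat across the field of view (measured nonuniformity on the
real probe is ≤ 1.85 dB) and the beam width is depth-independent by default.

One numerical constraint worth stating: the focal-spot sigma must be
resolvable on the phantom's voxel grid ($\sigma \gtrsim$ half a voxel).
A 3 µm spot on a 40 µm grid degenerates into a nearest-voxel lottery. The
desk-scale pipeline defaults therefore use a spot-to-pixel ratio matching
the real system (7 µm spot over 5 µm pixels), i.e. 12 µm sigma on the
default ~20 µm grid; resolution studies use fine grids with the true 3 µm
class spot.

## Reconstruction

Scattered (position, A-scan) samples become a regular volume by the
three-case rule: a pixel with exactly one sample takes that trace verbatim;
with several, their element-wise mean; an empty pixel inside the
field-of-view disc takes an inverse-distance-weighted blend of its
`k_neighbors = 4` nearest directly-hit pixels at power 1, applied to whole
traces with the same weight at every depth sample. The position-to-pixel map
anchors pixel centers 0 and `grid_size - 1` at ∓FOV/2 and rounds half away
from zero (so position (0, 0) on a 512 grid is pixel (256, 256)); the
manufacturer's proprietary sensor formula is replaced by this documented
affine map, which is exact in simulation because true positions are known.
Envelopes are analytic-signal magnitudes via FFT; the maximum amplitude
projection takes the per-pixel envelope maximum over depth, and the
depth-encoded image its argmax with a 5 % amplitude floor for background.

## Quantification

* **Lateral resolution**: the averaged profile across an edge target is fit
  to $a + b\,\Phi((x - x_0)/\sigma)$; the line-spread function is its
  Gaussian derivative and FWHM $= 2\sqrt{2\ln 2}\,\sigma$. Fits whose
  relative RMS residual exceeds a threshold (default 0.1) are rejected
  rather than reported.
* **Axial resolution**: Gaussian fit to the Hilbert envelope of a
  point-target A-line, FWHM converted through one-way $c$. A 31.3 ns
  envelope FWHM corresponds to the probe's 47 µm axial resolution at
  1500 m/s, which the tests recover through the full fit.
* **SNR**: $20\log_{10}$(peak in signal ROI / noise-ROI standard deviation).
* **Vessel morphometry** on a thresholded mask (Otsu by default, fixed
  threshold available): VAD = vessel area / imaging area; VSD = skeleton
  length / imaging area; VDI = area / skeleton length; VCI = perimeter² /
  (4π · area). The skeleton is Zhang-Suen thinning with diagonal steps
  counted √2. The perimeter uses Freeman chain codes with the
  Vossepoel-Smeulders corner correction: a raw 8-connected chain
  overestimates a smooth boundary by up to ~5.5 %, and since VCI is
  quadratic in perimeter that alone would push a disc's VCI to ~1.11; with
  the corrected estimator a digital disc lands within 5 % of the
  isoperimetric limit of 1. VDI × VSD = VAD holds algebraically and is
  asserted to machine precision.
* **Macro/micro split** at 100 µm diameter: local diameter is
  $2d - 1$ pixels from the Euclidean distance transform at the skeleton
  (the transform runs center-to-center, half a pixel beyond the boundary on
  each side), propagated to every vessel pixel via its nearest skeleton
  pixel.
* **Frame series**: per-frame mask density and mean in-mask amplitude in dB
  relative to a baseline frame, using the $20\log_{10}$ amplitude
  convention throughout.

The published in vivo numbers (tumor-versus-normal VAD/VSD/VDI/VCI, the 60 %
epinephrine density drop, lymphatic dB changes) require animal data; the
operations that compute them are all here and are exercised on constructed
phantoms with known ground truth instead.

## Reproducibility and problem sizes

`run_pipeline()` fans a single global seed out to fixed per-stage seeds
(global + 101 × stage index), so re-running one stage reproduces its slice
of a full run; two runs of the same configuration are bit-identical, which
the tests assert. The default pipeline divides the PRF schedule by 100
(`prf_divisor`) and reconstructs on a 128-pixel grid: a full synthetic
acquisition then runs in minutes on one CPU. The test suite uses 48-96 pixel
grids, 64³-class phantoms and 3,560-shot acquisitions; the acceptance script
runs the full 356,000-trigger density simulation (seconds) and the full
4096-point KLM solve.

## Known limitations

* No wave-propagation acoustics (no diffraction, refraction or attenuation);
  the forward model is a weighted line integral plus convolution.
* No piezo-tube hysteresis, cross-axis coupling or whirl; the braking and
  decay amplitude profiles are modeling choices, not measurements.
* Composite matching-layer constants are literature defaults, not measured;
  the KLM band metrics inherit their uncertainty.
* The shot-count uniformity band is evaluated on beam-traversed pixels; see
  the density section for why a strict minimum of 1 is unreachable under
  point binning.
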