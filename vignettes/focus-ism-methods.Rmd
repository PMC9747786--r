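---
title: "STED-ISM simulation, pixel reassignment and focus-ISM: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{STED-ISM simulation, pixel reassignment and focus-ISM: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(focusISM)
```

# The imaging model

A laser-scanning microscope with a 5×5 detector array records, at every
scan position $\mathbf{x}_s$, a small wide-field image of the illuminated
region — the *micro-image* $i(\mathbf{x}_d \mid \mathbf{x}_s)$ over the
detector coordinate $\mathbf{x}_d$. Read the other way, the dataset is a
set of 25 *scanned images* $i(\mathbf{x}_s \mid \mathbf{x}_d)$, one per
element $(n, m) \in [-2, 2]^2$. The scanned point spread function of
element $(n,m)$ is

$$h_{n,m}(\mathbf{x}, z) \;=\; h_\mathrm{exc}(\mathbf{x}, z)\,
\eta(\mathbf{x}, z)\;\cdot\;
\bigl(h_\mathrm{det}(\cdot, z) \circledast \Pi_{n,m}\bigr)(\mathbf{x}),$$

the product of the effective excitation (excitation PSF times the
depletion survival $\eta$) and the detection PSF integrated over the
element's active area $\Pi_{n,m}$. `scanned_psf_stack()` evaluates this
on the configuration grid; all defaults reproduce a far-red STED-ISM
system: $\lambda_\mathrm{exc} = 646$ nm, $\lambda_\mathrm{det} = 669$ nm,
$\lambda_\mathrm{STED} = 775$ nm, NA 1.4 (oil), a 5×5 array spanning 1.4
Airy units (1 AU $= 1.22\,\lambda_\mathrm{det}/\mathrm{NA}$) at fill
factor 1, and a $127^3$ voxel grid with 10 nm voxels. In-focus questions
need only the focal plane, so most computations here use `grid_shape =
c(1, 127, 127)`; 3D stacks use coarser lateral sampling (20 nm) to keep
simulation times in seconds.

## Focal fields

Two field models are provided (`focal_intensity()`).

* **`"debye"`** (default). The flat-phase beams use the scalar Debye
  pupil integral
  $A(r,z) = \int_0^1 P(\rho)\, J_0(2\pi \mathrm{NA}\, r\rho/\lambda)\,
  e^{i\phi_z(\rho)}\rho\, d\rho$ with defocus phase
  $\phi_z(\rho) = (2\pi/\lambda)\, z\, n\sqrt{1 - (\mathrm{NA}\rho/n)^2}$,
  so the in-focus detection profile is exactly the Airy pattern (first
  zero $0.61\lambda/\mathrm{NA}$). The depletion vortex uses the
  aplanatic vectorial (Richards–Wolf) treatment of a circularly polarized
  charge-1 helical ramp: three focal components carrying $J_1$
  (co-rotating), $J_2$ (longitudinal) and $J_3$ (counter-rotating) radial
  profiles. The choice matters: a purely scalar vortex has *exact*
  secondary ring nulls where depletion would vanish entirely, letting the
  excitation Airy sidelobes leak through at high saturation; the
  vectorial components fill those nulls, as they do in a real microscope,
  while preserving the strict on-axis null.
* **`"gaussian"`**. Analytic stand-ins — a Gaussian of FWHM
  $0.51\lambda/\mathrm{NA}$ and a doughnut $\propto r^2 e^{-r^2/\sigma^2}$,
  both with a defocus-broadened $\sigma(z) = \sigma_0\sqrt{1+(z/z_R)^2}$
  and per-plane energy conservation — for fast tests and for the
  textbook geometry checks below.

The laser beams (excitation and depletion) carry their Gaussian profile
into the pupil; `beam_fill_factor` (waist/pupil-radius, default 1)
controls this apodization, which suppresses the laser PSFs' Airy
sidelobes relative to the uniformly filled detection pupil. The measured
excitation FWHM at the default is 261 nm, about 11% above the
uniform-pupil value — the expected effect of a fill factor of one.

## Depletion survival

A rectangular depletion pulse of duration $T$ raises the decay rate to
$k_F(1 + \varsigma d)$, with $d$ the unit-peak doughnut intensity and
$\varsigma$ the saturation factor (referenced to the doughnut maximum);
molecules surviving the pulse fluoresce undepleted:

$$\eta \;=\; \frac{1 - e^{-(1+\varsigma d)T/\tau_F}}{1+\varsigma d}
\;+\; e^{-(1+\varsigma d)T/\tau_F},
\qquad \tau_F = 3.5\ \mathrm{ns},\ T = 1\ \mathrm{ns}.$$

$\eta \equiv 1$ at $\varsigma = 0$ (confocal limit) and decreases
monotonically in both $\varsigma$ and $d$. Note that with
$T/\tau_F \approx 0.29$ a single pulse cannot fully deplete: even at
$\varsigma = 300$ the effective excitation keeps a weak pedestal under
the doughnut. This is why the simulated fingerprint at $\varsigma = 300$
matches the element-integrated detection PSF closely (unit-sum $L_2$
discrepancy 0.046) but not perfectly — the residual is physics of the
pulsed model, not discretization.

# Pixel reassignment

The scanned images are mutually displaced by the shift vectors
$\boldsymbol{\mu}(\mathbf{x}_d)$ — theoretically the argmax of the
product of effective excitation and element detection PSFs
(`theoretical_shift_vectors()`, sub-voxel parabolic refinement, ties
toward the grid center). For equal-width Gaussian excitation and
detection PSFs with zero Stokes shift and point-like elements,
$|\boldsymbol{\mu}| = |\mathbf{x}_d|/2$: reassignment demagnifies the
micro-image by exactly two. With a fill factor of one the element's area
integration biases this ratio (we measure ≈ 0.45 rather than 0.5), so
the textbook factor is verified with a small fill factor.

`estimate_shifts()` implements the adaptive variant: phase correlation
of each scanned image against the central element, cross-power spectrum
normalized by its magnitude (floor $10^{-12}$), peak refined to
1/upsampling pixel (default 20) by a local matrix-multiply DFT, ties
broken toward the smallest shift. Elements whose fingerprint value is
below `low_signal_frac` (default 0.1) of the maximum carry too little
light to register; their shifts are replaced by a least-squares linear
model of shift versus element index fitted on the well-lit elements.
`reassign()` translates each channel by its shift with the Fourier-shift
theorem (periodic; the channel total — the DC coefficient — is exactly
preserved, hence photon conservation to machine precision) and sums.
An optional crop margin removes wrap-contaminated borders before
measurement. For 3D datasets shifts are estimated on the brightest plane
and applied laterally to all planes.

# Focus-ISM

After reassignment each micro-image ideally carries only axial
information: in-focus light concentrates in a narrow central spot
(asymptotically the detection PSF), defocused light spreads broadly.
Two classifiers act per scan point.

**f¹** (outer-frame subtraction): $\beta(\mathbf{x}_s)$ is the mean of
the 16 outer-frame elements, and the in-focus signal is
$A = (\bar i_{3\times3} - \beta)\cdot 25$ with $\bar i_{3\times3}$ the
inner 3×3 mean (the flux-consistent alternative $A = N - 25\beta$ is
available via `estimator = "total_minus_25beta"`). Negative pixels are
counted and, by default, trimmed to zero.

**f²** (constrained two-Gaussian fit): the unit-normalized micro-image
is fitted by bounded least squares to
$\alpha\, g(\mathbf{x}_d \mid 0, \sigma_\mathrm{sig}) +
\beta\, g(\mathbf{x}_d \mid 0, \sigma_\mathrm{bkg})$ with the
photon-flux constraint $\alpha + \beta = 1$, $\alpha \in [0,1]$.
Gaussians are evaluated at the element centers in pitch units
(adequate at fill factor 1). With $\sigma_\mathrm{bkg}$ fixed, the
profile over $\alpha$ is linear least squares with a clamp — exact and
vectorized over all scan points. With $\sigma_\mathrm{bkg}$ free, a
41-point log-spaced grid over
$[\sigma_\mathrm{bkg,min}, \sigma_\mathrm{bkg,max}]$ (defaults
$[1.5, 10]\,\sigma_\mathrm{sig}$) is searched and refined parabolically
in $\log\sigma$; the refinement is kept only where it lowers the
residual. Pixels with fewer than `min_counts` photons (default 10) are
fitted on their 3×3 scan-neighborhood sum, with the resulting fractions
applied to the pixel's own photons. Because $\alpha + \beta = 1$, signal
and background images sum *exactly* to the channel-summed input and are
non-negative by construction. The fitted background also yields the
per-element expectation
$b_{n,m} = \beta N g(\mathbf{x}_d^{(n,m)} \mid 0, \sigma_\mathrm{bkg})$
consumed by the deconvolution.

## Calibrating the two widths

$\sigma_\mathrm{sig}$ comes from a single-Gaussian least-squares fit to
a fingerprint of in-focus-only content (`calibrate_sigma_sig()`). The
$\sigma_\mathrm{bkg}$ policy matters more than it may appear. With
$\sigma_\mathrm{bkg}$ free and its lower bound close to
$\sigma_\mathrm{sig}$, micro-images that are only slightly broader than
the in-focus model — which happens away from intensity peaks, where
reassignment is imperfect and detection offsets skew the micro-image —
are absorbed wholesale by the background term, discarding 20–25% of
genuine in-focus light in our confocal bead simulations. Fixing
$\sigma_\mathrm{bkg}$ at a value calibrated from a defocused region
(here: the fingerprint of a 500 nm-defocused acquisition) restores
in-focus retention to 93% (confocal) and 99% (STED, $\varsigma = 300$)
while still suppressing a larger fraction of defocused light than a
closed pinhole (central element) does. Both calibrations are data-driven
and map onto standard practice: select an in-focus region for
$\sigma_\mathrm{sig}$, and either free $\sigma_\mathrm{bkg}$ with a
safe lower bound or pin it from a background-dominated region.

The sectioning figures above are measured on a two-plane bead phantom
(eight 23 nm beads in focus plus the same pattern defocused by 500 nm,
noiseless, common intensity scale): retention is the f² signal total on
the combined acquisition divided by the in-focus-only acquisition
total; suppression is probed by running f² on the defocus-only
acquisition (a linearity probe — f² itself is nonlinear, so the probe
quantifies what the classifier passes when shown pure background).

Anti-Stokes background — fluorescence excited directly by the
depletion doughnut — lands broadly on the array and is classified into
the background component by the same machinery (95% of its photons in
our simulation).

# Multi-image deconvolution

`rl_multi()` implements the multi-image Richardson–Lucy update

$$o^{k+1} = o^k \sum_{n,m} w_{n,m}\,
\Bigl[h^*_{n,m} \star \frac{i_{n,m}}{h_{n,m} * o^k}\Bigr],$$

and `rl_multi_background()` its background-aware variant with
$\bar h_{n,m} * o^k + b_{n,m}$ in the denominator (centered PSFs on
post-reassignment data; $b_{n,m}$ from f¹/f² and/or a dark-count map).
Weights are the inverse fingerprint, $w_{n,m} = f_{n,m}^{-1}$
(zero-fingerprint elements excluded), normalized to unit sum — the
normalization keeps the true object a fixed point and the weighted
Poisson likelihood monotone. Denominators and ratios are floored at
$10^{-12}$. PSFs are unit-sum Gaussians of a common FWHM
(`build_gaussian_psfs()`), shifted by the estimated shift vectors or
centered, with support chosen so the truncated mass is below $10^{-6}$.

Two numerical choices deserve a note:

* **Initialization.** The default start is the channel-summed image, not
  a flat constant. With a flat start the first multiplicative updates
  are spent reconstructing the data (iteration one is the data smoothed
  by the PSF), so a run "manually stopped at the 5th step" — the
  intended operating regime — may not yet have sharpened anything on a
  sparse scene. Starting from the data makes every early iteration a
  sharpening step; `init = "flat"` remains available.
* **PSF sizing.** The parameter-free route sizes the common FWHM with
  single-image Fourier ring correlation on the reconstruction
  (`frc_resolution()`): diagonal checkerboard split (odd/odd vs
  even/even pixels), cross-spectrum phase-corrected for the half-pixel
  diagonal offset of the two sub-grids, 3-ring moving average, fixed 1/7
  threshold, resolution $= 1/f_\mathrm{cross}$. FRC's crossing is
  SNR-dependent: on high-count images of sparse point sources it reports
  finer values than the PSF width (our spot-grid self-consistency check
  therefore runs at a realistic ~200 peak counts, where FRC sits within
  25% of the generating 200 nm FWHM). For bead fields the bead-fit FWHM
  of the reconstruction is the more faithful PSF measure and is what the
  bead-sharpening check uses.

# Synthetic data

`generate_phantom()` builds bead fields (default 23 nm diameter,
unit-brightness spheres rasterized with sub-voxel occupancy; positions
random within margins or caller-fixed) and 3D filament networks
(persistent random-walk tubes; `z_extent = 0` keeps all mass in the
focal plane). `simulate_acquisition()` applies the forward model
$\Lambda_{n,m} = \sum_z h_{n,m}(\cdot, z) * \mathrm{phantom}(\cdot, z)$
(periodic FFT convolution after zero-padding by half the grid, recorded
in the provenance), scales the brightest channel-summed pixel to the
photon budget (default $10^4$, typical of a bright STED-ISM frame; an
absolute `scale` override supports imaging related phantoms on a common
footing), adds a flat dark rate and draws Poisson counts under a fixed
seed.

What the generator emulates: diffraction-limited image formation with
per-element geometry, depletion-dependent resolution, defocus-broadened
micro-images, shot noise and dark counts. What it does not: optical
aberrations, detector cross-talk and afterpulsing, sample motion and
photobleaching, the vectorial fine structure of the excitation
polarization, and anisotropic emitter orientation effects. Passing
tests on these phantoms therefore validate the algorithms under the
stated image-formation model, not robustness to instrument
non-idealities — which is precisely what the adaptive (data-driven)
estimation steps are designed to absorb on real data.

# Numerical and design notes

* Odd grids only; the center voxel is the optical axis at focus. Arrays
  are `[y, x, z]` with physical coordinate $(k - (N+1)/2)\cdot\Delta$.
  Channel order is row-major in the detector row:
  $c = 5(n+2) + (m+2) + 1$, central element = channel 13.
* Element detection maps use zero-padded (linear) convolution of the
  detection PSF with the element indicator — periodic wrap-around would
  alias detection tails onto opposite corner elements of the 1.27 µm
  grid.
* OTF support edges are located by `otf_cutoff(method = "support")`: the
  midpoint of the frequency interval with the largest ring-to-ring
  log-decrement, i.e. where the MTF crashes into a transfer zero or its
  numerical floor. A fixed small threshold cannot measure both a
  widefield cutoff (edge of order $(1-\nu)^{3/2}$) and a confocal cutoff
  (order $(2-\nu)^4$) consistently; the crash detector locates either to
  half a frequency bin. The bandwidth-doubling check runs on a 257²
  grid at 30 nm pixels so both cutoffs are resolved by ≥ 33 rings.
* Dataset I/O uses multi-page TIFF with a YAML sidecar for geometry and
  provenance. Integer counts up to 65535 round-trip bit-exactly (16-bit);
  real-valued data are stored as 32-bit float scaled into [0, 1] with
  the scale recorded. Imports enforce the 25-channel layout and report
  the found channel count on mismatch.
* Bead quality control (`fit_beads()`): detection threshold is a
  multiple of the image median floored at a twentieth of the peak;
  fits are rejected when the center leaves the window, the FWHM exceeds
  the window or drops below one pixel, or the amplitude does not exceed
  the offset. The paper-style gains (`gains()`) are then ratios of mean
  FWHM and mean peak over successful fits, with standard errors
  propagated in quadrature.

# Known limitations

* The survival model is a single rectangular pulse without time-gated
  detection; time gating would deepen effective depletion and sharpen
  the high-$\varsigma$ fingerprint convergence.
* f² assumes an isotropic, centered two-Gaussian micro-image model;
  strong aberrations (astigmatism, coma) violate it and would first
  appear as in-focus light leaking into the background term.
* Deconvolution is 2D (plane-by-plane); axially coupled 3D deconvolution
  is intentionally out of scope — focus-ISM exists to avoid needing a
  z-stack in the first place.
* The FRC resolution estimate is SNR-dependent by construction; treat it
  as an effective image resolution, not a PSF measurement, on sparse
  high-count scenes.
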