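# focusISM

Simulation and reconstruction toolkit for **image scanning microscopy
(ISM)** with a 5×5 detector array and tunable **stimulated emission
depletion (STED)** — for microscopists and methods developers who want to
simulate, reconstruct and quantify STED-ISM data, and for anyone who
needs the **focus-ISM** background-removal step for array-detector
laser-scanning data.

Replacing the single detector of a confocal/STED microscope with a small
detector array records, at each scan position $\mathbf{x}_s$, a 5×5
*micro-image* $i(\mathbf{x}_d \mid \mathbf{x}_s)$. The package covers the
full computational stack built on that extra information:

* **Optics** — per-element scanned PSFs
  $h_{n,m}(\mathbf{x}) = h_\mathrm{exc}\,\eta \cdot
  (h_\mathrm{det} \circledast \Pi_{n,m})$
  from scalar-Debye / vectorial-vortex focal fields, with the pulsed
  depletion survival
  $\eta = \frac{1 - e^{-(1+\varsigma d)T/\tau_F}}{1+\varsigma d} +
  e^{-(1+\varsigma d)T/\tau_F}$
  at saturation factor $\varsigma$ (0 = confocal); plus fingerprints,
  theoretical shift vectors and axial energy curves.
* **Datasets** — an ISM count container (`[Ny, Nx, 25(, Nz)]`, channel
  $c = 5(n{+}2) + (m{+}2) + 1$), TIFF+YAML I/O, bead and 3D-filament
  phantoms, and a Poisson forward model.
* **Adaptive pixel reassignment (APR)** — per-element shift vectors
  $\boldsymbol{\mu}(\mathbf{x}_d)$ estimated by sub-pixel phase
  correlation against the central element, Fourier-shift registration,
  exact photon conservation.
* **Focus-ISM** — per-pixel classification of micro-image photons into
  in-focus and out-of-focus components: fast outer-frame subtraction
  (*f¹*) and the constrained two-Gaussian fit (*f²*),
  $\alpha\,g(\mathbf{x}_d \mid 0, \sigma_\mathrm{sig}) +
  \beta\,g(\mathbf{x}_d \mid 0, \sigma_\mathrm{bkg})$ with
  $\alpha + \beta = 1$.
* **Deconvolution** — multi-image Richardson–Lucy
  $o^{k+1} = o^k \sum_{n,m} w_{n,m} [h^*_{n,m} \star i_{n,m} /
  (h_{n,m} * o^k + b_{n,m})]$ with inverse-fingerprint weights and the
  focus-ISM background $b_{n,m}$ as prior, PSF width set by Fourier ring
  correlation or bead calibration.
* **Metrics** — bead Gaussian fits, resolution/signal gains, MTF and OTF
  cutoffs, axial fingerprint ratios, radial spectral contrast.

See `vignette("focus-ism-methods")` for the models, defaults and design
choices, and `inst/scripts/focusism.R` for the command-line front end
(`simulate-psf`, `phantom`, `acquire`, `apr`, `focus`, `deconv`, `frc`,
`metrics`).

## Worked example

Simulate a confocal ISM acquisition of four 23 nm beads, reconstruct by
adaptive pixel reassignment, remove the (here minimal) background with
f², and sharpen with five Richardson–Lucy steps:

```r
library(focusISM)

cfg <- optical_config(grid_shape = c(1, 127, 127))   # focal plane, 10 nm voxels
stk <- scanned_psf_stack(cfg, detector_geometry(cfg), depletion_model(0))

xy  <- 240 * cbind(c(-1, -1, 1, 1), c(-1, 1, -1, 1)) + c(13, -7, 4, -11)
ph  <- generate_phantom("beads", c(1, 127, 127), c(10, 10, 10),
                        seed = 1, bead_xy = xy)
acq <- simulate_acquisition(ph, stk, photon_budget = 1e4, seed = 2)
acq
#> ism_dataset: 127 x 127 scan, 25 channels, pixel 10 x 10 nm, total 2.799e+07

ar <- reassign(acq)                       # adaptive pixel reassignment
ar
#> apr_result: ISM total 2.79925e+07, open total 2.79925e+07, max |shift| 17.74 px

open_fit <- fit_beads(ar$open_image, 10, threshold = 2000, expected_fwhm = 300)
ism_fit  <- fit_beads(ar$ism_image, 10, threshold = 2000, expected_fwhm = 300)
ism_fit
#> bead_fit_result: 4 successful fits, FWHM 177.6 +/- 0.1 nm, peak 1.85e+04 +/- 28

g <- gains(open_fit, ism_fit)
sprintf("resolution gain %.2f, signal gain %.2f", g$resolution_gain, g$signal_gain)
#> "resolution gain 1.38, signal gain 1.79"

ssig  <- calibrate_sigma_sig(fingerprint(acq))       # 0.93 pitch units
model <- fingerprint_model(ssig, "fixed", sigma_bkg_value = 2.5 * ssig)
f2    <- f2_classify(ar$registered, model)
f2
#> focus_result (f2): signal 2.634e+07, background 1.674e+06 (0 negative pixels)

psfs <- build_gaussian_psfs(ar$shift_field, fwhm = ism_fit$mean_fwhm,
                            pixel_size = 10, centered = TRUE)
dec  <- rl_multi(ar$registered, psfs, deconv_config(iterations = 5))
fit_beads(dec$estimate, 10, expected_fwhm = 300)$mean_fwhm
#> 134.5
```

Reading the numbers: the open-pinhole (channel-sum) image measures the
beads at 244 nm FWHM; reassignment alone sharpens them to 178 nm
(resolution gain 1.38, close to the ISM bound of 2) while *raising* the
peak signal by 1.79× — no photons are traded away (ISM and open totals
agree to machine precision). The f² classifier attributes 94% of the
photons of this quasi-2D sample to the in-focus component, and five
deconvolution steps bring the beads to 135 nm. Increasing the
saturation factor (`depletion_model(30)`, `depletion_model(300)`, ...)
shrinks the PSFs, the shift vectors and the fingerprint, and the
reassignment gains fade — which is exactly the regime where focus-ISM
still improves contrast.

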