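test_that("configuration invariants are enforced", {
  expect_error(optical_config(grid_shape = c(2, 64, 64)), "odd")
  expect_error(optical_config(numerical_aperture = 1.6,
                              refractive_index = 1.5), "refractive")
  expect_error(optical_config(voxel_size = c(0, 10, 10)))
  # flat channel index is a bijection onto 1..25
  el <- element_tab()
  idx <- channel_index(el[, "n"], el[, "m"])
  expect_identical(sort(idx), 1:25)
  expect_identical(element_of(idx), el)
  expect_identical(channel_index(0, 0), 13L)
  au <- airy_unit(cfg_plane())
  expect_equal(au, 1.22 * 669 / 1.4)
  dg <- detector_geometry(cfg_plane())
  expect_equal(dg$pitch, 1.4 * au / 5)
})

test_that("focal fields have the correct structure", {
  cfg <- cfg_plane()
  expect_warning(focal_intensity(cfg, "detection"), "Airy")
  suppressWarnings({
    exc <- focal_intensity(cfg, "gaussian_excitation")
    det <- focal_intensity(cfg, "detection")
    vx <- focal_intensity(cfg, "vortex_sted")
  })
  # helical phase ramp: strict on-axis null; flat beams peak on axis
  expect_identical(vx$values[64, 64, 1], 0)
  expect_equal(which.max(exc$values[, , 1]),
               which.max(det$values[, , 1]))
  expect_equal(arrayInd(which.max(exc$values[, , 1]), c(127, 127)),
               matrix(c(64L, 64L), 1))
  # lateral FWHM within 15% of the diffraction estimate 0.51 lambda / NA
  fw <- lateral_fwhm(exc$values[, , 1], 10)
  expect_lt(abs(fw - 0.51 * 646 / 1.4) / (0.51 * 646 / 1.4), 0.15)
  # first lateral zero of the (uniform-pupil) detection PSF at the Airy
  # radius 0.61 lambda / NA, within one voxel (brute-force radial scan)
  prof <- det$values[64, 64:127, 1]
  first_min <- which(diff(prof) > 0)[1]
  expect_lt(abs((first_min - 1) * 10 - 0.61 * 669 / 1.4), 10)
  expect_error(focal_intensity(cfg, "bessel"))
})

test_that("survival factor follows the pulsed-depletion closed form", {
  dg <- array(runif(4^3), c(4, 4, 4))
  m0 <- depletion_model(0)
  eta0 <- survival_factor(m0, dg)
  expect_true(all(eta0$values == 1))
  m <- depletion_model(300, fluorescence_lifetime = 3.5,
                       sted_pulse_duration = 1)
  # independent transcription of the closed form at unit doughnut peak
  s <- 1 + 300 * 1
  g <- s * 1 / 3.5
  expect_equal(survival_factor(m, array(1, c(1, 1, 1)))$values[1, 1, 1],
               (1 - exp(-g)) / s + exp(-g), tolerance = 1e-12)
  # eta = 1 wherever the doughnut vanishes, regardless of saturation
  dg0 <- dg; dg0[2, 2, 2] <- 0
  expect_equal(survival_factor(m, dg0)$values[2, 2, 2], 1)
  # bounded and pointwise non-increasing in the saturation factor
  prev <- survival_factor(depletion_model(0), dg)$values
  for (s2 in c(1, 10, 30, 300)) {
    cur <- survival_factor(depletion_model(s2), dg)$values
    expect_true(all(cur >= 0 & cur <= 1))
    expect_true(all(cur <= prev + 1e-12))
    prev <- cur
  }
  expect_error(survival_factor(m, array(-1, c(1, 1, 1))), "non-negative")
})

test_that("scanned PSF stacks behave physically", {
  stk <- stack_sigma(0)
  open <- apply(stk$h[, , 1, ], c(1, 2), sum)
  central <- stk$h[, , 1, 13]
  # pinhole narrowing: the central element is at least as sharp as the sum
  expect_lte(lateral_fwhm(central, 10), lateral_fwhm(open, 10))
  # summing all elements equals the effective excitation times the
  # detection PSF convolved with the full-array window
  y <- focusISM:::axis_coords(127, 10)
  win <- focusISM:::element_indicator(y, y, 10, 10, c(0, 0),
                                      5 * stk$detector$pitch)
  rhs <- stk$h_eff[, , 1] *
    focusISM:::conv2_centered_linear(stk$h_det[, , 1], win)
  expect_lt(max(abs(open - rhs)) / max(rhs), 1e-10)
  # at saturation 300 every element peaks at the scan origin (within one
  # voxel): the scanned images vary in brightness, no longer in position
  stk300 <- stack_sigma(300)
  for (ch in 1:25) {
    pk <- arrayInd(which.max(stk300$h[, , 1, ch]), c(127, 127))
    expect_lte(max(abs(pk - 64)), 1)
  }
  # symmetry of the confocal stack under (n, m) -> (-n, -m)
  el <- element_tab()
  for (ch in c(1, 2, 7, 12)) {
    opp <- channel_index(-el[ch, "n"], -el[ch, "m"])
    expect_lt(max(abs(stk$h[, , 1, ch] -
                        stk$h[127:1, 127:1, 1, opp])) / max(stk$h), 1e-6)
  }
  # detector footprint must fit the grid
  cfg_small <- suppressWarnings(
    optical_config(grid_shape = c(1, 33, 33)))
  expect_error(
    suppressWarnings(
      scanned_psf_stack(cfg_small, detector_geometry(cfg_small))),
    "footprint")
})

test_that("theoretical shift vectors implement pixel reassignment geometry", {
  # matched Gaussian stand-ins, zero Stokes shift, point-like elements:
  # shifts are half the element displacement (2%)
  cfg <- suppressWarnings(
    optical_config(lambda_exc = 646, lambda_det = 646,
                   grid_shape = c(1, 127, 127)))
  dg <- detector_geometry(cfg, fill_factor = 0.02)
  stk <- suppressWarnings(scanned_psf_stack(cfg, dg, method = "gaussian"))
  sv <- theoretical_shift_vectors(stk)
  el <- element_tab()
  disp_px <- sqrt(rowSums(el^2)) * dg$pitch / 10
  mag <- sqrt(rowSums(unclass(sv)^2))
  expect_lt(max(abs(mag[-13] / disp_px[-13] - 0.5)), 0.02 * 0.5)
  # antisymmetry for the aberration-free simulation
  for (ch in (1:25)[-13]) {
    opp <- channel_index(-el[ch, "n"], -el[ch, "m"])
    expect_equal(unclass(sv)[ch, ], -unclass(sv)[opp, ],
                 tolerance = 0.05, ignore_attr = TRUE)
  }
  # high depletion shrinks all shifts below half a voxel
  sv300 <- theoretical_shift_vectors(stack_sigma(300))
  expect_lt(max(sqrt(rowSums(unclass(sv300)^2))), 0.5)
  # flat PSF has no argmax
  flat <- stack_sigma(0)
  flat$h[, , 1, 5] <- 1
  expect_error(theoretical_shift_vectors(flat), "flat")
})

test_that("shift magnitudes and fingerprint widths shrink with saturation", {
  widths <- numeric(0)
  mags <- NULL
  for (s in c(0, 10, 30, 300)) {
    stk <- stack_sigma(s)
    widths <- c(widths, fingerprint_width(fingerprint(stk)))
    mags <- cbind(mags,
                  sqrt(rowSums(unclass(theoretical_shift_vectors(stk))^2)))
  }
  expect_true(all(diff(widths) <= 1e-9))
  expect_true(all(diff(t(mags)) <= 1e-6))
  # open-pinhole in-focus FWHM non-increasing in saturation
  fw <- vapply(c(0, 10, 30, 300), function(s) {
    lateral_fwhm(apply(stack_sigma(s)$h[, , 1, ], c(1, 2), sum), 10)
  }, numeric(1))
  expect_true(all(diff(fw) <= 0))
  # at saturation 300 the fingerprint identifies with the detection PSF
  # integrated over the detector elements
  stk300 <- stack_sigma(300)
  expect_lte(fingerprint_l2(fp_vec(fingerprint(stk300)),
                            fp_vec(detection_fingerprint(stk300))), 0.05)
})

test_that("fingerprints sum micro-images exactly", {
  cts <- array(0L, c(8, 9, 25))
  cts[, , 13] <- matrix(7L, 8, 9)
  ds <- ism_dataset(cts, 40)
  fp <- fingerprint(ds)
  expect_equal(unclass(fp)[3, 3], 7 * 72)
  expect_equal(sum(fp), attr(fp, "total"))
  expect_true(all(unclass(fp)[-13] == 0))
  # totals preserved exactly for integer data
  set.seed(8)
  cts2 <- array(sample(0:30, 5 * 5 * 25, TRUE), c(5, 5, 25))
  expect_equal(sum(fingerprint(ism_dataset(cts2, 40))), sum(cts2))
})

test_that("axial energy curves measure optical sectioning", {
  ones <- array(1, c(127, 127, 3))
  expect_equal(axial_energy_curve(ones), rep(127^2, 3))
  expect_error(axial_energy_curve(array(1, c(4, 4, 2))), "3 planes")
  stk <- stack_3d(0)
  open <- apply(stk$h, c(1, 2, 3), sum)
  central <- stk$h[, , , 13]
  e_open <- axial_energy_curve(open)
  e_cen <- axial_energy_curve(central)
  # open pinhole collects defocused light the central element rejects
  expect_gt(min(e_open / max(e_open)), min(e_cen / max(e_cen)))
  # normalized curve of the open pinhole is wider at every depth
  expect_true(all(e_open / max(e_open) >= e_cen / max(e_cen) - 1e-12))
})
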