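# Shared fixtures, built lazily and cached for the whole test run. All
# simulations are small enough to run in seconds; seeds are fixed so every
# fixture is deterministic.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# Focal-plane configuration on the standard simulation grid (127 x 127
# lateral voxels, 10 nm): in-focus PSFs need only the focal plane.
cfg_plane <- function() {
  suppressWarnings(optical_config(grid_shape = c(1, 127, 127)))
}

# Scanned PSF stack at the focal plane for a given saturation factor.
stack_sigma <- function(s) {
  fixture(paste0("stack_s", s), function() {
    suppressWarnings(
      scanned_psf_stack(cfg_plane(), detector_geometry(cfg_plane()),
                        depletion_model(s)))
  })
}

# 3D stack (z in -500..500 nm, 100 nm planes; 95 x 95 lateral at 20 nm)
# used by the sectioning and axial-fingerprint fixtures.
stack_3d <- function(s) {
  fixture(paste0("stack3d_s", s), function() {
    cfg <- suppressWarnings(
      optical_config(grid_shape = c(11, 95, 95),
                     voxel_size = c(100, 20, 20)))
    suppressWarnings(
      scanned_psf_stack(cfg, detector_geometry(cfg), depletion_model(s)))
  })
}

# PSF stack re-packaged as a point-source ISM dataset (one plane).
stack_as_dataset <- function(stack, plane = NULL, scale = 1) {
  d <- dim(stack$h)
  if (is.null(plane)) plane <- (d[3] + 1) / 2
  cts <- stack$h[, , plane, ] * scale
  ism_dataset(cts, pixel_size = stack$config$voxel_size[2:3],
              detector = stack$detector)
}

# Two-plane bead sectioning experiment: beads in focus plus the same bead
# pattern defocused by 500 nm, acquired noiselessly on a common intensity
# scale, with in-only / out-only component acquisitions for probing.
sectioning_case <- function(s) {
  fixture(paste0("sect_s", s), function() {
    stk <- stack_3d(s)
    gg <- stk$config$grid_shape
    vv <- stk$config$voxel_size
    ph_in <- generate_phantom("beads", gg, vv, seed = 11, n_beads = 8,
                              bead_z = 0, margin = 300)
    ph_out <- generate_phantom("beads", gg, vv, seed = 11, n_beads = 8,
                               bead_z = 500, margin = 300)
    ph_all <- ph_in
    ph_all$volume <- ph_in$volume + ph_out$volume
    acq_all <- simulate_acquisition(ph_all, stk, photon_budget = 1e4,
                                    noise = FALSE)
    sc <- attr(acq_all, "scale")
    acq_in <- simulate_acquisition(ph_in, stk, noise = FALSE, scale = sc)
    acq_out <- simulate_acquisition(ph_out, stk, noise = FALSE, scale = sc)
    sigma_sig <- calibrate_sigma_sig(fingerprint(acq_in))
    sigma_bkg <- calibrate_sigma_sig(fingerprint(acq_out), upper = 20)
    model <- fingerprint_model(sigma_sig, "fixed",
                               sigma_bkg_value = sigma_bkg,
                               sigma_bkg_max = 20 * sigma_sig)
    ar_all <- reassign(acq_all)
    ar_in <- reassign(acq_in, ar_all$shift_field)
    ar_out <- reassign(acq_out, ar_all$shift_field)
    list(stack = stk, model = model,
         acq_all = acq_all, acq_in = acq_in, acq_out = acq_out,
         f_all = f2_classify(ar_all$registered, model),
         f_in = f2_classify(ar_in$registered, model),
         f_out = f2_classify(ar_out$registered, model),
         E_in = sum(sum_channels(acq_in)),
         E_out = sum(sum_channels(acq_out)))
  })
}

# Poisson bead-field acquisition at a given saturation (single plane).
# Beads sit on a well-separated 2x2 grid (plus sub-pixel offsets) so that
# their images stay resolvable even at the confocal PSF width.
bead_field <- function(s, budget = 1e4, seed = 21) {
  fixture(paste0("beads_s", s, "_b", budget), function() {
    stk <- stack_sigma(s)
    xy <- 240 * cbind(c(-1, -1, 1, 1), c(-1, 1, -1, 1)) +
      c(13, -7, 4, -11)
    ph <- generate_phantom("beads", c(1, 127, 127), c(10, 10, 10),
                           seed = seed, bead_xy = xy)
    simulate_acquisition(ph, stk, photon_budget = budget, seed = seed + 1)
  })
}

element_tab <- function() focusISM:::element_table()

# fingerprint object -> length-25 vector in channel order
fp_vec <- function(fp) {
  el <- element_tab()
  unclass(fp)[cbind(el[, "n"] + 3, el[, "m"] + 3)]
}

# single-scan-point dataset from a 25-vector micro-image
micro_dataset <- function(mi, pixel_size = 40) {
  cts <- array(0, c(1, 1, 25))
  cts[1, 1, ] <- mi
  ism_dataset(cts, pixel_size)
}
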