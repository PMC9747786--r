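test_that("outer-frame classification reproduces its worked micro-images", {
  el <- element_tab()
  outer <- as.numeric(abs(el[, "n"]) == 2 | abs(el[, "m"]) == 2)
  # flat micro-image: background equals the level, signal vanishes
  flat <- f1_classify(micro_dataset(rep(3, 25)), trim_negatives = FALSE)
  expect_equal(flat$background_image[1, 1] / 25, 3)
  expect_equal(flat$signal_image[1, 1], 0)
  # all 9 counts in the central element: signal 25, background 0
  center <- rep(0, 25); center[13] <- 9
  rc <- f1_classify(micro_dataset(center))
  expect_equal(rc$background_image[1, 1], 0)
  expect_equal(rc$signal_image[1, 1], 25)
  # outer frame only: beta 1, signal -25, trimmed to zero
  ru <- f1_classify(micro_dataset(outer), trim_negatives = FALSE)
  expect_equal(ru$background_image[1, 1] / 25, 1)
  expect_equal(ru$signal_image[1, 1], -25)
  rt <- f1_classify(micro_dataset(outer), trim_negatives = TRUE)
  expect_equal(rt$signal_image[1, 1], 0)
  expect_identical(rt$negatives, 1L)
  expect_identical(rt$negatives_trimmed, 1L)
  # flux-consistent alternative estimator
  ra <- f1_classify(micro_dataset(center), estimator = "total_minus_25beta")
  expect_equal(ra$signal_image[1, 1], 9 - 0)
  # inner-concentrated data give strictly positive signal; the reported
  # negative count matches a brute-force recount
  set.seed(6)
  cts <- array(rpois(10 * 10 * 25, 2), c(10, 10, 25))
  ds <- ism_dataset(cts, 40)
  r <- f1_classify(ds, trim_negatives = FALSE)
  inner_mean <- apply(cts[, , focusISM:::inner_channels()], c(1, 2), mean)
  beta <- apply(cts[, , focusISM:::outer_channels()], c(1, 2), mean)
  expect_equal(r$signal_image, (inner_mean - beta) * 25)
  expect_identical(r$negatives, sum((inner_mean - beta) < 0))
})

test_that("sigma_sig calibration recovers generating widths", {
  g <- focusISM:::detector_gauss(0.8)
  expect_lt(abs(calibrate_sigma_sig(focusISM:::as_fingerprint(g)) - 0.8),
            1e-3)
  # degenerate all-center fingerprint pins sigma at the lower bound
  delta <- rep(0, 25); delta[13] <- 100
  expect_warning(
    s <- calibrate_sigma_sig(focusISM:::as_fingerprint(delta)),
    "bound")
  expect_equal(s, 0.05)
  # in-focus high-depletion fingerprint width matches the detection PSF
  stk <- stack_sigma(300)
  s_fp <- calibrate_sigma_sig(fingerprint(stk))
  s_det <- calibrate_sigma_sig(detection_fingerprint(stk))
  expect_lt(abs(s_fp - s_det) / s_det, 0.1)
})

test_that("two-Gaussian fits recover the mixing fraction", {
  gs <- focusISM:::detector_gauss(0.8)
  gb <- focusISM:::detector_gauss(1.6)
  free <- fingerprint_model(0.8)
  fixed <- fingerprint_model(0.8, "fixed", sigma_bkg_value = 1.6)
  for (a in c(0.1, 0.5, 0.9)) {
    mi <- 1e4 * (a * gs + (1 - a) * gb)
    rf <- f2_classify(micro_dataset(mi), free)
    expect_lt(abs(rf$alpha_map[1, 1] - a), 0.02)
    rx <- f2_classify(micro_dataset(mi), fixed)
    expect_lt(abs(rx$alpha_map[1, 1] - a), 1e-6)
  }
  # pure in-focus micro-image
  rp <- f2_classify(micro_dataset(1e4 * gs), free)
  expect_gte(rp$alpha_map[1, 1], 0.99)
  # near-flat micro-image reads as very broad background
  rn <- f2_classify(micro_dataset(rep(400, 25)), free)
  expect_lte(rn$alpha_map[1, 1], 0.05)
  expect_gt(rn$sigma_bkg_map[1, 1], 0.9 * 8)
})

test_that("alpha recovery stays accurate under Poisson noise", {
  gs <- focusISM:::detector_gauss(0.8)
  gb <- focusISM:::detector_gauss(1.6)
  model <- fingerprint_model(0.8, "fixed", sigma_bkg_value = 1.6)
  set.seed(19)
  for (a in c(0.1, 0.5, 0.9)) {
    lam <- 1e4 * (a * gs + (1 - a) * gb)
    # 500 replicates fitted in one vectorized call
    cts <- array(rpois(500 * 25, rep(lam, 500)), c(25, 1, 500))
    ds <- ism_dataset(aperm(cts, c(2, 3, 1)), 40)
    r <- f2_classify(ds, model)
    expect_lt(abs(mean(r$alpha_map) - a), 0.05)
    expect_lt(mean(abs(r$alpha_map - a)), 0.05)
  }
})

test_that("photon flux is conserved exactly and outputs stay non-negative", {
  ds <- bead_field(0)
  ar <- reassign(ds)
  model <- fingerprint_model(
    calibrate_sigma_sig(fingerprint(ds)), "fixed",
    sigma_bkg_value = 2.5 * calibrate_sigma_sig(fingerprint(ds)))
  r <- f2_classify(ar$registered, model)
  imgs <- result_images(r)
  expect_lt(max(abs(imgs$signal + imgs$background - imgs$channel_sum)),
            1e-8 * max(imgs$channel_sum))
  expect_true(all(imgs$signal >= 0))
  expect_true(all(imgs$background >= 0))
  expect_true(all(imgs$alpha >= 0 & imgs$alpha <= 1))
  expect_true(all(imgs$alpha + imgs$beta - 1 < 1e-12 | imgs$channel_sum == 0))
  # per-element background images sum to the background image
  expect_equal(apply(r$background_per_element, c(1, 2), sum),
               r$background_image, tolerance = 1e-9)
  # empty dataset classifies to all-zero outputs
  r0 <- f2_classify(ism_dataset(array(0, c(4, 4, 25)), 40), model)
  expect_true(all(r0$signal_image == 0) && all(r0$background_image == 0))
})

test_that("two-plane sectioning retains in-focus light and beats the
           closed pinhole on background suppression", {
  for (s in c(0, 300)) {
    cs <- sectioning_case(s)
    retention <- sum(cs$f_all$signal_image) / cs$E_in
    expect_gte(retention, 0.9)
    leak_f2 <- sum(cs$f_out$signal_image) / cs$E_out
    leak_pinhole <- sum(scanned_image(cs$acq_out, 0, 0)) / cs$E_out
    expect_lt(leak_f2, leak_pinhole)
  }
})

test_that("the f2 signal volume is more optically sectioned than open
           pinhole and central element", {
  stk <- stack_3d(300)
  ds <- stack_as_dataset(stk, plane = NULL, scale = 1)
  # classify every plane of the 3D PSF (as a z-stack dataset)
  cts <- stk$h * 1e4 / max(apply(stk$h, c(1, 2, 3), sum))
  ds3 <- ism_dataset(aperm(cts, c(1, 2, 4, 3)), 20, z_spacing = 100)
  sigma_sig <- calibrate_sigma_sig(fingerprint(stk))
  model <- fingerprint_model(sigma_sig, "fixed",
                             sigma_bkg_value = 3 * sigma_sig,
                             sigma_bkg_max = 20 * sigma_sig)
  r <- f2_classify(ds3, model)
  e_sig <- axial_energy_curve(r$signal_image)
  e_open <- axial_energy_curve(apply(stk$h, c(1, 2, 3), sum))
  e_cen <- axial_energy_curve(stk$h[, , , 13])
  nrm <- function(e) e / max(e)
  hw <- function(e) sum(nrm(e) >= 0.5)
  expect_lte(hw(e_sig), hw(e_open))
  expect_lte(hw(e_sig), hw(e_cen))
  expect_lt(sum(nrm(e_sig)), sum(nrm(e_cen)))
})

test_that("anti-Stokes-like background is classified as background", {
  cfg <- suppressWarnings(
    optical_config(grid_shape = c(1, 95, 95), voxel_size = c(10, 20, 20)))
  det <- detector_geometry(cfg)
  stk <- suppressWarnings(
    scanned_psf_stack(cfg, det, depletion_model(30)))
  # fluorescence excited directly by the depletion doughnut: replace the
  # effective excitation with the doughnut profile
  dough <- suppressWarnings(
    focal_intensity(cfg, "vortex_sted"))$values
  stk_as <- stk
  y <- focusISM:::axis_coords(95, 20)
  for (ch in 1:25) {
    ind <- focusISM:::element_indicator(
      y, y, 20, 20, element_tab()[ch, ] * det$pitch, det$active_side)
    de <- focusISM:::conv2_centered_linear(stk$h_det[, , 1], ind)
    stk_as$h[, , 1, ch] <- dough[, , 1] * de
  }
  ph <- generate_phantom("beads", c(1, 95, 95), c(10, 20, 20), seed = 5,
                         n_beads = 6, margin = 250)
  acq <- simulate_acquisition(ph, stk_as, photon_budget = 5e3,
                              noise = FALSE)
  sigma_sig <- calibrate_sigma_sig(
    fingerprint(simulate_acquisition(ph, stk, noise = FALSE)))
  model <- fingerprint_model(sigma_sig, "fixed",
                             sigma_bkg_value = 2.5 * sigma_sig)
  r <- f2_classify(reassign(acq, shift_field(matrix(0, 25, 2)))$registered,
                   model)
  expect_gt(sum(r$background_image) / sum(sum_channels(acq)), 0.5)
})

test_that("low-count pixels fall back to the binned neighborhood fit", {
  gs <- focusISM:::detector_gauss(0.8)
  model <- fingerprint_model(0.8, "fixed", sigma_bkg_value = 1.6,
                             min_counts = 10)
  # a 3x3 patch of dim pure-signal pixels: each is below min_counts but
  # the binned neighborhood matches the in-focus model
  cts <- array(0, c(3, 3, 25))
  for (y in 1:3) for (x in 1:3) cts[y, x, ] <- 2 * gs
  r <- f2_classify(ism_dataset(cts, 40), model)
  expect_gt(r$fallback_pixels, 0)
  expect_true(all(r$alpha_map > 0.95))
})
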