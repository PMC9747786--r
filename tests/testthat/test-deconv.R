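make_spot_grid <- function(n = 128, px = 20, fwhm = 200) {
  sig <- fwhm / (2 * sqrt(2 * log(2))) / px
  yy <- matrix(seq_len(n), n, n); xx <- t(yy)
  img <- matrix(0, n, n)
  for (cy in seq(16, n - 16, 24)) {
    for (cx in seq(16, n - 16, 24)) {
      img <- img + exp(-((yy - cy)^2 + (xx - cx)^2) / (2 * sig^2))
    }
  }
  img
}

test_that("FRC resolution is consistent with the generating PSF width", {
  img <- make_spot_grid(fwhm = 200)
  set.seed(12)
  # realistic photon level: ~200 expected counts at the spot peaks
  res <- vapply(1:3, function(i) {
    as.numeric(frc_resolution(matrix(rpois(length(img), img * 200),
                                     nrow(img)), 20))
  }, numeric(1))
  expect_lt(abs(mean(res) - 200) / 200, 0.25)
  # a noise-free image keeps its halves fully correlated: Nyquist bound
  expect_warning(r0 <- frc_resolution(img * 200, 20), "Nyquist")
  expect_equal(as.numeric(r0), 2 * 2 * 20)
  expect_error(frc_resolution(matrix(0, 32, 32), 20), "64")
})

test_that("Gaussian PSF sets are unit-sum and correctly shifted", {
  sh <- matrix(0, 25, 2)
  sh[1, ] <- c(1.5, 0)
  sf <- shift_field(sh)
  ps <- build_gaussian_psfs(sf, fwhm = 4 * 40, pixel_size = 40)
  sums <- apply(ps$kernels, 3, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  # zero-shift kernels are identical and symmetric
  expect_equal(ps$kernels[, , 2], ps$kernels[, , 13])
  k13 <- ps$kernels[, , 13]
  expect_equal(k13, t(k13))
  expect_equal(k13, k13[rev(seq_len(nrow(k13))), ])
  # centroid of a shifted kernel sits at the shift
  k <- dim(ps$kernels)[1]
  cc <- seq_len(k) - (k + 1) / 2
  expect_lt(abs(sum(ps$kernels[, , 1] * matrix(cc, k, k)) - 1.5), 1e-3)
  expect_lt(abs(sum(ps$kernels[, , 1] * t(matrix(cc, k, k)))), 1e-3)
  # centered flag ignores the shifts
  pc <- build_gaussian_psfs(sf, fwhm = 4 * 40, pixel_size = 40,
                            centered = TRUE)
  expect_equal(pc$kernels[, , 1], pc$kernels[, , 13])
  expect_warning(build_gaussian_psfs(sf, fwhm = 10, pixel_size = 40),
                 "under-sampled")
})

rl_problem <- function(seed = 3, n = 64) {
  set.seed(seed)
  o_true <- matrix(0, n, n)
  o_true[cbind(sample(10:(n - 10), 12), sample(10:(n - 10), 12))] <-
    runif(12, 50, 200)
  psfs <- build_gaussian_psfs(shift_field(matrix(0, 25, 2)), fwhm = 160,
                              pixel_size = 40, centered = TRUE)
  cts <- array(0, c(n, n, 25))
  for (ch in 1:25) {
    cts[, , ch] <- focusISM:::conv2_circ(o_true, psfs$kernels[, , ch])
  }
  list(o_true = o_true, psfs = psfs, ds = ism_dataset(cts, 40), cts = cts)
}

test_that("the true object is a fixed point of the multi-image update", {
  pr <- rl_problem()
  d <- dim(pr$cts)
  H <- lapply(1:25, function(ch) {
    focusISM:::fft2(focusISM:::embed_kernel(pr$psfs$kernels[, , ch],
                                            d[1:2]))
  })
  ohat <- focusISM:::fft2(pr$o_true)
  mult <- matrix(0, d[1], d[2])
  for (ch in 1:25) {
    den <- pmax(focusISM:::ifft2_re(H[[ch]] * ohat), 1e-12)
    mult <- mult + (1 / 25) * focusISM:::ifft2_re(
      Conj(H[[ch]]) * focusISM:::fft2(pmax(pr$cts[, , ch] / den, 1e-12)))
  }
  o1 <- pr$o_true * mult
  expect_lt(max(abs(o1 - pr$o_true)) / max(pr$o_true), 1e-6)
})

test_that("degenerate weights reduce to single-image Richardson-Lucy", {
  pr <- rl_problem()
  w <- rep(0, 25); w[13] <- 1
  r <- rl_multi(pr$ds, pr$psfs,
                deconv_config(iterations = 5, weights = w, init = "flat"))
  # directly coded single-image RL oracle
  o <- matrix(mean(sum_channels(pr$ds)), 64, 64)
  k13 <- pr$psfs$kernels[, , 13]
  k13r <- k13[rev(seq_len(nrow(k13))), rev(seq_len(ncol(k13)))]
  for (k in 1:5) {
    den <- pmax(focusISM:::conv2_circ(o, k13), 1e-12)
    o <- o * focusISM:::conv2_circ(pmax(pr$cts[, , 13] / den, 1e-12), k13r)
  }
  expect_lt(max(abs(r$estimate - o)) / max(o), 1e-9)
  # zero iterations return the initial estimate
  r0 <- rl_multi(pr$ds, pr$psfs,
                 deconv_config(iterations = 0, init = "flat"))
  expect_equal(r0$estimate,
               matrix(mean(sum_channels(pr$ds)), 64, 64))
  r0s <- rl_multi(pr$ds, pr$psfs, deconv_config(iterations = 0))
  expect_equal(r0s$estimate, sum_channels(pr$ds))
})

test_that("likelihood decreases monotonically and flux is conserved", {
  pr <- rl_problem()
  r <- rl_multi(pr$ds, pr$psfs, deconv_config(iterations = 8))
  expect_true(all(diff(r$nll) <= 1e-8 * abs(r$nll[1])))
  # unit-sum weights and kernels: flux within 1% of the weighted data flux
  flux_data <- sum(vapply(1:25, function(ch)
    r$weights[ch] * sum(pr$cts[, , ch]), numeric(1)))
  expect_lt(abs(sum(r$estimate) - flux_data) / flux_data, 0.01)
  # noisy problem stays monotone too
  set.seed(5)
  noisy <- ism_dataset(array(rpois(length(pr$cts), pmax(pr$cts, 0)),
                             dim(pr$cts)), 40)
  rn <- rl_multi(noisy, pr$psfs, deconv_config(iterations = 8))
  expect_true(all(diff(rn$nll) <= 1e-8 * abs(rn$nll[1])))
})

test_that("the background-aware update reduces correctly and stays
           non-negative", {
  pr <- rl_problem()
  cfg <- deconv_config(iterations = 4, weights = rep(1 / 25, 25))
  r_plain <- rl_multi(pr$ds, pr$psfs, cfg)
  r_zero_b <- rl_multi_background(pr$ds, pr$psfs, rep(0, 25), cfg)
  expect_equal(r_zero_b$estimate, r_plain$estimate, tolerance = 1e-12)
  # fixed point with the correct background included
  b_flat <- rep(2, 25)
  cts_b <- pr$cts + rep(2, each = 64 * 64)
  ds_b <- ism_dataset(cts_b, 40)
  d <- c(64, 64)
  H <- lapply(1:25, function(ch) {
    focusISM:::fft2(focusISM:::embed_kernel(pr$psfs$kernels[, , ch], d))
  })
  ohat <- focusISM:::fft2(pr$o_true)
  mult <- matrix(0, 64, 64)
  for (ch in 1:25) {
    den <- pmax(focusISM:::ifft2_re(H[[ch]] * ohat) + 2, 1e-12)
    mult <- mult + (1 / 25) * focusISM:::ifft2_re(
      Conj(H[[ch]]) * focusISM:::fft2(pmax(cts_b[, , ch] / den, 1e-12)))
  }
  expect_lt(max(abs(pr$o_true * mult - pr$o_true)) / max(pr$o_true), 1e-6)
  # grossly overstated background keeps iterates non-negative
  r_over <- rl_multi_background(ds_b, pr$psfs, rep(4, 25), cfg)
  expect_true(all(r_over$estimate >= 0))
  expect_error(rl_multi_background(ds_b, pr$psfs, rep(-1, 25), cfg),
               "non-negative")
})

test_that("five RL iterations sharpen a STED-ISM bead image", {
  ds <- bead_field(30)
  ar <- reassign(ds)
  # size the deconvolution PSF from the bead-measured width of the APR
  # image (beads are sub-diffraction, so their image width is the PSF)
  fb_ism <- fit_beads(ar$ism_image, 10, expected_fwhm = 150)
  psfs <- build_gaussian_psfs(ar$shift_field, fwhm = fb_ism$mean_fwhm,
                              pixel_size = 10, centered = TRUE)
  r <- rl_multi(ar$registered, psfs, deconv_config(iterations = 5))
  fb_dec <- fit_beads(r$estimate, 10, expected_fwhm = 150)
  expect_lt(fb_dec$mean_fwhm, fb_ism$mean_fwhm)
})
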