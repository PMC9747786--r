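#' Detect and fit fluorescent beads with 2D Gaussians
#'
#' Detects isolated local maxima above a threshold and fits a 2D Gaussian
#' plus constant offset in a window around each. A fit is flagged
#' unsuccessful when the fitted center leaves the window, the FWHM exceeds
#' the window, or the amplitude does not exceed the offset. Per-image
#' means and standard errors of FWHM and peak are computed over the
#' successful fits only.
#'
#' @param image 2D numeric matrix.
#' @param pixel_size Pixel size in nm.
#' @param threshold Absolute detection threshold; default
#'   `threshold_factor` times the image median (falling back to a tenth of
#'   the maximum when the median is zero).
#' @param threshold_factor Multiple of the median used for the default
#'   threshold.
#' @param expected_fwhm Rough expected bead image FWHM in nm; sets the fit
#'   window (7x the expected FWHM).
#' @param window Optional odd window size in pixels, overriding
#'   `expected_fwhm`.
#' @return A `bead_fit_result`: list with the per-bead `table`
#'   (y, x, fwhm, peak, success), `mean_fwhm`, `se_fwhm`, `mean_peak`,
#'   `se_peak`, `n_success`.
#' @export
fit_beads <- function(image, pixel_size, threshold = NULL,
                      threshold_factor = 10, expected_fwhm = 250,
                      window = NULL) {
  d <- dim(image)
  if (is.null(threshold)) {
    # a multiple of the median tracks the background level, floored at a
    # twentieth of the peak so broad dim pedestals do not trigger spurious
    # detections
    threshold <- max(threshold_factor * stats::median(image),
                     max(image) / 20)
  }
  if (is.null(window)) {
    window <- 2 * floor(7 * expected_fwhm / pixel_size / 2) + 1
  }
  # the window cannot exceed what the image accommodates
  window <- min(window, 2 * floor((min(d) - 3) / 4) + 1)
  half <- (window - 1) / 2

  # 8-neighborhood local maxima above threshold, away from the borders
  pk <- which(image > threshold)
  pk <- pk[vapply(pk, function(i) {
    yx <- arrayInd(i, d)
    y <- yx[1]; x <- yx[2]
    if (y <= half || y > d[1] - half || x <= half || x > d[2] - half) {
      return(FALSE)
    }
    nb <- image[(y - 1):(y + 1), (x - 1):(x + 1)]
    image[y, x] >= max(nb)
  }, logical(1))]
  if (!length(pk)) stop("no bead detections above the threshold")

  rows <- lapply(pk, function(i) {
    yx <- arrayInd(i, d)
    win <- image[(yx[1] - half):(yx[1] + half),
                 (yx[2] - half):(yx[2] + half)]
    fit <- fit_gauss2d(win)
    ok <- fit$converged &&
      abs(fit$y0) <= half && abs(fit$x0) <= half &&
      fit$fwhm_px >= 1 && fit$fwhm_px <= window &&
      fit$amp > max(fit$offset, 0)
    data.frame(y = yx[1] + fit$y0, x = yx[2] + fit$x0,
               fwhm = fit$fwhm_px * pixel_size,
               peak = fit$amp + fit$offset, success = ok)
  })
  tab <- do.call(rbind, rows)
  okt <- tab[tab$success, , drop = FALSE]
  se <- function(v) if (nrow(okt) > 1) stats::sd(v) / sqrt(length(v)) else 0
  structure(list(table = tab,
                 mean_fwhm = mean(okt$fwhm), se_fwhm = se(okt$fwhm),
                 mean_peak = mean(okt$peak), se_peak = se(okt$peak),
                 n_success = nrow(okt)),
            class = "bead_fit_result")
}

# Least-squares fit of amp * exp(-r^2 / 2 sigma^2) + offset to a window;
# coordinates relative to the window center.
fit_gauss2d <- function(win) {
  k <- dim(win)[1]
  half <- (k - 1) / 2
  cc <- seq(-half, half)
  yy <- matrix(cc, k, k); xx <- t(yy)
  start <- c(amp = max(win) - min(win), y0 = 0, x0 = 0,
             sigma = max(1, half / 4), offset = min(win))
  obj <- function(p) {
    g <- p[1] * exp(-((yy - p[2])^2 + (xx - p[3])^2) / (2 * p[4]^2)) + p[5]
    sum((g - win)^2)
  }
  opt <- try(stats::optim(start, obj, method = "L-BFGS-B",
                          lower = c(0, -half, -half, 0.3, -Inf),
                          upper = c(Inf, half, half, k, Inf)),
             silent = TRUE)
  if (inherits(opt, "try-error")) {
    return(list(converged = FALSE, amp = NA, y0 = NA, x0 = NA,
                fwhm_px = NA, offset = NA))
  }
  p <- opt$par
  list(converged = opt$convergence == 0, amp = p[1], y0 = p[2], x0 = p[3],
       fwhm_px = 2 * sqrt(2 * log(2)) * p[4], offset = p[5])
}

#' @export
print.bead_fit_result <- function(x, ...) {
  cat(sprintf(
    "bead_fit_result: %d successful fit%s, FWHM %.1f +/- %.1f nm, peak %.3g +/- %.2g\n",
    x$n_success, if (x$n_success == 1) "" else "s",
    x$mean_fwhm, x$se_fwhm, x$mean_peak, x$se_peak))
  invisible(x)
}

#' Resolution and signal gain between two bead fields
#'
#' Compares bead-fit summaries of the same field imaged two ways:
#' resolution gain = mean FWHM(reference) / mean FWHM(test) and signal
#' gain = mean peak(test) / mean peak(reference), with standard errors
#' propagated in quadrature. Values above 1 mean the test image is sharper
#' / brighter; both gains are invariant under a common intensity scaling.
#'
#' @param reference A [fit_beads()] result for the reference (e.g.
#'   open-pinhole) image.
#' @param test A [fit_beads()] result for the test (e.g. ISM) image.
#' @return List with `resolution_gain`, `signal_gain` and their standard
#'   errors.
#' @export
gains <- function(reference, test) {
  stopifnot(inherits(reference, "bead_fit_result"),
            inherits(test, "bead_fit_result"))
  if (test$mean_fwhm <= 0 || reference$mean_peak <= 0) {
    stop("zero denominator in gain computation")
  }
  rg <- reference$mean_fwhm / test$mean_fwhm
  sg <- test$mean_peak / reference$mean_peak
  rel <- function(a, sa, b, sb) sqrt((sa / a)^2 + (sb / b)^2)
  list(resolution_gain = rg,
       resolution_gain_se = rg * rel(reference$mean_fwhm, reference$se_fwhm,
                                     test$mean_fwhm, test$se_fwhm),
       signal_gain = sg,
       signal_gain_se = sg * rel(test$mean_peak, test$se_peak,
                                 reference$mean_peak, reference$se_peak))
}

#' Radial modulation transfer function
#'
#' Radially averaged magnitude of the discrete Fourier transform of a
#' centered PSF, normalized to 1 at zero frequency.
#'
#' @param psf 2D PSF image (centered).
#' @param pixel_size Pixel size in nm.
#' @return Data frame with `freq` (1/nm) and `mtf`.
#' @export
mtf <- function(psf, pixel_size = 1) {
  d <- dim(psf)
  M <- Mod(fft2(psf))
  fy <- fft_freqs(d[1]) / d[1]; fx <- fft_freqs(d[2]) / d[2]
  fr <- sqrt(outer(fy^2, fx^2, `+`))
  nb <- floor(min(d) / 2)
  ring <- pmin(round(fr * min(d)), nb)
  m <- tapply(M, ring, mean)
  m <- as.numeric(m[order(as.integer(names(m)))])
  m <- m / m[1]
  data.frame(freq = (0:nb) / (min(d) * pixel_size), mtf = m)
}

#' Cutoff frequency of a radial MTF
#'
#' Two measures of the optical-transfer-function cutoff. `"threshold"`
#' returns the linear-interpolated first crossing of the MTF below
#' `threshold`. `"support"` returns the frequency where the curve first
#' stops decreasing after falling below `threshold`, i.e. where it either
#' dips into a transfer zero or meets its numerical noise floor; this
#' locates the true support edge to within one frequency bin regardless
#' of how fast the MTF vanishes at its edge (the band-limit of a
#' diffraction-limited PSF is a hard support, but the approach to it can
#' be of high order, e.g. for a confocal product PSF).
#'
#' @param mtf_df Data frame from [mtf()].
#' @param threshold Relative MTF level for the `"threshold"` method.
#' @param method `"threshold"`: linear-interpolated first crossing below
#'   `threshold`. `"support"`: midpoint of the ring interval with the
#'   largest log-decrement, i.e. where the curve crashes into a transfer
#'   zero or its numerical floor — this locates a hard band limit to
#'   within half a frequency bin however fast the MTF vanishes at its
#'   edge (a confocal product PSF approaches its support to high order).
#' @return Frequency in 1/nm (`NA` when no cutoff is found).
#' @export
otf_cutoff <- function(mtf_df, threshold = 1e-3,
                       method = c("threshold", "support")) {
  method <- match.arg(method)
  m <- mtf_df$mtf; f <- mtf_df$freq
  if (method == "threshold") {
    below <- which(m < threshold)
    if (!length(below)) return(NA_real_)
    i <- below[1]
    if (i == 1) return(f[1])
    return(f[i - 1] + (m[i - 1] - threshold) / (m[i - 1] - m[i]) *
             (f[i] - f[i - 1]))
  }
  ok <- m > .Machine$double.xmin
  ratio <- m[-length(m)] / pmax(m[-1], .Machine$double.xmin)
  ratio[!ok[-length(m)]] <- 1
  i <- which.max(ratio)
  if (ratio[i] < 5) return(NA_real_)   # no decisive edge
  (f[i] + f[i + 1]) / 2
}

#' Outer-to-center fingerprint intensity ratio
#'
#' For a sequence of fingerprints (e.g. one per z-plane), the ratio of the
#' summed intensity of the 16 outer-frame elements to the central element.
#' The ratio grows with defocus: out-of-focus light spreads to the outer
#' detector elements.
#'
#' @param fps A list of [fingerprint()]s / 5x5 matrices, or a 5x5xK array.
#' @return Numeric vector of ratios.
#' @export
fingerprint_outer_center_ratio <- function(fps) {
  if (is.array(fps) && length(dim(fps)) == 3) {
    fps <- lapply(seq_len(dim(fps)[3]), function(k) fps[, , k])
  }
  vapply(fps, function(f) {
    f <- unclass(f)
    stopifnot(all(dim(f) == c(5, 5)))
    if (f[3, 3] == 0) stop("central fingerprint element is zero")
    (sum(f) - sum(f[2:4, 2:4])) / f[3, 3]
  }, numeric(1))
}

#' High- to low-frequency energy ratio of an image spectrum
#'
#' Splits the radially averaged power spectrum at `split` times the
#' Nyquist frequency and returns the energy ratio above/below the split
#' (the DC term is excluded). Removing blurred out-of-focus content
#' raises this ratio.
#'
#' @param image 2D numeric matrix.
#' @param split Fraction of the Nyquist frequency separating "low" from
#'   "high" (default 0.25).
#' @return Scalar energy ratio.
#' @export
radial_spectrum_contrast <- function(image, split = 0.25) {
  d <- dim(image)
  P <- Mod(fft2(image))^2
  fy <- fft_freqs(d[1]) / d[1]; fx <- fft_freqs(d[2]) / d[2]
  fr <- sqrt(outer(fy^2, fx^2, `+`))
  hi <- sum(P[fr >= split * 0.5 & fr <= 0.5])
  lo <- sum(P[fr > 0 & fr < split * 0.5])
  hi / lo
}
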