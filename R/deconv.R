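#' Single-image resolution estimate by Fourier ring correlation
#'
#' Splits the image into two statistically independent sub-images by
#' diagonal checkerboard subsampling (odd/odd vs even/even pixels), and
#' computes the ring-wise normalized cross-correlation of their spectra.
#' The half-pixel diagonal offset between the two sub-grids is compensated
#' by a phase ramp on the cross-spectrum before ring averaging. The curve
#' is smoothed with a 3-ring moving average and the first crossing of the
#' fixed 1/7 threshold gives the resolution as the inverse of that spatial
#' frequency. Without a crossing (e.g. a noise-free image, whose halves
#' stay fully correlated), the sub-image Nyquist bound is returned with a
#' warning.
#'
#' @param image 2D numeric matrix, at least 64 x 64.
#' @param pixel_size Pixel size in nm.
#' @return Resolution in nm, with attributes `frc` (the ring curve) and
#'   `freq` (ring frequencies in 1/nm).
#' @export
frc_resolution <- function(image, pixel_size) {
  d <- dim(image)
  if (any(d < 64)) stop("FRC needs an image of at least 64 x 64 pixels")
  ny <- 2 * (d[1] %/% 2); nx <- 2 * (d[2] %/% 2)
  a <- image[seq(1, ny, 2), seq(1, nx, 2)]
  b <- image[seq(2, ny, 2), seq(2, nx, 2)]
  da <- dim(a)
  FA <- fft2(a); FB <- fft2(b)
  # the even/even grid sits (+1/2, +1/2) sub-pixels from the odd/odd grid
  py <- exp(2i * pi * fft_freqs(da[1]) * 0.5 / da[1])
  px <- exp(2i * pi * fft_freqs(da[2]) * 0.5 / da[2])
  cross <- FA * Conj(FB) * outer(py, px)

  fy <- fft_freqs(da[1]) / da[1]
  fx <- fft_freqs(da[2]) / da[2]
  fr <- sqrt(outer(fy^2, fx^2, `+`))      # cycles per sub-image pixel
  nring <- floor(min(da) / 2)
  ring <- pmin(pmax(round(fr * min(da)), 0), nring)
  num <- tapply(Re(cross), ring, sum)
  dna <- tapply(Mod(FA)^2, ring, sum)
  dnb <- tapply(Mod(FB)^2, ring, sum)
  frc <- as.numeric(num / sqrt(dna * dnb))
  rid <- as.integer(names(num))
  frc <- frc[order(rid)][-1]              # drop the DC ring
  nr <- length(frc)
  sm <- frc
  if (nr >= 3) {
    sm[2:(nr - 1)] <- (frc[1:(nr - 2)] + frc[2:(nr - 1)] + frc[3:nr]) / 3
  }
  sub_px <- 2 * pixel_size
  freq <- seq_len(nr) / (min(da) * sub_px)  # 1/nm
  thr <- 1 / 7
  below <- which(sm < thr)
  if (!length(below)) {
    warning("FRC never crosses 1/7; returning the sub-image Nyquist bound")
    res <- 2 * sub_px
  } else {
    i <- below[1]
    f_cross <- if (i == 1) freq[1] else {
      freq[i - 1] + (sm[i - 1] - thr) / (sm[i - 1] - sm[i]) *
        (freq[i] - freq[i - 1])
    }
    res <- 1 / f_cross
  }
  structure(res, frc = sm, freq = freq)
}

#' Gaussian PSF set for multi-image deconvolution
#'
#' Builds 25 unit-sum 2D Gaussian kernels of common FWHM, one per detector
#' element, centered at the element's shift vector (`centered = FALSE`,
#' for deconvolving raw scanned images) or all centered at zero
#' (`centered = TRUE`, for post-reassignment data). The kernel support is
#' chosen so that the truncated mass is below 1e-6 before normalization.
#'
#' @param shifts A [shift_field()].
#' @param fwhm Common PSF full width at half maximum in nm (typically the
#'   [frc_resolution()] of the ISM image).
#' @param pixel_size Scan pixel size in nm.
#' @param centered Ignore the shifts and center every kernel.
#' @return A `gaussian_psf_set`: list with `kernels` (array
#'   `[k, k, 25]`), `fwhm`, `pixel_size`, `shifts`, `centered`.
#' @export
build_gaussian_psfs <- function(shifts, fwhm, pixel_size,
                                centered = FALSE) {
  stopifnot(fwhm > 0, pixel_size > 0)
  if (fwhm < pixel_size) {
    warning("PSF FWHM (", signif(fwhm, 3), " nm) is below the pixel size; ",
            "the kernel is under-sampled")
  }
  sh <- if (centered) matrix(0, 25, 2) else unclass(shifts)
  sigma_px <- fwhm / (2 * sqrt(2 * log(2))) / pixel_size
  half <- ceiling(5.3 * sigma_px + max(abs(sh)))
  k <- 2 * half + 1
  yy <- seq_len(k) - half - 1
  kernels <- array(0, c(k, k, 25))
  for (ch in 1:25) {
    g <- exp(-(outer((yy - sh[ch, 1])^2, (yy - sh[ch, 2])^2, `+`)) /
               (2 * sigma_px^2))
    kernels[, , ch] <- g / sum(g)
  }
  structure(list(kernels = kernels, fwhm = fwhm, pixel_size = pixel_size,
                 shifts = sh, centered = centered),
            class = "gaussian_psf_set")
}

#' Deconvolution configuration
#'
#' @param iterations Number of multiplicative updates k (default 5).
#' @param weights Per-channel weights w_nm; default: inverse-fingerprint
#'   weights computed from the data (elements with zero fingerprint are
#'   excluded), normalized to unit sum.
#' @param epsilon Floor applied to denominators and ratios.
#' @param stop_tol Optional early-stopping threshold on the relative
#'   change of the estimate (`NULL` = always run `iterations` steps).
#' @param init Initial estimate: `"sum"` starts from the channel-summed
#'   image (so even a handful of iterations sharpens, matching the
#'   few-step manual stopping used in practice), `"flat"` from a constant
#'   image at the mean of the channel sum.
#' @return A `deconv_config` list.
#' @export
deconv_config <- function(iterations = 5, weights = NULL,
                          epsilon = 1e-12, stop_tol = NULL,
                          init = c("sum", "flat")) {
  stopifnot(iterations >= 0, epsilon > 0)
  init <- match.arg(init)
  if (!is.null(weights)) {
    stopifnot(length(weights) == 25, all(weights >= 0), sum(weights) > 0)
    weights <- weights / sum(weights)
  }
  structure(list(iterations = iterations, weights = weights,
                 epsilon = epsilon, stop_tol = stop_tol, init = init),
            class = "deconv_config")
}

#' Inverse-fingerprint channel weights
#'
#' The weight of element (n, m) is the inverse of its fingerprint value
#' (its total photon count), reflecting the per-channel signal-to-noise;
#' zero-fingerprint elements get zero weight. Weights are normalized to
#' unit sum, which preserves the Richardson-Lucy fixed point.
#'
#' @param x An [ism_dataset()] or a [fingerprint()].
#' @return Numeric vector of 25 weights summing to 1.
#' @export
inverse_fingerprint_weights <- function(x) {
  fp <- if (inherits(x, "fingerprint")) x else fingerprint(x)
  el <- element_table()
  f <- unclass(fp)[cbind(el[, "n"] + 3, el[, "m"] + 3)]
  w <- ifelse(f > 0, 1 / pmax(f, .Machine$double.xmin), 0)
  w[f <= 0] <- 0
  w / sum(w)
}

#' Multi-image Richardson-Lucy deconvolution
#'
#' Jointly deconvolves the 25 scanned images with the multiplicative
#' update
#' \deqn{o^{k+1} = o^k \sum_{n,m} w_{n,m}\, \left[h^*_{n,m} \star
#'   \frac{i_{n,m}}{h_{n,m} * o^k}\right],}
#' where * is convolution, the star is correlation (the adjoint), and the
#' weights w_nm sum to one. The initial estimate is the channel-summed
#' image (or a flat image at its mean, see [deconv_config()]).
#' Denominators and ratios are floored at
#' `epsilon`. With unit-sum kernels and weights the true object is a fixed
#' point of the update on noiseless data, and the weighted Poisson
#' negative log-likelihood (recorded per iteration) is non-increasing.
#'
#' Use shifted kernels on raw scanned images, or centered kernels on a
#' registered (post-reassignment) dataset.
#'
#' @param dataset A 2D [ism_dataset()].
#' @param psfs A [build_gaussian_psfs()] set.
#' @param config A [deconv_config()].
#' @param background Optional expected background: `NULL`, a vector of 25
#'   per-element values, or an array `[Ny, Nx, 25]` (e.g. the
#'   `background_per_element` of a [f2_classify()] result). See
#'   [rl_multi_background()].
#' @return An `rl_result`: list with `estimate`, the per-iteration
#'   `nll`, `iterations` actually run, and the configuration.
#' @export
rl_multi <- function(dataset, psfs, config = deconv_config(),
                     background = NULL) {
  d <- dim(dataset$counts)
  if (length(d) != 3) stop("rl_multi expects a single-plane (2D) dataset")
  if (sum(dataset$counts) <= 0) stop("dataset is empty")
  w <- config$weights
  if (is.null(w)) w <- inverse_fingerprint_weights(dataset)
  eps <- config$epsilon

  bg <- array(0, d)
  if (!is.null(background)) {
    if (is.null(dim(background))) {
      stopifnot(length(background) == 25)
      if (any(background < 0)) stop("background must be non-negative")
      bg <- aperm(array(background, c(25, d[1], d[2])), c(2, 3, 1))
    } else {
      stopifnot(all(dim(background) == d))
      if (any(background < 0)) stop("background must be non-negative")
      bg <- background
    }
  }

  H <- vector("list", 25)
  for (ch in 1:25) {
    H[[ch]] <- fft2(embed_kernel(psfs$kernels[, , ch], d[1:2]))
  }
  o <- if (identical(config$init, "flat")) {
    matrix(mean(sum_channels(dataset)), d[1], d[2])
  } else {
    pmax(sum_channels(dataset), 0)
  }
  nll <- numeric(0)
  used <- 0L
  for (k in seq_len(config$iterations)) {
    ohat <- fft2(o)
    mult <- matrix(0, d[1], d[2])
    ll <- 0
    for (ch in 1:25) {
      if (w[ch] == 0) next
      den <- pmax(ifft2_re(H[[ch]] * ohat) + bg[, , ch], eps)
      i_ch <- dataset$counts[, , ch]
      ll <- ll + w[ch] * sum(den - i_ch * log(den))
      ratio <- pmax(i_ch / den, eps)
      mult <- mult + w[ch] * ifft2_re(Conj(H[[ch]]) * fft2(ratio))
    }
    if (anyNA(mult)) stop("NaN in Richardson-Lucy update at iteration ", k)
    o_new <- pmax(o * mult, 0)
    nll <- c(nll, ll)
    relchg <- sum(abs(o_new - o)) / max(sum(o), eps)
    o <- o_new
    used <- k
    if (!is.null(config$stop_tol) && relchg < config$stop_tol) break
  }
  structure(list(estimate = o, nll = nll, iterations = used,
                 weights = w, config = config,
                 background_used = !is.null(background)),
            class = "rl_result")
}

#' Background-aware multi-image Richardson-Lucy deconvolution
#'
#' Variant of [rl_multi()] whose denominator includes the expected
#' per-element background b_nm (from [f1_classify()], [f2_classify()],
#' and/or a dark-count estimate):
#' \deqn{o^{k+1} = o^k \sum_{n,m} w_{n,m}\, \left[\bar h^*_{n,m} \star
#'   \frac{i_{n,m}}{\bar h_{n,m} * o^k + b_{n,m}}\right].}
#' Intended for post-reassignment data with centered kernels; the
#' multiplicative update keeps all iterates non-negative even when the
#' background is overstated.
#'
#' @param dataset A 2D registered [ism_dataset()].
#' @param psfs A centered [build_gaussian_psfs()] set (a warning is issued
#'   otherwise).
#' @param background 25 per-element values or an `[Ny, Nx, 25]` array.
#' @param config A [deconv_config()].
#' @return An `rl_result`.
#' @export
rl_multi_background <- function(dataset, psfs, background,
                                config = deconv_config()) {
  if (!psfs$centered) {
    warning("background-aware deconvolution expects centered PSFs ",
            "on post-reassignment data")
  }
  rl_multi(dataset, psfs, config, background = background)
}

#' @export
print.rl_result <- function(x, ...) {
  cat(sprintf(
    "rl_result: %d iteration%s, final NLL %.6g%s\n", x$iterations,
    if (x$iterations == 1) "" else "s",
    if (length(x$nll)) x$nll[length(x$nll)] else NA,
    if (x$background_used) ", background-aware" else ""))
  invisible(x)
}
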