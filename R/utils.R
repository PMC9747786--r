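# Internal numeric helpers shared across modules. All images are matrices
# indexed [y, x]; volumes are arrays [y, x, z]; the channel axis, when
# present, is the last margin before z (datasets) or the last margin (PSF
# stacks).

# Signed DFT frequency indices: 0, 1, ..., floor((n-1)/2), -floor(n/2), ..., -1
fft_freqs <- function(n) {
  k <- seq_len(n) - 1
  k[k > n / 2] <- k[k > n / 2] - n
  k
}

# Physical coordinate of each grid point along one axis; the center sample
# (odd n) sits exactly at 0.
axis_coords <- function(n, step) {
  (seq_len(n) - (n + 1) / 2) * step
}

# Roll a matrix so that out[i, j] = m[i - s1, j - s2] (circularly).
circshift2 <- function(m, s) {
  d <- dim(m)
  i <- ((seq_len(d[1]) - 1 - s[1]) %% d[1]) + 1
  j <- ((seq_len(d[2]) - 1 - s[2]) %% d[2]) + 1
  m[i, j, drop = FALSE]
}

# Embed a small odd-sized kernel into a zero matrix of size dim_out with the
# kernel's central pixel at position (1, 1), wrapped circularly, ready for
# FFT-based circular convolution without translation of the output.
embed_kernel <- function(kernel, dim_out) {
  dk <- dim(kernel)
  if (any(dk %% 2 == 0)) stop("kernel must have odd dimensions")
  if (any(dk > dim_out)) stop("kernel larger than target image")
  ctr <- (dk + 1) / 2
  out <- matrix(0, dim_out[1], dim_out[2])
  i <- ((seq_len(dk[1]) - ctr[1]) %% dim_out[1]) + 1
  j <- ((seq_len(dk[2]) - ctr[2]) %% dim_out[2]) + 1
  out[i, j] <- kernel
  out
}

fft2 <- function(m) stats::fft(m)
ifft2_re <- function(m) Re(stats::fft(m, inverse = TRUE)) / length(m)

# Circular convolution of an image with a kernel (odd size, centered).
conv2_circ <- function(image, kernel) {
  ifft2_re(fft2(image) * fft2(embed_kernel(kernel, dim(image))))
}

# Circular convolution of two same-size arrays both centered at the grid
# center voxel; the result stays centered.
conv2_centered <- function(a, b) {
  ctr <- (dim(b) + 1) / 2
  if (any(ctr != round(ctr))) stop("conv2_centered requires odd dimensions")
  ifft2_re(fft2(a) * fft2(circshift2(b, -(ctr - 1))))
}

# Linear (zero-padded) convolution of two same-size odd arrays, both
# centered at the grid center voxel; the result is cropped back to the
# input grid and stays centered. Avoids periodic wrap-around of tails.
conv2_centered_linear <- function(a, b) {
  d <- dim(a)
  if (any(d != dim(b))) stop("arrays must have the same size")
  dp <- 2 * d - 1
  pa <- matrix(0, dp[1], dp[2]); pb <- matrix(0, dp[1], dp[2])
  off <- (d - 1) / 2
  pa[off[1] + seq_len(d[1]), off[2] + seq_len(d[2])] <- a
  pb[off[1] + seq_len(d[1]), off[2] + seq_len(d[2])] <- b
  full <- conv2_centered(pa, pb)
  full[off[1] + seq_len(d[1]), off[2] + seq_len(d[2])]
}

# Translate an image by a (possibly fractional) shift via the Fourier shift
# theorem; periodic boundaries, exact preservation of the total (DC term).
fourier_shift2d <- function(img, dy, dx) {
  d <- dim(img)
  py <- exp(-2i * pi * fft_freqs(d[1]) * dy / d[1])
  px <- exp(-2i * pi * fft_freqs(d[2]) * dx / d[2])
  # make the unmatched Nyquist component real so the output stays real
  if (d[1] %% 2 == 0) py[d[1] / 2 + 1] <- Re(py[d[1] / 2 + 1])
  if (d[2] %% 2 == 0) px[d[2] / 2 + 1] <- Re(px[d[2] / 2 + 1])
  ifft2_re(fft2(img) * outer(py, px))
}

# One-dimensional parabolic refinement of a discrete peak from its 3-point
# neighborhood; returns the fractional offset in [-1/2, 1/2].
parabolic_offset <- function(ym, y0, yp) {
  den <- ym - 2 * y0 + yp
  if (!is.finite(den) || abs(den) < .Machine$double.eps * max(abs(c(ym, y0, yp)), 1)) {
    return(0)
  }
  max(-0.5, min(0.5, 0.5 * (ym - yp) / den))
}

# Position of the maximum of a matrix/3D array with sub-sample parabolic
# refinement along each axis; ties broken toward the grid center.
subvoxel_argmax <- function(a) {
  d <- dim(a)
  mx <- max(a)
  if (mx == min(a)) stop("argmax undefined: array is flat")
  cand <- which(a >= mx * (1 - 1e-12))
  idx <- arrayInd(cand, d)
  ctr <- (d + 1) / 2
  dist2 <- rowSums((sweep(idx, 2, ctr))^2)
  pk <- idx[which.min(dist2), ]
  pos <- as.numeric(pk)
  for (ax in seq_along(d)) {
    if (pk[ax] > 1 && pk[ax] < d[ax]) {
      at <- function(off) {
        i <- pk
        i[ax] <- i[ax] + off
        a[matrix(i, 1)]
      }
      pos[ax] <- pos[ax] + parabolic_offset(at(-1), at(0), at(1))
    }
  }
  pos
}

# Full width at half maximum of a sampled 1D profile (baseline assumed 0),
# with linear interpolation of the half-max crossings. Returns NA when the
# profile does not fall below half max on both sides.
profile_fwhm <- function(y, step = 1) {
  n <- length(y)
  pk <- which.max(y)
  half <- y[pk] / 2
  left <- NA_real_
  for (i in seq(pk, 2)) {
    if (y[i - 1] < half) {
      left <- (i - 1) + (half - y[i - 1]) / (y[i] - y[i - 1])
      break
    }
  }
  right <- NA_real_
  for (i in seq(pk, n - 1)) {
    if (y[i + 1] < half) {
      right <- i + (y[i] - half) / (y[i] - y[i + 1])
      break
    }
  }
  (right - left) * step
}

#' Lateral full width at half maximum of a peaked image
#'
#' Measures the FWHM of a single bright structure (typically a PSF) by
#' linear interpolation of the half-maximum crossings along the row and the
#' column passing through the peak, and returns their mean.
#'
#' @param image Numeric matrix with a single dominant peak.
#' @param pixel_size Physical size of one pixel (same units as the result).
#' @return FWHM in units of `pixel_size`.
#' @export
lateral_fwhm <- function(image, pixel_size = 1) {
  pk <- arrayInd(which.max(image), dim(image))
  wy <- profile_fwhm(image[, pk[2]], pixel_size)
  wx <- profile_fwhm(image[pk[1], ], pixel_size)
  mean(c(wy, wx), na.rm = TRUE)
}

# Simpson quadrature weights on n (odd) equispaced nodes, unit spacing.
simpson_weights <- function(n) {
  if (n %% 2 == 0) stop("Simpson rule needs an odd number of nodes")
  w <- rep(2, n)
  w[seq(2, n - 1, by = 2)] <- 4
  w[c(1, n)] <- 1
  w / 3
}

# 3x3 box sum over the scan dimensions of a matrix, edge-truncated.
boxsum3 <- function(m) {
  pad <- function(v, side) {
    if (side == "pre") rbind(m[1, , drop = FALSE] * 0, m[-nrow(m), , drop = FALSE])
    else rbind(m[-1, , drop = FALSE], m[1, , drop = FALSE] * 0)
  }
  up <- pad(m, "pre"); dn <- pad(m, "post")
  s <- m + up + dn
  left <- cbind(s[, 1, drop = FALSE] * 0, s[, -ncol(s), drop = FALSE])
  right <- cbind(s[, -1, drop = FALSE], s[, 1, drop = FALSE] * 0)
  s + left + right
}
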