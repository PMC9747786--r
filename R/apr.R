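#' Estimate shift vectors by phase correlation
#'
#' Estimates, for every detector element, the translation that registers
#' its scanned image onto the central-element image. The cross-power
#' spectrum is normalized by its magnitude (with a small floor), its
#' inverse transform is searched for the correlation peak, and the peak is
#' refined to `1/upsampling` pixel by a local matrix-multiply discrete
#' Fourier transform. Ties between equal peaks are broken toward the
#' smallest-magnitude shift. The sign convention is such that a channel
#' whose structure sits at +d relative to the reference receives shift -d,
#' i.e. applying the returned shift aligns the channel with the reference.
#'
#' Channels whose fingerprint value falls below `low_signal_frac` of the
#' fingerprint maximum carry little signal; when `regularize` is `TRUE`
#' their estimates are replaced by a least-squares linear model of shift
#' versus element displacement fitted on the well-lit channels. All-zero
#' channels are always replaced by the model prediction, with a warning.
#'
#' For 3D datasets the shifts are estimated on the brightest plane and
#' apply to all planes.
#'
#' @param dataset An [ism_dataset()].
#' @param upsampling Sub-pixel refinement factor (integer >= 1).
#' @param regularize Replace low-signal estimates by the linear model.
#' @param low_signal_frac Fingerprint fraction below which an element
#'   counts as low-signal.
#' @param plane Plane used for estimation (default: brightest).
#' @return A [shift_field()].
#' @export
estimate_shifts <- function(dataset, upsampling = 20, regularize = TRUE,
                            low_signal_frac = 0.1, plane = NULL) {
  stopifnot(upsampling >= 1)
  if (is.null(plane)) {
    plane <- if (n_planes(dataset) == 1) 1 else {
      which.max(vapply(seq_len(n_planes(dataset)),
                       function(z) sum(plane_counts(dataset, z)),
                       numeric(1)))
    }
  }
  cts <- plane_counts(dataset, plane)
  ref <- cts[, , 13]
  if (max(ref) == min(ref)) {
    stop("central-element image is empty or flat; cannot register")
  }
  fp <- apply(cts, 3, sum)
  shifts <- matrix(NA_real_, 25, 2)
  shifts[13, ] <- 0
  for (ch in (1:25)[-13]) {
    img <- cts[, , ch]
    if (max(img) == min(img)) next  # left NA, filled by the model below
    shifts[ch, ] <- -phase_corr_shift(img, ref, upsampling)
  }

  el <- element_table()
  bad <- which(!is.finite(shifts[, 1]))
  low <- which(fp < low_signal_frac * max(fp))
  replace <- if (regularize) union(bad, low) else bad
  replace <- setdiff(replace, 13L)
  if (length(replace)) {
    good <- setdiff(which(is.finite(shifts[, 1])), replace)
    if (length(good) < 3) {
      stop("too few well-lit channels to regularize the shift field")
    }
    X <- cbind(1, el[, "n"], el[, "m"])
    fit <- stats::lm.fit(X[good, , drop = FALSE],
                         shifts[good, , drop = FALSE])
    pred <- X %*% fit$coefficients
    if (length(bad)) {
      warning("channel(s) ", paste(bad, collapse = ", "),
              " carry no signal; shifts replaced by the linear model")
    }
    shifts[replace, ] <- pred[replace, ]
  }
  shifts <- sweep(shifts, 2, shifts[13, ])
  shift_field(shifts, method = "phase_correlation",
              upsampling = upsampling, regularized = replace)
}

# Displacement (dy, dx) of image `a` relative to image `b` maximizing the
# normalized cross-power correlation, refined to 1/upsampling pixel by a
# local matrix-multiply DFT; ties go to the smallest-magnitude shift.
phase_corr_shift <- function(a, b, upsampling = 20, eps = 1e-12) {
  d <- dim(a)
  R <- fft2(a) * Conj(fft2(b))
  R <- R / pmax(Mod(R), eps)
  r <- Re(stats::fft(R, inverse = TRUE))
  mx <- max(r)
  cand <- which(r >= mx * (1 - 1e-9))
  ci <- arrayInd(cand, d)
  sh <- ci - 1
  sh[, 1] <- ifelse(sh[, 1] > d[1] / 2, sh[, 1] - d[1], sh[, 1])
  sh[, 2] <- ifelse(sh[, 2] > d[2] / 2, sh[, 2] - d[2], sh[, 2])
  pk <- sh[which.min(rowSums(sh^2)), ]
  if (upsampling <= 1) return(as.numeric(pk))

  ys <- pk[1] + seq(-1, 1, by = 1 / upsampling)
  xs <- pk[2] + seq(-1, 1, by = 1 / upsampling)
  Wy <- exp(2i * pi * outer(ys, fft_freqs(d[1])) / d[1])
  Wx <- exp(2i * pi * outer(fft_freqs(d[2]), xs) / d[2])
  C <- Re(Wy %*% R %*% Wx)
  mx <- max(C)
  cand <- arrayInd(which(C >= mx * (1 - 1e-12)), dim(C))
  best <- cbind(ys[cand[, 1]], xs[cand[, 2]])
  as.numeric(best[which.min(rowSums(best^2)), ])
}

#' Adaptive pixel reassignment
#'
#' Registers the 25 scanned images by translating each by its shift vector
#' (Fourier-shift interpolation, periodic boundaries) and sums them into
#' the ISM image; the open-pinhole image is the sum of the unshifted
#' channels. The periodic shift preserves each channel's total exactly, so
#' the ISM and open images carry the same photon count. An optional crop
#' margin (default `ceil(max |shift|)` when `crop = TRUE`) trims the
#' wrap-contaminated borders of the returned images.
#'
#' @param dataset An [ism_dataset()].
#' @param shifts A [shift_field()]; estimated from the data when `NULL`.
#' @param crop Logical or integer margin (pixels) to trim from the output
#'   images (the registered dataset is never cropped).
#' @param ... Passed to [estimate_shifts()] when `shifts` is `NULL`.
#' @return An `apr_result`: list with the real-valued `registered` dataset,
#'   `ism_image`, `open_image`, `shift_field` and `crop_margin`.
#' @export
reassign <- function(dataset, shifts = NULL, crop = FALSE, ...) {
  if (is.null(shifts)) shifts <- estimate_shifts(dataset, ...)
  stopifnot(inherits(shifts, "shift_field"))
  d <- dim(dataset$counts)
  maxsh <- max(abs(unclass(shifts)))
  if (maxsh > min(d[1], d[2]) / 4) {
    warning("largest shift (", round(maxsh, 1), " px) exceeds a quarter ",
            "of the image extent; likely mis-registration")
  }
  nz <- n_planes(dataset)
  reg <- array(0, dim = d)
  for (z in seq_len(nz)) {
    pc <- plane_counts(dataset, z)
    for (ch in 1:25) {
      img <- fourier_shift2d(pc[, , ch], unclass(shifts)[ch, 1],
                             unclass(shifts)[ch, 2])
      if (nz == 1) reg[, , ch] <- img else reg[, , ch, z] <- img
    }
  }
  registered <- ism_dataset(reg, pixel_size = dataset$pixel_size,
                            z_spacing = dataset$z_spacing,
                            detector = dataset$detector,
                            provenance = c(dataset$provenance,
                                           list(registered = TRUE)))
  ism <- sum_channels(registered)
  open <- sum_channels(dataset)
  margin <- if (isTRUE(crop)) ceiling(maxsh) else if (is.numeric(crop)) crop else 0
  if (margin > 0) {
    keep_y <- (margin + 1):(d[1] - margin)
    keep_x <- (margin + 1):(d[2] - margin)
    ism <- if (nz == 1) ism[keep_y, keep_x] else ism[keep_y, keep_x, ]
    open <- if (nz == 1) open[keep_y, keep_x] else open[keep_y, keep_x, ]
  }
  structure(list(registered = registered, ism_image = ism,
                 open_image = open, shift_field = shifts,
                 crop_margin = margin),
            class = "apr_result")
}

#' @export
print.apr_result <- function(x, ...) {
  cat(sprintf(
    "apr_result: ISM total %.6g, open total %.6g, max |shift| %.2f px\n",
    sum(x$ism_image), sum(x$open_image),
    max(abs(unclass(x$shift_field)))))
  invisible(x)
}
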