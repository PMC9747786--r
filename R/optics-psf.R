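#' Per-element scanned PSFs of the (STED-)ISM microscope
#'
#' Builds the 25 scanned point spread functions h_nm(x_s), one per detector
#' element, on the configuration grid:
#' \deqn{h_{n,m}(x, z) = h_\mathrm{exc}(x, z)\,\eta(x, z)\;\cdot\;
#'   (h_\mathrm{det}(\cdot, z) \circledast \Pi_{n,m})(x),}
#' where eta is the depletion survival factor (identically 1 for saturation
#' factor 0) and Pi_nm is the indicator of element (n, m)'s active area
#' mapped to sample space. The element indicator is rasterized with exact
#' per-pixel area coverage, so at fill factor 1 the active squares tile the
#' array.
#'
#' @param config An [optical_config()].
#' @param detector A [detector_geometry()].
#' @param depletion A [depletion_model()]; the default (saturation 0)
#'   simulates the confocal/ISM case.
#' @param method Field model passed to [focal_intensity()]: `"debye"`
#'   (scalar pupil integrals) or `"gaussian"` (fast analytic stand-ins).
#' @param n_quad Quadrature nodes for the Debye integrals.
#' @return A `psf_stack`: list with `h` (array `[Ny, Nx, Nz, 25]`), the
#'   component volumes (`h_exc`, `h_det`, `doughnut`, `survival`, `h_eff`),
#'   and the input descriptors.
#' @export
scanned_psf_stack <- function(config, detector,
                              depletion = depletion_model(0),
                              method = c("debye", "gaussian"),
                              n_quad = 201) {
  method <- match.arg(method)
  gs <- config$grid_shape; vs <- config$voxel_size
  ny <- gs[2]; nx <- gs[3]; nz <- gs[1]

  # detector footprint must fit the grid
  half_extent <- min((ny - 1) / 2 * vs[2], (nx - 1) / 2 * vs[3])
  footprint <- 2 * detector$pitch + detector$active_side / 2
  if (footprint > half_extent) {
    stop("detector element footprint (", round(footprint), " nm) exceeds ",
         "the lateral half-extent of the grid (", round(half_extent), " nm)")
  }

  h_exc <- focal_intensity(config, "gaussian_excitation", method, n_quad)
  h_det <- focal_intensity(config, "detection", method, n_quad)

  if (depletion$saturation_factor > 0) {
    doughnut <- focal_intensity(config, "vortex_sted", method, n_quad)
    survival <- survival_factor(depletion, doughnut)
    h_eff <- h_exc$values * survival$values
  } else {
    doughnut <- NULL
    survival <- NULL
    h_eff <- h_exc$values
  }

  elems <- element_table()
  y <- axis_coords(ny, vs[2]); x <- axis_coords(nx, vs[3])
  # linear (zero-padded) convolution of the detection PSF with each
  # element's active-area indicator, so detection tails do not wrap around
  # the grid; padded size 2N - 1 keeps a center voxel.
  dp <- c(2 * ny - 1, 2 * nx - 1)
  off <- c(ny - 1, nx - 1) / 2
  ctr_p <- (dp + 1) / 2
  iy <- off[1] + seq_len(ny); ix <- off[2] + seq_len(nx)
  ind_fft <- vector("list", 25)
  for (ch in 1:25) {
    ind <- element_indicator(y, x, vs[2], vs[3],
                             center = elems[ch, ] * detector$pitch,
                             side = detector$active_side)
    ind_p <- matrix(0, dp[1], dp[2]); ind_p[iy, ix] <- ind
    ind_fft[[ch]] <- fft2(circshift2(ind_p, -(ctr_p - 1)))
  }

  h <- array(0, c(ny, nx, nz, 25))
  det_p <- matrix(0, dp[1], dp[2])
  for (k in seq_len(nz)) {
    det_p[iy, ix] <- h_det$values[, , k]
    det_hat <- fft2(det_p)
    for (ch in 1:25) {
      det_elem <- ifft2_re(det_hat * ind_fft[[ch]])[iy, ix]
      h[, , k, ch] <- pmax(h_eff[, , k] * det_elem, 0)
    }
  }

  structure(list(h = h, h_exc = h_exc$values, h_det = h_det$values,
                 doughnut = if (is.null(doughnut)) NULL else doughnut$values,
                 survival = if (is.null(survival)) NULL else survival$values,
                 h_eff = h_eff, config = config, detector = detector,
                 depletion = depletion, method = method),
            class = "psf_stack")
}

# Rasterize one element's active square (side `side`, centered at
# `center` = c(cy, cx) nm) with exact per-pixel area coverage.
element_indicator <- function(y, x, dy, dx, center, side) {
  cov <- function(centers, step, c0) {
    lo <- pmax(centers - step / 2, c0 - side / 2)
    hi <- pmin(centers + step / 2, c0 + side / 2)
    pmax(hi - lo, 0) / step
  }
  outer(cov(y, dy, center[1]), cov(x, dx, center[2]))
}

#' @export
print.psf_stack <- function(x, ...) {
  d <- dim(x$h)
  cat(sprintf(
    "psf_stack: 25 elements, %d x %d x %d voxels, saturation %g (%s fields)\n",
    d[1], d[2], d[3], x$depletion$saturation_factor, x$method))
  invisible(x)
}

#' Theoretical shift vectors of a PSF stack
#'
#' The shift vector of element (n, m) is the position of the maximum of its
#' scanned PSF in the chosen plane — theoretically, the argmax of the
#' product of the (effective) excitation and element detection PSFs. Maxima
#' are refined to sub-voxel precision by parabolic interpolation, ties are
#' broken toward the grid center, and the field is re-centered so that the
#' central element has shift exactly (0, 0).
#'
#' @param stack A [scanned_psf_stack()].
#' @param plane z-plane index (default: the focal/central plane).
#' @return A `shift_field`: 25 x 2 matrix of `(dy, dx)` shifts in scan-pixel
#'   units with estimation metadata attributes.
#' @export
theoretical_shift_vectors <- function(stack, plane = NULL) {
  d <- dim(stack$h)
  if (is.null(plane)) plane <- (d[3] + 1) / 2
  stopifnot(plane >= 1, plane <= d[3])
  pos <- matrix(NA_real_, 25, 2)
  for (ch in 1:25) {
    img <- stack$h[, , plane, ch]
    if (max(img) == min(img)) {
      stop("argmax undefined for element channel ", ch, ": PSF is flat")
    }
    pos[ch, ] <- subvoxel_argmax(img)
  }
  mu <- sweep(pos, 2, pos[13, ])
  shift_field(mu, method = "theoretical")
}

#' Construct a shift field
#'
#' @param shifts 25 x 2 numeric matrix of `(dy, dx)` shifts in scan-pixel
#'   units; the central element (channel 13) must be `(0, 0)`.
#' @param method Free-text provenance tag.
#' @param upsampling,regularized Estimation metadata (optional).
#' @return A `shift_field` object.
#' @export
shift_field <- function(shifts, method = "manual", upsampling = NA,
                        regularized = integer(0)) {
  shifts <- as.matrix(shifts)
  stopifnot(nrow(shifts) == 25, ncol(shifts) == 2, all(is.finite(shifts)))
  if (max(abs(shifts[13, ])) > 1e-9) {
    stop("the reference (central) element must have zero shift")
  }
  dimnames(shifts) <- list(NULL, c("dy", "dx"))
  structure(shifts, class = c("shift_field", "matrix", "array"),
            method = method, upsampling = upsampling,
            regularized = regularized)
}

#' @export
print.shift_field <- function(x, ...) {
  mag <- sqrt(rowSums(unclass(x)^2))
  cat(sprintf("shift_field (%s): |shift| in [%.3f, %.3f] px\n",
              attr(x, "method"), min(mag), max(mag)))
  invisible(x)
}

#' Detector fingerprint
#'
#' The fingerprint is the 5x5 photon distribution over the detector array,
#' obtained by summing all micro-images (equivalently, by summing each
#' scanned image over all scan points). Up to a scale factor it is
#' independent of the sample and, at high depletion power, identifies with
#' the detection PSF sampled on the element grid.
#'
#' @param x A `psf_stack`, an [ism_dataset()], or a bare array whose
#'   third margin is the 25-element channel axis.
#' @param plane For a `psf_stack`: z-plane to use (default the central
#'   plane); `NA` sums over all planes.
#' @param ... Unused.
#' @return A `fingerprint`: 5x5 matrix (rows n = -2..2, columns m = -2..2)
#'   with attribute `total`.
#' @export
fingerprint <- function(x, ...) UseMethod("fingerprint")

#' @rdname fingerprint
#' @export
fingerprint.psf_stack <- function(x, plane = NULL, ...) {
  d <- dim(x$h)
  if (is.null(plane)) plane <- (d[3] + 1) / 2
  f <- if (is.na(plane)) apply(x$h, 4, sum)
       else apply(x$h[, , plane, , drop = FALSE], 4, sum)
  as_fingerprint(f)
}

#' @rdname fingerprint
#' @export
fingerprint.ism_dataset <- function(x, ...) {
  as_fingerprint(apply(x$counts, 3, sum))
}

#' @rdname fingerprint
#' @export
fingerprint.default <- function(x, ...) {
  stopifnot(is.array(x), dim(x)[3] == 25)
  as_fingerprint(apply(x, 3, sum))
}

as_fingerprint <- function(f25) {
  stopifnot(length(f25) == 25)
  # channel order is row-major in n: channel c -> (n, m); matrix[n+3, m+3]
  fp <- matrix(0, 5, 5, dimnames = list(n = -2:2, m = -2:2))
  el <- element_table()
  fp[cbind(el[, "n"] + 3, el[, "m"] + 3)] <- f25
  structure(fp, class = c("fingerprint", "matrix", "array"),
            total = sum(f25))
}

#' L2 discrepancy between two photon distributions
#'
#' Both inputs are normalized to unit total (the convention used for
#' micro-images and fingerprints throughout: they are probability
#' distributions of photons over the detector array) and the Euclidean norm
#' of their difference is returned.
#'
#' @param a,b Fingerprints, 5x5 matrices, or numeric vectors of equal
#'   length with positive totals.
#' @return Non-negative scalar; 0 means proportional distributions.
#' @export
fingerprint_l2 <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  stopifnot(length(a) == length(b), sum(a) > 0, sum(b) > 0)
  sqrt(sum((a / sum(a) - b / sum(b))^2))
}

#' Detection PSF integrated over the detector elements
#'
#' Reference photon distribution of a point emitter under point-like
#' excitation: the detection PSF at the chosen plane integrated over each
#' element's active area. At high saturation factors the simulated
#' fingerprint converges to this distribution.
#'
#' @param stack A [scanned_psf_stack()] (supplies the detection PSF and
#'   geometry).
#' @param plane z-plane index (default central).
#' @return A [fingerprint()] (5x5 matrix).
#' @export
detection_fingerprint <- function(stack, plane = NULL) {
  d <- dim(stack$h)
  if (is.null(plane)) plane <- (d[3] + 1) / 2
  vs <- stack$config$voxel_size
  y <- axis_coords(d[1], vs[2]); x <- axis_coords(d[2], vs[3])
  el <- element_table()
  f <- vapply(1:25, function(ch) {
    ind <- element_indicator(y, x, vs[2], vs[3],
                             center = el[ch, ] * stack$detector$pitch,
                             side = stack$detector$active_side)
    sum(stack$h_det[, , plane] * ind)
  }, numeric(1))
  as_fingerprint(f)
}

#' Second-moment width of a fingerprint
#'
#' Root-mean-square radial distance of the photon distribution from the
#' array center, in element-pitch units; a compact summary of how broadly
#' the light spreads over the detector.
#'
#' @param fp A [fingerprint()].
#' @return Width in pitch units.
#' @export
fingerprint_width <- function(fp) {
  f <- unclass(fp)
  stopifnot(all(dim(f) == c(5, 5)), sum(f) > 0)
  r2 <- outer((-2:2)^2, (-2:2)^2, `+`)
  sqrt(sum(f * r2) / sum(f))
}

#' Axial energy curve
#'
#' Total intensity per z-plane, E(z) = sum over (x, y) of the volume. The
#' width of this curve measures optical sectioning: the narrower the curve,
#' the less out-of-focus light the method retains.
#'
#' @param x A 3D array `[Ny, Nx, Nz]`, a `psf_stack` (channels are summed
#'   first), or a list of per-plane images.
#' @return Numeric vector of length Nz.
#' @export
axial_energy_curve <- function(x) {
  vol <- if (inherits(x, "psf_stack")) {
    apply(x$h, c(1, 2, 3), sum)
  } else if (is.list(x)) {
    simplify2array(x)
  } else {
    x
  }
  stopifnot(is.array(vol), length(dim(vol)) == 3)
  if (dim(vol)[3] < 3) stop("axial energy curve needs at least 3 planes")
  apply(vol, 3, sum)
}
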