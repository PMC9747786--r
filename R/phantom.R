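#' Generate a synthetic phantom
#'
#' Builds a 3D emitter-density volume on the acquisition grid. Two kinds
#' are available:
#' \describe{
#'   \item{`beads`}{`n_beads` spheres of the given diameter (default 23 nm,
#'     a typical calibration bead) placed uniformly at random within the
#'     lateral margins and within `z_extent` of the focal plane. Each bead
#'     is rasterized with sub-voxel area sampling and carries unit total
#'     brightness (times `brightness`).}
#'   \item{`filaments3d`}{`n_filaments` smooth persistent random-walk tubes
#'     emulating a cytoskeletal network; the walk direction decorrelates
#'     over `persistence` nm and the tubes span `z_extent` nm around the
#'     focal plane (0 keeps all mass in the focal plane).}
#' }
#' Generation is deterministic for a given `seed`.
#'
#' @param kind `"beads"` or `"filaments3d"`.
#' @param grid_shape Volume size `c(Nz, Ny, Nx)` in voxels.
#' @param voxel_size Voxel size `c(dz, dy, dx)` in nm.
#' @param seed Integer RNG seed.
#' @param n_beads,bead_diameter,brightness Bead parameters (diameter in nm).
#' @param bead_z Optional vector of fixed bead z-positions (nm, 0 = focal
#'   plane); overrides random z placement.
#' @param bead_xy Optional two-column matrix of fixed lateral bead
#'   positions (y, x) in nm relative to the grid center; overrides random
#'   placement (and `n_beads`).
#' @param n_filaments,persistence,tube_radius Filament parameters (nm).
#' @param z_extent Axial extent of the phantom in nm.
#' @param margin Lateral margin in nm kept free of structure.
#' @return A `phantom`: list with `volume` (`[Ny, Nx, Nz]`), geometry, the
#'   bead table (for beads) and the generation parameters.
#' @export
generate_phantom <- function(kind = c("beads", "filaments3d"),
                             grid_shape, voxel_size, seed = 1,
                             n_beads = 50, bead_diameter = 23,
                             brightness = 1, bead_z = NULL,
                             bead_xy = NULL,
                             n_filaments = 5, persistence = 500,
                             tube_radius = 0, z_extent = 0,
                             margin = NULL) {
  kind <- match.arg(kind)
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 1),
            length(voxel_size) == 3, all(voxel_size > 0))
  nz <- grid_shape[1]; ny <- grid_shape[2]; nx <- grid_shape[3]
  dz <- voxel_size[1]; dy <- voxel_size[2]; dx <- voxel_size[3]
  if (is.null(margin)) margin <- bead_diameter / 2 + 2 * max(dy, dx)
  yext <- (ny - 1) / 2 * dy; xext <- (nx - 1) / 2 * dx
  zext2 <- (nz - 1) / 2 * dz
  if (margin >= min(yext, xext)) stop("margin exceeds the grid half-extent")
  if (z_extent / 2 > zext2 && nz > 1) {
    stop("phantom z extent exceeds the grid")
  }
  set.seed(seed)
  vol <- array(0, c(ny, nx, nz))
  beads <- NULL

  if (kind == "beads") {
    if (!is.null(bead_xy)) {
      bead_xy <- as.matrix(bead_xy)
      n_beads <- nrow(bead_xy)
      yb <- bead_xy[, 1]; xb <- bead_xy[, 2]
      if (any(abs(yb) > yext) || any(abs(xb) > xext)) {
        stop("bead outside the grid")
      }
    } else {
      yb <- stats::runif(n_beads, -(yext - margin), yext - margin)
      xb <- stats::runif(n_beads, -(xext - margin), xext - margin)
    }
    zb <- if (!is.null(bead_z)) {
      rep(bead_z, length.out = n_beads)
    } else if (nz == 1 || z_extent == 0) {
      rep(0, n_beads)
    } else {
      stats::runif(n_beads, -z_extent / 2, z_extent / 2)
    }
    if (any(abs(zb) > zext2 + dz / 2)) stop("bead outside the grid")
    for (b in seq_len(n_beads)) {
      vol <- vol + brightness *
        rasterize_sphere(c(zb[b], yb[b], xb[b]), bead_diameter / 2,
                         grid_shape, voxel_size)
    }
    beads <- data.frame(z = zb, y = yb, x = xb,
                        brightness = rep(brightness, length.out = n_beads),
                        diameter = rep(bead_diameter, length.out = n_beads))
  } else {
    step <- min(dy, dx)
    n_steps <- ceiling(2 * (yext + xext) / step)
    kappa <- step / persistence
    for (fl in seq_len(n_filaments)) {
      p <- c(stats::runif(1, -(yext - margin), yext - margin),
             stats::runif(1, -(xext - margin), xext - margin),
             if (z_extent > 0) stats::runif(1, -z_extent / 2, z_extent / 2)
             else 0)
      th <- stats::runif(1, 0, 2 * pi)
      dir <- c(sin(th), cos(th), 0)
      for (s in seq_len(n_steps)) {
        dir <- dir + kappa * stats::rnorm(3) *
          c(1, 1, if (z_extent > 0) 0.5 else 0)
        dir <- dir / sqrt(sum(dir^2))
        p2 <- p + step * dir
        # reflect off the walls
        if (abs(p2[1]) > yext - margin) dir[1] <- -dir[1]
        if (abs(p2[2]) > xext - margin) dir[2] <- -dir[2]
        if (z_extent > 0 && abs(p2[3]) > z_extent / 2) dir[3] <- -dir[3]
        p <- p + step * dir
        deposit_point(vol, p, tube_radius, voxel_size) -> vol
      }
    }
  }

  structure(list(volume = vol, grid_shape = grid_shape,
                 voxel_size = as.numeric(voxel_size), kind = kind,
                 beads = beads, seed = seed,
                 params = list(n_beads = n_beads,
                               bead_diameter = bead_diameter,
                               n_filaments = n_filaments,
                               persistence = persistence,
                               tube_radius = tube_radius,
                               z_extent = z_extent, margin = margin)),
            class = "phantom")
}

# Rasterize a sphere of radius R (nm) centered at (z, y, x) nm with 3x3x3
# sub-voxel occupancy sampling; the returned volume has unit total.
rasterize_sphere <- function(center, radius, grid_shape, voxel_size) {
  nz <- grid_shape[1]; ny <- grid_shape[2]; nx <- grid_shape[3]
  dz <- voxel_size[1]; dy <- voxel_size[2]; dx <- voxel_size[3]
  yc <- axis_coords(ny, dy); xc <- axis_coords(nx, dx); zc <- axis_coords(nz, dz)
  iy <- which(abs(yc - center[2]) <= radius + dy)
  ix <- which(abs(xc - center[3]) <= radius + dx)
  iz <- if (nz == 1) 1L else which(abs(zc - center[1]) <= radius + dz)
  if (!length(iy) || !length(ix) || !length(iz)) {
    stop("bead outside the grid")
  }
  sub <- c(-1, 0, 1) / 3
  vol <- array(0, c(ny, nx, nz))
  for (k in iz) {
    zo <- if (nz == 1) 0 else zc[k] + sub * dz
    for (j in ix) {
      xo <- xc[j] + sub * dx
      for (i in iy) {
        yo <- yc[i] + sub * dy
        d2 <- outer(outer((yo - center[2])^2, (xo - center[3])^2, `+`),
                    (zo - center[1])^2, `+`)
        vol[i, j, k] <- mean(d2 <= radius^2)
      }
    }
  }
  s <- sum(vol)
  if (s == 0) {
    # bead smaller than the sub-voxel sampling: all mass in nearest voxel
    i <- which.min(abs(yc - center[2])); j <- which.min(abs(xc - center[3]))
    k <- if (nz == 1) 1L else which.min(abs(zc - center[1]))
    vol[i, j, k] <- 1
    return(vol)
  }
  vol / s
}

# Add unit brightness at a physical point (y, x, z) nm, optionally spread
# over a small sphere of the given radius.
deposit_point <- function(vol, p, radius, voxel_size) {
  d <- dim(vol)
  dy <- voxel_size[2]; dx <- voxel_size[3]; dz <- voxel_size[1]
  i <- round(p[1] / dy + (d[1] + 1) / 2)
  j <- round(p[2] / dx + (d[2] + 1) / 2)
  k <- if (d[3] == 1) 1 else round(p[3] / dz + (d[3] + 1) / 2)
  if (i < 1 || i > d[1] || j < 1 || j > d[2] || k < 1 || k > d[3]) {
    return(vol)
  }
  if (radius <= 0) {
    vol[i, j, k] <- vol[i, j, k] + 1
    return(vol)
  }
  ri <- ceiling(radius / dy)
  ii <- max(1, i - ri):min(d[1], i + ri)
  jj <- max(1, j - ri):min(d[2], j + ri)
  for (a in ii) for (b in jj) {
    if ((a - i)^2 * dy^2 + (b - j)^2 * dx^2 <= radius^2) {
      vol[a, b, k] <- vol[a, b, k] + 1 / (1 + length(ii))
    }
  }
  vol
}

#' @export
print.phantom <- function(x, ...) {
  d <- dim(x$volume)
  cat(sprintf("phantom (%s): %d x %d x %d voxels, total brightness %.4g\n",
              x$kind, d[1], d[2], d[3], sum(x$volume)))
  invisible(x)
}

#' Simulate an ISM acquisition from a phantom
#'
#' Poisson forward model: the expected counts of element (n, m) are the
#' phantom convolved plane-by-plane with that element's scanned PSF and
#' summed over depth,
#' \deqn{\Lambda_{n,m}(x_s) = \sum_z (h_{n,m}(\cdot, z) \ast
#'   \mathrm{phantom}(\cdot, z))(x_s),}
#' scaled so that the brightest channel-summed scan point equals
#' `photon_budget`, plus a flat `dark_rate`. Convolutions are periodic
#' (FFT) after zero-padding the phantom by at least half the PSF support,
#' which suppresses wrap-around; the padding used is recorded in the
#' provenance.
#'
#' @param phantom A [generate_phantom()] result (lateral grid and voxel
#'   size must match the PSF stack).
#' @param stack A [scanned_psf_stack()].
#' @param photon_budget Expected channel-summed counts at the brightest
#'   scan point.
#' @param dark_rate Expected dark counts per pixel and element.
#' @param seed RNG seed for the Poisson draw.
#' @param noise If `FALSE`, return the noiseless expectation as the counts.
#' @param scale Absolute intensity scale overriding the photon-budget
#'   normalization; use the `"scale"` attribute of a previous acquisition
#'   to image related phantoms on a common intensity footing.
#' @return An [ism_dataset()]; the noiseless expectation is attached as
#'   attribute `"expected"` and the applied scale as attribute `"scale"`.
#' @export
simulate_acquisition <- function(phantom, stack, photon_budget = 1e4,
                                 dark_rate = 0, seed = 1, noise = TRUE,
                                 scale = NULL) {
  if (photon_budget < 0) stop("photon budget must be non-negative")
  dph <- dim(phantom$volume)
  dh <- dim(stack$h)
  if (any(dph[1:2] != dh[1:2]) || dph[3] != dh[3]) {
    stop("phantom grid does not match the PSF stack grid")
  }
  vs <- stack$config$voxel_size
  if (any(abs(phantom$voxel_size - vs) > 1e-9)) {
    stop("phantom voxel size does not match the PSF stack")
  }
  ny <- dph[1]; nx <- dph[2]; nzp <- dph[3]
  pad <- c(floor(ny / 2), floor(nx / 2))
  npad <- c(ny, nx) + 2 * pad
  iy <- pad[1] + seq_len(ny); ix <- pad[2] + seq_len(nx)
  ctr_p <- (npad + 1) / 2

  lam <- array(0, c(ny, nx, 25))
  ph_p <- matrix(0, npad[1], npad[2])
  h_p <- matrix(0, npad[1], npad[2])
  for (z in seq_len(nzp)) {
    if (sum(phantom$volume[, , z]) == 0) next
    ph_p[iy, ix] <- phantom$volume[, , z]
    ph_hat <- fft2(ph_p)
    for (ch in 1:25) {
      h_p[iy, ix] <- stack$h[, , z, ch]
      lam[, , ch] <- lam[, , ch] +
        ifft2_re(ph_hat * fft2(circshift2(h_p, -(ctr_p - 1))))[iy, ix]
    }
  }
  lam <- pmax(lam, 0)
  if (is.null(scale)) {
    peak <- max(apply(lam, c(1, 2), sum))
    scale <- if (peak > 0) photon_budget / peak else 0
  }
  lam <- lam * scale + dark_rate

  counts <- if (noise) {
    set.seed(seed)
    array(stats::rpois(length(lam), lam), dim(lam))
  } else {
    lam
  }
  out <- ism_dataset(
    counts, pixel_size = vs[2:3],
    detector = stack$detector,
    provenance = list(
      saturation = stack$depletion$saturation_factor,
      photon_budget = photon_budget, dark_rate = dark_rate,
      seed = seed, noise = noise, pad = pad, kind = phantom$kind))
  attr(out, "expected") <- lam
  attr(out, "scale") <- scale
  out
}
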