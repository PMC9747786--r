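#' ISM photon-count dataset
#'
#' Container for a (STED-)ISM acquisition: a non-negative count array with
#' scan dimensions `[Ny, Nx]`, a 25-element channel axis, and optionally a
#' stack of z-planes, stored as `[Ny, Nx, 25]` or `[Ny, Nx, 25, Nz]`. The
#' channel order is fixed: channel `c = 5 (n + 2) + (m + 2) + 1` for
#' detector element `(n, m)` (see [channel_index()]), so the central
#' element is channel 13. Raw data are integer photon counts; processed
#' (e.g. registered) datasets may hold real values.
#'
#' @param counts Numeric array `[Ny, Nx, 25]` or `[Ny, Nx, 25, Nz]`.
#' @param pixel_size Scan pixel size `c(dy, dx)` in nm (a scalar is
#'   recycled).
#' @param z_spacing Plane spacing in nm for 3D datasets.
#' @param detector Optional [detector_geometry()].
#' @param provenance Named list of free-form acquisition metadata
#'   (saturation factor, photon budget, seed, ...).
#' @return An object of class `ism_dataset`.
#' @export
ism_dataset <- function(counts, pixel_size, z_spacing = NULL,
                        detector = NULL, provenance = list()) {
  stopifnot(is.array(counts), length(dim(counts)) %in% c(3, 4))
  if (dim(counts)[3] != 25) {
    stop("expected 25 channels, found ", dim(counts)[3])
  }
  if (anyNA(counts)) stop("counts contain NA")
  pixel_size <- rep(as.numeric(pixel_size), length.out = 2)
  stopifnot(all(pixel_size > 0))
  if (length(dim(counts)) == 4 && is.null(z_spacing)) {
    stop("3D datasets need a z_spacing")
  }
  structure(list(counts = counts, pixel_size = pixel_size,
                 z_spacing = z_spacing, detector = detector,
                 provenance = provenance),
            class = "ism_dataset")
}

#' @export
print.ism_dataset <- function(x, ...) {
  d <- dim(x$counts)
  nz <- if (length(d) == 4) d[4] else 1
  cat(sprintf(
    "ism_dataset: %d x %d scan, 25 channels%s, pixel %g x %g nm, total %.4g\n",
    d[1], d[2], if (nz > 1) sprintf(", %d planes", nz) else "",
    x$pixel_size[1], x$pixel_size[2], sum(x$counts)))
  invisible(x)
}

n_planes <- function(dataset) {
  d <- dim(dataset$counts)
  if (length(d) == 4) d[4] else 1L
}

# counts of one plane as [Ny, Nx, 25]
plane_counts <- function(dataset, plane = 1) {
  d <- dim(dataset$counts)
  if (length(d) == 3) {
    stopifnot(plane == 1)
    dataset$counts
  } else {
    dataset$counts[, , , plane]
  }
}

#' Micro-image at one scan point
#'
#' The 5x5 wide-field image recorded by the detector array at a single
#' scan position, arranged with n (row, y) and m (column, x) in -2..2.
#'
#' @param dataset An [ism_dataset()].
#' @param y,x Scan-point indices.
#' @param plane z-plane index for 3D datasets.
#' @return 5x5 matrix.
#' @export
micro_image <- function(dataset, y, x, plane = 1) {
  d <- dim(dataset$counts)
  stopifnot(y >= 1, y <= d[1], x >= 1, x <= d[2])
  v <- plane_counts(dataset, plane)[y, x, ]
  el <- element_table()
  mi <- matrix(0, 5, 5, dimnames = list(n = -2:2, m = -2:2))
  mi[cbind(el[, "n"] + 3, el[, "m"] + 3)] <- v
  mi
}

#' Scanned image of one detector element
#'
#' The full-field image built from a single detector element across all
#' scan positions.
#'
#' @param dataset An [ism_dataset()].
#' @param n,m Element indices in -2..2 (alternatively give `channel`).
#' @param channel Flat channel index in 1..25.
#' @return Matrix `[Ny, Nx]` (or array `[Ny, Nx, Nz]` for 3D data).
#' @export
scanned_image <- function(dataset, n = 0, m = 0,
                          channel = channel_index(n, m)) {
  d <- dim(dataset$counts)
  stopifnot(channel >= 1, channel <= 25)
  if (length(d) == 3) dataset$counts[, , channel]
  else dataset$counts[, , channel, ]
}

#' Write an ISM dataset to multi-page TIFF
#'
#' Pages are ordered plane-major, channel-minor: for each z-plane the 25
#' channel images in flat channel order. Integer counts up to 65535 are
#' stored losslessly at 16 bit; other data are scaled into `[0, 1]` and
#' stored as 32-bit float with the scale factor recorded. A YAML sidecar
#' (`<path>.yml`) carries the geometry and provenance metadata.
#'
#' @param dataset An [ism_dataset()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @seealso [read_ism()]
#' @export
write_ism <- function(dataset, path) {
  cts <- dataset$counts
  d <- dim(cts)
  nz <- n_planes(dataset)
  integral <- max(abs(cts - round(cts))) == 0 && min(cts) >= 0 &&
    max(cts) <= 65535
  scale <- if (integral) 65535 else max(max(cts), 1e-300)
  if (!integral && min(cts) < 0) {
    stop("cannot store negative-valued datasets")
  }
  pages <- vector("list", 25 * nz)
  for (z in seq_len(nz)) {
    pc <- plane_counts(dataset, z)
    for (ch in 1:25) {
      pages[[(z - 1) * 25 + ch]] <- pc[, , ch] / scale
    }
  }
  tiff::writeTIFF(pages, path,
                  bits.per.sample = if (integral) 16L else 32L)
  meta <- list(
    format = "focusISM-ism",
    ny = d[1], nx = d[2], channels = 25L, nz = nz,
    pixel_size = as.numeric(dataset$pixel_size),
    z_spacing = dataset$z_spacing,
    dtype = if (integral) "uint16" else "float32",
    scale = scale,
    provenance = dataset$provenance)
  yaml::write_yaml(meta, paste0(path, ".yml"))
  invisible(path)
}

#' Read an ISM dataset from multi-page TIFF
#'
#' Reads a file written by [write_ism()] (using its YAML sidecar), or any
#' multi-page TIFF whose page count is a multiple of 25, mapping pages onto
#' the flat channel order documented in [ism_dataset()].
#'
#' @param path TIFF path.
#' @param pixel_size Pixel size `c(dy, dx)` in nm; required when no sidecar
#'   is present.
#' @param z_spacing Plane spacing in nm for sidecar-less 3D imports.
#' @return An [ism_dataset()].
#' @export
read_ism <- function(path, pixel_size = NULL, z_spacing = NULL) {
  sidecar <- paste0(path, ".yml")
  meta <- if (file.exists(sidecar)) yaml::read_yaml(sidecar) else NULL
  integral <- !is.null(meta) && identical(meta$dtype, "uint16")
  pages <- tiff::readTIFF(path, all = TRUE, as.is = integral)
  np <- length(pages)
  if (np %% 25 != 0) {
    stop("expected 25 channels, found ", if (np < 25) np else
      paste0(np, " pages (not a multiple of 25)"))
  }
  nz <- np %/% 25
  if (!is.null(meta) && nz != meta$nz) {
    stop("page count disagrees with sidecar metadata")
  }
  d1 <- dim(pages[[1]])
  cts <- array(0, c(d1[1], d1[2], 25, nz))
  for (z in seq_len(nz)) {
    for (ch in 1:25) {
      cts[, , ch, z] <- pages[[(z - 1) * 25 + ch]]
    }
  }
  if (!is.null(meta)) {
    cts <- if (integral) {
      storage.mode(cts) <- "integer"
      cts
    } else {
      cts * meta$scale
    }
    pixel_size <- unlist(meta$pixel_size)
    z_spacing <- meta$z_spacing
    prov <- meta$provenance
  } else {
    if (is.null(pixel_size)) {
      stop("pixel_size is required when no metadata sidecar is present")
    }
    prov <- list()
  }
  if (nz == 1) cts <- array(cts, dim(cts)[1:3])
  ism_dataset(cts, pixel_size = pixel_size, z_spacing = z_spacing,
              provenance = if (is.null(prov)) list() else prov)
}

#' Sum of all detector channels
#'
#' The conventional (open-pinhole) confocal/STED image: the dataset summed
#' over the channel axis, as a single-element detector of the array's total
#' size would record it.
#'
#' @param dataset An [ism_dataset()].
#' @return Matrix `[Ny, Nx]` or array `[Ny, Nx, Nz]`.
#' @export
sum_channels <- function(dataset) {
  d <- dim(dataset$counts)
  if (length(d) == 3) {
    apply(dataset$counts, c(1, 2), sum)
  } else {
    apply(dataset$counts, c(1, 2, 4), sum)
  }
}
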