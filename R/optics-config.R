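#' Optical configuration of the scanning microscope
#'
#' Bundles the wavelengths, objective parameters and simulation grid used by
#' the focal-field and PSF simulators. The defaults reproduce a far-red
#' STED-ISM system: excitation at 646 nm, detection at 669 nm, depletion at
#' 775 nm, oil objective of numerical aperture 1.4, and a 127^3 voxel grid
#' with 10 nm isotropic voxels. Grids must be odd along every axis so that a
#' center voxel lies exactly on the optical axis at focus.
#'
#' @param lambda_exc,lambda_det,lambda_sted Excitation, detection (emission)
#'   and depletion wavelengths in nm.
#' @param numerical_aperture Objective numerical aperture (must be smaller
#'   than `refractive_index`).
#' @param refractive_index Immersion refractive index.
#' @param voxel_size Voxel size `c(dz, dy, dx)` in nm.
#' @param grid_shape Grid size `c(Nz, Ny, Nx)` in voxels, all odd.
#' @param beam_fill_factor Ratio of the laser beam waist to the pupil radius
#'   for the excitation and depletion beams; the Gaussian beam profile
#'   apodizes the pupil and suppresses the focal sidelobes relative to the
#'   uniformly filled detection pupil. Use `Inf` for an ideal flat
#'   (overfilled) pupil.
#' @return An object of class `optical_config`.
#' @examples
#' cfg <- optical_config(grid_shape = c(1, 65, 65))
#' @export
optical_config <- function(lambda_exc = 646, lambda_det = 669,
                           lambda_sted = 775, numerical_aperture = 1.4,
                           refractive_index = 1.518,
                           voxel_size = c(10, 10, 10),
                           grid_shape = c(127, 127, 127),
                           beam_fill_factor = 1) {
  stopifnot(lambda_exc > 0, lambda_det > 0, lambda_sted > 0,
            numerical_aperture > 0, length(voxel_size) == 3,
            all(voxel_size > 0), length(grid_shape) == 3,
            beam_fill_factor > 0)
  if (numerical_aperture >= refractive_index) {
    stop("numerical aperture must be smaller than the refractive index")
  }
  grid_shape <- as.integer(grid_shape)
  if (any(grid_shape %% 2 == 0)) {
    stop("grid_shape must be odd along every axis (a center voxel must exist)")
  }
  structure(
    list(lambda_exc = lambda_exc, lambda_det = lambda_det,
         lambda_sted = lambda_sted,
         numerical_aperture = numerical_aperture,
         refractive_index = refractive_index,
         voxel_size = as.numeric(voxel_size),
         grid_shape = grid_shape,
         beam_fill_factor = beam_fill_factor),
    class = "optical_config")
}

#' @export
print.optical_config <- function(x, ...) {
  cat(sprintf(
    "optical_config: lambda exc/det/STED = %g/%g/%g nm, NA = %g (n = %g)\n",
    x$lambda_exc, x$lambda_det, x$lambda_sted, x$numerical_aperture,
    x$refractive_index))
  cat(sprintf("  grid %d x %d x %d voxels (z,y,x), voxel %g x %g x %g nm\n",
              x$grid_shape[1], x$grid_shape[2], x$grid_shape[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  invisible(x)
}

#' Airy unit of a configuration
#'
#' One Airy unit (AU) is the diameter of the Airy disc at the detection
#' wavelength: 1.22 lambda_det / NA.
#'
#' @param config An [optical_config()].
#' @return The Airy unit in nm.
#' @export
airy_unit <- function(config) {
  1.22 * config$lambda_det / config$numerical_aperture
}

#' Geometry of the 5x5 detector array
#'
#' Describes the square detector array in sample-space units. The array has
#' 5 x 5 sensitive elements indexed by `(n, m)` with n, m in -2..2 (n = row,
#' along y; m = column, along x), a total side length expressed in Airy
#' units, and a fill factor giving the fraction of each element pitch that
#' is light sensitive (1 = the active squares tile the array exactly).
#'
#' @param config An [optical_config()]; supplies the Airy unit.
#' @param side_length_au Side length of the whole array in Airy units.
#' @param fill_factor Active-area fraction of each element, in (0, 1].
#' @return An object of class `detector_geometry` with the element pitch and
#'   active-area side in nm.
#' @export
detector_geometry <- function(config, side_length_au = 1.4, fill_factor = 1) {
  stopifnot(side_length_au > 0, fill_factor > 0, fill_factor <= 1)
  au <- airy_unit(config)
  pitch <- side_length_au * au / 5
  structure(
    list(n_rows = 5L, n_cols = 5L, side_length_au = side_length_au,
         fill_factor = fill_factor, airy_unit = au, pitch = pitch,
         active_side = sqrt(fill_factor) * pitch),
    class = "detector_geometry")
}

#' @export
print.detector_geometry <- function(x, ...) {
  cat(sprintf(
    "detector_geometry: 5 x 5 elements, side %g AU (1 AU = %.1f nm),\n  pitch %.1f nm, fill factor %g\n",
    x$side_length_au, x$airy_unit, x$pitch, x$fill_factor))
  invisible(x)
}

#' Flat channel index of a detector element
#'
#' Channels are stored row-major with n (the detector row) varying slowest:
#' the 1-based flat index is `5 * (n + 2) + (m + 2) + 1`, so the central
#' element (0, 0) is channel 13.
#'
#' @param n,m Element indices in -2..2.
#' @return Integer channel index in 1..25.
#' @seealso [element_of()]
#' @export
channel_index <- function(n, m) {
  stopifnot(all(n %in% -2:2), all(m %in% -2:2))
  as.integer(5 * (n + 2) + (m + 2) + 1)
}

#' Detector element of a flat channel index
#'
#' @param channel Integer channel index in 1..25.
#' @return A two-column matrix of `(n, m)` element indices.
#' @export
element_of <- function(channel) {
  stopifnot(all(channel %in% 1:25))
  c0 <- as.integer(channel) - 1L
  cbind(n = c0 %/% 5L - 2L, m = c0 %% 5L - 2L)
}

# (n, m) pairs for all 25 channels in storage order.
element_table <- function() element_of(1:25)

#' Stimulated-emission depletion model parameters
#'
#' The depletion strength is parameterized by the saturation factor
#' (the peak depletion rate in units of the spontaneous decay rate,
#' referenced to the doughnut maximum), the fluorescence lifetime tau_F and
#' the depletion pulse duration T. A saturation factor of 0 reproduces the
#' confocal (no-STED) case.
#'
#' @param saturation_factor Dimensionless saturation factor, >= 0.
#' @param fluorescence_lifetime Fluorescence lifetime tau_F in ns.
#' @param sted_pulse_duration Depletion pulse duration T in ns.
#' @return An object of class `depletion_model`.
#' @export
depletion_model <- function(saturation_factor = 0,
                            fluorescence_lifetime = 3.5,
                            sted_pulse_duration = 1) {
  stopifnot(saturation_factor >= 0, fluorescence_lifetime > 0,
            sted_pulse_duration >= 0)
  structure(
    list(saturation_factor = saturation_factor,
         fluorescence_lifetime = fluorescence_lifetime,
         sted_pulse_duration = sted_pulse_duration),
    class = "depletion_model")
}

#' @export
print.depletion_model <- function(x, ...) {
  cat(sprintf("depletion_model: saturation %g, tau_F %g ns, T %g ns\n",
              x$saturation_factor, x$fluorescence_lifetime,
              x$sted_pulse_duration))
  invisible(x)
}
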