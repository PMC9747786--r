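#' Focal intensity distribution of an illumination or detection beam
#'
#' Computes the normalized (unit-maximum) 3D intensity distribution of one
#' of the three beams of the microscope on the configuration grid:
#' the Gaussian excitation beam, the detection (emission) PSF, or the
#' doughnut-shaped depletion beam obtained from a 0-2*pi helical phase ramp
#' (vortex) in the pupil.
#'
#' Two field models are available. `"debye"` evaluates the scalar Debye
#' pupil integral
#' \deqn{A_l(r, z) = \int_0^1 J_l(2\pi \mathrm{NA}\, r \rho/\lambda)\,
#'   e^{i\phi_z(\rho)}\, \rho\, d\rho,}
#' with defocus phase
#' \eqn{\phi_z(\rho) = (2\pi/\lambda)\, z\, n \sqrt{1 - (\mathrm{NA}\rho/n)^2}}
#' and azimuthal order l = 0 for the flat-phase beams and l = 1 for the
#' vortex; the in-focus lateral profile of the l = 0 beams is then exactly
#' the Airy pattern (first zero at 0.61 lambda/NA, FWHM 0.51 lambda/NA) and
#' the vortex has a strict on-axis null. `"gaussian"` substitutes fast
#' analytic stand-ins: a Gaussian of FWHM 0.51 lambda/NA whose width grows
#' with defocus as \eqn{\sigma(z) = \sigma_0\sqrt{1 + (z/z_R)^2}} (with
#' per-plane energy conservation), and a doughnut
#' \eqn{\propto r^2 e^{-r^2/\sigma(z)^2}}.
#'
#' @param config An [optical_config()].
#' @param beam One of `"gaussian_excitation"`, `"detection"`,
#'   `"vortex_sted"`; selects the wavelength and the pupil phase.
#' @param method Field model, `"debye"` (default) or `"gaussian"`.
#' @param n_quad Number of quadrature nodes for the pupil integral (odd).
#' @return A `volume_map`: list with `values` (array `[Ny, Nx, Nz]`,
#'   normalized to unit maximum), `role` tag, `beam`, `wavelength` and the
#'   `config`.
#' @export
focal_intensity <- function(config,
                            beam = c("gaussian_excitation", "detection",
                                     "vortex_sted"),
                            method = c("debye", "gaussian"),
                            n_quad = 201) {
  beam <- match.arg(beam)
  method <- match.arg(method)
  lambda <- switch(beam,
                   gaussian_excitation = config$lambda_exc,
                   detection = config$lambda_det,
                   vortex_sted = config$lambda_sted)
  role <- switch(beam,
                 gaussian_excitation = "excitation",
                 detection = "detection",
                 vortex_sted = "doughnut")
  gs <- config$grid_shape           # (Nz, Ny, Nx)
  vs <- config$voxel_size           # (dz, dy, dx)
  extent <- min((gs[2] - 1) * vs[2], (gs[3] - 1) * vs[3])
  if (extent < 3 * airy_unit(config)) {
    warning("lateral grid extent is below 3 Airy units; ",
            "the first Airy ring may be truncated")
  }
  y <- axis_coords(gs[2], vs[2])
  x <- axis_coords(gs[3], vs[3])
  z <- axis_coords(gs[1], vs[1])
  r <- sqrt(outer(y^2, x^2, `+`))

  # the laser beams carry the Gaussian beam profile into the pupil; the
  # detection pupil is filled uniformly by the fluorescence emission
  fill <- if (beam == "detection") Inf else config$beam_fill_factor
  vals <- if (method == "debye") {
    if (beam == "vortex_sted") {
      vortex_intensity(r, z, lambda, config$numerical_aperture,
                       config$refractive_index, fill = fill, n_quad = n_quad)
    } else {
      debye_intensity(r, z, lambda, config$numerical_aperture,
                      config$refractive_index, fill = fill, order = 0L,
                      n_quad = n_quad)
    }
  } else {
    standin_intensity(r, z, lambda, config$numerical_aperture,
                      config$refractive_index,
                      doughnut = beam == "vortex_sted")
  }
  vals <- vals / max(vals)
  if (beam == "vortex_sted") {
    # enforce the exact on-axis null of the helical phase ramp
    ctr_y <- (gs[2] + 1) / 2; ctr_x <- (gs[3] + 1) / 2
    vals[ctr_y, ctr_x, ] <- 0
  }
  structure(list(values = vals, role = role, beam = beam,
                 wavelength = lambda, method = method, config = config),
            class = "volume_map")
}

# Scalar Debye pupil integral evaluated over unique lateral radii; the
# z dependence enters only through complex quadrature weights, so a single
# matrix product gives all planes at once.
debye_intensity <- function(r, z, lambda, na, nref, order, n_quad,
                            fill = Inf) {
  rho <- seq(0, 1, length.out = n_quad)
  w <- simpson_weights(n_quad) * (rho[2] - rho[1]) * rho *
    exp(-(rho / fill)^2)
  rkey <- signif(r, 12)
  ru <- sort(unique(as.vector(rkey)))
  idx <- match(as.vector(rkey), ru)
  B <- besselJ(2 * pi * na / lambda * outer(ru, rho), order)
  B <- sweep(B, 2, w, `*`)
  cosmed <- sqrt(pmax(0, 1 - (na * rho / nref)^2))
  phi <- (2 * pi / lambda) * nref * outer(cosmed, z)  # n_quad x Nz
  A_re <- B %*% cos(phi)
  A_im <- B %*% sin(phi)
  I_u <- A_re^2 + A_im^2                              # length(ru) x Nz
  out <- array(0, c(dim(r), length(z)))
  for (k in seq_along(z)) {
    out[, , k] <- I_u[idx, k]
  }
  out
}

# Aplanatic vectorial (Richards-Wolf) focal intensity of a circularly
# polarized charge-1 vortex beam, handedness matched to the phase ramp so
# the on-axis null survives. The three focal components carry J1 (co-
# rotating), J2 (longitudinal) and J3 (counter-rotating) radial profiles;
# the latter two fill the secondary ring nulls of the scalar vortex, which
# matters for depletion at high saturation factors.
vortex_intensity <- function(r, z, lambda, na, nref, n_quad, fill = Inf) {
  alpha <- asin(na / nref)
  theta <- seq(0, alpha, length.out = n_quad)
  w <- simpson_weights(n_quad) * (theta[2] - theta[1])
  st <- sin(theta); ct <- cos(theta)
  base <- w * sqrt(ct) * st * exp(-(st / (fill * sin(alpha)))^2)
  k <- 2 * pi * nref / lambda
  rkey <- signif(r, 12)
  ru <- sort(unique(as.vector(rkey)))
  idx <- match(as.vector(rkey), ru)
  arg <- k * outer(ru, st)
  B1 <- sweep(besselJ(arg, 1), 2, base * (1 + ct) / 2, `*`)
  B2 <- sweep(besselJ(arg, 2), 2, base * st / sqrt(2), `*`)
  B3 <- sweep(besselJ(arg, 3), 2, base * (1 - ct) / 2, `*`)
  phi <- k * outer(ct, z)                    # n_quad x Nz
  cphi <- cos(phi); sphi <- sin(phi)
  I_u <- (B1 %*% cphi)^2 + (B1 %*% sphi)^2 +
    2 * ((B2 %*% cphi)^2 + (B2 %*% sphi)^2) +
    (B3 %*% cphi)^2 + (B3 %*% sphi)^2
  out <- array(0, c(dim(r), length(z)))
  for (k2 in seq_along(z)) {
    out[, , k2] <- I_u[idx, k2]
  }
  out
}

# Analytic Gaussian / r^2-Gaussian stand-ins with a defocus-broadened width
# and per-plane energy conservation (widefield light is spread, not lost).
standin_intensity <- function(r, z, lambda, na, nref, doughnut) {
  sigma0 <- 0.51 * lambda / na / (2 * sqrt(2 * log(2)))
  zr <- nref * lambda / na^2
  out <- array(0, c(dim(r), length(z)))
  for (k in seq_along(z)) {
    s <- sigma0 * sqrt(1 + (z[k] / zr)^2)
    out[, , k] <- if (doughnut) {
      (sigma0 / s)^4 * (r^2 / s^2) * exp(-r^2 / s^2)
    } else {
      (sigma0 / s)^2 * exp(-r^2 / (2 * s^2))
    }
  }
  out
}

#' Fluorescence survival probability under pulsed depletion
#'
#' Maps the (unit-peak) doughnut intensity d to the fraction of excited
#' molecules whose fluorescence survives a rectangular depletion pulse of
#' duration T followed by undepleted decay:
#' \deqn{\eta = \frac{1 - e^{-(1+\varsigma d)T/\tau_F}}{1+\varsigma d}
#'   + e^{-(1+\varsigma d)T/\tau_F}.}
#' For saturation factor 0 (or wherever the doughnut is zero) the survival
#' is exactly 1; it decreases monotonically with both the saturation factor
#' and the local doughnut intensity.
#'
#' @param model A [depletion_model()].
#' @param doughnut A `volume_map` with role `"doughnut"` (unit-peak), or a
#'   bare numeric array of doughnut intensities.
#' @return A `volume_map` with role `"survival"`, values in `[0, 1]`.
#' @export
survival_factor <- function(model, doughnut) {
  d <- if (inherits(doughnut, "volume_map")) doughnut$values else doughnut
  if (any(d < 0)) stop("doughnut intensities must be non-negative")
  if (max(d) > 1 + 1e-9) {
    warning("doughnut is not normalized to unit maximum; ",
            "the saturation factor is referenced to the doughnut peak")
  }
  s <- 1 + model$saturation_factor * d
  g <- s * model$sted_pulse_duration / model$fluorescence_lifetime
  eta <- (1 - exp(-g)) / s + exp(-g)
  structure(list(values = eta, role = "survival",
                 model = model,
                 config = if (inherits(doughnut, "volume_map"))
                   doughnut$config else NULL),
            class = "volume_map")
}

#' @export
print.volume_map <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("volume_map (%s): %d x %d x %d, range [%.3g, %.3g]\n",
              x$role, d[1], d[2], d[3], min(x$values), max(x$values)))
  invisible(x)
}
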