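## Core domain containers. Lightweight S3: each is a list wrapping plain
## matrices plus physical metadata, so that numeric code can work on the
## matrices directly.

#' Complex scalar wave field on a regular grid
#'
#' The propagating x-ray disturbance: a complex amplitude sampled on a
#' regular 2D grid with physical pitch (micrometres per node) and wavelength.
#'
#' @param amplitude Complex (or numeric) matrix of field values.
#' @param grid_pitch Grid pitch in micrometres (> 0).
#' @param wavelength X-ray wavelength in micrometres (> 0).
#' @return An object of class `wave_field` with elements `amplitude`,
#'   `grid_pitch`, `wavelength`, `grid_shape`.
#' @export
wave_field <- function(amplitude, grid_pitch, wavelength) {
  stopifnot(is.matrix(amplitude),
            is_scalar_num(grid_pitch), grid_pitch > 0,
            is_scalar_num(wavelength), wavelength > 0)
  if (!is.complex(amplitude)) amplitude <- amplitude + 0i
  if (any(!is.finite(Re(amplitude)) | !is.finite(Im(amplitude))))
    stop("wave_field amplitude must be finite everywhere")
  structure(list(amplitude = amplitude, grid_pitch = grid_pitch,
                 wavelength = wavelength, grid_shape = dim(amplitude)),
            class = "wave_field")
}

#' X-ray wavelength from photon energy
#'
#' lambda \[um\] = 1.23984193e-3 / E \[keV\] (hc = 1.23984 eV um).
#'
#' @param energy_kev Photon energy in keV.
#' @return Wavelength in micrometres.
#' @export
wavelength_um <- function(energy_kev) 1.23984193e-3 / energy_kev

#' Total intensity of a wave field
#'
#' Sum of |amplitude|^2 times the grid cell area; conserved by free-space
#' propagation.
#'
#' @param field A `wave_field`.
#' @return Scalar total intensity.
#' @export
total_intensity <- function(field) {
  sum(Mod(field$amplitude)^2) * field$grid_pitch^2
}

#' @export
print.wave_field <- function(x, ...) {
  cat(sprintf("<wave_field %d x %d, pitch %.3g um, lambda %.4g um>\n",
              x$grid_shape[1], x$grid_shape[2], x$grid_pitch, x$wavelength))
  invisible(x)
}

#' Detector-plane speckle image
#'
#' @param data Numeric matrix of pixel intensities.
#' @param pixel_pitch Detector pixel pitch in micrometres.
#' @param meta Optional named list of acquisition metadata.
#' @return An object of class `speckle_image`.
#' @export
speckle_image <- function(data, pixel_pitch = NA_real_, meta = list()) {
  stopifnot(is.matrix(data), is.numeric(data))
  structure(list(data = data, pixel_pitch = pixel_pitch, meta = meta),
            class = "speckle_image")
}

#' @export
print.speckle_image <- function(x, ...) {
  cat(sprintf("<speckle_image %d x %d, pitch %.3g um, mean %.4g, visibility %.3f>\n",
              nrow(x$data), ncol(x$data), x$pixel_pitch, mean(x$data),
              visibility(x)))
  invisible(x)
}

## Accept either a speckle_image or a bare matrix.
as_image_matrix <- function(x) {
  if (inherits(x, "speckle_image")) x$data
  else if (is.matrix(x)) x
  else stop("expected a speckle_image or a matrix")
}

#' Speckle visibility (contrast)
#'
#' Standard deviation over mean of the intensity pattern.
#'
#' @param image A `speckle_image` or matrix.
#' @return Scalar visibility.
#' @export
visibility <- function(image) {
  m <- as_image_matrix(image)
  stats::sd(m) / mean(m)
}

#' Per-pixel displacement field
#'
#' Two matrices `ux`, `uy` holding the transverse speckle displacement in
#' detector-pixel units (x = columns, y = rows).
#'
#' @param ux,uy Numeric matrices of identical shape.
#' @return An object of class `displacement_field`.
#' @export
displacement_field <- function(ux, uy) {
  stopifnot(is.matrix(ux), is.matrix(uy), all(dim(ux) == dim(uy)))
  structure(list(ux = ux, uy = uy), class = "displacement_field")
}

#' @export
print.displacement_field <- function(x, ...) {
  cat(sprintf("<displacement_field %d x %d, |u| in [%.3g, %.3g] px>\n",
              nrow(x$ux), ncol(x$ux),
              min(sqrt(x$ux^2 + x$uy^2)), max(sqrt(x$ux^2 + x$uy^2))))
  invisible(x)
}

#' Constant displacement field
#'
#' @param shape `c(rows, cols)`.
#' @param ux,uy Scalar displacements in pixels.
#' @return A `displacement_field`.
#' @export
constant_field <- function(shape, ux, uy = 0) {
  displacement_field(matrix(ux, shape[1], shape[2]),
                     matrix(uy, shape[1], shape[2]))
}

#' Projected-thickness sample model
#'
#' A thin object in projection approximation: a projected thickness map plus
#' the material optical constants at the working energy.
#'
#' @param thickness_map Non-negative numeric matrix, micrometres.
#' @param delta Refractive index decrement (dimensionless, > 0).
#' @param mu Linear attenuation coefficient in 1/um (>= 0).
#' @param label Material name.
#' @return An object of class `sample_model`.
#' @export
sample_model <- function(thickness_map, delta, mu, label = "material") {
  stopifnot(is.matrix(thickness_map), all(thickness_map >= 0),
            is_scalar_num(delta), delta > 0, is_scalar_num(mu), mu >= 0)
  structure(list(thickness_map = thickness_map, delta = delta, mu = mu,
                 label = label), class = "sample_model")
}

#' @export
print.sample_model <- function(x, ...) {
  cat(sprintf("<sample_model '%s' %d x %d, t in [%.3g, %.3g] um, delta %.3g, mu %.3g /um>\n",
              x$label, nrow(x$thickness_map), ncol(x$thickness_map),
              min(x$thickness_map), max(x$thickness_map), x$delta, x$mu))
  invisible(x)
}
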