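#' Divergent-beam imaging geometry
#'
#' Describes the cone-beam speckle setup: point source, diffuser, optional
#' sample plane, and detector. The default values are the simulation
#' configuration used throughout: a monochromatic 30 keV point source with a
#' 10 um focal spot, diffuser at 1 m, detector at 3 m, 12 um effective pixel
#' size and a Gaussian detector PSF of sigma = 1/2.355 pixel (FWHM 1 px).
#'
#' The divergent beam is handled by the Fresnel scaling theorem: the package
#' simulates an equivalent parallel-beam system in the demagnified
#' (sample-plane) frame, with effective propagation distance
#' `z_eff = z1 * z2 / (z1 + z2)` and transverse magnification
#' `M = (z1 + z2) / z1`; the 12 um pixel is the effective pixel in that
#' frame. The simulation grid is `oversample` times finer than the pixel.
#'
#' @param source_to_diffuser Source-diffuser distance z1 in metres.
#' @param source_to_detector Source-detector distance in metres.
#' @param sample_position Source-sample distance in metres (default: the
#'   diffuser plane).
#' @param detector_pixel_pitch Effective detector pixel pitch in um.
#' @param focal_spot_fwhm Source focal spot FWHM in um.
#' @param psf_sigma Detector PSF Gaussian sigma in detector pixels.
#' @param photon_energy Photon energy in keV.
#' @param oversample Integer simulation oversampling factor per pixel.
#' @return An object of class `imaging_geometry` with the stated fields plus
#'   derived `magnification`, `z_eff_m` (effective diffuser-to-detector
#'   propagation distance), `sim_pitch` (grid pitch, um) and `wavelength`
#'   (um).
#' @export
imaging_geometry <- function(source_to_diffuser = 1,
                             source_to_detector = 3,
                             sample_position = source_to_diffuser,
                             detector_pixel_pitch = 12,
                             focal_spot_fwhm = 10,
                             psf_sigma = 1 / 2.355,
                             photon_energy = 30,
                             oversample = 4L) {
  stopifnot(source_to_diffuser > 0,
            source_to_diffuser < source_to_detector,
            sample_position > 0, sample_position < source_to_detector,
            detector_pixel_pitch > 0, focal_spot_fwhm >= 0,
            psf_sigma >= 0, photon_energy > 0, oversample >= 1)
  oversample <- as.integer(oversample)
  z1 <- source_to_diffuser
  z2 <- source_to_detector - source_to_diffuser
  M <- (z1 + z2) / z1
  g <- list(source_to_diffuser = source_to_diffuser,
            source_to_detector = source_to_detector,
            sample_position = sample_position,
            detector_pixel_pitch = detector_pixel_pitch,
            focal_spot_fwhm = focal_spot_fwhm,
            psf_sigma = psf_sigma,
            photon_energy = photon_energy,
            oversample = oversample,
            magnification = M,
            z_eff_m = z1 * z2 / (z1 + z2),
            sim_pitch = detector_pixel_pitch / oversample,
            wavelength = wavelength_um(photon_energy))
  class(g) <- "imaging_geometry"
  g
}

#' @export
print.imaging_geometry <- function(x, ...) {
  cat(sprintf(paste0("<imaging_geometry: %g keV, diffuser %g m, detector %g m, ",
                     "pixel %g um (x%d), M = %.3g, z_eff = %.3g m>\n"),
              x$photon_energy, x$source_to_diffuser, x$source_to_detector,
              x$detector_pixel_pitch, x$oversample, x$magnification,
              x$z_eff_m))
  invisible(x)
}

#' Effective sample-to-detector distance for refraction conversion
#'
#' In the demagnified simulation frame a refraction angle `alpha` at the
#' sample displaces the speckle by `alpha * d_eff / p` pixels, where
#' `d_eff = (source_to_detector - sample_position) / magnification` is the
#' magnification-corrected (Fresnel-scaled) sample-to-detector distance and
#' `p` the effective pixel pitch. Equivalently `alpha = u * p_phys / z2`
#' with the physical detector pitch `p_phys = M * p`.
#'
#' @param geometry An `imaging_geometry`.
#' @return Effective distance in metres.
#' @export
effective_sample_distance <- function(geometry) {
  (geometry$source_to_detector - geometry$sample_position) /
    geometry$magnification
}
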