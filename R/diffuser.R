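#' Sandpaper diffuser specification
#'
#' The diffuser is modeled as a stack of sandpaper sheets, each a random
#' rough layer of Al2O3 grains on a uniform 200 um backing. Each sheet's
#' grain surface is generated as white noise low-pass filtered by a Gaussian
#' kernel of FWHM `grain_fwhm`, scaled to RMS roughness `rms_roughness` and
#' offset to non-negative thickness. Grain size controls the speckle size at
#' the detector; roughness controls the speckle contrast.
#'
#' The default roughness scales with the grain size (`1.5 * grain_fwhm`),
#' reflecting that coarser grit is also taller; with the default geometry
#' this yields reference-image visibilities of about 0.2-0.4 over grain
#' sizes 70-150 um (speckle autocorrelation FWHM about 2-10 detector px).
#'
#' @param n_layers Number of sandpaper sheets (>= 1).
#' @param grain_fwhm Lateral grain correlation FWHM in um.
#' @param rms_roughness RMS thickness variation of the grain surface, um;
#'   `NULL` (default) uses `1.5 * grain_fwhm`.
#' @param backing_thickness Uniform backing thickness in um.
#' @param layer_materials Character pair: grain material, backing material
#'   (names in [optical_constants()]).
#' @param layer_spacing Distance between consecutive sheet planes, um.
#' @param seed Integer seed for the random surfaces.
#' @return An object of class `diffuser_spec`.
#' @export
diffuser_spec <- function(n_layers = 10L, grain_fwhm = 100,
                          rms_roughness = NULL, backing_thickness = 200,
                          layer_materials = c("Al2O3", "C6H10O5"),
                          layer_spacing = 250, seed = 1L) {
  if (is.null(rms_roughness)) rms_roughness <- 1.5 * grain_fwhm
  stopifnot(n_layers >= 1, grain_fwhm > 0, rms_roughness > 0,
            backing_thickness >= 0, length(layer_materials) == 2L,
            layer_spacing >= 0)
  structure(list(n_layers = as.integer(n_layers), grain_fwhm = grain_fwhm,
                 rms_roughness = rms_roughness,
                 backing_thickness = backing_thickness,
                 layer_materials = layer_materials,
                 layer_spacing = layer_spacing, seed = as.integer(seed)),
            class = "diffuser_spec")
}

## One random rough grain surface: filtered white noise, sd = rms, offset to
## non-negative thickness (mean 3 * rms, rare negatives clamped).
rough_surface <- function(shape, grain_fwhm, rms, pitch) {
  z <- matrix(stats::rnorm(prod(shape)), shape[1], shape[2])
  sigma_px <- grain_fwhm / 2.355 / pitch
  z <- gauss_blur(z, sigma_px)
  z <- z / stats::sd(z) * rms
  pmax(z + 3 * rms, 0)
}

#' Synthesize the diffuser layer stack
#'
#' Generates `n_layers` independent rough-surface thickness maps (grain
#' material) each paired with a uniform backing. Identical seeds give
#' identical output.
#'
#' @param spec A [diffuser_spec()].
#' @param shape Grid shape `c(rows, cols)` of the simulation grid.
#' @param pitch Grid pitch in um.
#' @param seed Optional seed overriding `spec$seed`.
#' @return A list of class `diffuser`: one element per layer, each a list
#'   with `grain` and `backing` [sample_model()]s.
#' @export
synthesize_diffuser <- function(spec, shape, pitch, seed = NULL) {
  stopifnot(inherits(spec, "diffuser_spec"))
  grain_mat <- optical_constants(spec$layer_materials[1])
  back_mat <- optical_constants(spec$layer_materials[2])
  if (is.null(seed)) seed <- spec$seed
  layers <- with_seed(seed, {
    lapply(seq_len(spec$n_layers), function(i) {
      t_grain <- rough_surface(shape, spec$grain_fwhm, spec$rms_roughness,
                               pitch)
      list(grain = sample_model(t_grain, grain_mat$delta, grain_mat$mu,
                                label = spec$layer_materials[1]),
           backing = sample_model(matrix(spec$backing_thickness,
                                         shape[1], shape[2]),
                                  back_mat$delta, back_mat$mu,
                                  label = spec$layer_materials[2]))
    })
  })
  structure(layers, class = "diffuser",
            spec = spec, pitch = pitch)
}
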