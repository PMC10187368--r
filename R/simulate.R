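## End-to-end image formation: source -> diffuser -> (sample) -> detector.

## Source-size blur sigma in detector pixels: the focal spot (FWHM f) at
## distance z1 projects onto the detector as a blur of FWHM f * z2 / z1
## physical um = f * z2 / z1 / M effective um (source-size convolution).
source_blur_sigma_px <- function(geometry) {
  z1 <- geometry$source_to_diffuser
  z2 <- geometry$source_to_detector - geometry$source_to_diffuser
  fwhm_eff <- geometry$focal_spot_fwhm * (z2 / z1) / geometry$magnification
  fwhm_eff / 2.355 / geometry$detector_pixel_pitch
}

## detect() plus source blur: combined Gaussian of
## sigma = sqrt(psf^2 + src^2) detector pixels applied on the fine grid.
detect_with_source <- function(field, geometry) {
  g2 <- geometry
  g2$psf_sigma <- sqrt(geometry$psf_sigma^2 + source_blur_sigma_px(geometry)^2)
  img <- detect(field, g2)
  img$meta$psf_sigma <- geometry$psf_sigma
  img$meta$source_blur_sigma <- source_blur_sigma_px(geometry)
  img
}

## Field just downstream of the diffuser stack: unit plane wave modulated by
## each sheet (grains + backing) with short angular-spectrum hops between
## sheets (cyclic, pad-free: the hop distances are far below the sampling
## bound and wrap-around is negligible at these distances).
field_after_diffuser <- function(geometry, diffuser) {
  pitch <- attr(diffuser, "pitch")
  shape <- dim(diffuser[[1]]$grain$thickness_map)
  f <- wave_field(matrix(1 + 0i, shape[1], shape[2]), pitch,
                  geometry$wavelength)
  spacing <- attr(diffuser, "spec")$layer_spacing
  for (i in seq_along(diffuser)) {
    f <- apply_object(f, diffuser[[i]]$grain)
    f <- apply_object(f, diffuser[[i]]$backing)
    if (i < length(diffuser) && spacing > 0) {
      f <- propagate(f, spacing, pad = FALSE)
    }
  }
  f
}

#' Simulate a reference/sample speckle image pair
#'
#' Runs the full chain: plane wave (divergent beam folded into the
#' Fresnel-scaled frame of `geometry`) -> stacked sandpaper diffuser ->
#' optional thin sample at the diffuser plane -> free-space propagation to
#' the detector -> source-size blur, detector PSF and pixel integration.
#' No photon noise is added (see [add_poisson_noise()]).
#'
#' When a sample is given, the analytic ground-truth displacement field is
#' returned alongside: `u = alpha * d_eff / p`, with the refraction angle
#' `alpha = -delta * grad t` from the sample's thickness gradient and
#' `d_eff` the magnification-corrected sample-to-detector distance.
#'
#' @param geometry An [imaging_geometry()].
#' @param diffuser_spec A [diffuser_spec()].
#' @param sample Optional [sample_model()] on the simulation grid
#'   (`shape * oversample`).
#' @param shape Detector image shape `c(rows, cols)`.
#' @param seed Integer seed for the diffuser surfaces.
#' @return A list of class `speckle_pair` with elements `reference`,
#'   `sample` ([speckle_image()]s), `ground_truth`
#'   ([displacement_field()] or `NULL`), `visibility`, `geometry`, `seed`.
#' @export
simulate_pair <- function(geometry, diffuser_spec, sample = NULL,
                          shape = c(256L, 256L), seed = 1L) {
  stopifnot(inherits(geometry, "imaging_geometry"),
            inherits(diffuser_spec, "diffuser_spec"))
  os <- geometry$oversample
  grid_shape <- shape * os
  diff_layers <- synthesize_diffuser(diffuser_spec, grid_shape,
                                     geometry$sim_pitch, seed = seed)
  f0 <- field_after_diffuser(geometry, diff_layers)
  z_eff_um <- geometry$z_eff_m * 1e6 -
    (diffuser_spec$n_layers - 1L) * diffuser_spec$layer_spacing
  ref_field <- propagate(f0, z_eff_um)
  reference <- detect_with_source(ref_field, geometry)
  if (is.null(sample)) {
    sample_img <- reference
    gt <- NULL
  } else {
    fs <- apply_object(f0, sample)
    sample_img <- detect_with_source(propagate(fs, z_eff_um), geometry)
    gt <- sample_ground_truth(sample, geometry)
  }
  structure(list(reference = reference, sample = sample_img,
                 ground_truth = gt,
                 visibility = visibility(reference),
                 geometry = geometry, seed = seed),
            class = "speckle_pair")
}

## Analytic ground-truth displacement of a thin sample: refraction angle
## alpha = -delta * grad t (centered differences on the fine grid), block
## averaged to detector pixels, converted to pixels via the effective
## sample-to-detector distance.
sample_ground_truth <- function(sample, geometry) {
  t_map <- sample$thickness_map
  h <- geometry$sim_pitch
  n <- nrow(t_map); p <- ncol(t_map)
  gx <- (t_map[, c(2:p, p)] - t_map[, c(1, 1:(p - 1))]) /
    (h * rep(c(1, rep(2, p - 2), 1), each = n))
  gy <- (t_map[c(2:n, n), ] - t_map[c(1, 1:(n - 1)), ]) /
    (h * rep(c(1, rep(2, n - 2), 1), times = p))
  alpha_x <- -sample$delta * gx     # radians
  alpha_y <- -sample$delta * gy
  d_eff_um <- effective_sample_distance(geometry) * 1e6
  fac <- d_eff_um / geometry$detector_pixel_pitch
  os <- geometry$oversample
  displacement_field(bin_mean(alpha_x, os) * fac,
                     bin_mean(alpha_y, os) * fac)
}

#' @export
print.speckle_pair <- function(x, ...) {
  cat(sprintf("<speckle_pair %d x %d, visibility %.3f, %s>\n",
              nrow(x$reference$data), ncol(x$reference$data), x$visibility,
              if (is.null(x$ground_truth)) "no sample" else "with sample"))
  invisible(x)
}
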