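## Sine-wave PMMA phantom: thickness model, analytic refraction ground
## truth, displacement <-> refraction conversion, and the end-to-end
## validation protocol.

#' Sine-wave phantom specification
#'
#' A PMMA slab of thickness `t(x) = b + A sin(w x)` inside a band of the
#' stated width, zero outside: base thickness b = 1000 um, modulation
#' amplitude A = 800 um, spatial frequency w = 1.33e-3 1/um, band width
#' 1500 um.
#'
#' @param base_thickness b, um.
#' @param amplitude A, um (must not exceed b).
#' @param frequency w, 1/um.
#' @param width Band width, um.
#' @param material Material name in [optical_constants()].
#' @return An object of class `sine_phantom_spec`.
#' @export
sine_phantom_spec <- function(base_thickness = 1000, amplitude = 800,
                              frequency = 1.33e-3, width = 1500,
                              material = "PMMA") {
  stopifnot(base_thickness >= amplitude, amplitude >= 0, frequency > 0,
            width > 0)
  structure(list(base_thickness = base_thickness, amplitude = amplitude,
                 frequency = frequency, width = width, material = material),
            class = "sine_phantom_spec")
}

#' Build the phantom thickness model on a simulation grid
#'
#' The band runs vertically (modulation along x), centred horizontally;
#' x = 0 of the sine is at the left edge of the band.
#'
#' @param spec A [sine_phantom_spec()].
#' @param shape Grid shape `c(rows, cols)`.
#' @param pitch Grid pitch, um.
#' @return A [sample_model()].
#' @export
build_phantom <- function(spec, shape, pitch) {
  stopifnot(inherits(spec, "sine_phantom_spec"))
  period <- 2 * pi / spec$frequency
  if (period / pitch < 8) {
    stop(sprintf("grid pitch %g um undersamples the %g um modulation period",
                 pitch, period))
  }
  p <- shape[2]
  xc <- (seq_len(p) - 0.5) * pitch          # physical x of column centres
  x0 <- (p * pitch - spec$width) / 2         # left edge of the band
  inband <- xc >= x0 & xc < x0 + spec$width
  prof <- ifelse(inband,
                 spec$base_thickness +
                   spec$amplitude * sin(spec$frequency * (xc - x0)),
                 0)
  mat <- optical_constants(spec$material)
  sample_model(matrix(prof, shape[1], p, byrow = TRUE),
               delta = mat$delta, mu = mat$mu, label = spec$material)
}

#' Analytic ground-truth refraction of the sine phantom
#'
#' `alpha_x(x) = -delta * A * w * cos(w x)` inside the band (zero outside
#' and zero everywhere in y), with x measured from the band's left edge.
#'
#' @param spec A [sine_phantom_spec()].
#' @param x Physical positions from the band's left edge, um.
#' @param delta Refractive index decrement; defaults to the embedded table
#'   value for the phantom material.
#' @return List with `alpha_x` (microradians) and `alpha_y` (zero).
#' @export
analytic_refraction <- function(spec, x, delta = NULL) {
  if (is.null(delta)) delta <- optical_constants(spec$material)$delta
  ax <- -delta * spec$amplitude * spec$frequency * cos(spec$frequency * x)
  list(alpha_x = ax * 1e6, alpha_y = rep(0, length(x)))  # urad
}

#' Phase map from a projected thickness map
#'
#' `Phi = -2 pi delta t / lambda` (radians), negative for positive delta
#' and thickness.
#'
#' @param sample A [sample_model()].
#' @param wavelength X-ray wavelength, um.
#' @return Matrix of phase shifts (radians).
#' @export
phase_from_thickness <- function(sample, wavelength) {
  -2 * pi * sample$delta / wavelength * sample$thickness_map
}

#' Convert tracked displacement to refraction angles
#'
#' Small-angle relation `alpha = u * p / d`: `u` in detector pixels, `p`
#' the pixel pitch, `d` the sample-to-detector distance. For the
#' divergent-beam simulation pass the magnification-corrected effective
#' distance (see [effective_sample_distance()]).
#'
#' @param field A [displacement_field()] (pixels).
#' @param pixel_pitch p, um.
#' @param distance d, metres (> 0).
#' @return List with `alpha_x`, `alpha_y` matrices in microradians.
#' @export
displacement_to_refraction <- function(field, pixel_pitch, distance) {
  if (!is_scalar_num(distance) || distance <= 0) {
    stop("sample-to-detector distance must be positive")
  }
  fac <- pixel_pitch / (distance * 1e6) * 1e6   # px -> urad
  list(alpha_x = field$ux * fac, alpha_y = field$uy * fac)
}

#' @rdname displacement_to_refraction
#' @param alpha_x,alpha_y Refraction angles, microradians.
#' @export
refraction_to_displacement <- function(alpha_x, alpha_y, pixel_pitch,
                                       distance) {
  fac <- pixel_pitch / (distance * 1e6) * 1e6
  displacement_field(alpha_x / fac, alpha_y / fac)
}

#' Run the sine-phantom validation protocol
#'
#' Simulates the reference and phantom-sample speckle images with the full
#' wave-optics chain, optionally applies transmission/noise, tracks with
#' every supplied tracker, converts displacements to refraction angles via
#' the effective sample-to-detector distance, and reports per-tracker
#' displacement RMSE against the analytic ground truth plus central-band
#' refraction profiles (mean over the central 20 rows).
#'
#' The comparison region excludes a margin around the band edges (where
#' the thickness discontinuity makes the analytic in-band formula and the
#' tracked field both singular).
#'
#' @param trackers Named list of tracker functions.
#' @param geometry An [imaging_geometry()].
#' @param diffuser A [diffuser_spec()].
#' @param phantom A [sine_phantom_spec()].
#' @param shape Detector image shape.
#' @param transmission,fluence Noise conditions applied to the tracked
#'   pair (`NULL` for clean).
#' @param edge_margin_px Columns excluded on each side of the band edges.
#' @param seed Integer seed.
#' @return An object of class `phantom_report`: list with `metrics`
#'   (data.frame: algorithm, rmse, correlation with the analytic profile),
#'   `profiles` (data.frame of central-row refraction profiles in urad),
#'   `ground_truth`, `conversion` (recorded conversion factors), `pair`.
#' @export
run_phantom_validation <- function(trackers, geometry = imaging_geometry(),
                                   diffuser = diffuser_spec(),
                                   phantom = sine_phantom_spec(),
                                   shape = c(256L, 256L),
                                   transmission = 0.9,
                                   fluence = default_fluence(),
                                   edge_margin_px = 24L, seed = 1L) {
  os <- geometry$oversample
  grid_shape <- as.integer(shape) * os
  sample <- build_phantom(phantom, grid_shape, geometry$sim_pitch)
  pair <- simulate_pair(geometry, diffuser, sample = sample, shape = shape,
                        seed = seed)
  ref <- pair$reference$data
  sam <- pair$sample$data
  if (!is.null(transmission)) sam <- sam * transmission
  if (!is.null(fluence)) {
    ref <- add_poisson_noise(ref, fluence, seed = derive_seed(seed, 31L))
    sam <- add_poisson_noise(sam, fluence, seed = derive_seed(seed, 32L))
  }
  gt <- pair$ground_truth
  d_eff <- effective_sample_distance(geometry)
  p_eff <- geometry$detector_pixel_pitch
  ## evaluation region: inside the band, away from the edges
  prof_fine <- sample$thickness_map[1, ]
  inband_det <- bin_mean(matrix(as.numeric(prof_fine > 0),
                                grid_shape[1], grid_shape[2],
                                byrow = TRUE), os)[1, ] > 0.99
  cols <- which(inband_det)
  if (length(cols) == 0L) stop("phantom band outside the field of view")
  cols <- cols[cols > min(cols) + edge_margin_px &
               cols < max(cols) - edge_margin_px]
  if (length(cols) == 0L) stop("edge margin leaves no evaluable band columns")
  region <- matrix(FALSE, shape[1], shape[2])
  region[, cols] <- TRUE
  mid <- (shape[1] %/% 2) + (-9:10)   # central 20 rows
  gt_alpha <- displacement_to_refraction(gt, p_eff, d_eff)
  profiles <- data.frame(column = seq_len(shape[2]),
                         ground_truth = colMeans(gt_alpha$alpha_x[mid, ]))
  metrics <- list()
  for (nm in names(trackers)) {
    res <- trackers[[nm]](ref, sam, gt)
    v <- res$valid_mask & region
    er <- rmse(res$displacement, gt, mask = v)
    al <- displacement_to_refraction(res$displacement, p_eff, d_eff)
    prof <- colMeans(al$alpha_x[mid, , drop = FALSE])
    profiles[[nm]] <- prof
    cor_prof <- stats::cor(prof[cols], profiles$ground_truth[cols])
    metrics[[nm]] <- data.frame(algorithm = nm,
                                rmse_x = er[["ux"]], rmse = er[["combined"]],
                                profile_correlation = cor_prof,
                                n = sum(v))
  }
  structure(list(metrics = do.call(rbind, metrics),
                 profiles = profiles,
                 ground_truth = gt,
                 region = region,
                 conversion = list(pixel_pitch_um = p_eff,
                                   effective_distance_m = d_eff,
                                   urad_per_pixel = p_eff / (d_eff * 1e6) * 1e6,
                                   sample_position_m = geometry$sample_position),
                 visibility = pair$visibility,
                 seed = seed),
            class = "phantom_report")
}

#' @export
print.phantom_report <- function(x, ...) {
  cat("Sine-phantom validation (", sprintf("%.3g urad per pixel",
      x$conversion$urad_per_pixel), "):\n", sep = "")
  print(x$metrics, row.names = FALSE)
  invisible(x)
}
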