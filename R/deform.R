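## Sub-pixel deformation generation, image warping, patchwise attenuation and
## Poisson noise: the augmentation pipeline that turns reference speckle
## images into (reference, sample, ground truth) training triplets.

#' Deformation specification
#'
#' @param kind One of `"random_patches"`, `"identity"`, `"constant_x"`,
#'   `"constant_y"`, `"constant_xy"`.
#' @param patch_size Patch side in pixels (one of 4, 8, 16, 32, 64, 128);
#'   must divide the image size.
#' @param amplitude_range Length-2 range of displacements in pixels, a
#'   subset of \[-1, 1\]. Constant kinds draw their value from this range
#'   (use `c(-0.15, 0.15)` for the small-displacement augmentation).
#' @param seed Integer seed.
#' @return An object of class `deformation_spec`.
#' @export
deformation_spec <- function(kind = "random_patches", patch_size = 16L,
                             amplitude_range = c(-1, 1), seed = 1L) {
  kind <- match.arg(kind, c("random_patches", "identity", "constant_x",
                            "constant_y", "constant_xy"))
  stopifnot(patch_size %in% c(4L, 8L, 16L, 32L, 64L, 128L),
            length(amplitude_range) == 2L,
            amplitude_range[1] >= -1, amplitude_range[2] <= 1,
            amplitude_range[1] <= amplitude_range[2])
  structure(list(kind = kind, patch_size = as.integer(patch_size),
                 amplitude_range = amplitude_range, seed = as.integer(seed)),
            class = "deformation_spec")
}

## Piecewise-bilinear field over independent patches. Each patch draws one
## sign per component; its four corner values share that sign ("smooth
## displacements in only one direction" per patch). Values interpolate
## bilinearly within the patch; patches are independent, so the field is
## piecewise smooth with possible jumps at patch borders.
patch_component <- function(shape, ps, rng) {
  npy <- shape[1] %/% ps; npx <- shape[2] %/% ps
  lo <- rng[1]; hi <- rng[2]
  out <- matrix(0, shape[1], shape[2])
  ## bilinear weights at pixel centers within one patch, corners at the
  ## patch corners (0-based coords 0 .. ps-1)
  w <- (seq_len(ps) - 1) / (ps - 1)
  for (py in seq_len(npy)) {
    for (px in seq_len(npx)) {
      s <- sample(c(-1, 1), 1L)
      ## corner magnitudes drawn from |range| respecting the shared sign
      cmax <- if (s > 0) hi else -lo
      corners <- s * stats::runif(4L, 0, max(cmax, 0))
      c00 <- corners[1]; c01 <- corners[2]; c10 <- corners[3]; c11 <- corners[4]
      ## bilinear: v(y,x) = (1-wy)(1-wx)c00 + (1-wy)wx c01 + wy(1-wx)c10 + wy wx c11
      v <- outer(1 - w, 1 - w) * c00 + outer(1 - w, w) * c01 +
        outer(w, 1 - w) * c10 + outer(w, w) * c11
      out[(py - 1L) * ps + seq_len(ps), (px - 1L) * ps + seq_len(ps)] <- v
    }
  }
  out
}

#' Generate a displacement field from a deformation specification
#'
#' `random_patches` produces independent piecewise-bilinear patches, each
#' monotone in sign per component, with displacements within the amplitude
#' range (a subset of \[-1, 1\]); pooled over many draws the values are
#' approximately symmetric around zero. `identity` is all-zero; the
#' `constant_*` kinds are spatially uniform with values drawn uniformly
#' from the amplitude range (zero in the unconstrained component for
#' `constant_x` / `constant_y`).
#'
#' @param spec A [deformation_spec()].
#' @param image_shape `c(rows, cols)`; must be divisible by the patch size
#'   for `random_patches`.
#' @return A [displacement_field()].
#' @export
generate_deformation <- function(spec, image_shape) {
  stopifnot(inherits(spec, "deformation_spec"))
  shape <- as.integer(image_shape)
  zero <- matrix(0, shape[1], shape[2])
  with_seed(spec$seed, switch(
    spec$kind,
    identity = displacement_field(zero, zero),
    constant_x = displacement_field(
      zero + stats::runif(1, spec$amplitude_range[1], spec$amplitude_range[2]),
      zero),
    constant_y = displacement_field(
      zero,
      zero + stats::runif(1, spec$amplitude_range[1], spec$amplitude_range[2])),
    constant_xy = displacement_field(
      zero + stats::runif(1, spec$amplitude_range[1], spec$amplitude_range[2]),
      zero + stats::runif(1, spec$amplitude_range[1], spec$amplitude_range[2])),
    random_patches = {
      ps <- spec$patch_size
      if (any(shape %% ps != 0L)) {
        stop(sprintf("patch size %d does not divide image shape %d x %d",
                     ps, shape[1], shape[2]))
      }
      displacement_field(patch_component(shape, ps, spec$amplitude_range),
                         patch_component(shape, ps, spec$amplitude_range))
    }))
}

## Cubic B-spline interpolation (Unser-style): a separable prefilter turns
## the image into B-spline coefficients, which are then sampled with the
## cubic B-spline basis. Unlike cubic convolution, the interpolating
## spline has near-ideal phase response close to Nyquist, which keeps the
## effective shift of warped speckle faithful to the nominal field.

## Coefficient prefilter by FFT deconvolution of the sampled B3 kernel
## [1/6, 4/6, 1/6] per axis. For non-circular use the image is
## edge-replicated by `pad` pixels first; returns the (padded)
## coefficient array and the offset of the original origin.
bspline_coeffs <- function(m, circular = FALSE, pad = 16L) {
  if (circular) {
    oy <- 0L; ox <- 0L
  } else {
    oy <- pad; ox <- pad
    m <- pad_edge(m, nrow(m) + 2L * pad, ncol(m) + 2L * pad, pad, pad)
  }
  n <- nrow(m); p <- ncol(m)
  By <- (4 + 2 * cos(2 * pi * fft_freq(n))) / 6
  Bx <- (4 + 2 * cos(2 * pi * fft_freq(p))) / 6
  co <- Re(stats::fft(stats::fft(m) / outer(By, Bx), inverse = TRUE)) / (n * p)
  list(c = co, oy = oy, ox = ox)
}

## Cubic B-spline basis weights for taps k = -1, 0, 1, 2 at fraction t.
bspline_weights <- function(t) {
  list(`-1` = (1 - t)^3 / 6,
       `0` = (3 * t^3 - 6 * t^2 + 4) / 6,
       `1` = (-3 * t^3 + 3 * t^2 + 3 * t + 1) / 6,
       `2` = t^3 / 6)
}

## Sample B-spline coefficients at (y, x) (1-based fractional positions in
## the original image frame). Clamped or wrapped lookups per `circular`.
interp_bspline <- function(cf, y, x, circular = FALSE) {
  co <- cf$c
  n <- nrow(co); p <- ncol(co)
  y <- y + cf$oy; x <- x + cf$ox
  y0 <- floor(y); x0 <- floor(x)
  wy <- bspline_weights(y - y0)
  wx <- bspline_weights(x - x0)
  acc <- numeric(length(y))
  for (ky in -1:2) {
    iy <- if (circular) (y0 + ky - 1L) %% n + 1L else pmin(pmax(y0 + ky, 1), n)
    for (kx in -1:2) {
      ix <- if (circular) (x0 + kx - 1L) %% p + 1L else pmin(pmax(x0 + kx, 1), p)
      acc <- acc + wy[[ky + 2]] * wx[[kx + 2]] * co[cbind(iy, ix)]
    }
  }
  acc
}

#' Warp a reference image by a displacement field
#'
#' Inverse mapping with cubic B-spline sub-pixel interpolation:
#' `sample(x, y) = reference(x - ux(x, y), y - uy(x, y))`, i.e. the speckle
#' at reference position x appears displaced by +u in the sample image.
#' Border lookups are edge-clamped.
#'
#' @param reference A [speckle_image()] or matrix.
#' @param field A [displacement_field()] matching the image shape.
#' @param circular Logical; if `TRUE`, lookups wrap around (useful for
#'   constructing exact integer-shift test pairs).
#' @return An object of the same type as `reference`.
#' @export
warp <- function(reference, field, circular = FALSE) {
  m <- as_image_matrix(reference)
  stopifnot(inherits(field, "displacement_field"),
            all(dim(m) == dim(field$ux)))
  if (all(field$ux == 0) && all(field$uy == 0)) return(reference)
  n <- nrow(m); p <- ncol(m)
  yy <- rep(seq_len(n), times = p) - as.vector(field$uy)
  xx <- rep(seq_len(p), each = n) - as.vector(field$ux)
  cf <- bspline_coeffs(m, circular = circular)
  out <- matrix(interp_bspline(cf, yy, xx, circular = circular), n, p)
  if (inherits(reference, "speckle_image")) {
    speckle_image(out, reference$pixel_pitch,
                  meta = c(reference$meta, list(warped = TRUE)))
  } else out
}

#' Apply a patchwise random transmission map
#'
#' Multiplies the image by a piecewise-bilinear transmission map T(x, y)
#' generated in the same manner as the deformation patches, with values in
#' `range` (default 50-100% transmission).
#'
#' @param image A [speckle_image()] or matrix.
#' @param patch_size Patch side in pixels.
#' @param range Transmission range, within (0, 1\].
#' @param seed Integer seed.
#' @return A list with `image` (attenuated, same type as input) and
#'   `transmission` (the map, matrix).
#' @export
apply_transmission <- function(image, patch_size = 16L, range = c(0.5, 1.0),
                               seed = 1L) {
  if (range[1] <= 0 || range[2] > 1 || range[1] > range[2]) {
    stop("transmission range must lie within (0, 1]")
  }
  m <- as_image_matrix(image)
  shape <- dim(m)
  tmap <- with_seed(seed, {
    if (diff(range) == 0) {
      matrix(range[1], shape[1], shape[2])
    } else {
      ## reuse the patch generator on [0, width] then offset: transmission
      ## has no sign structure, so draw positive-sign patches spanning range
      f <- patch_component(shape, as.integer(patch_size), c(0, diff(range)))
      range[1] + abs(f)
    }
  })
  out <- m * tmap
  img <- if (inherits(image, "speckle_image")) {
    speckle_image(out, image$pixel_pitch,
                  meta = c(image$meta, list(transmission_range = range)))
  } else out
  list(image = img, transmission = tmap)
}

#' Add Poisson photon noise
#'
#' Scales the image to expected photon counts (`mean_photons_per_pixel` at
#' the image mean), draws independent Poisson counts per pixel, and rescales
#' back to the original intensity units.
#'
#' @param image A [speckle_image()] or matrix (non-negative).
#' @param mean_photons_per_pixel Expected photons per pixel at the image
#'   mean intensity (> 0).
#' @param seed Integer seed.
#' @return Same type as `image`.
#' @export
add_poisson_noise <- function(image, mean_photons_per_pixel, seed = 1L) {
  if (!is_scalar_num(mean_photons_per_pixel) || mean_photons_per_pixel <= 0) {
    stop("mean_photons_per_pixel must be a positive number")
  }
  m <- as_image_matrix(image)
  scale <- mean_photons_per_pixel / mean(m)
  noisy <- with_seed(seed, {
    matrix(stats::rpois(length(m), lambda = pmax(m * scale, 0)),
           nrow(m), ncol(m)) / scale
  })
  if (inherits(image, "speckle_image")) {
    speckle_image(noisy, image$pixel_pitch,
                  meta = c(image$meta,
                           list(mean_photons = mean_photons_per_pixel)))
  } else noisy
}

#' Default photon fluence
#'
#' Expected photons per detector pixel used when noise is requested and no
#' fluence is given: 10^4, a typical well-exposed microfocus acquisition,
#' giving about 1% relative intensity noise per pixel.
#' @export
default_fluence <- function() 1e4
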