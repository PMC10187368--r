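## Free-space propagation (angular spectrum method), projection-approximation
## object insertion, and detector integration.

#' Propagate a wave field through free space
#'
#' Angular spectrum method: the field's 2D spectrum is multiplied by the
#' exact propagation kernel `exp(2*pi*i*z*sqrt(1/lambda^2 - fx^2 - fy^2))`.
#' Evanescent components (spatial frequencies beyond 1/lambda) are discarded.
#' Negative distances are allowed (back-propagation).
#'
#' With `pad = TRUE` (default) the field is edge-replicated by `pad_frac` of
#' its size on every side before the FFT and cropped afterwards, suppressing
#' periodic wrap-around. `pad = FALSE` computes the plain cyclic propagation,
#' which is exactly unitary (total intensity conserved to machine precision).
#'
#' The grid must sample the kernel adequately: the method errors if
#' `|z| > N * pitch^2 / lambda` (per padded axis), the distance beyond which
#' the quadratic kernel phase aliases between frequency samples.
#'
#' @param field A [wave_field()].
#' @param distance Propagation distance in micrometres.
#' @param pad Logical; edge-pad before the FFT.
#' @param pad_frac Fractional padding per side (>= 0.25 recommended).
#' @return The propagated `wave_field` on the same grid.
#' @export
propagate <- function(field, distance, pad = TRUE, pad_frac = 0.25) {
  stopifnot(inherits(field, "wave_field"), is_scalar_num(distance))
  if (distance == 0) return(field)
  h <- field$grid_pitch
  lam <- field$wavelength
  u <- field$amplitude
  n0 <- nrow(u); p0 <- ncol(u)
  if (pad) {
    ny <- next_fast_len(ceiling(n0 * (1 + 2 * pad_frac)))
    nx <- next_fast_len(ceiling(p0 * (1 + 2 * pad_frac)))
    oy <- (ny - n0) %/% 2L; ox <- (nx - p0) %/% 2L
    u <- pad_edge(u, ny, nx, oy, ox)
  } else {
    ny <- n0; nx <- p0; oy <- 0L; ox <- 0L
  }
  ## per-axis kernel sampling bound; axes shorter than 16 samples are
  ## treated as quasi-uniform (their band is essentially DC) and skipped
  sizes <- c(ny, nx)
  zmax <- min(sizes[sizes >= 16L], Inf) * h^2 / lam
  if (abs(distance) > zmax) {
    stop(sprintf(paste0("angular-spectrum sampling bound violated: |z| = %g um ",
                        "exceeds N*pitch^2/lambda = %g um; use a finer grid ",
                        "or a larger field"), abs(distance), zmax))
  }
  fy <- fft_freq(ny, h)
  fx <- fft_freq(nx, h)
  arg <- 1 / lam^2 - outer(fy^2, rep(1, nx)) - outer(rep(1, ny), fx^2)
  kz <- sqrt(pmax(arg, 0))
  H <- exp(2i * pi * distance * kz)
  H[arg <= 0] <- 0            # evanescent cut
  U <- stats::fft(u)
  out <- stats::fft(U * H, inverse = TRUE) / (ny * nx)
  out <- out[oy + seq_len(n0), ox + seq_len(p0), drop = FALSE]
  wave_field(out, h, lam)
}

#' Insert a thin object in projection approximation
#'
#' Multiplies the amplitude by `exp(-mu * t / 2)` and advances the phase by
#' `-2 * pi * delta * t / lambda`, where `t` is the projected thickness map
#' of the sample (resampled to the field grid by the caller).
#'
#' @param field A [wave_field()].
#' @param sample A [sample_model()] whose thickness map matches the field
#'   grid.
#' @return The modulated `wave_field`.
#' @export
apply_object <- function(field, sample) {
  stopifnot(inherits(field, "wave_field"), inherits(sample, "sample_model"))
  t_map <- sample$thickness_map
  if (!all(dim(t_map) == field$grid_shape)) {
    stop(sprintf("sample grid (%d x %d) does not match field grid (%d x %d)",
                 nrow(t_map), ncol(t_map),
                 field$grid_shape[1], field$grid_shape[2]))
  }
  trans <- exp(-(sample$mu / 2) * t_map +
               (-2i * pi * sample$delta / field$wavelength) * t_map)
  wave_field(field$amplitude * trans, field$grid_pitch, field$wavelength)
}

#' Integrate a wave field onto the detector
#'
#' Computes the intensity `|amplitude|^2`, blurs it with the Gaussian
#' detector PSF (sigma = `geometry$psf_sigma` detector pixels), and sums the
#' intensity over `oversample x oversample` blocks to form detector pixels.
#' No noise is added here. The field pitch must divide the detector pitch
#' (integer oversampling).
#'
#' @param field A [wave_field()].
#' @param geometry An [imaging_geometry()].
#' @return A [speckle_image()].
#' @export
detect <- function(field, geometry) {
  stopifnot(inherits(field, "wave_field"),
            inherits(geometry, "imaging_geometry"))
  ratio <- geometry$detector_pixel_pitch / field$grid_pitch
  if (abs(ratio - round(ratio)) > 1e-9) {
    stop(sprintf("field pitch %g um does not divide detector pitch %g um",
                 field$grid_pitch, geometry$detector_pixel_pitch))
  }
  f <- as.integer(round(ratio))
  intens <- Mod(field$amplitude)^2
  intens <- gauss_blur(intens, geometry$psf_sigma * f)
  img <- bin_sum(intens, f)
  speckle_image(img, geometry$detector_pixel_pitch,
                meta = list(oversample = f,
                            psf_sigma = geometry$psf_sigma))
}
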