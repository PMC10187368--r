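## Angular-spectrum propagation, projection approximation, detection and
## the diffuser model.

test_that("propagation conserves energy, is reciprocal, and is the identity at z = 0", {
  set.seed(7)
  amp <- matrix(complex(real = rnorm(96^2), imaginary = rnorm(96^2)), 96, 96)
  f <- wave_field(amp, grid_pitch = 3, wavelength = wavelength_um(30))
  expect_identical(propagate(f, 0)$amplitude, f$amplitude)
  g <- propagate(f, 4e5, pad = FALSE)
  expect_lt(abs(total_intensity(g) - total_intensity(f)) / total_intensity(f),
            1e-10)
  back <- propagate(g, -4e5, pad = FALSE)
  expect_lt(max(Mod(back$amplitude - f$amplitude)) / max(Mod(f$amplitude)),
            1e-8)
})

test_that("propagation errors when the kernel sampling bound is violated", {
  f <- wave_field(matrix(1 + 0i, 64, 64), grid_pitch = 1,
                  wavelength = wavelength_um(30))
  expect_error(propagate(f, 1e10, pad = FALSE), "sampling bound")
})

test_that("angular spectrum matches the Fresnel quadrature oracle for a slit", {
  skip_if_not_installed("pracma")
  lam <- wavelength_um(30)
  z <- 1e6                       # 1 m in um
  h <- 0.5
  N <- 4096L
  xs <- (seq_len(N) - N / 2 - 0.5) * h
  ## 100 um slit; edges band-limited (erf over ~1 um, far below the
  ## sqrt(lambda z) ~ 6.4 um Fresnel scale) so the sampled field and the
  ## quadrature integrand describe the same aperture
  erf <- function(t) 2 * pnorm(t * sqrt(2)) - 1
  s_edge <- 1.0
  ap <- 0.5 * (erf((xs + 50) / s_edge) - erf((xs - 50) / s_edge))
  fld <- wave_field(matrix(ap, 4, N, byrow = TRUE) + 0i, h, lam)
  out <- propagate(fld, z, pad = FALSE)
  I_as <- Mod(out$amplitude[2, ])^2
  gl <- pracma::gaussLegendre(6000, -62, 62)
  apq <- 0.5 * (erf((gl$x + 50) / s_edge) - erf((gl$x - 50) / s_edge))
  ke <- pi / (lam * z)
  sel <- abs(xs) <= 160
  U <- vapply(xs[sel], function(x0)
    sum(gl$w * apq * exp(1i * ke * (x0 - gl$x)^2)), complex(1))
  I_or <- Mod(U)^2 / (lam * z)
  expect_lt(max(abs(I_as[sel] - I_or)) / max(I_or), 1e-3)
})

test_that("projection approximation: identity, Beer-Lambert, and the delta table", {
  f <- wave_field(matrix(1 + 0i, 32, 32), 3, wavelength_um(30))
  zero <- sample_model(matrix(0, 32, 32), delta = 1e-7, mu = 1e-5)
  expect_equal(apply_object(f, zero)$amplitude, f$amplitude)
  t0 <- 500
  mat <- optical_constants("PMMA")
  slab <- sample_model(matrix(t0, 32, 32), mat$delta, mat$mu)
  g <- apply_object(f, slab)
  expect_equal(Mod(g$amplitude[1, 1])^2, exp(-mat$mu * t0), tolerance = 1e-12)
  ## phase advance per Phi = -2 pi delta t / lambda
  expect_equal(Arg(g$amplitude[1, 1]),
               ((-2 * pi * mat$delta * t0 / f$wavelength + pi) %% (2 * pi)) - pi,
               tolerance = 1e-9)
  expect_error(apply_object(f, sample_model(matrix(1, 8, 8), 1e-7, 0)),
               "does not match")
})

test_that("embedded optical constants agree with an independent free-electron computation", {
  ## delta = r_e lambda^2 n_e / (2 pi), classical electron radius and
  ## Avogadro number written out independently of the table
  re_um <- 2.8179403262e-9
  lam <- 1.23984193e-3 / 30
  ne_per_um3 <- function(rho, Z, A) rho * (Z / A) * 6.02214076e11
  delta_of <- function(rho, Z, A) re_um * lam^2 * ne_per_um3(rho, Z, A) / (2 * pi)
  expect_equal(optical_constants("PMMA")$delta,
               delta_of(1.19, 54, 100.12), tolerance = 2e-3)
  expect_equal(optical_constants("Al2O3")$delta,
               delta_of(3.97, 50, 101.961), tolerance = 2e-3)
  expect_error(optical_constants("unobtainium"), "unknown material")
})

test_that("detection: flat field stays flat, signal is conserved, PSF is Gaussian", {
  geom <- imaging_geometry(oversample = 4L)
  f <- wave_field(matrix(1 + 0i, 64, 64), geom$sim_pitch, geom$wavelength)
  img <- detect(f, geom)
  expect_equal(dim(img$data), c(16L, 16L))
  expect_lt(diff(range(img$data)) / mean(img$data), 1e-10)
  ## total detected signal equals total incident intensity
  set.seed(1)
  amp <- matrix(complex(real = rnorm(64^2), imaginary = rnorm(64^2)), 64, 64)
  f2 <- wave_field(amp, geom$sim_pitch, geom$wavelength)
  img2 <- detect(f2, geom)
  expect_equal(sum(img2$data), sum(Mod(amp)^2), tolerance = 1e-10)
  ## single bright sub-pixel point -> sampled Gaussian PSF
  amp3 <- matrix(0 + 0i, 64, 64)
  amp3[33, 33] <- 1
  img3 <- detect(wave_field(amp3, geom$sim_pitch, geom$wavelength), geom)
  sig_f <- geom$psf_sigma * geom$oversample      # sigma in fine pixels
  centre <- 33
  expected <- outer(seq_len(16), seq_len(16), function(iy, ix) {
    py <- (iy - 1) * 4 + 2.5; px <- (ix - 1) * 4 + 2.5
    ## integrate the Gaussian over each 4x4 block via pnorm differences
    (pnorm(py + 2 - centre, sd = sig_f) - pnorm(py - 2 - centre, sd = sig_f)) *
      (pnorm(px + 2 - centre, sd = sig_f) - pnorm(px - 2 - centre, sd = sig_f))
  })
  ## the implementation convolves with the sampled, renormalized kernel;
  ## for sigma ~1.7 fine px that differs from the continuous Gaussian
  ## integral at the percent level
  expect_lt(max(abs(img3$data - expected)) / max(expected), 2e-2)
  ## non-integer oversampling rejected
  bad <- wave_field(matrix(1 + 0i, 10, 10), geom$detector_pixel_pitch / 2.5,
                    geom$wavelength)
  expect_error(detect(bad, geom), "does not divide")
})

test_that("diffuser synthesis is deterministic with the stated backing", {
  sp <- diffuser_spec(n_layers = 3L, seed = 11L)
  d1 <- synthesize_diffuser(sp, c(32L, 32L), pitch = 3)
  d2 <- synthesize_diffuser(sp, c(32L, 32L), pitch = 3)
  expect_identical(d1[[2]]$grain$thickness_map, d2[[2]]$grain$thickness_map)
  for (l in d1) {
    expect_true(all(l$backing$thickness_map == 200))
    expect_true(all(l$grain$thickness_map >= 0))
    expect_equal(l$grain$label, "Al2O3")
    expect_equal(l$backing$label, "C6H10O5")
  }
})

test_that("simulated speckle: visibility, size range and monotone statistics", {
  geom <- imaging_geometry()
  grains <- c(70, 90, 110, 130, 150)
  stats <- t(vapply(grains, function(g) {
    pr <- simulate_pair(geom, diffuser_spec(grain_fwhm = g, seed = 31L),
                        shape = c(128L, 128L), seed = 31L)
    c(vis = pr$visibility, fwhm = autocorr_fwhm(pr$reference$data))
  }, numeric(2)))
  ## autocorrelation FWHM spans ~2-10 detector px (22-120 um) and both
  ## statistics rise monotonically with grain size
  expect_true(all(stats[, "fwhm"] >= 1.8))
  expect_gt(max(stats[, "fwhm"]), 8)
  expect_lt(min(stats[, "fwhm"]), 3)
  expect_true(all(diff(stats[, "fwhm"]) > 0))
  expect_true(all(diff(stats[, "vis"]) > 0))
  expect_true(all(stats[, "vis"] >= 0.19))
})

test_that("simulate_pair without a sample returns identical images and no truth", {
  geom <- imaging_geometry()
  pr <- simulate_pair(geom, diffuser_spec(seed = 3L), shape = c(32L, 32L),
                      seed = 3L)
  expect_null(pr$ground_truth)
  expect_identical(pr$reference$data, pr$sample$data)
  ## determinism: same seed, same image
  pr2 <- simulate_pair(geom, diffuser_spec(seed = 3L), shape = c(32L, 32L),
                       seed = 3L)
  expect_identical(pr$reference$data, pr2$reference$data)
})
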