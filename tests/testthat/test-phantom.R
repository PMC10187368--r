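## Sine-wave phantom: thickness, analytic refraction, conversions and the
## end-to-end validation chain.

test_that("phantom thickness profile follows b + A sin(w x) inside the band", {
  spec <- sine_phantom_spec()
  sm <- build_phantom(spec, c(8L, 1024L), pitch = 3)
  prof <- sm$thickness_map[1, ]
  xc <- (seq_len(1024) - 0.5) * 3
  x0 <- (1024 * 3 - 1500) / 2
  inband <- xc >= x0 & xc < x0 + 1500
  expect_true(all(prof[!inband] == 0))
  ## at the band edge sin(w * 0) = 0, so the thickness starts at b
  col <- which(inband)[1]
  expect_lt(abs(prof[col] - 1000), 5)
  ## extremes bounded by b +/- A = [200, 1800]; the 1500 um band spans
  ## 2 rad of phase from sin(0), so the maximum 1800 is attained but the
  ## in-band minimum stays at the band-edge value b
  expect_lt(abs(max(prof) - 1800), 1)
  expect_gte(min(prof[inband]), 200 - 1e-9)
  expect_lt(abs(min(prof[inband]) - 1000), 5)
  expect_error(build_phantom(sine_phantom_spec(frequency = 0.5), c(8L, 64L),
                             pitch = 3), "undersamples")
})

test_that("analytic refraction equals the finite-difference phase chain", {
  spec <- sine_phantom_spec()
  mat <- optical_constants("PMMA")
  lam <- wavelength_um(30)
  h <- 0.25
  x <- seq(100, 3000, by = h)
  t_x <- spec$base_thickness + spec$amplitude * sin(spec$frequency * x)
  phi <- -2 * pi * mat$delta / lam * t_x
  ## alpha_x = (lambda / 2 pi) dPhi/dx, centered differences
  alpha_fd <- (lam / (2 * pi)) * (phi[3:length(phi)] - phi[1:(length(phi) - 2)]) /
    (2 * h) * 1e6
  alpha_an <- analytic_refraction(spec, x[2:(length(x) - 1)])$alpha_x
  expect_lt(max(abs(alpha_fd - alpha_an)) / max(abs(alpha_an)), 1e-6)
  ## peak magnitude = delta A w
  expect_equal(max(abs(alpha_an)),
               mat$delta * spec$amplitude * spec$frequency * 1e6,
               tolerance = 1e-6)
  expect_equal(analytic_refraction(spec, pi / 2 / spec$frequency)$alpha_x, 0,
               tolerance = 1e-9)
})

test_that("phase_from_thickness is linear and consistent with the refraction chain", {
  sm <- build_phantom(sine_phantom_spec(), c(4L, 2048L), pitch = 3)
  lam <- wavelength_um(30)
  phi <- phase_from_thickness(sm, lam)
  expect_true(all(phi[sm$thickness_map > 0] < 0))
  expect_equal(phase_from_thickness(
    sample_model(2 * sm$thickness_map, sm$delta, sm$mu), lam), 2 * phi,
    tolerance = 1e-12)
  expect_equal(phase_from_thickness(
    sample_model(matrix(0, 2, 2), sm$delta, sm$mu), lam), matrix(0, 2, 2))
  ## gradient of Phi inside the band reproduces 2 pi / lambda * alpha_x
  row <- phi[1, ]
  inb <- which(sm$thickness_map[1, ] > 0)
  core <- inb[50:(length(inb) - 50)]
  dphi <- (row[core + 1] - row[core - 1]) / (2 * 3)
  xc <- (core - 0.5) * 3 - (2048 * 3 - 1500) / 2
  alpha <- analytic_refraction(sine_phantom_spec(), xc)$alpha_x * 1e-6
  expect_lt(max(abs(dphi - 2 * pi / lam * alpha)) / max(abs(dphi)), 1e-5)
})

test_that("displacement/refraction conversions: arithmetic and round trip", {
  f <- constant_field(c(4L, 4L), 1, 0)
  a <- displacement_to_refraction(f, pixel_pitch = 12, distance = 2)
  expect_equal(a$alpha_x[1, 1], 6, tolerance = 1e-12)   # urad
  expect_true(all(a$alpha_y == 0))
  z <- displacement_to_refraction(constant_field(c(2L, 2L), 0, 0), 12, 2)
  expect_true(all(z$alpha_x == 0))
  set.seed(1)
  g <- displacement_field(matrix(rnorm(16), 4), matrix(rnorm(16), 4))
  ar <- displacement_to_refraction(g, 12, 0.667)
  back <- refraction_to_displacement(ar$alpha_x, ar$alpha_y, 12, 0.667)
  expect_equal(back$ux, g$ux, tolerance = 1e-12)
  expect_error(displacement_to_refraction(g, 12, -1), "positive")
})

test_that("tracked refraction follows the analytic cosine when the modulation is strong", {
  ## At the physical PMMA delta the peak displacement is ~0.018 px, at the
  ## trackers' speckle-systematic noise floor. A hypothetical material
  ## with 6x the refraction (delta labelled synthetic) lifts the signal
  ## well above that floor; the tracked profile must then follow the
  ## analytic cosine with near-unit gain. (The residual spatially
  ## correlated speckle noise of a single acquisition caps the raw
  ## profile correlation around 0.6-0.8.)
  geom <- imaging_geometry()
  spec <- sine_phantom_spec()
  sm <- build_phantom(spec, c(256L, 256L) * geom$oversample, geom$sim_pitch)
  strong <- sample_model(sm$thickness_map, sm$delta * 6, sm$mu,
                         label = "synthetic high-delta PMMA")
  pair <- simulate_pair(geom, diffuser_spec(seed = 33L), sample = strong,
                        shape = c(256L, 256L), seed = 33L)
  tz <- speckle_track(pair$reference, pair$sample, "zncc")
  gt <- pair$ground_truth
  cols <- 70:187                 # band interior, away from the edges
  mid <- 100:157
  prof_t <- colMeans(tz$displacement$ux[mid, cols])
  prof_g <- colMeans(gt$ux[mid, cols])
  expect_gt(max(abs(prof_g)), 0.08)      # signal above the ~0.02 px floor
  expect_gt(cor(prof_t, prof_g), 0.55)
  slope <- stats::coef(stats::lm(prof_t ~ prof_g))[[2]]
  expect_gt(slope, 0.7)
  expect_lt(slope, 1.35)
})

test_that("phantom validation: oracle matches the analytic profile; period is right", {
  rep <- run_phantom_validation(list(oracle = oracle_tracker()),
                                shape = c(96L, 96L),
                                transmission = NULL, fluence = NULL,
                                edge_margin_px = 10L, seed = 21L)
  expect_equal(rep$metrics$rmse, 0)
  expect_equal(rep$metrics$profile_correlation, 1, tolerance = 1e-9)
  ## simulated ground truth equals the analytic refraction in the band
  ## interior to interpolation accuracy
  geom <- imaging_geometry()
  cols <- which(colSums(rep$region) > 0)
  prof_gt <- rep$profiles$ground_truth
  p_eff <- geom$detector_pixel_pitch
  x0 <- (96 * p_eff - 1500) / 2
  xc <- (cols - 0.5) * p_eff - x0
  alpha_an <- analytic_refraction(sine_phantom_spec(), xc)$alpha_x
  expect_lt(max(abs(prof_gt[cols] - alpha_an)) / max(abs(alpha_an)), 0.05)
})
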