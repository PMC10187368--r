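## Deformation generation, warping, attenuation, Poisson noise and the
## dataset builder.

test_that("identity and constant deformation kinds", {
  shape <- c(32L, 32L)
  idf <- generate_deformation(deformation_spec("identity"), shape)
  expect_true(all(idf$ux == 0) && all(idf$uy == 0))
  cf <- generate_deformation(
    deformation_spec("constant_xy", amplitude_range = c(-0.15, 0.15),
                     seed = 4L), shape)
  expect_equal(length(unique(as.vector(cf$ux))), 1L)
  expect_equal(length(unique(as.vector(cf$uy))), 1L)
  expect_true(max(abs(c(cf$ux, cf$uy))) <= 0.15)
  cx <- generate_deformation(deformation_spec("constant_x", seed = 5L), shape)
  expect_true(all(cx$uy == 0) && all(cx$ux == cx$ux[1, 1]))
})

test_that("random patches are piecewise bilinear, sign-monotone, within [-1, 1]", {
  shape <- c(64L, 64L)
  ps <- 8L
  f <- generate_deformation(deformation_spec("random_patches", ps, seed = 9L),
                            shape)
  expect_true(max(abs(c(f$ux, f$uy))) <= 1)
  for (comp in c("ux", "uy")) {
    m <- f[[comp]]
    for (py in seq_len(64 %/% ps)) {
      for (px in seq_len(64 %/% ps)) {
        blk <- m[(py - 1) * ps + seq_len(ps), (px - 1) * ps + seq_len(ps)]
        ## one sign per patch and per component
        expect_true(all(blk >= 0) || all(blk <= 0))
        ## linear along each axis: interior second differences vanish
        d2x <- blk[, 1:(ps - 2)] - 2 * blk[, 2:(ps - 1)] + blk[, 3:ps]
        d2y <- blk[1:(ps - 2), ] - 2 * blk[2:(ps - 1), ] + blk[3:ps, ]
        expect_lt(max(abs(d2x)), 1e-10)
        expect_lt(max(abs(d2y)), 1e-10)
      }
    }
  }
  expect_error(generate_deformation(
    deformation_spec("random_patches", 128L), c(64L, 64L)), "does not divide")
})

test_that("pooled random-patch displacements are centred and bounded", {
  vals <- unlist(lapply(1:40, function(i) {
    f <- generate_deformation(
      deformation_spec("random_patches", 16L, seed = i), c(32L, 32L))
    c(f$ux, f$uy)
  }))
  expect_lt(abs(mean(vals)), 0.03)
  expect_true(all(abs(vals) <= 1))
})

test_that("warp: identity, integer translation, Fourier-shift oracle", {
  fx <- fixtures()
  ref <- fx$references[[1]]
  shape <- dim(ref)
  expect_identical(warp(ref, constant_field(shape, 0, 0)), ref)
  ## integer shift: interior pixels exact
  sh <- warp(ref, constant_field(shape, 1, 0))
  expect_equal(sh[, 2:ncol(ref)], ref[, 1:(ncol(ref) - 1)], tolerance = 1e-12)
  ## sub-pixel constant shift vs the Fourier shift theorem on a
  ## band-limited pattern
  n <- 64
  set.seed(3)
  spec <- matrix(complex(real = rnorm(n^2), imaginary = rnorm(n^2)), n, n)
  keep <- outer(abs(speckletrack:::fft_freq_index(n)) <= 6,
                abs(speckletrack:::fft_freq_index(n)) <= 6)
  spec[!keep] <- 0
  img <- Re(fft(spec, inverse = TRUE)) / n^2
  img <- img - min(img) + 1
  dx <- 0.3
  shifted_fft <- Re(fft(fft(img) * exp(-2i * pi * dx *
    outer(rep(1, n), speckletrack:::fft_freq(n))), inverse = TRUE)) / n^2
  got <- warp(img, constant_field(c(n, n), dx, 0), circular = TRUE)
  interior <- 9:(n - 8)
  expect_lt(max(abs(got[interior, interior] - shifted_fft[interior, interior])),
            1e-3 * diff(range(img)))
})

test_that("patchwise transmission maps multiply and are recoverable", {
  fx <- fixtures()
  ref <- fx$references[[1]]
  one <- apply_transmission(ref, 16L, range = c(1, 1), seed = 2L)
  expect_identical(one$image, ref)
  expect_true(all(one$transmission == 1))
  at <- apply_transmission(ref, 16L, range = c(0.5, 1), seed = 2L)
  expect_true(all(at$transmission >= 0.5 & at$transmission <= 1))
  expect_lt(max(abs(at$image / ref - at$transmission)), 1e-10)
  expect_error(apply_transmission(ref, 16L, range = c(0, 1.2)), "range")
  half <- ref * 0.5
  expect_equal(half, apply_transmission(ref, 16L, c(0.5, 0.5), 1L)$image,
               tolerance = 1e-12)
})

test_that("Poisson noise is unbiased with the expected variance scaling", {
  fx <- fixtures()
  ref <- fx$references[[1]]
  ## high-fluence limit: essentially noise free
  hi <- add_poisson_noise(ref, 1e8, seed = 3L)
  expect_lt(sqrt(mean((hi - ref)^2)) / mean(ref), 1e-3)
  ## unbiasedness at working fluence
  lo <- add_poisson_noise(ref, 1e3, seed = 4L)
  se <- sd(lo - ref) / sqrt(length(ref))
  expect_lt(abs(mean(lo - ref)), 3 * se)
  ## per-pixel variance ~ value/scale over 1e4 draws of one pixel
  img1 <- matrix(5, 1, 1)
  draws <- vapply(1:10000, function(i)
    add_poisson_noise(img1, 400, seed = i)[1, 1], numeric(1))
  ## scale = 400/5 = 80; var = lambda/scale^2 = 400/6400
  expect_equal(var(draws), 400 / 80^2, tolerance = 0.05)
  expect_error(add_poisson_noise(ref, 0), "positive")
})

test_that("dataset builder: counts, composition bookkeeping and determinism", {
  fx <- fixtures()
  man <- dataset_manifest(n_references = 2L,
                          deformations_per_reference = c(train = 3L, test = 2L),
                          seed = 7L)
  ds <- build_dataset(man, fx$references[1:2])
  expect_equal(unname(ds$counts), c(6L, 4L))
  expect_length(ds$items, 10L)
  ## regenerating an item from its logged seeds reproduces the field
  it <- ds$items[[3]]
  dspec <- deformation_spec(it$spec$kind, it$spec$patch_size,
                            it$spec$amplitude_range,
                            seed = it$spec$deform_seed)
  again <- generate_deformation(dspec, dim(fx$references[[1]]))
  expect_identical(again$ux, it$truth$ux)
  ## full rebuild is bit-identical
  ds2 <- build_dataset(man, fx$references[1:2])
  expect_identical(ds$items[[5]]$sample, ds2$items[[5]]$sample)
})

test_that("special deformation kinds appear at the configured fraction", {
  man <- dataset_manifest(n_references = 1L,
                          deformations_per_reference = c(train = 0L, test = 0L),
                          special_fraction = 0.02, seed = 1L)
  kinds <- vapply(1:4000, function(i)
    speckletrack:::item_spec(man, i, c(64L, 64L))$kind, character(1))
  frac <- mean(kinds != "random_patches")
  expect_gt(frac, 0.008)
  expect_lt(frac, 0.04)
  specials <- table(kinds[kinds != "random_patches"])
  expect_gte(length(specials), 3L)   # all four kinds drawn over 4000 items
})

test_that("warp/track consistency: an FFT cross-correlation oracle recovers constant shifts", {
  fx <- fixtures()
  ref <- fx$references[[2]]
  n <- nrow(ref)
  w <- speckletrack:::fft_freq_index(n)
  ## cross-correlation at 50x upsampling via matrix DFTs, restricted to
  ## the well-sampled band (|f| <= 0.7 Nyquist) where the interpolation
  ## model is alias-free
  keep <- outer(abs(w) <= 0.35 * n, abs(w) <= 0.35 * n)
  lags <- seq(-1, 1, by = 1 / 50)
  ey <- exp(2i * pi * outer(lags, w) / n)
  for (truth in list(c(0.35, -0.15), c(-0.6, 0.2))) {
    sam <- warp(ref, constant_field(dim(ref), truth[1], truth[2]),
                circular = TRUE)
    R <- fft(sam - mean(sam)) * Conj(fft(ref - mean(ref)))
    R[!keep] <- 0
    cc <- Mod(ey %*% R %*% t(ey))
    pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    expect_lt(abs(lags[pk[1]] - truth[2]), 0.02)
    expect_lt(abs(lags[pk[2]] - truth[1]), 0.02)
  }
})
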