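## CADE network: architecture contracts, EPE and multiscale loss, the
## backward pass, training mechanics and inference.

small_net <- function(seed = 3L) cade_network(cade_config(width_scale = 1 / 32),
                                              seed = seed)

test_that("network builds with the stated layer plan and full-resolution output", {
  net <- small_net()
  tab <- net$layers
  ## 10 feature-extraction convolutions: 7x7, 5x5, 5x5, seven 3x3
  feat <- tab[1:10, ]
  expect_equal(feat$k, c(7L, 5L, 5L, rep(3L, 7L)))
  expect_equal(sum(feat$stride == 2L), 4L)            # four downsamplings
  ## prediction head: five 3x3 convolutions + eight transposed convolutions
  head <- tab[11:nrow(tab), ]
  expect_equal(sum(head$type == "conv"), 5L)
  expect_true(all(head$k[head$type == "conv"] == 3L))
  expect_equal(sum(head$type == "tconv"), 8L)
  ## output matches input resolution with 2 channels
  x <- array(0, c(64, 64, 2))
  fl <- speckletrack:::cade_forward(net, x)$flows
  expect_equal(dim(fl[[5]]), c(64L, 64L, 2L))
  expect_equal(dim(fl[[1]]), c(4L, 4L, 2L))
  expect_true(all(vapply(fl, function(f) all(is.finite(f)), logical(1))))
  ## same config -> identical architecture and parameter count
  expect_equal(n_parameters(small_net(seed = 99L)), n_parameters(net))
})

test_that("epe: trivial values and brute-force loop oracle", {
  z <- matrix(0, 4, 4)
  expect_equal(epe(displacement_field(z, z), displacement_field(z, z))$value, 0)
  one <- displacement_field(matrix(0.3, 1, 1), matrix(0.4, 1, 1))
  expect_equal(epe(one, displacement_field(matrix(0, 1, 1),
                                           matrix(0, 1, 1)))$value, 0.5)
  set.seed(8)
  p <- displacement_field(matrix(rnorm(64), 8, 8), matrix(rnorm(64), 8, 8))
  t_ <- displacement_field(matrix(rnorm(64), 8, 8), matrix(rnorm(64), 8, 8))
  acc <- 0
  for (i in 1:8) for (j in 1:8) {
    acc <- acc + sqrt((p$ux[i, j] - t_$ux[i, j])^2 +
                      (p$uy[i, j] - t_$uy[i, j])^2)
  }
  expect_equal(epe(p, t_)$value, acc / 64, tolerance = 1e-12)
  expect_error(epe(p, displacement_field(matrix(0, 4, 4), matrix(0, 4, 4))),
               "differ")
})

test_that("multiscale loss: zero at exact predictions, reduces to epe, weighted sum", {
  set.seed(2)
  tr <- displacement_field(matrix(rnorm(256), 16, 16),
                           matrix(rnorm(256), 16, 16))
  preds <- list()
  tr_arr <- array(c(tr$ux, tr$uy), c(16, 16, 2))
  pyr <- list(tr_arr)
  for (i in 1:4) pyr <- c(list(speckletrack:::avgpool2(pyr[[1]])), pyr)
  expect_equal(multiscale_loss(pyr, tr), 0)
  ## single scale with weight 1 equals epe
  p1 <- array(rnorm(512), c(16, 16, 2))
  expect_equal(multiscale_loss(list(p1), tr, weights = 1),
               epe(displacement_field(p1[, , 1], p1[, , 2]), tr)$value,
               tolerance = 1e-12)
  ## two scales: w1 e1 + w2 e2
  p_c <- pyr[[4]] + 0.2
  p_f <- tr_arr + 0.5
  tr_half <- speckletrack:::avgpool2(tr_arr)
  e_c <- mean(sqrt((p_c[, , 1] - tr_half[, , 1])^2 +
                   (p_c[, , 2] - tr_half[, , 2])^2))
  e_f <- mean(sqrt((p_f[, , 1] - tr_arr[, , 1])^2 +
                   (p_f[, , 2] - tr_arr[, , 2])^2))
  expect_equal(multiscale_loss(list(p_c, p_f), tr, weights = c(0.3, 0.7)),
               0.3 * e_c + 0.7 * e_f, tolerance = 1e-12)
  expect_error(multiscale_loss(list(p_c), tr, weights = c(1, 2)), "weights")
})

test_that("analytic gradients match numerical differentiation", {
  net <- small_net()
  set.seed(4)
  it <- speckletrack:::prep_item(
    list(reference = matrix(rnorm(32 * 32), 32),
         sample = matrix(rnorm(32 * 32), 32),
         truth = constant_field(c(32L, 32L), 0.2, -0.1)),
    div_flow = 2)
  w <- c(0.005, 0.01, 0.02, 0.08, 0.32)
  fw <- speckletrack:::cade_forward(net, it$x, keep = TRUE)
  lg <- speckletrack:::loss_and_grads(fw$flows, it$pyr, w)
  G <- speckletrack:::cade_backward(net, it$x, fw$act, lg$dflows)
  lossfun <- function(n2) {
    fl <- speckletrack:::cade_forward(n2, it$x)$flows
    speckletrack:::loss_and_grads(fl, it$pyr, w)$loss
  }
  eps <- 1e-5
  for (nm in c("conv1", "conv5", "pf2", "deconv1", "upf3")) {
    i <- 3L
    np <- net; np$params[[nm]]$W[i] <- np$params[[nm]]$W[i] + eps
    nm2 <- net; nm2$params[[nm]]$W[i] <- nm2$params[[nm]]$W[i] - eps
    num <- (lossfun(np) - lossfun(nm2)) / (2 * eps)
    expect_equal(G[[nm]]$W[i], num, tolerance = 1e-4)
  }
})

test_that("training is seeded, loss trends down, divergence aborts cleanly", {
  fx <- fixtures()
  items <- fx$train_items[1:2]
  cfg <- cade_train_config(epochs = 3L, batch_size = 2L,
                           learning_rate = 1e-3, seed = 11L)
  n1 <- cade_train(small_net(7L), items, cfg)
  n2 <- cade_train(small_net(7L), items, cfg)
  expect_identical(n1$history$loss[1], n2$history$loss[1])
  expect_equal(nrow(n1$history), 3L)
  expect_true(all(is.finite(n1$history$loss)))
  ## a wildly excessive learning rate must abort, not return garbage
  ## (Adam steps are ~lr in magnitude, so this overflows within a few
  ## steps and the non-finite-loss guard must fire)
  bad <- cade_train_config(epochs = 50L, batch_size = 2L,
                           learning_rate = 1e154, seed = 1L)
  expect_error(cade_train(small_net(7L), items, bad), "diverged|non-finite")
})

test_that("prediction contracts: shape, padding, normalization invariance", {
  fx <- fixtures()
  net <- small_net()
  ref <- fx$known_shift$reference
  sam <- fx$known_shift$sample
  d <- predict(net, ref, sam)
  expect_equal(dim(d$ux), dim(ref))
  expect_true(all(is.finite(c(d$ux, d$uy))))
  ## non-multiple-of-16 input is padded internally and cropped back
  d2 <- predict(net, ref[1:50, 1:45], sam[1:50, 1:45])
  expect_equal(dim(d2$ux), c(50L, 45L))
  ## invariance to affine intensity changes of the inputs
  d3 <- predict(net, 2.5 * ref + 7, sam + 100)
  expect_equal(d3$ux, d$ux, tolerance = 1e-8)
  ## checkpoint round trip preserves predictions
  path <- tempfile(fileext = ".rds")
  save_checkpoint(net, path)
  d4 <- predict(load_checkpoint(path), ref, sam)
  expect_identical(d4$ux, d$ux)
})

test_that("a tiny network overfits a single constant-shift pair", {
  fx <- fixtures()
  item <- fx$train_items[[2]]          # shift (-0.5, 0.1)
  net <- cade_network(cade_config(width_scale = 1 / 32), seed = 13L)
  cfg <- cade_train_config(learning_rate = 1e-2, epochs = 60L,
                           batch_size = 1L, milestones = c(40L), seed = 13L)
  net <- cade_train(net, list(item), cfg)
  ## loss trend: exponential moving average decreases over the run
  h <- net$history$loss
  expect_lt(mean(tail(h, 10)), mean(head(h, 10)))
  d <- predict(net, item$reference, item$sample)
  expect_lt(abs(mean(d$ux) - (-0.5)), 0.1)
  expect_lt(abs(mean(d$uy) - 0.1), 0.1)
})
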