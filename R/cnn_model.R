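## CADE: a full-resolution optical-flow network for sub-pixel speckle
## displacement estimation, adapted from the StrainNet-f / FlowNetS family:
## a 10-layer convolutional feature extractor (7x7, 5x5, 5x5, then seven
## 3x3 layers; four stride-2 downsamplings) and a prediction head of five
## 3x3 flow-prediction convolutions and eight transposed convolutions
## (four feature upsamplings + four flow upsamplings), emitting
## displacement predictions at five scales (1/16 ... full resolution).

#' Network configuration
#'
#' @param width_scale Multiplier on the published channel widths
#'   (64/128/256/512); small values give a fast, low-capacity network for
#'   scaled-down training. 1 is the full-fidelity configuration.
#' @param div_flow Constant output/target scaling (the network internally
#'   regresses `u / div_flow`).
#' @param leaky_slope Negative slope of the leaky ReLU feature
#'   activations.
#' @return An object of class `cade_config`.
#' @export
cade_config <- function(width_scale = 1, div_flow = 2, leaky_slope = 0.1) {
  stopifnot(width_scale > 0, div_flow > 0)
  structure(list(width_scale = width_scale, div_flow = div_flow,
                 leaky_slope = leaky_slope,
                 feature_filters = c(7L, 5L, 5L, rep(3L, 7L)),
                 n_downsamplings = 4L, n_upsamplings = 4L),
            class = "cade_config")
}

## Scaled channel width
cw <- function(n, scale) max(2L, as.integer(round(n * scale)))

## Layer table: name, type (conv/tconv), kernel, stride, pad, in, out
cade_layer_table <- function(config) {
  s <- config$width_scale
  w1 <- cw(64, s); w2 <- cw(128, s); w3 <- cw(256, s); w4 <- cw(512, s)
  d3 <- cw(128, s); d2 <- cw(64, s); d1 <- cw(32, s); d0 <- cw(16, s)
  L <- function(name, type, k, st, p, ci, co)
    data.frame(name = name, type = type, k = k, stride = st, pad = p,
               c_in = ci, c_out = co, stringsAsFactors = FALSE)
  rbind(
    L("conv1",   "conv", 7L, 2L, 3L, 2L, w1),
    L("conv2",   "conv", 5L, 2L, 2L, w1, w2),
    L("conv3",   "conv", 5L, 2L, 2L, w2, w3),
    L("conv3_1", "conv", 3L, 1L, 1L, w3, w3),
    L("conv4",   "conv", 3L, 2L, 1L, w3, w4),
    L("conv4_1", "conv", 3L, 1L, 1L, w4, w4),
    L("conv5",   "conv", 3L, 1L, 1L, w4, w4),
    L("conv5_1", "conv", 3L, 1L, 1L, w4, w4),
    L("conv6",   "conv", 3L, 1L, 1L, w4, w4),
    L("conv6_1", "conv", 3L, 1L, 1L, w4, w4),
    L("pf4",     "conv", 3L, 1L, 1L, w4, 2L),
    L("deconv3", "tconv", 4L, 2L, 1L, w4, d3),
    L("upf4",    "tconv", 4L, 2L, 1L, 2L, 2L),
    L("pf3",     "conv", 3L, 1L, 1L, w3 + d3 + 2L, 2L),
    L("deconv2", "tconv", 4L, 2L, 1L, w3 + d3 + 2L, d2),
    L("upf3",    "tconv", 4L, 2L, 1L, 2L, 2L),
    L("pf2",     "conv", 3L, 1L, 1L, w2 + d2 + 2L, 2L),
    L("deconv1", "tconv", 4L, 2L, 1L, w2 + d2 + 2L, d1),
    L("upf2",    "tconv", 4L, 2L, 1L, 2L, 2L),
    L("pf1",     "conv", 3L, 1L, 1L, w1 + d1 + 2L, 2L),
    L("deconv0", "tconv", 4L, 2L, 1L, w1 + d1 + 2L, d0),
    L("upf1",    "tconv", 4L, 2L, 1L, 2L, 2L),
    L("pf0",     "conv", 3L, 1L, 1L, 2L + d0 + 2L, 2L))
}

#' Build the CADE network
#'
#' Initializes all convolution / transposed-convolution parameters
#' (He-style scaled normal, seeded). Two builds with the same
#' configuration have identical layer shapes and parameter count.
#'
#' @param config A [cade_config()].
#' @param seed Integer seed for the weight initialization.
#' @return An object of class `cade_model`.
#' @export
cade_network <- function(config = cade_config(), seed = 1L) {
  tab <- cade_layer_table(config)
  params <- with_seed(seed, {
    out <- list()
    for (i in seq_len(nrow(tab))) {
      k <- tab$k[i]; ci <- tab$c_in[i]; co <- tab$c_out[i]
      sd0 <- sqrt(2 / (k * k * ci))
      ## flow-prediction and flow-upsampling layers start near zero so the
      ## untrained network predicts (almost) zero displacement
      if (grepl("^(pf|upf)", tab$name[i])) sd0 <- sd0 * 0.01
      out[[tab$name[i]]] <- list(
        W = matrix(stats::rnorm(k * k * ci * co, sd = sd0), k * k * ci, co),
        b = numeric(co))
    }
    out
  })
  structure(list(config = config, layers = tab, params = params,
                 normalization = "per-image standardization",
                 seed = seed, trained_epochs = 0L),
            class = "cade_model")
}

#' Number of trainable parameters
#' @param model A `cade_model`.
#' @return Integer count.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$params, function(p) length(p$W) + length(p$b), numeric(1)))
}

#' @export
print.cade_model <- function(x, ...) {
  cat(sprintf("<cade_model: width scale %.3g, %d layers, %d parameters, %d epochs trained>\n",
              x$config$width_scale, nrow(x$layers), n_parameters(x),
              x$trained_epochs))
  invisible(x)
}

## Full forward pass on one standardized input (H, W, 2) array, H and W
## multiples of 16. Returns the five flow predictions (coarsest first, in
## network units, i.e. u / div_flow) and, if keep = TRUE, the caches for
## the backward pass.
cade_forward <- function(model, x, keep = FALSE) {
  P <- model$params
  sl <- model$config$leaky_slope
  cv <- function(nm, inp) {
    r <- model$layers[model$layers$name == nm, ]
    conv_fwd(inp, P[[nm]]$W, P[[nm]]$b, r$k, r$stride, r$pad)
  }
  tcv <- function(nm, inp) tconv_fwd(inp, P[[nm]]$W, P[[nm]]$b)
  act <- list()
  a <- function(nm, val) { if (keep) act[[nm]] <<- val; val }
  c1 <- cv("conv1", x);        r1 <- lrelu_fwd(c1$y, sl); a("c1", c1); a("r1", r1)
  c2 <- cv("conv2", r1$y);     r2 <- lrelu_fwd(c2$y, sl); a("c2", c2); a("r2", r2)
  c3 <- cv("conv3", r2$y);     r3 <- lrelu_fwd(c3$y, sl); a("c3", c3); a("r3", r3)
  c31 <- cv("conv3_1", r3$y);  r31 <- lrelu_fwd(c31$y, sl); a("c31", c31); a("r31", r31)
  c4 <- cv("conv4", r31$y);    r4 <- lrelu_fwd(c4$y, sl); a("c4", c4); a("r4", r4)
  c41 <- cv("conv4_1", r4$y);  r41 <- lrelu_fwd(c41$y, sl); a("c41", c41); a("r41", r41)
  c5 <- cv("conv5", r41$y);    r5 <- lrelu_fwd(c5$y, sl); a("c5", c5); a("r5", r5)
  c51 <- cv("conv5_1", r5$y);  r51 <- lrelu_fwd(c51$y, sl); a("c51", c51); a("r51", r51)
  c6 <- cv("conv6", r51$y);    r6 <- lrelu_fwd(c6$y, sl); a("c6", c6); a("r6", r6)
  c61 <- cv("conv6_1", r6$y);  r61 <- lrelu_fwd(c61$y, sl); a("c61", c61); a("r61", r61)
  f4 <- cv("pf4", r61$y); a("f4", f4)
  dd3 <- tcv("deconv3", r61$y); rd3 <- lrelu_fwd(dd3$y, sl); a("dd3", dd3); a("rd3", rd3)
  u4 <- tcv("upf4", f4$y); a("u4", u4)
  cat3v <- concat3(r31$y, rd3$y, u4$y); a("cat3", cat3v)
  f3 <- cv("pf3", cat3v); a("f3", f3)
  dd2 <- tcv("deconv2", cat3v); rd2 <- lrelu_fwd(dd2$y, sl); a("dd2", dd2); a("rd2", rd2)
  u3 <- tcv("upf3", f3$y); a("u3", u3)
  cat2v <- concat3(r2$y, rd2$y, u3$y); a("cat2", cat2v)
  f2 <- cv("pf2", cat2v); a("f2", f2)
  dd1 <- tcv("deconv1", cat2v); rd1 <- lrelu_fwd(dd1$y, sl); a("dd1", dd1); a("rd1", rd1)
  u2 <- tcv("upf2", f2$y); a("u2", u2)
  cat1v <- concat3(r1$y, rd1$y, u2$y); a("cat1", cat1v)
  f1 <- cv("pf1", cat1v); a("f1", f1)
  dd0 <- tcv("deconv0", cat1v); rd0 <- lrelu_fwd(dd0$y, sl); a("dd0", dd0); a("rd0", rd0)
  u1 <- tcv("upf1", f1$y); a("u1", u1)
  cat0v <- concat3(x, rd0$y, u1$y); a("cat0", cat0v)
  f0 <- cv("pf0", cat0v); a("f0", f0)
  list(flows = list(f4$y, f3$y, f2$y, f1$y, f0$y),
       act = if (keep) act else NULL)
}

## Backward pass: dflows are the gradients wrt the five flow predictions
## (same order, coarsest first). Returns the parameter gradient list.
cade_backward <- function(model, x, act, dflows) {
  P <- model$params
  tabr <- model$layers
  grads <- lapply(P, function(p) list(W = p$W * 0, b = p$b * 0))
  addg <- function(nm, g) {
    grads[[nm]]$W <<- grads[[nm]]$W + g$dW
    grads[[nm]]$b <<- grads[[nm]]$b + g$db
    g$dx
  }
  bcv <- function(nm, dy, cache) addg(nm, conv_bwd(dy, cache, P[[nm]]$W))
  btcv <- function(nm, dy, cache) addg(nm, tconv_bwd(dy, cache, P[[nm]]$W))
  sizes <- function(...) vapply(list(...), function(a) dim(a)[3], integer(1))
  ## scale 0 (full resolution)
  dcat0 <- bcv("pf0", dflows[[5]], act$f0)
  s0 <- split3(dcat0, sizes(x, act$rd0$y, act$u1$y))
  dd0x <- btcv("deconv0", lrelu_bwd(s0[[2]], act$rd0), act$dd0)
  df1_extra <- btcv("upf1", s0[[3]], act$u1)
  dcat1 <- bcv("pf1", dflows[[4]] + df1_extra, act$f1) + 0
  dcat1 <- dcat1 + dd0x
  s1 <- split3(dcat1, sizes(act$r1$y, act$rd1$y, act$u2$y))
  dd1x <- btcv("deconv1", lrelu_bwd(s1[[2]], act$rd1), act$dd1)
  df2_extra <- btcv("upf2", s1[[3]], act$u2)
  dcat2 <- bcv("pf2", dflows[[3]] + df2_extra, act$f2) + dd1x
  s2 <- split3(dcat2, sizes(act$r2$y, act$rd2$y, act$u3$y))
  dd2x <- btcv("deconv2", lrelu_bwd(s2[[2]], act$rd2), act$dd2)
  df3_extra <- btcv("upf3", s2[[3]], act$u3)
  dcat3 <- bcv("pf3", dflows[[2]] + df3_extra, act$f3) + dd2x
  s3 <- split3(dcat3, sizes(act$r31$y, act$rd3$y, act$u4$y))
  dd3x <- btcv("deconv3", lrelu_bwd(s3[[2]], act$rd3), act$dd3)
  df4_extra <- btcv("upf4", s3[[3]], act$u4)
  dr61 <- bcv("pf4", dflows[[1]] + df4_extra, act$f4) + dd3x
  ## encoder tail
  dr6 <- bcv("conv6_1", lrelu_bwd(dr61, act$r61), act$c61)
  dr51 <- bcv("conv6", lrelu_bwd(dr6, act$r6), act$c6)
  dr5 <- bcv("conv5_1", lrelu_bwd(dr51, act$r51), act$c51)
  dr41 <- bcv("conv5", lrelu_bwd(dr5, act$r5), act$c5)
  dr4 <- bcv("conv4_1", lrelu_bwd(dr41, act$r41), act$c41)
  dr31 <- bcv("conv4", lrelu_bwd(dr4, act$r4), act$c4) + s3[[1]]
  dr3 <- bcv("conv3_1", lrelu_bwd(dr31, act$r31), act$c31)
  dr2 <- bcv("conv3", lrelu_bwd(dr3, act$r3), act$c3) + s2[[1]]
  dr1 <- bcv("conv2", lrelu_bwd(dr2, act$r2), act$c2) + s1[[1]]
  bcv("conv1", lrelu_bwd(dr1, act$r1), act$c1)
  grads
}
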