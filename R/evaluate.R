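## Evaluation protocol: accuracy vs constant shifts, star-pattern spatial
## resolution, noise and window-size sweeps, timing.

#' Relative displacement bias
#'
#' `Bias = (u_GT - mean(u)) / u_GT`: the relative bias of the mean
#' prediction against the (constant) ground truth over the evaluated
#' region. Undefined where the ground truth is zero.
#'
#' @param prediction,truth [displacement_field()]s.
#' @param mask Optional logical matrix restricting the region.
#' @param component `"ux"` or `"uy"`.
#' @return Scalar relative bias.
#' @export
displacement_bias <- function(prediction, truth, mask = NULL,
                              component = "ux") {
  p <- prediction[[component]]
  t <- truth[[component]]
  stopifnot(all(dim(p) == dim(t)))
  if (is.null(mask)) mask <- matrix(TRUE, nrow(p), ncol(p))
  tbar <- mean(t[mask])
  if (abs(tbar) < .Machine$double.eps * 10) {
    stop("bias undefined: ground truth is zero over the region; ",
         "use the mean error instead")
  }
  (tbar - mean(p[mask])) / tbar
}

#' Root-mean-square displacement error
#'
#' `RMSE = sqrt(sum((u - u_GT)^2) / N)` per component, plus the pooled
#' value over both components.
#'
#' @param prediction,truth [displacement_field()]s.
#' @param mask Optional logical matrix restricting the region.
#' @return Named vector `c(ux, uy, combined)` in pixels.
#' @export
rmse <- function(prediction, truth, mask = NULL) {
  stopifnot(all(dim(prediction$ux) == dim(truth$ux)))
  if (is.null(mask)) mask <- matrix(TRUE, nrow(truth$ux), ncol(truth$ux))
  ex <- (prediction$ux - truth$ux)[mask]
  ey <- (prediction$uy - truth$uy)[mask]
  c(ux = sqrt(mean(ex^2)), uy = sqrt(mean(ey^2)),
    combined = sqrt(mean(c(ex^2, ey^2))))
}

#' Tracker adapters for the evaluation protocol
#'
#' Every sweep takes a named list of tracker functions with signature
#' `function(reference, sample, truth)` returning a list with at least
#' `displacement` and `valid_mask`. `classical_tracker()` wraps
#' [speckle_track()]; `oracle_tracker()` passes the ground truth through
#' (a plumbing check: every metric must be exactly zero); `cnn_tracker()`
#' wraps a trained [cade_model].
#'
#' @param method,config As in [speckle_track()].
#' @return A tracker function.
#' @export
classical_tracker <- function(method = "zncc", config = tracker_config()) {
  force(method); force(config)
  function(reference, sample, truth = NULL) {
    speckle_track(reference, sample, method, config)
  }
}

#' @rdname classical_tracker
#' @export
oracle_tracker <- function() {
  function(reference, sample, truth = NULL) {
    if (is.null(truth)) stop("oracle tracker needs the ground truth")
    m <- as_image_matrix(reference)
    list(displacement = truth,
         valid_mask = matrix(TRUE, nrow(m), ncol(m)),
         method = "oracle", elapsed = 0)
  }
}

#' @rdname classical_tracker
#' @param model A trained [cade_model].
#' @export
cnn_tracker <- function(model) {
  force(model)
  function(reference, sample, truth = NULL) {
    t0 <- proc.time()[[3]]
    disp <- predict(model, reference, sample)
    m <- as_image_matrix(reference)
    list(displacement = disp,
         valid_mask = matrix(TRUE, nrow(m), ncol(m)),
         method = "cade", elapsed = proc.time()[[3]] - t0)
  }
}

## Prepare one noisy evaluation pair: warp by the truth field, attenuate the
## sample uniformly, Poisson both images independently.
eval_pair <- function(ref, field, transmission, fluence, seed) {
  refm <- as_image_matrix(ref)
  sam <- warp(refm, field)
  if (!is.null(transmission)) sam <- sam * transmission
  if (!is.null(fluence)) {
    refm <- add_poisson_noise(refm, fluence, seed = derive_seed(seed, 1L))
    sam <- add_poisson_noise(sam, fluence, seed = derive_seed(seed, 2L))
  }
  list(reference = refm, sample = sam)
}

#' Accuracy sweep over constant displacements
#'
#' For every reference image and constant shift (in x), warps the clean
#' reference, applies the stated transmission and Poisson noise to the
#' pair, runs each tracker, and records RMSE per component and the relative
#' bias (undefined and omitted at zero shift).
#'
#' @param trackers Named list of tracker functions
#'   (see [classical_tracker()]).
#' @param references List of reference images.
#' @param shifts Constant displacements in pixels.
#' @param transmission Uniform sample transmission (`NULL` = none).
#' @param fluence Mean photons/pixel for the noise (`NULL` = clean).
#' @param seed Integer seed.
#' @return A data.frame of class `metric_table` with one row per
#'   (algorithm, shift, reference); `summary()` aggregates per shift and
#'   reports grand means.
#' @export
accuracy_sweep <- function(trackers, references,
                           shifts = seq(0, 1, by = 0.1),
                           transmission = 0.9,
                           fluence = default_fluence(), seed = 1L) {
  stopifnot(length(trackers) >= 1, length(references) >= 1)
  rows <- list()
  ctr <- 0L
  for (r in seq_along(references)) {
    shape <- dim(as_image_matrix(references[[r]]))
    for (s in shifts) {
      ctr <- ctr + 1L
      field <- constant_field(shape, ux = s, uy = 0)
      pair <- eval_pair(references[[r]], field, transmission, fluence,
                        derive_seed(seed, ctr))
      for (nm in names(trackers)) {
        res <- trackers[[nm]](pair$reference, pair$sample, field)
        v <- res$valid_mask
        er <- rmse(res$displacement, field, mask = v)
        b <- if (s != 0) displacement_bias(res$displacement, field, mask = v)
             else NA_real_
        rows[[length(rows) + 1L]] <-
          data.frame(algorithm = nm, shift = s, reference = r,
                     rmse_x = er[["ux"]], rmse_y = er[["uy"]],
                     rmse = er[["combined"]], bias = b, n = sum(v),
                     elapsed = if (!is.null(res$elapsed)) res$elapsed else NA)
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("metric_table", class(out))
  attr(out, "condition") <- list(transmission = transmission,
                                 fluence = fluence, seed = seed)
  out
}

#' @export
summary.metric_table <- function(object, ...) {
  df <- as.data.frame(object)
  per_shift <- stats::aggregate(cbind(rmse_x, bias) ~ algorithm + shift,
                                data = df, FUN = mean, na.action = stats::na.pass,
                                na.rm = TRUE)
  grand <- do.call(rbind, lapply(split(df, df$algorithm), function(d) {
    data.frame(algorithm = d$algorithm[1],
               mean_rmse = mean(d$rmse_x),
               mean_bias = mean(d$bias, na.rm = TRUE),
               n_pairs = nrow(d))
  }))
  rownames(grand) <- NULL
  out <- list(per_shift = per_shift, grand = grand)
  class(out) <- "summary.metric_table"
  out
}

#' @export
print.summary.metric_table <- function(x, ...) {
  cat("Grand means over the sweep:\n")
  print(x$grand, row.names = FALSE)
  invisible(x)
}

#' Star displacement pattern for spatial-resolution measurement
#'
#' A unidirectional sinusoidal displacement `u_x = A sin(phi(x))`, `u_y = 0`
#' whose local spatial wavelength decreases linearly toward the left edge
#' (frequency increases leftward); the amplitude is constant (0.5 px by
#' default) along every row, in particular the horizontal symmetry axis.
#'
#' @param shape Image shape `c(rows, cols)`.
#' @param amplitude Displacement amplitude in pixels.
#' @param wavelength_range `c(min, max)` wavelengths in pixels: `min` at
#'   the left edge, `max` at the right edge. Must be >= 2 px (Nyquist).
#' @return An object of class `star_pattern`: list with `field`
#'   ([displacement_field()]), `wavelength` (per-column local wavelength),
#'   `amplitude`.
#' @export
make_star_pattern <- function(shape, amplitude = 0.5,
                              wavelength_range = c(4, 200)) {
  stopifnot(length(wavelength_range) == 2L,
            wavelength_range[1] < wavelength_range[2])
  if (wavelength_range[1] < 2) {
    stop("minimum wavelength below 2 px is unresolvable (Nyquist)")
  }
  n <- shape[1]; p <- shape[2]
  wl <- wavelength_range[1] +
    (wavelength_range[2] - wavelength_range[1]) * (seq_len(p) - 1) / (p - 1)
  phase <- cumsum(2 * pi / wl)
  ux <- matrix(amplitude * sin(phase), n, p, byrow = TRUE)
  structure(list(field = displacement_field(ux, matrix(0, n, p)),
                 wavelength = wl, amplitude = amplitude),
            class = "star_pattern")
}

#' Limiting spatial resolution from a star-pattern tracking result
#'
#' Per column, the recovered sinusoid amplitude is estimated by regressing
#' the recovered `u_x` on the true `u_x` over a window of one local period
#' (all valid rows); the bias is `1 - slope`. The per-column bias profile
#' is moving-averaged along the wavelength axis and the limiting
#' resolution is the largest wavelength at which the averaged bias first
#' reaches the threshold, scanning from long to short wavelengths.
#'
#' @param predictions A [displacement_field()] or list of them (profiles
#'   are averaged); each may carry a `valid_mask` attribute, or pass
#'   `masks`.
#' @param star The [make_star_pattern()] used to deform the images.
#' @param masks Optional logical matrix or list of matrices.
#' @param moving_avg_window Columns; default one tenth of the evaluated
#'   span.
#' @param threshold Bias threshold (default 10%).
#' @return An object of class `resolution_result`: list with
#'   `limiting_wavelength` (px), `crossed` (FALSE if the bias never
#'   reaches the threshold; the minimum evaluated wavelength is then
#'   returned as a sentinel), and `profile` (data.frame with column,
#'   wavelength, bias, bias_ma).
#' @export
spatial_resolution <- function(predictions, star, masks = NULL,
                               moving_avg_window = NULL, threshold = 0.10) {
  stopifnot(inherits(star, "star_pattern"))
  if (inherits(predictions, "displacement_field")) {
    predictions <- list(predictions)
  }
  if (!is.null(masks) && is.matrix(masks)) masks <- list(masks)
  tru <- star$field$ux
  p <- ncol(tru)
  ratios <- matrix(NA_real_, length(predictions), p)
  for (i in seq_along(predictions)) {
    pred <- predictions[[i]]$ux
    msk <- if (!is.null(masks)) masks[[i]] else matrix(TRUE, nrow(tru), p)
    for (x in seq_len(p)) {
      hw <- max(2L, ceiling(star$wavelength[x] / 2))
      cols <- max(1L, x - hw):min(p, x + hw)
      sel <- msk[, cols, drop = FALSE]
      tt <- tru[, cols, drop = FALSE][sel]
      pp <- pred[, cols, drop = FALSE][sel]
      den <- sum(tt * tt)
      if (is.finite(den) && den > 0 && length(tt) > 4) {
        ratios[i, x] <- sum(pp * tt) / den
      }
    }
  }
  bias_col <- 1 - colMeans(ratios, na.rm = TRUE)
  ok <- which(is.finite(bias_col))
  if (length(ok) < 8L) stop("too few evaluable columns for a bias profile")
  if (is.null(moving_avg_window)) {
    moving_avg_window <- max(3L, round(length(ok) / 10))
  }
  ma <- rep(NA_real_, p)
  ma[ok] <- stats::filter(bias_col[ok], rep(1 / moving_avg_window,
                                            moving_avg_window), sides = 2)
  ## scan from the longest wavelength (right edge) toward the shortest
  ordcols <- ok[order(star$wavelength[ok], decreasing = TRUE)]
  cross <- NA_integer_
  for (x in ordcols) {
    if (is.finite(ma[x]) && ma[x] >= threshold) { cross <- x; break }
  }
  crossed <- !is.na(cross)
  lw <- if (crossed) star$wavelength[cross] else min(star$wavelength[ok])
  structure(list(limiting_wavelength = lw, crossed = crossed,
                 threshold = threshold,
                 profile = data.frame(column = seq_len(p),
                                      wavelength = star$wavelength,
                                      bias = bias_col, bias_ma = ma)),
            class = "resolution_result")
}

#' @export
print.resolution_result <- function(x, ...) {
  cat(sprintf("<resolution_result: limiting wavelength %.1f px at %.0f%% bias%s>\n",
              x$limiting_wavelength, 100 * x$threshold,
              if (x$crossed) "" else " (never crossed; sentinel)"))
  invisible(x)
}

#' Star-pattern resolution protocol for a set of trackers
#'
#' Warps each reference by the star field, applies transmission and noise,
#' tracks, and measures the limiting wavelength per tracker.
#'
#' @inheritParams accuracy_sweep
#' @param star A [make_star_pattern()]; default matches the reference
#'   shape with wavelengths 4-200 px.
#' @return Named list of [spatial_resolution()] results.
#' @export
resolution_protocol <- function(trackers, references, star = NULL,
                                transmission = 0.9,
                                fluence = default_fluence(), seed = 1L) {
  shape <- dim(as_image_matrix(references[[1]]))
  if (is.null(star)) star <- make_star_pattern(shape)
  preds <- stats::setNames(vector("list", length(trackers)), names(trackers))
  masks <- preds
  for (r in seq_along(references)) {
    pair <- eval_pair(references[[r]], star$field, transmission, fluence,
                      derive_seed(seed, 100L + r))
    for (nm in names(trackers)) {
      res <- trackers[[nm]](pair$reference, pair$sample, star$field)
      preds[[nm]] <- c(preds[[nm]], list(res$displacement))
      masks[[nm]] <- c(masks[[nm]], list(res$valid_mask))
    }
  }
  lapply(stats::setNames(names(trackers), names(trackers)), function(nm) {
    spatial_resolution(preds[[nm]], star, masks = masks[[nm]])
  })
}

#' Noise sweep on a linear gradient deformation
#'
#' Deforms each reference by a horizontal gradient map (u_x rising
#' linearly 0 to +1 px across the image), then evaluates tracker RMSE at
#' noise levels expressed as a percentage SNR loss: a loss of x% maps to
#' fluence `fluence0 * (1 - x/100)^2` (Poisson SNR scales with the square
#' root of the fluence).
#'
#' @inheritParams accuracy_sweep
#' @param snr_loss_percent Vector of SNR-loss levels (0-6% in the
#'   protocol).
#' @param fluence0 Baseline fluence at zero loss.
#' @return A `metric_table` data.frame (one row per algorithm, level,
#'   reference).
#' @export
noise_sweep <- function(trackers, references,
                        snr_loss_percent = 0:6,
                        transmission = 0.9,
                        fluence0 = default_fluence(), seed = 1L) {
  rows <- list()
  ctr <- 0L
  for (r in seq_along(references)) {
    shape <- dim(as_image_matrix(references[[r]]))
    grad <- matrix(seq(0, 1, length.out = shape[2]), shape[1], shape[2],
                   byrow = TRUE)
    field <- displacement_field(grad, matrix(0, shape[1], shape[2]))
    for (lv in snr_loss_percent) {
      ctr <- ctr + 1L
      fl <- if (is.null(fluence0)) NULL else fluence0 * (1 - lv / 100)^2
      pair <- eval_pair(references[[r]], field, transmission, fl,
                        derive_seed(seed, 200L + ctr))
      for (nm in names(trackers)) {
        res <- trackers[[nm]](pair$reference, pair$sample, field)
        er <- rmse(res$displacement, field, mask = res$valid_mask)
        rows[[length(rows) + 1L]] <-
          data.frame(algorithm = nm, snr_loss = lv, reference = r,
                     fluence = if (is.null(fl)) NA_real_ else fl,
                     rmse_x = er[["ux"]],
                     rmse = er[["combined"]], n = sum(res$valid_mask))
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("metric_table", class(out))
  out
}

#' Window-size sweep for the classical trackers
#'
#' Evaluates gradient-map RMSE and star-pattern limiting resolution for
#' ZNCC and UMPA at a range of correlation window sizes; an optional CNN
#' tracker is evaluated once as the window-independent baseline and
#' repeated across the window column.
#'
#' @param references List of reference images.
#' @param windows Full window sides in pixels (10-50 in the protocol);
#'   mapped to half windows `M = round((w - 1) / 2)`.
#' @param cnn Optional tracker function evaluated once.
#' @param star Optional [make_star_pattern()].
#' @inheritParams accuracy_sweep
#' @return List with `accuracy` and `resolution` data.frames.
#' @export
window_sweep <- function(references, windows = seq(10, 50, by = 10),
                         cnn = NULL, star = NULL, transmission = 0.9,
                         fluence = default_fluence(), seed = 1L) {
  acc <- list(); res <- list()
  for (w in windows) {
    M <- max(1L, as.integer(round((w - 1) / 2)))
    cfg <- tracker_config(half_window = M)
    tr <- list(zncc = classical_tracker("zncc", cfg),
               umpa = classical_tracker("umpa", cfg))
    ns <- noise_sweep(tr, references, snr_loss_percent = 0,
                      transmission = transmission, fluence0 = fluence,
                      seed = derive_seed(seed, w))
    ns$window <- w
    acc[[length(acc) + 1L]] <- ns
    rp <- resolution_protocol(tr, references, star = star,
                              transmission = transmission,
                              fluence = fluence,
                              seed = derive_seed(seed, 1000L + w))
    res[[length(res) + 1L]] <-
      data.frame(algorithm = names(rp), window = w,
                 limiting_wavelength = vapply(rp, function(x)
                   x$limiting_wavelength, numeric(1)),
                 crossed = vapply(rp, function(x) x$crossed, logical(1)))
  }
  if (!is.null(cnn)) {
    ns <- noise_sweep(list(cade = cnn), references, snr_loss_percent = 0,
                      transmission = transmission, fluence0 = fluence,
                      seed = derive_seed(seed, 7L))
    rp <- resolution_protocol(list(cade = cnn), references, star = star,
                              transmission = transmission, fluence = fluence,
                              seed = derive_seed(seed, 8L))
    for (w in windows) {
      ns$window <- w
      acc[[length(acc) + 1L]] <- ns
      res[[length(res) + 1L]] <-
        data.frame(algorithm = "cade", window = w,
                   limiting_wavelength = rp$cade$limiting_wavelength,
                   crossed = rp$cade$crossed)
    }
  }
  list(accuracy = do.call(rbind, acc),
       resolution = do.call(rbind, lapply(res, function(d) {
         rownames(d) <- NULL; d
       })))
}

#' Tracker timing benchmark
#'
#' Measures wall-clock tracking time on synthetic speckle-like image pairs
#' (filtered white noise with a small constant shift) of the given sizes,
#' and fits time against pixel count. Absolute numbers are
#' environment-relative and logged, not asserted.
#'
#' @param trackers Named list of tracker functions.
#' @param sizes Image sides in pixels.
#' @param n_pairs Pairs per size.
#' @param seed Integer seed.
#' @return List with `table` (per-run timings) and `fit` (per-algorithm
#'   linear-model slope in s/Mpixel and R^2).
#' @export
timing_benchmark <- function(trackers, sizes = c(256L, 512L, 768L),
                             n_pairs = 10L, seed = 1L) {
  rows <- list()
  for (sz in sizes) {
    for (i in seq_len(n_pairs)) {
      ref <- with_seed(derive_seed(seed, sz + i), {
        gauss_blur(matrix(stats::rnorm(sz * sz), sz, sz), 1.5) + 10
      })
      field <- constant_field(c(sz, sz), 0.3, -0.2)
      sam <- warp(ref, field)
      for (nm in names(trackers)) {
        t0 <- proc.time()[[3]]
        res <- trackers[[nm]](ref, sam, field)
        dt <- proc.time()[[3]] - t0
        rows[[length(rows) + 1L]] <-
          data.frame(algorithm = nm, size = sz, pair = i, seconds = dt)
      }
    }
  }
  tab <- do.call(rbind, rows)
  fit <- do.call(rbind, lapply(split(tab, tab$algorithm), function(d) {
    m <- stats::lm(seconds ~ I(size^2 / 1e6), data = d)
    data.frame(algorithm = d$algorithm[1],
               s_per_mpixel = stats::coef(m)[[2]],
               r_squared = summary(m)$r.squared)
  }))
  rownames(fit) <- NULL
  list(table = tab, fit = fit,
       hardware = paste(Sys.info()[["sysname"]], Sys.info()[["machine"]]))
}
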