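## Minimal CNN engine: 2D convolution, transposed convolution, leaky ReLU
## and average pooling with hand-written backward passes. Convolutions use
## im2col gathers plus BLAS matrix multiplication; the gather/scatter index
## maps are cached per input geometry. Tensors are (H, W, C) arrays
## (column-major), weights are (k*k*Cin) x Cout matrices.

.im2col_cache <- new.env(parent = emptyenv())

## Gather index for an input of dims (H, W, C) padded by p, kernel k,
## stride s: a (Ho*Wo) x (k*k*C) integer matrix of linear indices into the
## padded array, plus output dims.
im2col_index <- function(H, W, C, k, s, p) {
  key <- paste(H, W, C, k, s, p, sep = "_")
  hit <- .im2col_cache[[key]]
  if (!is.null(hit)) return(hit)
  Hp <- H + 2L * p; Wp <- W + 2L * p
  Ho <- (Hp - k) %/% s + 1L
  Wo <- (Wp - k) %/% s + 1L
  i_out <- rep(seq_len(Ho), times = Wo)             # row of output px
  j_out <- rep(seq_len(Wo), each = Ho)
  base <- (i_out - 1L) * s + (j_out - 1L) * s * Hp  # top-left of window
  ki <- rep(seq_len(k), times = k)
  kj <- rep(seq_len(k), each = k)
  koff <- (ki - 1L) + (kj - 1L) * Hp
  koff <- as.vector(outer(koff, (seq_len(C) - 1L) * (Hp * Wp), "+"))
  idx <- outer(base, koff, "+") + 1L
  out <- list(idx = idx, Ho = Ho, Wo = Wo, Hp = Hp, Wp = Wp)
  .im2col_cache[[key]] <- out
  out
}

pad_zero3 <- function(x, p) {
  if (p == 0L) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1] + 2L * p, d[2] + 2L * p, d[3]))
  xp[p + seq_len(d[1]), p + seq_len(d[2]), ] <- x
  xp
}

## Forward convolution. Returns y (Ho, Wo, Cout) and the cache needed for
## the backward pass.
conv_fwd <- function(x, Wm, b, k, s, p) {
  d <- dim(x)
  ix <- im2col_index(d[1], d[2], d[3], k, s, p)
  xp <- pad_zero3(x, p)
  col <- matrix(xp[ix$idx], nrow(ix$idx), ncol(ix$idx))
  y <- col %*% Wm
  y <- sweep(y, 2L, b, "+")
  list(y = array(y, c(ix$Ho, ix$Wo, ncol(Wm))),
       col = col, in_dims = d, k = k, s = s, p = p)
}

## Backward convolution: gradients wrt input, weights and bias.
conv_bwd <- function(dy, cache, Wm) {
  d <- cache$in_dims
  ix <- im2col_index(d[1], d[2], d[3], cache$k, cache$s, cache$p)
  dY <- matrix(dy, nrow(ix$idx), ncol(Wm))
  dW <- crossprod(cache$col, dY)
  db <- colSums(dY)
  dcol <- dY %*% t(Wm)
  acc <- numeric(ix$Hp * ix$Wp * d[3])
  rs <- rowsum(as.vector(dcol), group = as.vector(ix$idx))
  acc[as.integer(rownames(rs))] <- rs
  dxp <- array(acc, c(ix$Hp, ix$Wp, d[3]))
  p <- cache$p
  dx <- if (p > 0L) dxp[p + seq_len(d[1]), p + seq_len(d[2]), , drop = FALSE]
        else dxp
  list(dx = dx, dW = dW, db = db)
}

## Transposed convolution with kernel 4, stride 2, pad 1 (output = 2 x
## input): implemented as zero-stuffing to (2H-1, 2W-1) followed by a
## stride-1 convolution with pad 2.
tconv_fwd <- function(x, Wm, b) {
  d <- dim(x)
  z <- array(0, c(2L * d[1] - 1L, 2L * d[2] - 1L, d[3]))
  z[seq(1L, 2L * d[1] - 1L, by = 2L), seq(1L, 2L * d[2] - 1L, by = 2L), ] <- x
  out <- conv_fwd(z, Wm, b, k = 4L, s = 1L, p = 2L)
  out$orig_dims <- d
  out
}

tconv_bwd <- function(dy, cache, Wm) {
  g <- conv_bwd(dy, cache, Wm)
  d <- cache$orig_dims
  dx <- g$dx[seq(1L, 2L * d[1] - 1L, by = 2L),
             seq(1L, 2L * d[2] - 1L, by = 2L), , drop = FALSE]
  list(dx = array(dx, d), dW = g$dW, db = g$db)
}

lrelu_fwd <- function(x, slope = 0.1) {
  neg <- !is.na(x) & x < 0       # NaNs pass through to the loss guard
  x[neg] <- x[neg] * slope
  list(y = x, neg = neg, slope = slope)
}

lrelu_bwd <- function(dy, cache) {
  dy[cache$neg] <- dy[cache$neg] * cache$slope
  dy
}

## 2x average pooling of an (H, W, C) array (used to downsample truth).
avgpool2 <- function(x) {
  d <- dim(x)
  out <- array(0, c(d[1] %/% 2L, d[2] %/% 2L, d[3]))
  for (c_ in seq_len(d[3])) out[, , c_] <- bin_mean(x[, , c_], 2L)
  out
}

concat3 <- function(...) {
  xs <- list(...)
  d <- dim(xs[[1]])
  array(do.call(c, xs), c(d[1], d[2], sum(vapply(xs, function(x) dim(x)[3],
                                                 integer(1)))))
}

split3 <- function(dx, sizes) {
  d <- dim(dx)
  out <- vector("list", length(sizes))
  off <- 0L
  for (i in seq_along(sizes)) {
    out[[i]] <- dx[, , off + seq_len(sizes[i]), drop = FALSE]
    off <- off + sizes[i]
  }
  out
}
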