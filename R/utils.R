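#' @keywords internal
"_PACKAGE"

## Shared numeric helpers: seeded evaluation, FFT-friendly sizes, padding,
## windowed box sums and Gaussian blurring. All image matrices are row-major
## in the sense of the package convention: x = column index increasing
## rightward, y = row index increasing downward, 0-based pixel centers.

#' Evaluate an expression with a local, restored RNG state
#'
#' All stochastic operations in the package funnel their `seed` argument
#' through this helper so that callers' RNG streams are never disturbed and
#' identical seeds give bit-identical results.
#'
#' @param seed Integer seed, or `NULL` to use the current RNG stream.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Derive a stage-specific sub-seed from a global seed
#'
#' Documented derivation: `(seed * 48271 + index) mod (2^31 - 1)`, a
#' Lehmer-style mixing step keeping results in 32-bit integer range.
#'
#' @param seed Integer global seed.
#' @param index Integer stage index (each random consumer uses its own).
#' @return Integer sub-seed.
#' @export
derive_seed <- function(seed, index) {
  m <- 2147483647
  ## double-precision arithmetic is exact here: 48271 * 2^31 < 2^53
  as.integer(((as.numeric(seed) %% m) * 48271 + as.numeric(index)) %% m)
}

## Next 5-smooth integer >= n, so that stats::fft stays fast (mixed radix).
next_fast_len <- function(n) {
  n <- as.integer(n)
  repeat {
    m <- n
    for (p in c(2L, 3L, 5L)) while (m %% p == 0L) m <- m %/% p
    if (m == 1L) return(n)
    n <- n + 1L
  }
}

## Pad a matrix by edge replication to size (ny, nx), original in top-left
## corner offset by (oy, ox).
pad_edge <- function(m, ny, nx, oy, ox) {
  r <- nrow(m); c <- ncol(m)
  iy <- pmin(pmax(seq_len(ny) - oy, 1L), r)
  ix <- pmin(pmax(seq_len(nx) - ox, 1L), c)
  m[iy, ix, drop = FALSE]
}

## Windowed (2M+1)x(2M+1) box sum of a matrix, same size output.
## Values within M of the border are computed against an implicit zero pad;
## callers mask those out. Implemented with cumulative sums (O(n) per axis).
box_sum <- function(m, M) {
  if (M == 0L) return(m)
  n <- nrow(m); p <- ncol(m)
  ## cumulative along rows (y)
  cs <- rbind(matrix(0, 1L, p), apply(m, 2L, cumsum))
  hi <- pmin(seq_len(n) + M, n) + 1L
  lo <- pmax(seq_len(n) - M - 1L, 0L) + 1L
  m1 <- cs[hi, , drop = FALSE] - cs[lo, , drop = FALSE]
  ## cumulative along cols (x)
  cs2 <- cbind(matrix(0, n, 1L), t(apply(m1, 1L, cumsum)))
  hi2 <- pmin(seq_len(p) + M, p) + 1L
  lo2 <- pmax(seq_len(p) - M - 1L, 0L) + 1L
  cs2[, hi2, drop = FALSE] - cs2[, lo2, drop = FALSE]
}

## Shift a matrix by integer (dy, dx): out[y, x] = m[y - dy, x - dx],
## replicating edges (shifted-in values are masked downstream).
shift_int <- function(m, dy, dx) {
  n <- nrow(m); p <- ncol(m)
  iy <- pmin(pmax(seq_len(n) - dy, 1L), n)
  ix <- pmin(pmax(seq_len(p) - dx, 1L), p)
  m[iy, ix, drop = FALSE]
}

## FFT-based circular convolution of an image with a normalized sampled
## Gaussian kernel of standard deviation `sigma` (pixels). sigma = 0 is a
## no-op. Used for the detector PSF and the source-size blur.
gauss_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  n <- nrow(m); p <- ncol(m)
  gy <- stats::dnorm(fft_freq_index(n), sd = sigma)
  gx <- stats::dnorm(fft_freq_index(p), sd = sigma)
  ker <- outer(gy, gx)
  ker <- ker / sum(ker)
  Re(stats::fft(stats::fft(m) * stats::fft(ker), inverse = TRUE)) / (n * p)
}

## Signed sample offsets in FFT layout: 0, 1, ..., n/2, -(n/2-1), ..., -1
fft_freq_index <- function(n) {
  k <- seq_len(n) - 1L
  k[k > n / 2] <- k[k > n / 2] - n
  k
}

## FFT sample frequencies (cycles per sample spacing unit)
fft_freq <- function(n, d = 1) fft_freq_index(n) / (n * d)

## Sum a matrix over non-overlapping f x f blocks -> (n/f, p/f) matrix.
bin_sum <- function(m, f) {
  if (f == 1L) return(m)
  n <- nrow(m); p <- ncol(m)
  stopifnot(n %% f == 0L, p %% f == 0L)
  m <- matrix(colSums(matrix(m, f, n %/% f * p)), n %/% f, p)
  t(matrix(colSums(matrix(t(m), f, p %/% f * (n %/% f))), p %/% f, n %/% f))
}

## Block mean over f x f blocks.
bin_mean <- function(m, f) bin_sum(m, f) / f^2

#' Speckle-size estimate: autocorrelation FWHM
#'
#' Full width at half maximum of the image autocorrelation (mean of the
#' x and y cuts, linear interpolation between integer lags), in pixels.
#' The standard speckle-size statistic.
#'
#' @param img Numeric matrix (or [speckle_image()] data).
#' @return FWHM in pixels.
#' @export
autocorr_fwhm <- function(img) {
  if (inherits(img, "speckle_image")) img <- img$data
  m <- img - mean(img)
  n <- nrow(m); p <- ncol(m)
  ac <- Re(stats::fft(Mod(stats::fft(m))^2, inverse = TRUE)) / (n * p)
  ac <- ac / ac[1L, 1L]
  half_width <- function(prof) {
    ## prof[1] = 1 at lag 0, decreasing; find first crossing of 0.5
    k <- which(prof < 0.5)
    if (length(k) == 0L) return(NA_real_)
    k <- k[1L]
    ## linear interpolation between lag k-2 and k-1
    p0 <- prof[k - 1L]; p1 <- prof[k]
    (k - 2L) + (p0 - 0.5) / (p0 - p1)
  }
  wx <- half_width(ac[1L, seq_len(p %/% 2)])
  wy <- half_width(ac[seq_len(n %/% 2), 1L])
  ## FWHM = twice the half-width at half maximum, averaged over axes
  mean(c(wx, wy), na.rm = TRUE) * 2
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
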