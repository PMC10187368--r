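## Sub-pixel refinement primitives shared by the classical trackers.

#' Gaussian three-point sub-pixel peak interpolation
#'
#' For samples `c(-1), c(0), c(+1)` of a correlation profile with the
#' maximum at the centre, the log-quadratic (Gaussian) peak offset is
#' `delta = (ln c(-1) - ln c(+1)) / (2 (ln c(-1) - 2 ln c(0) + ln c(+1)))`,
#' clamped to \[-0.5, 0.5\]. Exact for samples of any Gaussian.
#'
#' @param triple Numeric length-3 vector, or a 3-column matrix (one triple
#'   per row) for vectorized use. Values must be positive; callers shift
#'   correlation values into the positive range first.
#' @return For a vector: list with `offset` and `ok` (FALSE if the centre
#'   is not a strict local maximum or values are non-positive, in which
#'   case the offset is 0). For a matrix: list of vectors.
#' @export
gaussian_subpixel <- function(triple) {
  m <- if (is.matrix(triple)) triple else matrix(triple, 1L, 3L)
  stopifnot(ncol(m) == 3L)
  ok <- m[, 1] > 0 & m[, 2] > 0 & m[, 3] > 0 &
    m[, 2] >= m[, 1] & m[, 2] >= m[, 3]
  l1 <- log(pmax(m[, 1], .Machine$double.xmin))
  l0 <- log(pmax(m[, 2], .Machine$double.xmin))
  l2 <- log(pmax(m[, 3], .Machine$double.xmin))
  den <- 2 * (l1 - 2 * l0 + l2)
  ok <- unname(ok & is.finite(den) & den < 0)
  off <- ifelse(ok, (l1 - l2) / den, 0)
  off <- unname(pmin(pmax(off, -0.5), 0.5))
  if (is.matrix(triple)) list(offset = off, ok = ok)
  else list(offset = off[1], ok = ok[1])
}

## Precomputed least-squares design for the 3x3 paraboloid fit:
## f(x, y) = a + b x + c y + d x^2 + e y^2 + g x y on the 9 offsets
## (x, y) in {-1, 0, 1}^2 (x varies fastest).
.parab_pinv <- local({
  xs <- rep(c(-1, 0, 1), times = 3)
  ys <- rep(c(-1, 0, 1), each = 3)
  X <- cbind(1, xs, ys, xs^2, ys^2, xs * ys)
  solve(crossprod(X), t(X))
})

#' Paraboloid sub-pixel refinement of a 3x3 cost neighborhood
#'
#' Least-squares 2D quadratic fit to the nine costs around an integer
#' minimum; returns the stationary point clamped to \[-0.5, 0.5\] per axis.
#' Saddle points / non-positive-definite curvature are flagged and return
#' offset (0, 0).
#'
#' @param costs Length-9 vector (x offset varying fastest, row-major
#'   `(y, x)` in \{-1, 0, 1\}), or a 9-column matrix for vectorized use.
#' @return List with `dx`, `dy`, `ok`.
#' @export
paraboloid_subpixel <- function(costs) {
  m <- if (is.matrix(costs)) costs else matrix(costs, 1L, 9L)
  stopifnot(ncol(m) == 9L)
  beta <- .parab_pinv %*% t(m)   # 6 x n
  b <- beta[2, ]; cc <- beta[3, ]; d <- beta[4, ]; e <- beta[5, ]; g <- beta[6, ]
  det <- 4 * d * e - g^2
  ok <- d > 0 & det > 1e-12 * pmax(abs(d) * abs(e), 1e-300)
  dx <- ifelse(ok, (-2 * e * b + g * cc) / det, 0)
  dy <- ifelse(ok, (-2 * d * cc + g * b) / det, 0)
  dx <- unname(pmin(pmax(dx, -0.5), 0.5))
  dy <- unname(pmin(pmax(dy, -0.5), 0.5))
  ok <- unname(ok)
  if (is.matrix(costs)) list(dx = dx, dy = dy, ok = ok)
  else list(dx = dx[1], dy = dy[1], ok = ok[1])
}
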