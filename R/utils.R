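# Internal numeric helpers shared across modules.

#' Bilinear interpolation of a 2D image at sub-pixel positions
#'
#' Pixel centers sit at integer coordinates (1-based, row = y, col = x).
#' Positions outside the image return `NA`.
#'
#' @param img numeric matrix (y by x).
#' @param y,x numeric vectors of equal length.
#' @return numeric vector of interpolated values.
#' @keywords internal
#' @noRd
bilinear <- function(img, y, x) {
  ny <- nrow(img); nx <- ncol(img)
  out <- rep(NA_real_, length(y))
  ok <- y >= 1 & y <= ny & x >= 1 & x <= nx & is.finite(y) & is.finite(x)
  if (!any(ok)) return(out)
  yy <- y[ok]; xx <- x[ok]
  y0 <- pmin(floor(yy), ny - 1L); x0 <- pmin(floor(xx), nx - 1L)
  y0 <- pmax(y0, 1L); x0 <- pmax(x0, 1L)
  fy <- yy - y0; fx <- xx - x0
  i00 <- cbind(y0, x0); i10 <- cbind(y0 + 1, x0)
  i01 <- cbind(y0, x0 + 1); i11 <- cbind(y0 + 1, x0 + 1)
  v <- img[i00] * (1 - fy) * (1 - fx) + img[i10] * fy * (1 - fx) +
    img[i01] * (1 - fy) * fx + img[i11] * fy * fx
  out[ok] <- v
  out
}

#' Discrete Gaussian kernel (1D, normalized)
#' @keywords internal
#' @noRd
gauss_kernel1d <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k / sum(k)
}

#' Smooth a vector with a Gaussian kernel, optionally circularly
#' @keywords internal
#' @noRd
smooth1d <- function(v, sigma, circular = FALSE) {
  k <- gauss_kernel1d(sigma)
  if (length(k) == 1L) return(v)
  r <- (length(k) - 1L) / 2L
  n <- length(v)
  if (circular) {
    idx <- c((n - r + 1L):n, 1L:n, 1L:r)
    vp <- v[idx]
  } else {
    vp <- c(rep(v[1L], r), v, rep(v[n], r))
  }
  as.numeric(stats::filter(vp, k, sides = 2))[(r + 1L):(r + n)]
}

#' Robust noise scale: 1.4826 * median absolute deviation about zero
#' @keywords internal
#' @noRd
mad_scale <- function(resid) {
  1.4826 * stats::median(abs(resid))
}

#' Derive a reproducible sub-seed for a named random substream
#'
#' Keeps derived seeds within the 32-bit integer range.
#' @keywords internal
#' @noRd
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 1103L + h) %% 2147483629)
}

#' Stop unless a condition holds
#' @keywords internal
#' @noRd
assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}
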