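#' Savitzky-Golay smoothing of a spectrum
#'
#' Local least-squares polynomial smoothing: at each point a polynomial of
#' degree `order` is fitted to the window of `window` neighbouring points
#' centred on it and evaluated there. Interior points on a uniform grid
#' reproduce the classic Savitzky-Golay convolution weights; near the edges
#' the window is truncated on the short side (no reflection padding — the
#' measured range edges carry real signal) and, if the truncated window holds
#' fewer than `order + 1` points, the degree is reduced to fit. The fit is
#' re-solved per point, so arbitrary strictly increasing grids are supported.
#'
#' The filter is linear in the absorbance values and reproduces any
#' polynomial of degree `<= order` exactly (including at the edges).
#'
#' @param s A [spectrum()].
#' @param window Odd window length in points (default 9).
#' @param order Polynomial degree, `1 <= order < window` (default 3).
#' @return A smoothed `spectrum` on the same grid; metadata preserved, with a
#'   provenance note appended to `$processing`.
#' @export
smooth_savitzky_golay <- function(s, window = 9L, order = 3L) {
  stopifnot(inherits(s, "spectrum"))
  n <- length(s$wavelength)
  if (window %% 2L != 1L) stop("window must be odd", call. = FALSE)
  if (window < 3L || window > n) {
    stop("window must satisfy 3 <= window <= length(spectrum)", call. = FALSE)
  }
  if (order < 1L || order >= window) {
    stop("order must satisfy 1 <= order < window", call. = FALSE)
  }
  h <- (window - 1L) %/% 2L
  wl <- s$wavelength
  y <- s$absorbance
  out <- numeric(n)
  for (i in seq_len(n)) {
    j <- max(1L, i - h):min(n, i + h)
    deg <- min(order, length(j) - 1L)
    # centred/scaled abscissa keeps the Vandermonde well conditioned
    x <- (wl[j] - wl[i]) / max(diff(range(wl[j])), 1)
    X <- outer(x, 0:deg, `^`)
    beta <- qr.coef(qr(X), y[j])
    out[i] <- beta[1L]  # polynomial value at x = 0
  }
  s$absorbance <- out
  s$processing <- c(s$processing,
                    sprintf("savitzky_golay(window=%d, order=%d)",
                            as.integer(window), as.integer(order)))
  s
}
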