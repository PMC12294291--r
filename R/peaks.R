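#' Absorbance at an arbitrary wavelength
#'
#' Piecewise-linear interpolation between bracketing grid points; an exact
#' grid hit returns the stored value. Linear (rather than spline)
#' interpolation is deliberate: it is monotone on monotone segments and
#' cannot overshoot near sharp bands.
#'
#' @param s A [spectrum()].
#' @param lambda Wavelength(s) in nm; must lie within the grid span.
#' @return Absorbance (AU), vectorised over `lambda`.
#' @export
absorbance_at <- function(s, lambda) {
  stopifnot(inherits(s, "spectrum"))
  rng <- span(s)
  if (any(lambda < rng[1L] | lambda > rng[2L])) {
    stop(sprintf("wavelength %g nm outside spectrum span [%g, %g]",
                 lambda[which(lambda < rng[1L] | lambda > rng[2L])[1L]],
                 rng[1L], rng[2L]), call. = FALSE)
  }
  stats::approx(s$wavelength, s$absorbance, xout = lambda,
                method = "linear", ties = "ordered")$y
}

#' Locate the absorbance maximum with sub-nanometre refinement
#'
#' Finds the grid maximum inside `window` and refines it by a parabola
#' through the maximum and its two neighbours (exact for a noiseless
#' quadratic). Ties between equal grid maxima are broken toward the longer
#' wavelength. If the maximum sits on the window edge no parabola exists;
#' the edge wavelength is returned with attribute `refined = FALSE`.
#'
#' @param s A [spectrum()].
#' @param window Length-2 numeric, nm interval to search (default whole span).
#' @return The peak wavelength (nm) with attribute `refined` (logical).
#' @export
find_lambda_max <- function(s, window = span(s)) {
  stopifnot(inherits(s, "spectrum"), length(window) == 2L)
  rng <- span(s)
  if (window[1L] < rng[1L] || window[2L] > rng[2L]) {
    stop("search window outside spectrum span", call. = FALSE)
  }
  idx <- which(s$wavelength >= window[1L] & s$wavelength <= window[2L])
  if (length(idx) < 3L) stop("search window spans fewer than 3 grid points",
                             call. = FALSE)
  y <- s$absorbance[idx]
  imax <- idx[max(which(y == max(y)))]   # tie -> longer wavelength
  if (imax == idx[1L] || imax == idx[length(idx)]) {
    return(structure(s$wavelength[imax], refined = FALSE))
  }
  x1 <- s$wavelength[imax - 1L]; x2 <- s$wavelength[imax]
  x3 <- s$wavelength[imax + 1L]
  y1 <- s$absorbance[imax - 1L]; y2 <- s$absorbance[imax]
  y3 <- s$absorbance[imax + 1L]
  # vertex of the parabola through three (possibly non-uniform) points
  den <- (x2 - x1) * (y2 - y3) - (x2 - x3) * (y2 - y1)
  if (abs(den) < .Machine$double.eps * max(abs(c(y1, y2, y3)), 1)) {
    return(structure(x2, refined = FALSE))   # locally flat
  }
  num <- (x2 - x1)^2 * (y2 - y3) - (x2 - x3)^2 * (y2 - y1)
  structure(x2 - 0.5 * num / den, refined = TRUE)
}

#' Absorbance band ratio
#'
#' Ratio of absorbances at two wavelengths (default 440/510 nm, the
#' yellow-to-red balance index used for aged pigment solutions).
#'
#' @param s A [spectrum()].
#' @param lambda_num Numerator wavelength (default 440 nm).
#' @param lambda_den Denominator wavelength (default 510 nm).
#' @param floor Smallest admissible denominator absorbance (default 1e-4 AU);
#'   below it the ratio is baseline noise over baseline noise and an error is
#'   raised.
#' @return Dimensionless ratio.
#' @export
band_ratio <- function(s, lambda_num = 440, lambda_den = 510, floor = 1e-4) {
  a_den <- absorbance_at(s, lambda_den)
  if (a_den <= floor) {
    stop(sprintf("ratio undefined at baseline: A(%g nm) = %.3g <= floor %g",
                 lambda_den, a_den, floor), call. = FALSE)
  }
  absorbance_at(s, lambda_num) / a_den
}
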