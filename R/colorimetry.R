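#' Transmittance from absorbance
#'
#' Decadic Beer-Lambert inversion `T = 10^(-A)`, clipped to `[0, 1]` (small
#' negative baseline absorbances would otherwise give T slightly above 1).
#'
#' @param s A [spectrum()].
#' @return A list with `wavelength` and `transmittance` vectors.
#' @export
transmittance <- function(s) {
  stopifnot(inherits(s, "spectrum"))
  tr <- 10^(-s$absorbance)
  list(wavelength = s$wavelength, transmittance = pmin(pmax(tr, 0), 1))
}

#' CIE tristimulus values of a transmittance spectrum
#'
#' Rectangular summation on the working grid:
#' `X = k * sum(T * S * xbar) * dl` (likewise Y, Z) with
#' `k = 100 / (sum(S * ybar) * dl)` over the same range, so the perfect
#' transmitter gives `Y = 100` exactly. The transmittance is linearly
#' interpolated onto the working grid; beyond its last measured wavelength
#' it is extended as a constant (measured spectra typically stop at 700 nm
#' while the observer extends to 780 nm, where anthocyanin absorbance is at
#' baseline) provided the measurement reaches `extend_from`. A coverage gap
#' at the blue end or a spectrum stopping short of `extend_from` is an
#' error naming the missing interval.
#'
#' @param wavelength Wavelengths (nm) where transmittance is known.
#' @param tr Transmittance values in `[0, 1]`.
#' @param tables An [observer_illuminant()].
#' @param extend_from Minimum red-end coverage (nm) required before constant
#'   extension is applied (default 700).
#' @return Named numeric vector `c(X, Y, Z)`.
#' @export
tristimulus <- function(wavelength, tr, tables = observer_illuminant(),
                        extend_from = 700) {
  stopifnot(inherits(tables, "observer_illuminant"))
  wl <- tables$wavelength
  lo <- min(wl); hi <- max(wl)
  if (min(wavelength) > lo) {
    stop(sprintf("transmittance does not cover [%g, %g] nm", lo,
                 min(wavelength)), call. = FALSE)
  }
  if (max(wavelength) < min(extend_from, hi)) {
    stop(sprintf("transmittance does not cover [%g, %g] nm",
                 max(wavelength), min(extend_from, hi)), call. = FALSE)
  }
  Tg <- stats::approx(wavelength, tr, xout = wl, method = "linear",
                      rule = 2, ties = "ordered")$y  # rule 2: constant ends
  k <- 100 / sum(tables$S * tables$ybar)
  c(X = k * sum(Tg * tables$S * tables$xbar),
    Y = k * sum(Tg * tables$S * tables$ybar),
    Z = k * sum(Tg * tables$S * tables$zbar))
}

#' White point of an observer/illuminant pair
#'
#' Tristimulus of the perfect transmitter (`T == 1`); `Y = 100` by
#' construction.
#'
#' @param tables An [observer_illuminant()].
#' @return Named numeric vector `c(X, Y, Z)`.
#' @export
white_point <- function(tables = observer_illuminant()) {
  wl <- tables$wavelength
  tristimulus(wl, rep(1, length(wl)), tables,
              extend_from = max(wl))
}

# CIE 1976 forward companding function and inverse
.lab_f <- function(t) {
  d <- 6 / 29
  ifelse(t > d^3, t^(1 / 3), t / (3 * d^2) + 4 / 29)
}
.lab_finv <- function(t) {
  d <- 6 / 29
  ifelse(t > d, t^3, 3 * d^2 * (t - 4 / 29))
}

#' CIELAB coordinates from tristimulus values
#'
#' Standard CIE 1976 L*a*b* with the cube-root companding function and its
#' linear segment below (6/29)^3.
#'
#' @param xyz Named or ordered numeric vector `c(X, Y, Z)`.
#' @param white White point `c(Xn, Yn, Zn)`, componentwise positive.
#' @return Named numeric vector `c(L, a, b)`.
#' @export
lab_from_xyz <- function(xyz, white = white_point()) {
  if (any(white <= 0)) stop("white point must be positive componentwise",
                            call. = FALSE)
  fx <- .lab_f(xyz[[1L]] / white[[1L]])
  fy <- .lab_f(xyz[[2L]] / white[[2L]])
  fz <- .lab_f(xyz[[3L]] / white[[3L]])
  c(L = 116 * fy - 16, a = 500 * (fx - fy), b = 200 * (fy - fz))
}

#' Tristimulus values from CIELAB coordinates
#'
#' Exact inverse of [lab_from_xyz()] for the same white point.
#'
#' @param lab Named or ordered numeric vector `c(L, a, b)`.
#' @param white White point `c(Xn, Yn, Zn)`.
#' @return Named numeric vector `c(X, Y, Z)`.
#' @export
xyz_from_lab <- function(lab, white = white_point()) {
  if (any(white <= 0)) stop("white point must be positive componentwise",
                            call. = FALSE)
  fy <- (lab[[1L]] + 16) / 116
  fx <- fy + lab[[2L]] / 500
  fz <- fy - lab[[3L]] / 200
  c(X = white[[1L]] * .lab_finv(fx),
    Y = white[[2L]] * .lab_finv(fy),
    Z = white[[3L]] * .lab_finv(fz))
}

#' Chroma and hue angle from a*, b*
#'
#' `C* = sqrt(a*^2 + b*^2)`; `H* = atan2(b*, a*)` in signed degrees within
#' `(-180, 180]` (printed hue angles for these solutions use the signed
#' convention — near-neutral reds can print slightly negative H*). At the
#' neutral point `(0, 0)` the hue is undefined: `H = 0` is returned with
#' `hue_defined = FALSE`.
#'
#' @param a,b CIELAB opponent coordinates.
#' @return List with `C`, `H` (degrees), `hue_defined`.
#' @export
chroma_hue <- function(a, b) {
  stopifnot(is.finite(a), is.finite(b))
  C <- sqrt(a^2 + b^2)
  if (C == 0) return(list(C = 0, H = 0, hue_defined = FALSE))
  H <- atan2(b, a) * 180 / pi
  if (H <= -180) H <- H + 360
  list(C = C, H = H, hue_defined = TRUE)
}

# sRGB (IEC 61966-2-1) D65 white and XYZ -> linear RGB matrix, Y in [0,1]
.srgb_white <- c(X = 95.047, Y = 100, Z = 108.883)
.srgb_m <- matrix(c(3.2404542, -1.5371385, -0.4985314,
                    -0.9692660, 1.8760108, 0.0415560,
                    0.0556434, -0.2040259, 1.0572252),
                  nrow = 3, byrow = TRUE)

#' sRGB hex swatch for a CIELAB colour
#'
#' Lab -> XYZ -> linear sRGB (D65) -> gamma-encoded 8-bit hex. Out-of-gamut
#' channels are clipped to `[0, 1]`; attribute `gamut_clipped` records
#' whether clipping occurred.
#'
#' @param L,a,b CIELAB coordinates.
#' @param white White point used for the Lab -> XYZ step; defaults to the
#'   sRGB standard D65 white so that sRGB primaries round-trip exactly.
#' @return Hex string like `"#AA3355"` with attribute `gamut_clipped`.
#' @export
srgb_swatch <- function(L, a, b, white = .srgb_white) {
  xyz <- xyz_from_lab(c(L, a, b), white = white) / 100
  lin <- as.numeric(.srgb_m %*% xyz)
  clipped <- any(lin < 0 | lin > 1)
  lin <- pmin(pmax(lin, 0), 1)
  enc <- ifelse(lin <= 0.0031308, 12.92 * lin,
                1.055 * lin^(1 / 2.4) - 0.055)
  hex <- grDevices::rgb(enc[1L], enc[2L], enc[3L])
  structure(toupper(hex), gamut_clipped = clipped)
}

#' Full colour characterisation of an absorbance spectrum
#'
#' Absorbance -> transmittance -> XYZ (D65, 10-degree observer) -> CIELAB ->
#' chroma, hue and sRGB swatch.
#'
#' @param s A [spectrum()].
#' @param tables An [observer_illuminant()].
#' @param extend_from Passed to [tristimulus()].
#' @return An object of class `color_result`: list with `XYZ`, `L`, `a`,
#'   `b`, `C`, `H`, `hue_defined`, `srgb_hex`.
#' @export
spectrum_color <- function(s, tables = observer_illuminant(),
                           extend_from = 700) {
  tr <- transmittance(s)
  xyz <- tristimulus(tr$wavelength, tr$transmittance, tables, extend_from)
  wp <- white_point(tables)
  lab <- lab_from_xyz(xyz, wp)
  ch <- chroma_hue(lab[["a"]], lab[["b"]])
  structure(list(XYZ = xyz, L = lab[["L"]], a = lab[["a"]], b = lab[["b"]],
                 C = ch$C, H = ch$H, hue_defined = ch$hue_defined,
                 srgb_hex = as.character(srgb_swatch(lab[["L"]], lab[["a"]],
                                                     lab[["b"]]))),
            class = "color_result")
}

#' @export
print.color_result <- function(x, ...) {
  cat(sprintf(
    "<color_result> L* %.2f  a* %.2f  b* %.2f  C* %.2f  H* %.2f  %s\n",
    x$L, x$a, x$b, x$C, x$H, x$srgb_hex))
  invisible(x)
}

#' Colour table for a collection of spectra
#'
#' One row per spectrum with sample metadata and the CIELAB summary, in the
#' layout of published colour tables (pH, treatment, timepoint, molar ratio,
#' C*, H*, L*, a*, b*, swatch).
#'
#' @param spectra Named list of [spectrum()] objects.
#' @param tables An [observer_illuminant()].
#' @return Data frame.
#' @export
color_table <- function(spectra, tables = observer_illuminant()) {
  do.call(rbind, lapply(names(spectra), function(id) {
    s <- spectra[[id]]
    cr <- spectrum_color(s, tables)
    m <- s$meta
    data.frame(sample_id = id, pH = m$pH, copigment = m$copigment,
               timepoint = m$timepoint, molar_ratio = m$molar_ratio,
               C = cr$C, H = cr$H, L = cr$L, a = cr$a, b = cr$b,
               srgb_hex = cr$srgb_hex)
  }))
}

#' Validate printed CIELAB records
#'
#' Recomputes `C* = sqrt(a*^2 + b*^2)` and `H* = atan2(b*, a*)` from printed
#' `a*, b*` coordinates and reports the discrepancy against the printed
#' `C*, H*` — a consistency audit of device-reported colour tables (devices
#' round internally, so printed hue can differ from the identity by a few
#' hundredths of a degree).
#'
#' @param records Data frame with columns `a`, `b`, `C`, `H`.
#' @return The input with extra columns `C_calc`, `H_calc`, `dC`, `dH`.
#' @export
validate_printed_lab <- function(records) {
  stopifnot(all(c("a", "b", "C", "H") %in% names(records)))
  ch <- lapply(seq_len(nrow(records)),
               function(i) chroma_hue(records$a[i], records$b[i]))
  records$C_calc <- vapply(ch, `[[`, numeric(1), "C")
  records$H_calc <- vapply(ch, `[[`, numeric(1), "H")
  records$dC <- records$C_calc - records$C
  records$dH <- records$H_calc - records$H
  records
}
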