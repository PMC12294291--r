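#' Sample metadata for a model-wine spectrum
#'
#' Describes the solution a UV-Vis spectrum was recorded from: which pigment
#' (the anthocyanin, by default malvidin-3-O-glucoside at 5e-5 M), which
#' copigment was added (caffeic acid `"CAF"`, (+)-catechin `"CA"`, syringic
#' acid `"SI"`, or `"none"` for the pigment-only reference), the pH of the
#' tartaric buffer, the copigment:pigment molar ratio, and bookkeeping fields.
#'
#' @param pigment Pigment identifier (default `"Mv-3-O-glc"`).
#' @param copigment One of `"CAF"`, `"CA"`, `"SI"`, `"none"`.
#' @param pH Solution pH; must lie in `[2, 4.5]` when given.
#' @param molar_ratio Positive copigment:pigment molar ratio (e.g. 20 for
#'   a 1:20 pigment:copigment mix). `NA` for pigment-only samples.
#' @param pigment_conc Final molar pigment concentration (default 5e-5 M).
#' @param copigment_conc Final molar copigment concentration. When both
#'   `molar_ratio` and `pigment_conc` are given it must equal their product
#'   (tolerance 1e-12).
#' @param replicate Positive integer replicate index.
#' @param timepoint Label, typically `"T0"` (fresh) or `"T12"` (12 months).
#'
#' @return An object of class `sample_meta` (a named list).
#' @export
sample_meta <- function(pigment = "Mv-3-O-glc", copigment = "none",
                        pH = NA_real_, molar_ratio = NA_real_,
                        pigment_conc = 5e-5, copigment_conc = NA_real_,
                        replicate = 1L, timepoint = "T0") {
  copigment <- match.arg(copigment, c("none", "CAF", "CA", "SI"))
  if (!is.na(pH) && (pH < 2 || pH > 4.5)) {
    stop("pH must lie in [2, 4.5], got ", pH, call. = FALSE)
  }
  if (!is.na(molar_ratio)) {
    if (molar_ratio <= 0 || molar_ratio != round(molar_ratio)) {
      stop("molar_ratio must be a positive integer", call. = FALSE)
    }
    molar_ratio <- as.integer(molar_ratio)
  }
  if (!is.na(copigment_conc) && !is.na(molar_ratio) && !is.na(pigment_conc)) {
    if (abs(copigment_conc - molar_ratio * pigment_conc) > 1e-12) {
      stop("copigment_conc (", copigment_conc,
           ") != molar_ratio * pigment_conc (", molar_ratio * pigment_conc,
           ")", call. = FALSE)
    }
  }
  if (is.na(copigment_conc) && !is.na(molar_ratio) && !is.na(pigment_conc)) {
    copigment_conc <- molar_ratio * pigment_conc
  }
  if (!is.na(replicate) && (replicate < 1 || replicate != round(replicate))) {
    stop("replicate must be a positive integer", call. = FALSE)
  }
  structure(list(pigment = pigment, copigment = copigment, pH = pH,
                 molar_ratio = molar_ratio, pigment_conc = pigment_conc,
                 copigment_conc = copigment_conc,
                 replicate = as.integer(replicate), timepoint = timepoint),
            class = "sample_meta")
}

#' Construct a UV-Vis absorbance spectrum
#'
#' A spectrum is a strictly increasing wavelength grid (nominally 300-700 nm
#' at 1 nm, but any strictly increasing grid is accepted) with one decadic
#' absorbance value per wavelength (1 cm path implied) and sample metadata.
#' Slightly negative absorbances are tolerated down to `baseline_tol`
#' (instrument baseline noise); anything lower is rejected as corrupt.
#'
#' @param wavelength Numeric vector of wavelengths in nm, strictly increasing.
#' @param absorbance Numeric vector of absorbance values (AU), same length.
#' @param meta A [sample_meta()] object.
#' @param baseline_tol Most negative admissible absorbance (default -0.005 AU).
#'
#' @return An object of class `spectrum`.
#' @export
spectrum <- function(wavelength, absorbance, meta = sample_meta(),
                     baseline_tol = -0.005) {
  wavelength <- as.numeric(wavelength)
  absorbance <- as.numeric(absorbance)
  if (length(wavelength) != length(absorbance)) {
    stop("wavelength and absorbance must have the same length", call. = FALSE)
  }
  if (length(wavelength) < 1L) stop("empty spectrum", call. = FALSE)
  if (anyNA(wavelength) || anyNA(absorbance) ||
      any(!is.finite(wavelength)) || any(!is.finite(absorbance))) {
    stop("wavelength and absorbance must be finite", call. = FALSE)
  }
  if (length(wavelength) > 1L && any(diff(wavelength) <= 0)) {
    bad <- which(diff(wavelength) <= 0)[1L] + 1L
    stop("wavelengths not strictly increasing at position ", bad,
         call. = FALSE)
  }
  if (any(absorbance < baseline_tol)) {
    stop("absorbance below baseline tolerance (", baseline_tol,
         " AU); corrupt spectrum?", call. = FALSE)
  }
  if (!inherits(meta, "sample_meta")) stop("meta must be a sample_meta")
  structure(list(wavelength = wavelength, absorbance = absorbance,
                 meta = meta, processing = character()),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %d points, %.7g-%.7g nm\n", length(x$wavelength),
              min(x$wavelength), max(x$wavelength)))
  m <- x$meta
  cat(sprintf("  %s / %s  pH %.4g  ratio 1:%s  rep %s  %s\n", m$pigment,
              m$copigment, m$pH, format(m$molar_ratio), format(m$replicate),
              m$timepoint))
  if (length(x$processing)) cat("  processing:", paste(x$processing, collapse = "; "), "\n")
  invisible(x)
}

#' @export
print.sample_meta <- function(x, ...) {
  cat(sprintf("<sample_meta> %s / %s  pH %.4g  ratio 1:%s  rep %s  %s\n",
              x$pigment, x$copigment, x$pH, format(x$molar_ratio),
              format(x$replicate), x$timepoint))
  invisible(x)
}

span <- function(s) range(s$wavelength)
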