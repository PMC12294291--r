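#' Read absorbance spectra from CSV
#'
#' Two layouts are supported. Long format has columns `sample_id`,
#' `wavelength_nm`, `absorbance` (one row per point). Wide format has a
#' `wavelength_nm` column followed by one absorbance column per sample.
#' Decimal separator is `.`, a header row is mandatory, encoding UTF-8.
#'
#' An optional sidecar metadata table (CSV path or data frame) with columns
#' `sample_id, pigment, copigment, pH, molar_ratio, pigment_conc_M,
#' copigment_conc_M, replicate, timepoint` populates each spectrum's
#' [sample_meta()]; samples absent from the sidecar get default metadata.
#'
#' @param path CSV file path (or connection) with the spectral table.
#' @param format `"auto"` (default), `"long"` or `"wide"`. Auto-detection
#'   keys on the presence of a `sample_id` column.
#' @param meta Optional metadata CSV path or data frame keyed by `sample_id`.
#' @param baseline_tol Passed to [spectrum()].
#'
#' @return Named list of `spectrum` objects (names are sample ids).
#' @export
read_spectra <- function(path, format = c("auto", "long", "wide"),
                         meta = NULL, baseline_tol = -0.005) {
  format <- match.arg(format)
  df <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  if (format == "auto") {
    format <- if ("sample_id" %in% names(df)) "long" else "wide"
  }
  meta_df <- NULL
  if (!is.null(meta)) {
    meta_df <- if (is.data.frame(meta)) meta else utils::read.csv(meta)
    if (!"sample_id" %in% names(meta_df)) {
      stop("metadata table lacks required field 'sample_id'", call. = FALSE)
    }
  }

  spectra <- if (format == "long") {
    need <- c("sample_id", "wavelength_nm", "absorbance")
    missing <- setdiff(need, names(df))
    if (length(missing)) {
      stop("long-format spectra file missing field(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    out <- list()
    for (id in unique(df$sample_id)) {
      rows <- which(df$sample_id == id)
      wl <- df$wavelength_nm[rows]
      if (anyDuplicated(wl)) {
        d <- wl[duplicated(wl)][1L]
        stop("duplicate (sample, wavelength) pair: sample '", id,
             "', wavelength ", d, " nm", call. = FALSE)
      }
      if (length(wl) > 1L && any(diff(wl) <= 0)) {
        bad <- rows[which(diff(wl) <= 0)[1L] + 1L]
        stop("non-monotonic wavelengths for sample '", id,
             "' at data row ", bad, call. = FALSE)
      }
      out[[as.character(id)]] <- spectrum(wl, df$absorbance[rows],
                                          baseline_tol = baseline_tol)
    }
    out
  } else {
    if (!"wavelength_nm" %in% names(df)) {
      stop("wide-format spectra file missing field 'wavelength_nm'",
           call. = FALSE)
    }
    wl <- df$wavelength_nm
    if (anyDuplicated(wl)) {
      stop("duplicate wavelength ", wl[duplicated(wl)][1L],
           " nm in wide-format file", call. = FALSE)
    }
    if (length(wl) > 1L && any(diff(wl) <= 0)) {
      stop("non-monotonic wavelengths at data row ",
           which(diff(wl) <= 0)[1L] + 1L, call. = FALSE)
    }
    ids <- setdiff(names(df), "wavelength_nm")
    stats::setNames(
      lapply(ids, function(id) spectrum(wl, df[[id]],
                                        baseline_tol = baseline_tol)),
      ids)
  }

  if (!is.null(meta_df)) {
    for (id in names(spectra)) {
      row <- meta_df[meta_df$sample_id == id, , drop = FALSE]
      if (nrow(row) == 1L) {
        spectra[[id]]$meta <- sample_meta(
          pigment = as.character(row$pigment),
          copigment = as.character(row$copigment),
          pH = as.numeric(row$pH),
          molar_ratio = as.numeric(row$molar_ratio),
          pigment_conc = as.numeric(row$pigment_conc_M),
          copigment_conc = as.numeric(row$copigment_conc_M),
          replicate = as.integer(row$replicate),
          timepoint = as.character(row$timepoint))
      }
    }
  }
  spectra
}

#' Write spectra to CSV
#'
#' Inverse of [read_spectra()]: `read_spectra(write_spectra(x, f), f)` is the
#' identity on wavelengths and absorbances. Wide format requires all spectra
#' to share one wavelength grid.
#'
#' @param spectra Named list of `spectrum` objects.
#' @param path Output CSV path.
#' @param format `"long"` or `"wide"`.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(spectra, path, format = c("long", "wide")) {
  format <- match.arg(format)
  if (is.null(names(spectra)) || any(names(spectra) == "")) {
    names(spectra) <- paste0("S", seq_along(spectra))
  }
  fmt <- function(x) formatC(x, digits = 17, format = "g")  # lossless
  df <- if (format == "long") {
    do.call(rbind, lapply(names(spectra), function(id) {
      s <- spectra[[id]]
      data.frame(sample_id = id, wavelength_nm = fmt(s$wavelength),
                 absorbance = fmt(s$absorbance))
    }))
  } else {
    grids <- lapply(spectra, `[[`, "wavelength")
    if (!all(vapply(grids, identical, logical(1), grids[[1L]]))) {
      stop("wide format requires a shared wavelength grid", call. = FALSE)
    }
    out <- data.frame(wavelength_nm = fmt(grids[[1L]]))
    for (id in names(spectra)) out[[id]] <- fmt(spectra[[id]]$absorbance)
    out
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write the sidecar metadata table for a list of spectra
#'
#' @param spectra Named list of `spectrum` objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_spectra_meta <- function(spectra, path) {
  df <- do.call(rbind, lapply(names(spectra), function(id) {
    m <- spectra[[id]]$meta
    data.frame(sample_id = id, pigment = m$pigment, copigment = m$copigment,
               pH = m$pH, molar_ratio = m$molar_ratio,
               pigment_conc_M = m$pigment_conc,
               copigment_conc_M = m$copigment_conc,
               replicate = m$replicate, timepoint = m$timepoint)
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
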