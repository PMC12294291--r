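#' Write a result table as CSV with a provenance header
#'
#' Prepends comment lines carrying the package version and a hash of the
#' run configuration, so output files are traceable to the run that made
#' them; identical configuration and seed give byte-identical files.
#'
#' @param df Data frame to write.
#' @param path Output path.
#' @param config Arbitrary R object describing the run (hashed with MD5).
#' @return `path`, invisibly.
#' @export
write_result_csv <- function(df, path, config = NULL) {
  ver <- as.character(utils::packageVersion("copigmentr"))
  hash <- config_hash(config)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# copigmentr %s", ver),
               sprintf("# config_hash %s", hash)), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' MD5 hash of an R object (for provenance headers)
#'
#' @param config Any serialisable object (`NULL` hashes the empty string).
#' @return Hex string.
#' @export
config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(config, f, version = 2)  # version pinned for stable hashing
  unname(tools::md5sum(f))
}

#' Short-term pipeline: titrations to thermodynamic table
#'
#' Runs the hyperchromic-shift analysis end to end: combine replicate
#' titration series per condition, fit the log-log association model, and
#' assemble the thermodynamic summary table. Input is either a list of
#' [titration_series()] (e.g. from [generate_titration()] or
#' [shift_table_series()]) or, with `series = NULL`, the packaged published
#' shift table. With `out_dir` the table is written as
#' `thermo_table.csv` with a provenance header; every dropped point or fit
#' flag is reported via `message()`.
#'
#' @param series List of `titration_series`, or `NULL` for the packaged
#'   shift fixture.
#' @param settings A [fit_settings()].
#' @param method Replicate combination, see [fit_condition()].
#' @param out_dir Optional output directory.
#' @return List with `table` (data frame) and `fits` (named list of
#'   `thermo_fit_result`).
#' @export
run_short_term <- function(series = NULL, settings = fit_settings(),
                           method = "mean_shift", out_dir = NULL) {
  if (is.null(series)) series <- shift_table_series()
  if (length(series) == 0L) stop("no titration series to analyse",
                                 call. = FALSE)
  tab <- withCallingHandlers(
    build_thermo_table(series, settings = settings, method = method),
    warning = function(w) {
      message("note: ", conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  flagged <- tab$flags != ""
  for (i in which(flagged)) {
    message(sprintf("flagged condition %s pH %s: %s", tab$copigment[i],
                    format(tab$pH[i]), tab$flags[i]))
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_result_csv(tab, file.path(out_dir, "thermo_table.csv"),
                     config = list(settings = settings, method = method,
                                   n_series = length(series)))
  }
  list(table = tab, fits = attr(tab, "fits"))
}

#' Long-term pipeline: colour table and band-ratio statistics
#'
#' Two complementary modes. With `spectra`, each spectrum is converted to
#' CIELAB (D65, 10-degree observer) for a colour table, and 440/510 nm band
#' ratios are extracted and grouped by (pH, molar ratio) for one-way ANOVA
#' with Tukey letters per pH; spectra without usable 440/510 nm coverage
#' are flagged per sample, not fatal. With `printed` (a CIELAB record table
#' with `a`, `b`, `C`, `H` columns, e.g. [load_cielab_table()]), chroma and
#' hue are recomputed from the printed opponent coordinates and the
#' discrepancies reported — a validation audit of device-printed colour
#' tables.
#'
#' @param spectra Named list of [spectrum()] objects, or `NULL`.
#' @param printed Data frame of printed CIELAB records, or `NULL`.
#' @param tables An [observer_illuminant()].
#' @param alpha Significance level for the ratio statistics.
#' @param out_dir Optional output directory (`color_table.csv`,
#'   `ratio_table.csv`, `lab_validation.csv`).
#' @return List with any of `colors`, `ratio_stats` (per-pH
#'   `group_stats_result`s), `ratio_table`, `flags`, `validation`.
#' @export
run_long_term <- function(spectra = NULL, printed = NULL,
                          tables = observer_illuminant(), alpha = 0.05,
                          out_dir = NULL) {
  if (is.null(spectra) && is.null(printed)) {
    stop("supply spectra and/or printed CIELAB records", call. = FALSE)
  }
  out <- list()
  cfg <- list(alpha = alpha, range = range(tables$wavelength))
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                    recursive = TRUE)
  if (!is.null(spectra)) {
    out$colors <- do.call(rbind, lapply(names(spectra), function(id) {
      s <- spectra[[id]]
      m <- s$meta
      cr <- tryCatch(spectrum_color(s, tables), error = function(e) {
        message("no colour for sample ", id, ": ", conditionMessage(e))
        NULL
      })
      data.frame(sample_id = id, pH = m$pH, copigment = m$copigment,
                 timepoint = m$timepoint, molar_ratio = m$molar_ratio,
                 C = if (is.null(cr)) NA_real_ else cr$C,
                 H = if (is.null(cr)) NA_real_ else cr$H,
                 L = if (is.null(cr)) NA_real_ else cr$L,
                 a = if (is.null(cr)) NA_real_ else cr$a,
                 b = if (is.null(cr)) NA_real_ else cr$b,
                 srgb_hex = if (is.null(cr)) NA_character_ else cr$srgb_hex)
    }))
    ratios <- lapply(names(spectra), function(id) {
      s <- spectra[[id]]
      r <- tryCatch(band_ratio(s), error = function(e) NA_real_)
      data.frame(sample_id = id, pH = s$meta$pH,
                 molar_ratio = s$meta$molar_ratio,
                 replicate = s$meta$replicate, ratio = r)
    })
    ratios <- do.call(rbind, ratios)
    bad <- is.na(ratios$ratio)
    out$flags <- ratios$sample_id[bad]
    for (id in out$flags) {
      message("no usable 440/510 nm ratio for sample ", id)
    }
    usable <- ratios[!bad & !is.na(ratios$molar_ratio), , drop = FALSE]
    if (nrow(usable)) {
      out$ratio_stats <- list()
      rows <- list()
      for (ph in sort(unique(usable$pH))) {
        sub <- usable[usable$pH == ph, , drop = FALSE]
        if (length(unique(sub$molar_ratio)) < 2L) next
        gs <- anova_tukey(sub$ratio, factor(sub$molar_ratio), alpha)
        out$ratio_stats[[format(ph)]] <- gs
        rows[[format(ph)]] <- data.frame(
          pH = ph, molar_ratio = names(gs$means),
          mean = as.numeric(gs$means), sd = as.numeric(gs$sd),
          letter = unname(gs$letters))
      }
      out$ratio_table <- do.call(rbind, rows)
      rownames(out$ratio_table) <- NULL
    }
    if (!is.null(out_dir)) {
      write_result_csv(out$colors, file.path(out_dir, "color_table.csv"),
                       config = cfg)
      if (!is.null(out$ratio_table)) {
        write_result_csv(out$ratio_table,
                         file.path(out_dir, "ratio_table.csv"), config = cfg)
      }
    }
  }
  if (!is.null(printed)) {
    out$validation <- validate_printed_lab(printed)
    if (!is.null(out_dir)) {
      write_result_csv(out$validation,
                       file.path(out_dir, "lab_validation.csv"), config = cfg)
    }
  }
  out
}
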