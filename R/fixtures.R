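#' Packaged published summary tables
#'
#' Accessors for the transcribed summary tables shipped with the package:
#' the mean hyperchromic shifts with printed regression summaries
#' (`load_shift_table()`), the CIELAB colour records (`load_cielab_table()`)
#' and the 440/510 nm band-ratio means with Tukey letters
#' (`load_ratio_table()`).
#'
#' @return A data frame.
#' @name fixtures
NULL

.extdata <- function(file) {
  system.file("extdata", file, package = "copigmentr", mustWork = TRUE)
}

#' @rdname fixtures
#' @export
load_shift_table <- function() {
  utils::read.csv(.extdata("table1_hyperchromic_shifts.csv"),
                  comment.char = "#")
}

#' @rdname fixtures
#' @export
load_cielab_table <- function() {
  utils::read.csv(.extdata("table2_cielab.csv"), comment.char = "#")
}

#' @rdname fixtures
#' @export
load_ratio_table <- function() {
  utils::read.csv(.extdata("table3_band_ratios.csv"), comment.char = "#")
}

#' Titration series from a table of mean hyperchromic shifts
#'
#' Rebuilds [titration_series()] objects from published shift summaries
#' (shift columns named `shift_1_<ratio>`). Only shifts are printed, so the
#' reference absorbance is set to 1 and `A = 1 + shift` — the log-log fit
#' depends on the shifts alone, not on `A0`.
#'
#' @param table Data frame in the layout of [load_shift_table()].
#' @param pigment_conc Final pigment concentration, M (default 5e-5), used
#'   to turn molar ratios into final copigment concentrations.
#' @return Named list of `titration_series`.
#' @export
shift_table_series <- function(table = load_shift_table(),
                               pigment_conc = 5e-5) {
  shift_cols <- grep("^shift_1_", names(table), value = TRUE)
  ratios <- as.numeric(sub("^shift_1_", "", shift_cols))
  ord <- order(ratios)
  shift_cols <- shift_cols[ord]; ratios <- ratios[ord]
  cp0 <- ratios * pigment_conc
  out <- list()
  for (i in seq_len(nrow(table))) {
    id <- sprintf("%s_pH%s", table$copigment[i], format(table$pH[i]))
    sh <- as.numeric(table[i, shift_cols])
    out[[id]] <- titration_series(A0 = 1, cp0 = cp0, A = 1 + sh,
                                  copigment = table$copigment[i],
                                  pH = table$pH[i])
  }
  out
}
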