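#' Build a thermodynamic summary table over many titration series
#'
#' One row per (copigment, pH) condition with the hyperchromic shifts at each
#' molar ratio, the regression quality (`r2`, `rmse`), the apparent
#' stoichiometry `n`, `ln(Keq)`, `Keq` and `dG0`. A condition whose fit fails
#' (too few positive shifts, degenerate ladder) yields a flagged row with
#' `NA` estimates, never a global failure.
#'
#' @param series_list List of [titration_series()] (one per condition, or
#'   replicates that will be combined by [fit_condition()]).
#' @param settings A [fit_settings()].
#' @param method Replicate combination passed to [fit_condition()].
#' @param pigment_conc Pigment concentration (M) used to express each `cp0`
#'   as a molar ratio in the shift column names (default 5e-5).
#' @return A data frame, one row per condition; attribute `"fits"` carries
#'   the underlying `thermo_fit_result` objects.
#' @export
build_thermo_table <- function(series_list, settings = fit_settings(),
                               method = "mean_shift", pigment_conc = 5e-5) {
  if (length(series_list) == 0L) {
    warning("no titration series supplied; empty table", call. = FALSE)
    return(data.frame(copigment = character(), pH = numeric(),
                      r2 = numeric(), n = numeric(), lnKeq = numeric(),
                      Keq_M = numeric(), dG0_kJ_mol = numeric(),
                      flags = character()))
  }
  if (inherits(series_list, "titration_series")) series_list <- list(series_list)
  cond <- vapply(series_list, function(s)
    paste(s$pigment, s$copigment, format(s$pH), sep = "|"), character(1))
  rows <- list(); fits <- list()
  for (cnd in unique(cond)) {
    group <- series_list[cond == cnd]
    s1 <- group[[1L]]
    sh <- withCallingHandlers(
      colMeans(do.call(rbind, lapply(group, function(s)
        hyperchromic_shift(s$A, s$A0)))),
      warning = function(w) invokeRestart("muffleWarning"))
    ratios <- round(s1$cp0 / pigment_conc)
    shift_cols <- stats::setNames(as.list(sh), sprintf("shift_1_%d", ratios))
    fit <- tryCatch(
      suppressWarnings(fit_condition(group, method = method,
                                     settings = settings)),
      error = function(e) e)
    if (inherits(fit, "error")) {
      row <- data.frame(copigment = s1$copigment, pH = s1$pH, shift_cols,
                        r2 = NA_real_, n = NA_real_, lnKeq = NA_real_,
                        Keq_M = NA_real_, dG0_kJ_mol = NA_real_,
                        flags = paste("fit failed:", conditionMessage(fit)),
                        check.names = FALSE)
    } else {
      fits[[cnd]] <- fit
      row <- data.frame(copigment = s1$copigment, pH = s1$pH, shift_cols,
                        r2 = fit$r2, n = fit$n, lnKeq = fit$lnKeq,
                        Keq_M = fit$Keq, dG0_kJ_mol = fit$dG0,
                        flags = paste(fit$flags, collapse = "; "),
                        check.names = FALSE)
    }
    rows[[cnd]] <- row
  }
  cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) { r[setdiff(cols, names(r))] <- NA; r[cols] })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  out
}

#' Rank copigments by association strength at a fixed pH
#'
#' Orders fitted conditions by descending `Keq`. Conditions whose `Keq`
#' differ by less than `tie_tol` (default 1 M^-1) share a rank.
#'
#' @param fits List of `thermo_fit_result` objects sharing one pH.
#' @param tie_tol Keq difference (M^-1) below which two conditions tie.
#' @return Data frame with `copigment`, `Keq_M`, `dG0_kJ_mol`, `rank`,
#'   ordered strongest first.
#' @export
rank_copigments <- function(fits, tie_tol = 1) {
  if (length(fits) == 0L) stop("no fits to rank", call. = FALSE)
  pHs <- vapply(fits, `[[`, numeric(1), "pH")
  if (length(unique(pHs)) != 1L) {
    stop("cannot rank across mixed pH values: ",
         paste(unique(pHs), collapse = ", "), call. = FALSE)
  }
  keq <- vapply(fits, `[[`, numeric(1), "Keq")
  ord <- order(keq, decreasing = TRUE)
  keq <- keq[ord]
  rank <- integer(length(keq))
  if (length(keq)) {
    rank[1L] <- 1L
    for (i in seq_along(keq)[-1L]) {
      rank[i] <- if (keq[i - 1L] - keq[i] < tie_tol) rank[i - 1L] else i
    }
  }
  data.frame(
    copigment = vapply(fits[ord], `[[`, character(1), "copigment"),
    Keq_M = keq,
    dG0_kJ_mol = vapply(fits[ord], `[[`, numeric(1), "dG0"),
    rank = rank)
}
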