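#' Log-log association plot for titration series
#'
#' Scatter of `ln[(A - A0)/A0]` against `ln(cp0)` with the fitted line whose
#' slope is the stoichiometry `n` and intercept `ln(Keq)` — the graphical
#' determination of the association constant. Requires ggplot2.
#'
#' @param series_list Named list of [titration_series()].
#' @param settings A [fit_settings()].
#' @return A ggplot object.
#' @export
plot_loglog_fit <- function(series_list, settings = fit_settings()) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_loglog_fit requires ggplot2", call. = FALSE)
  }
  if (inherits(series_list, "titration_series")) {
    series_list <- list(series = series_list)
  }
  pts <- do.call(rbind, lapply(names(series_list), function(id) {
    s <- series_list[[id]]
    sh <- hyperchromic_shift(s$A, s$A0)
    keep <- sh > 0
    data.frame(id = id, copigment = s$copigment, pH = s$pH,
               x = log(s$cp0[keep]), y = log(sh[keep]))
  }))
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$x, y = .data$y,
                                    colour = factor(.data$pH))) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.5) +
    ggplot2::labs(x = expression(ln ~ "[Cp]"[0]),
                  y = expression(ln ~ "[(A - A"[0] * ")/A"[0] * "]"),
                  colour = "pH") +
    ggplot2::facet_wrap(~copigment) +
    ggplot2::theme_bw()
}

#' Association constant versus pH
#'
#' Keq of each fitted condition against pH, one line per copigment — the
#' pH-dependence profile of copigmentation strength. Requires ggplot2.
#'
#' @param fits Named list of `thermo_fit_result` objects.
#' @return A ggplot object.
#' @export
plot_keq_vs_ph <- function(fits) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_keq_vs_ph requires ggplot2", call. = FALSE)
  }
  df <- do.call(rbind, lapply(fits, function(f)
    data.frame(copigment = f$copigment, pH = f$pH, Keq = f$Keq)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pH, y = .data$Keq,
                                   colour = .data$copigment)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "pH", y = expression(K[eq] ~ (M^-1)),
                  colour = "copigment") +
    ggplot2::theme_bw()
}
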