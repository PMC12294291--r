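#' Settings for the copigmentation equilibrium fit
#'
#' @param R Gas constant, J mol^-1 K^-1 (default 8.314).
#' @param T_K Absolute temperature in K. Fixed at 298 K by convention for the
#'   standard Gibbs energy, regardless of storage temperature.
#' @param lambda_ref Reference wavelength (nm) where hyperchromicity is read,
#'   default 523 (the flavylium visible maximum of malvidin-3-O-glucoside).
#' @param min_points Minimum number of positive-shift observations required
#'   for a fit (default 3).
#' @return An object of class `fit_settings`.
#' @export
fit_settings <- function(R = 8.314, T_K = 298, lambda_ref = 523,
                         min_points = 3L) {
  if (T_K <= 0) stop("temperature must be positive", call. = FALSE)
  structure(list(R = R, T_K = T_K, lambda_ref = lambda_ref,
                 min_points = as.integer(min_points)),
            class = "fit_settings")
}

#' A spectrophotometric titration series
#'
#' One copigmentation titration at fixed pigment, copigment and pH: the
#' reference absorbance `A0` of the pigment alone at `lambda_ref`, and the
#' absorbance `A` after adding copigment at each final concentration `cp0`
#' (mol/L after 1:1 mixing). Hypochromic observations (`A < A0`) may be
#' stored; they are excluded from the log-log fit with a warning.
#'
#' @param A0 Reference absorbance (AU), must be positive.
#' @param cp0 Final copigment concentrations (M), positive and strictly
#'   increasing.
#' @param A Absorbances (AU) at `lambda_ref`, same length as `cp0`.
#' @param lambda_ref Reference wavelength, default 523 nm.
#' @param pigment,copigment,pH,replicate Condition labels.
#' @return An object of class `titration_series`.
#' @export
titration_series <- function(A0, cp0, A, lambda_ref = 523,
                             pigment = "Mv-3-O-glc", copigment = "none",
                             pH = NA_real_, replicate = 1L) {
  if (A0 <= 0) stop("reference absorbance must be positive", call. = FALSE)
  if (length(cp0) != length(A)) stop("cp0 and A lengths differ", call. = FALSE)
  if (any(cp0 <= 0)) stop("copigment concentrations must be positive",
                          call. = FALSE)
  if (length(cp0) > 1L && any(diff(cp0) <= 0)) {
    stop("copigment concentrations must be strictly increasing",
         call. = FALSE)
  }
  structure(list(A0 = A0, cp0 = as.numeric(cp0), A = as.numeric(A),
                 lambda_ref = lambda_ref, pigment = pigment,
                 copigment = copigment, pH = pH,
                 replicate = as.integer(replicate)),
            class = "titration_series")
}

#' Hyperchromic shift
#'
#' `(A - A0) / A0`: the relative absorbance gain at the visible maximum upon
#' copigment addition. Negative values (hypochromic) are allowed.
#'
#' @param A Absorbance after copigment addition (AU).
#' @param A0 Reference absorbance of the pigment alone (AU), positive.
#' @return Dimensionless shift, vectorised over `A`.
#' @export
hyperchromic_shift <- function(A, A0) {
  if (any(A0 <= 0)) stop("reference absorbance must be positive",
                         call. = FALSE)
  (A - A0) / A0
}

#' Standard Gibbs free energy from ln(Keq)
#'
#' `-R * T * ln(Keq)`, reported in kJ mol^-1. Negative values mean the
#' association is spontaneous.
#'
#' @param lnKeq Natural log of the association constant (Keq in M^-1).
#' @param settings A [fit_settings()].
#' @return Gibbs energy in kJ mol^-1, vectorised over `lnKeq`.
#' @export
gibbs_free_energy <- function(lnKeq, settings = fit_settings()) {
  if (any(!is.finite(lnKeq))) stop("lnKeq must be finite", call. = FALSE)
  -settings$R * settings$T_K * lnKeq / 1000
}

#' Fit the copigmentation association model to a titration series
#'
#' Linearises the 1:n binding isotherm `A = A0 * (1 + Keq * cp0^n)` as
#' `ln[(A - A0)/A0] = ln(Keq) + n * ln(cp0)` and fits it by ordinary
#' unweighted least squares (natural logs, `cp0` in mol/L final
#' concentration). The slope is the apparent stoichiometry `n`, the intercept
#' `ln(Keq)`; the Gibbs energy follows from [gibbs_free_energy()].
#' Non-positive shifts are dropped with a warning (their log is undefined);
#' a slope outside `[0.5, 2]`, the physically plausible stoichiometry range,
#' is flagged but not rejected.
#'
#' @param series A [titration_series()].
#' @param settings A [fit_settings()].
#' @return An object of class `thermo_fit_result`: a list with `n`, `lnKeq`,
#'   `Keq` (M^-1), `dG0` (kJ mol^-1), `r2`, `rmse` (ln-shift units),
#'   `residuals`, `points_used`, `flags`, and the condition labels.
#' @export
fit_copigmentation <- function(series, settings = fit_settings()) {
  stopifnot(inherits(series, "titration_series"))
  sh <- hyperchromic_shift(series$A, series$A0)
  pos <- sh > 0
  if (any(!pos)) {
    for (k in which(!pos)) {
      warning(sprintf(
        "dropping non-positive shift %.4g at cp0 = %.3g M (log undefined)",
        sh[k], series$cp0[k]), call. = FALSE)
    }
  }
  if (sum(pos) < settings$min_points) {
    stop("fewer than ", settings$min_points,
         " positive-shift observations; cannot fit", call. = FALSE)
  }
  x <- log(series$cp0[pos])
  y <- log(sh[pos])
  if (stats::var(x) == 0) stop("zero variance in ln(cp0); cannot fit",
                               call. = FALSE)
  fit <- stats::lm(y ~ x)
  n <- unname(stats::coef(fit)[2L])
  lnKeq <- unname(stats::coef(fit)[1L])
  res <- unname(stats::residuals(fit))
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) NA_real_ else 1 - sum(res^2) / ss_tot
  flags <- character()
  if (n < 0.5 || n > 2) flags <- c(flags, "n outside 0.5-2")
  structure(list(
    n = n, lnKeq = lnKeq, Keq = exp(lnKeq),
    dG0 = gibbs_free_energy(lnKeq, settings),
    r2 = r2,
    rmse = sqrt(mean(res^2)),
    residuals = res, points_used = sum(pos), flags = flags,
    pigment = series$pigment, copigment = series$copigment, pH = series$pH),
    class = "thermo_fit_result")
}

#' @export
print.thermo_fit_result <- function(x, ...) {
  cat(sprintf("<thermo_fit_result> %s / %s  pH %.4g\n",
              x$pigment, x$copigment, x$pH))
  cat(sprintf("  n = %.3f  Keq = %.2f M^-1  dG0 = %.2f kJ/mol  r2 = %.3f  rmse = %.3g  (%d pts)\n",
              x$n, x$Keq, x$dG0, x$r2, x$rmse, x$points_used))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Fit one experimental condition from replicate titration series
#'
#' Replicates of the same (pigment, copigment, pH) condition can be combined
#' in two ways. `"mean_shift"` (default) averages the absorbances over
#' replicates at each concentration and fits the mean series once — the way
#' published tables of mean shifts are refit. `"per_replicate"` fits every
#' replicate separately and averages the fitted `n` and `ln(Keq)` (so `Keq`
#' is the geometric mean), which is how replicate-level instrument data are
#' usually summarised.
#'
#' @param series_list List of [titration_series()] sharing one condition.
#' @param method `"mean_shift"` or `"per_replicate"`.
#' @param settings A [fit_settings()].
#' @return A `thermo_fit_result` (for `"per_replicate"` with extra fields
#'   `n_sd` and `lnKeq_sd` across replicates).
#' @export
fit_condition <- function(series_list, method = c("mean_shift",
                                                  "per_replicate"),
                          settings = fit_settings()) {
  method <- match.arg(method)
  if (inherits(series_list, "titration_series")) {
    series_list <- list(series_list)
  }
  key <- unique(t(vapply(series_list, function(s)
    c(s$pigment, s$copigment, format(s$pH)), character(3))))
  if (nrow(key) != 1L) {
    stop("replicate series span more than one condition", call. = FALSE)
  }
  if (method == "mean_shift" || length(series_list) == 1L) {
    cp0 <- series_list[[1L]]$cp0
    for (s in series_list) {
      if (!isTRUE(all.equal(s$cp0, cp0))) {
        stop("replicates disagree on the concentration ladder", call. = FALSE)
      }
    }
    Abar <- rowMeans(vapply(series_list, `[[`, numeric(length(cp0)), "A"))
    A0bar <- mean(vapply(series_list, `[[`, numeric(1), "A0"))
    s1 <- series_list[[1L]]
    mean_series <- titration_series(A0bar, cp0, Abar,
                                    lambda_ref = s1$lambda_ref,
                                    pigment = s1$pigment,
                                    copigment = s1$copigment, pH = s1$pH)
    fit_copigmentation(mean_series, settings)
  } else {
    fits <- lapply(series_list, fit_copigmentation, settings = settings)
    n <- mean(vapply(fits, `[[`, numeric(1), "n"))
    lnKeq <- mean(vapply(fits, `[[`, numeric(1), "lnKeq"))
    out <- fits[[1L]]
    out$n <- n
    out$lnKeq <- lnKeq
    out$Keq <- exp(lnKeq)
    out$dG0 <- gibbs_free_energy(lnKeq, settings)
    out$r2 <- mean(vapply(fits, `[[`, numeric(1), "r2"))
    out$rmse <- mean(vapply(fits, `[[`, numeric(1), "rmse"))
    out$residuals <- unlist(lapply(fits, `[[`, "residuals"))
    out$points_used <- sum(vapply(fits, `[[`, integer(1), "points_used"))
    out$n_sd <- stats::sd(vapply(fits, `[[`, numeric(1), "n"))
    out$lnKeq_sd <- stats::sd(vapply(fits, `[[`, numeric(1), "lnKeq"))
    out$flags <- unique(unlist(lapply(fits, `[[`, "flags")))
    out
  }
}
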