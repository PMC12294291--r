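#' Configuration of the synthetic titration generator
#'
#' Defines the forward model the pipeline is tested against. The pigment's
#' reference absorbance follows the flavylium hydration equilibrium,
#' `A0(pH) = A0_base * 10^(-pH) / (10^(-pH) + 10^(-pKh))`, and copigment
#' addition enhances it along the 1:n binding isotherm
#' `A = A0 * (1 + Keq * cp^n)`. Measurement scatter is modelled as
#' multiplicative Gaussian noise on the copigmentation increment,
#' `A = A0 * (1 + Keq * cp^n * (1 + eps))` with
#' `eps ~ Normal(0, noise_sd_rel)` — i.e. relative noise on the
#' hyperchromic shift, which is the replicate-to-replicate variability the
#' log-log fit actually sees. (Scaling the whole absorbance by `1 + eps`
#' instead would put an absolute noise floor of `A0 * sd` under the shift
#' and drown the low-ratio points, which is incompatible with the replicate
#' precision real titrations of this kind achieve; see the methods
#' vignette.) Optional additive baseline noise on emitted spectra is also
#' available.
#'
#' @param Keq_true True association constant (M^-1); default 65, the
#'   strongest couple measured in the study design this emulates.
#' @param n_true True stoichiometry exponent; default 1 (1:1 complex).
#' @param A0_base Flavylium-band peak absorbance of the fully coloured
#'   pigment (default 1.4, i.e. 5e-5 M with a molar absorptivity of
#'   2.8e4 M^-1 cm^-1 at 523 nm).
#' @param pKh Apparent hydration constant controlling the pH decay of A0
#'   (default 2.6). A modelling knob, not a measured value.
#' @param pH Vector of pH conditions (default `c(2.8, 3.2, 3.6, 3.8)`).
#' @param molar_ratio Copigment:pigment ratios (default `c(1, 5, 10, 20)`).
#' @param pigment_conc Final pigment concentration, M (default 5e-5).
#' @param bands Data frame of Gaussian bands (`center` nm, `width` nm as the
#'   Gaussian sigma, `amplitude` relative to the flavylium peak) used when
#'   emitting full spectra. Default: flavylium band at 523 nm.
#' @param uv_band_center,uv_band_width,uv_band_eps Copigment UV band
#'   (default 324 nm, sigma 25 nm, molar absorptivity 2000 M^-1 cm^-1)
#'   added to emitted spectra in proportion to the copigment concentration.
#' @param noise_sd_rel Relative SD of the multiplicative increment noise
#'   (default 0.02).
#' @param baseline_noise_sd Additive absorbance noise SD for emitted spectra
#'   (default 0).
#' @param replicates Replicates per condition (default 3).
#' @param seed RNG seed.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(Keq_true = 65, n_true = 1, A0_base = 1.4,
                             pKh = 2.6, pH = c(2.8, 3.2, 3.6, 3.8),
                             molar_ratio = c(1, 5, 10, 20),
                             pigment_conc = 5e-5,
                             bands = data.frame(center = 523, width = 45,
                                                amplitude = 1),
                             uv_band_center = 324, uv_band_width = 25,
                             uv_band_eps = 2000,
                             noise_sd_rel = 0.02, baseline_noise_sd = 0,
                             replicates = 3L, seed = 1L) {
  stopifnot(Keq_true > 0, all(bands$width > 0), noise_sd_rel >= 0,
            baseline_noise_sd >= 0, replicates >= 1, pigment_conc > 0,
            all(molar_ratio > 0))
  structure(list(Keq_true = Keq_true, n_true = n_true, A0_base = A0_base,
                 pKh = pKh, pH = pH, molar_ratio = molar_ratio,
                 pigment_conc = pigment_conc, bands = bands,
                 uv_band_center = uv_band_center,
                 uv_band_width = uv_band_width, uv_band_eps = uv_band_eps,
                 noise_sd_rel = noise_sd_rel,
                 baseline_noise_sd = baseline_noise_sd,
                 replicates = as.integer(replicates),
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Flavylium fraction of the reference absorbance
#'
#' `A0(pH) = A0_base * 10^(-pH) / (10^(-pH) + 10^(-pKh))`: the coloured
#' flavylium fraction decreases monotonically with pH.
#'
#' @param pH Vector of pH values.
#' @param A0_base Peak absorbance of the fully coloured pigment.
#' @param pKh Apparent hydration constant.
#' @return Reference absorbances.
#' @export
flavylium_a0 <- function(pH, A0_base = 1.4, pKh = 2.6) {
  A0_base * 10^(-pH) / (10^(-pH) + 10^(-pKh))
}

#' Generate synthetic titration series (and optionally full spectra)
#'
#' Forward-simulates the short-term copigmentation experiment: for every
#' pH and replicate, a [titration_series()] over the molar-ratio ladder with
#' seeded multiplicative increment noise (see [generator_config()]). With
#' `emit_spectra = TRUE` each observation also yields a full 300-700 nm
#' [spectrum()]: the flavylium Gaussian band scaled so its 523 nm peak
#' equals the scalar absorbance, plus the copigment UV band and optional
#' additive baseline noise.
#'
#' @param config A [generator_config()].
#' @param emit_spectra Also return full spectra (default `FALSE`).
#' @param grid Wavelength grid for emitted spectra (default `300:700`).
#' @return List with `series` (list of `titration_series`, one per
#'   pH x replicate, named `pH<ph>_r<rep>`) and, when requested, `spectra`
#'   (named list of `spectrum`, one per pH x replicate x ratio plus the
#'   pigment-only references).
#' @export
generate_titration <- function(config = generator_config(),
                               emit_spectra = FALSE, grid = 300:700) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  cp0 <- config$molar_ratio * config$pigment_conc
  series <- list()
  spectra <- list()
  for (ph in config$pH) {
    A0 <- flavylium_a0(ph, config$A0_base, config$pKh)
    for (r in seq_len(config$replicates)) {
      eps <- stats::rnorm(length(cp0), 0, config$noise_sd_rel)
      A <- A0 * (1 + config$Keq_true * cp0^config$n_true * (1 + eps))
      id <- sprintf("pH%s_r%d", format(ph), r)
      series[[id]] <- titration_series(
        A0 = A0, cp0 = cp0, A = A, copigment = "CAF", pH = ph,
        replicate = r)
      if (emit_spectra) {
        ref_id <- sprintf("%s_ref", id)
        spectra[[ref_id]] <- .emit_spectrum(grid, A0, 0, config, ph, NA, r)
        for (k in seq_along(cp0)) {
          sid <- sprintf("%s_ratio%d", id, config$molar_ratio[k])
          spectra[[sid]] <- .emit_spectrum(grid, A[k], cp0[k], config, ph,
                                           config$molar_ratio[k], r)
        }
      }
    }
  }
  out <- list(series = series)
  if (emit_spectra) out$spectra <- spectra
  out
}

.emit_spectrum <- function(grid, peak_abs, cp, config, ph, ratio, rep) {
  shape <- aged_band_value(config$bands, grid)
  peak_shape <- max(shape)
  a <- peak_abs * shape / peak_shape
  a <- a + config$uv_band_eps * cp *
    exp(-0.5 * ((grid - config$uv_band_center) / config$uv_band_width)^2)
  if (config$baseline_noise_sd > 0) {
    a <- a + stats::rnorm(length(grid), 0, config$baseline_noise_sd)
  }
  spectrum(grid, pmax(a, 0),
           meta = sample_meta(copigment = if (cp > 0) "CAF" else "none",
                              pH = ph,
                              molar_ratio = if (is.na(ratio)) NA_real_ else ratio,
                              pigment_conc = config$pigment_conc,
                              copigment_conc = if (cp > 0) cp else NA_real_,
                              replicate = rep))
}

#' Closed-form absorbance of a Gaussian band set
#'
#' Evaluates `sum(amplitude * exp(-0.5 * ((lambda - center) / width)^2))`,
#' the noiseless absorbance of [generate_aged_spectrum()], so expected band
#' ratios are computable analytically before any spectrum is built.
#'
#' @param bands Data frame with `center`, `width` (Gaussian sigma),
#'   `amplitude` columns.
#' @param lambda Wavelengths (nm), vectorised.
#' @return Absorbance values.
#' @export
aged_band_value <- function(bands, lambda) {
  out <- numeric(length(lambda))
  for (i in seq_len(nrow(bands))) {
    out <- out + bands$amplitude[i] *
      exp(-0.5 * ((lambda - bands$center[i]) / bands$width[i])^2)
  }
  out
}

#' Generate a synthetic aged-pigment spectrum
#'
#' Sum-of-Gaussians absorbance on a wavelength grid plus seeded
#' multiplicative noise — a qualitative stand-in for 12-month-aged pigment
#' solutions, whose visible spectra show a 440-450 nm maximum with a 510 nm
#' shoulder (or vice versa). The noiseless band values are exposed through
#' [aged_band_value()].
#'
#' @param bands Data frame with `center`, `width`, `amplitude` columns.
#' @param noise_sd_rel Relative multiplicative noise SD (default 0).
#' @param seed Optional RNG seed for reproducibility.
#' @param grid Wavelength grid (default `300:700`).
#' @param meta A [sample_meta()] attached to the result.
#' @return A [spectrum()].
#' @export
generate_aged_spectrum <- function(bands, noise_sd_rel = 0, seed = NULL,
                                   grid = 300:700, meta = sample_meta(
                                     timepoint = "T12")) {
  if (!is.null(seed)) set.seed(seed)
  a <- aged_band_value(bands, grid)
  if (noise_sd_rel > 0) {
    a <- a * (1 + stats::rnorm(length(grid), 0, noise_sd_rel))
  }
  spectrum(grid, pmax(a, 0), meta = meta)
}

#' Simulate replicate band ratios for a grouped design
#'
#' Draws `replicates` Normal values per group around the given means — the
#' generator behind letter-pattern simulations, parameterised directly by
#' published mean +/- SD summaries (an SD printed as 0 is honoured and
#' produces constant replicates, the exact-separation path).
#'
#' @param means Named numeric vector of group means.
#' @param sds SD per group (recycled).
#' @param replicates Replicates per group (default 3).
#' @param seed Optional RNG seed.
#' @return Data frame with `group` (factor, level order as `means`) and
#'   `value`.
#' @export
simulate_band_ratios <- function(means, sds, replicates = 3L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sds <- rep_len(sds, length(means))
  g <- names(means)
  if (is.null(g)) g <- as.character(seq_along(means))
  data.frame(
    group = factor(rep(g, each = replicates), levels = g),
    value = unlist(lapply(seq_along(means), function(i)
      stats::rnorm(replicates, means[i], sds[i]))))
}
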