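test_that("spectrum constructor enforces its invariants", {
  s <- spectrum(c(500, 501, 502), c(0.1, 0.2, 0.1))
  expect_s3_class(s, "spectrum")
  expect_error(spectrum(c(500, 502, 501), c(0.1, 0.2, 0.1)),
               "not strictly increasing")
  expect_error(spectrum(500:502, c(0.1, NA, 0.1)), "finite")
  expect_error(spectrum(500:502, c(0.1, -0.02, 0.1)), "baseline tolerance")
  # within the configurable tolerance, small negatives pass
  expect_silent(spectrum(500:502, c(0.1, -0.004, 0.1)))
  expect_silent(spectrum(500:502, c(0.1, -0.02, 0.1), baseline_tol = -0.05))
})

test_that("sample metadata validates pH range and concentration consistency", {
  expect_error(sample_meta(pH = 5), "pH")
  m <- sample_meta(copigment = "CAF", pH = 3.6, molar_ratio = 20)
  expect_equal(m$copigment_conc, 20 * 5e-5)
  expect_error(sample_meta(copigment = "CAF", molar_ratio = 20,
                           copigment_conc = 9e-4), "copigment_conc")
  expect_error(sample_meta(copigment = "XX"), "arg")
})

test_that("long-format reading handles toy input and rejects bad files", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,wavelength_nm,absorbance",
               "s1,500,0.10", "s1,501,0.20", "s1,502,0.10"), f)
  sp <- read_spectra(f)
  expect_length(sp, 1L)
  expect_equal(sp$s1$wavelength, c(500, 501, 502))
  expect_equal(sp$s1$absorbance, c(0.10, 0.20, 0.10))

  writeLines(c("sample_id,wavelength_nm,absorbance",
               "s1,502,0.10", "s1,500,0.20", "s1,501,0.10"), f)
  expect_error(read_spectra(f), "non-monotonic.*row 2")

  writeLines(c("sample_id,wavelength_nm,absorbance",
               "s1,500,0.10", "s1,500,0.20"), f)
  expect_error(read_spectra(f), "duplicate")

  writeLines(c("sample_id,wavelength_nm", "s1,500"), f)
  expect_error(read_spectra(f), "absorbance")
})

test_that("wide-format round trip is bitwise identical, metadata included", {
  grid <- 300:700
  set.seed(11)
  sp <- list(
    a = spectrum(grid, runif(length(grid), 0, 1.2),
                 meta = sample_meta(copigment = "CAF", pH = 3.6,
                                    molar_ratio = 5, replicate = 2,
                                    timepoint = "T12")),
    b = spectrum(grid, runif(length(grid), 0, 1.2),
                 meta = sample_meta(pH = 2.8)))
  f <- withr::local_tempfile(fileext = ".csv")
  fm <- withr::local_tempfile(fileext = ".csv")
  write_spectra(sp, f, format = "wide")
  write_spectra_meta(sp, fm)
  back <- read_spectra(f, meta = fm)
  expect_length(back, 2L)
  expect_identical(back$a$wavelength, sp$a$wavelength)
  expect_identical(back$a$absorbance, sp$a$absorbance)
  expect_identical(back$b$absorbance, sp$b$absorbance)
  expect_equal(back$a$meta$copigment, "CAF")
  expect_equal(back$a$meta$pH, 3.6)
  expect_equal(back$a$meta$molar_ratio, 5L)
  expect_equal(back$a$meta$timepoint, "T12")
  # long-format round trip too
  write_spectra(sp, f, format = "long")
  back2 <- read_spectra(f)
  expect_identical(back2$b$absorbance, sp$b$absorbance)
})

test_that("Savitzky-Golay smoothing preserves polynomials and validates args", {
  grid <- 300:700
  const <- spectrum(grid, rep(0.5, length(grid)))
  expect_equal(smooth_savitzky_golay(const)$absorbance,
               rep(0.5, length(grid)), tolerance = 1e-12)
  cubic <- spectrum(grid, 1e-6 * as.numeric(grid)^3)
  sm <- smooth_savitzky_golay(cubic, window = 9, order = 3)
  expect_lt(max(abs(sm$absorbance - cubic$absorbance)), 1e-10)
  expect_error(smooth_savitzky_golay(const, window = 8), "odd")
  expect_error(smooth_savitzky_golay(const, window = 9, order = 9), "order")
  expect_match(sm$processing, "savitzky_golay", all = FALSE)
})

test_that("smoothing reduces white-noise variance and is linear", {
  grid <- 300:700
  set.seed(42)
  noisy <- spectrum(grid, 0.5 + rnorm(length(grid), 0, 0.01))
  sm <- smooth_savitzky_golay(noisy)
  expect_lt(var(sm$absorbance), var(noisy$absorbance))
  # linearity: smooth(a*s1 + b*s2) == a*smooth(s1) + b*smooth(s2)
  s1 <- spectrum(grid, runif(length(grid)))
  s2 <- spectrum(grid, runif(length(grid)))
  comb <- spectrum(grid, 0.3 * s1$absorbance + 1.7 * s2$absorbance)
  lhs <- smooth_savitzky_golay(comb)$absorbance
  rhs <- 0.3 * smooth_savitzky_golay(s1)$absorbance +
    1.7 * smooth_savitzky_golay(s2)$absorbance
  expect_lt(max(abs(lhs - rhs)), 1e-12)
})

test_that("interior smoothing matches the classic convolution filter", {
  skip_if_not_installed("signal")
  grid <- 300:700
  set.seed(7)
  y <- 0.5 * exp(-0.5 * ((grid - 523) / 40)^2) + rnorm(length(grid), 0, 0.005)
  s <- spectrum(grid, pmax(y, 0))
  mine <- smooth_savitzky_golay(s, window = 9, order = 3)$absorbance
  ref <- signal::sgolayfilt(s$absorbance, p = 3, n = 9)
  interior <- 5:(length(grid) - 4)
  expect_equal(mine[interior], ref[interior], tolerance = 1e-10)
})

test_that("absorbance_at interpolates linearly and enforces the span", {
  s <- spectrum(c(522, 523, 524), c(0.10, 0.20, 0.10))
  expect_identical(absorbance_at(s, 523), 0.20)
  expect_equal(absorbance_at(s, 522.5), 0.15)
  expect_error(absorbance_at(s, 521), "outside")
  full <- spectrum(300:700, seq(0, 1, length.out = 401))
  expect_error(absorbance_at(full, 299), "outside")
  # exact on grid points and monotone on a monotone segment
  expect_identical(absorbance_at(full, 400), full$absorbance[101])
  probe <- absorbance_at(full, seq(350, 450, by = 0.25))
  expect_true(all(diff(probe) >= 0))
})

test_that("find_lambda_max refines to sub-nanometre accuracy", {
  # noiseless parabola: vertex recovered to numerical precision
  grid <- seq(500, 546, by = 2)  # non-uniform-free but offset vertex
  par <- spectrum(grid, 1 - 0.001 * (grid - 523.7)^2)
  lm1 <- find_lambda_max(par)
  expect_equal(as.numeric(lm1), 523.7, tolerance = 1e-9)
  expect_true(attr(lm1, "refined"))

  g1 <- gaussian_spectrum(523, 40, 0.6)
  expect_equal(as.numeric(find_lambda_max(g1, c(450, 600))), 523,
               tolerance = 0.05)
  g2 <- gaussian_spectrum(524.3, 40, 0.6)
  expect_equal(as.numeric(find_lambda_max(g2, c(450, 600))), 524.3,
               tolerance = 0.1)

  ramp <- spectrum(300:700, seq(0, 1, length.out = 401))
  lm2 <- find_lambda_max(ramp, c(400, 500))
  expect_false(attr(lm2, "refined"))
  expect_equal(as.numeric(lm2), 500)

  # ties break toward the longer wavelength: the plateau maximum is taken at
  # 503 (not 501), so the parabola through (502, 503, 504) refines to 502.5
  flat <- spectrum(500:504, c(0, 1, 1, 1, 0))
  tied <- find_lambda_max(flat)
  expect_equal(as.numeric(tied), 502.5)

  expect_error(find_lambda_max(g1, c(200, 600)), "outside")
  expect_error(find_lambda_max(g1, c(523, 524)), "fewer than 3")
})

test_that("band_ratio matches the closed-form band sum and guards baseline", {
  flat <- spectrum(300:700, rep(0.3, 401))
  expect_equal(band_ratio(flat), 1.0)

  # two bands solved so that A(440) = 0.378 and A(510) = 0.200 exactly
  M <- matrix(c(1, exp(-0.5 * (70 / 20)^2),
                exp(-0.5 * (70 / 20)^2), 1), 2, 2)
  amp <- solve(M, c(0.378, 0.200))
  bands <- data.frame(center = c(440, 510), width = 20, amplitude = amp)
  expect_equal(aged_band_value(bands, 440), 0.378, tolerance = 1e-12)
  expect_equal(aged_band_value(bands, 510), 0.200, tolerance = 1e-12)
  aged <- generate_aged_spectrum(bands)
  expect_equal(band_ratio(aged), 1.89, tolerance = 1e-10)

  low <- spectrum(300:700, rep(1e-6, 401))
  expect_error(band_ratio(low), "baseline")
})
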