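tables <- observer_illuminant()

test_that("transmittance is the decadic Beer-Lambert inverse, clipped", {
  s <- spectrum(c(400, 401, 402, 403), c(0, 1, 0.3010, -0.004))
  tr <- transmittance(s)$transmittance
  expect_equal(tr[1], 1)
  expect_equal(tr[2], 0.1)
  expect_equal(tr[3], 0.5, tolerance = 1e-4 / 0.5)
  expect_equal(tr[4], 1)  # negative baseline clips to 1
})

test_that("tristimulus normalisation, linearity and boxcar oracle hold", {
  wl <- tables$wavelength
  ones <- rep(1, length(wl))
  wp <- tristimulus(wl, ones, tables, extend_from = max(wl))
  expect_equal(unname(wp["Y"]), 100, tolerance = 1e-12)

  half <- tristimulus(wl, 0.5 * ones, tables, extend_from = max(wl))
  expect_equal(unname(half), unname(wp) / 2, tolerance = 1e-12)

  # boxcar window: Y is the captured fraction of the luminous sum
  box <- as.numeric(wl >= 520 & wl <= 530)
  y_box <- tristimulus(wl, box, tables, extend_from = max(wl))["Y"]
  frac <- sum((tables$S * tables$ybar)[wl >= 520 & wl <= 530]) /
    sum(tables$S * tables$ybar)
  expect_equal(unname(y_box), 100 * frac, tolerance = 1e-12)

  # scaling T by alpha scales X, Y, Z by alpha
  set.seed(3)
  tr <- runif(length(wl))
  expect_equal(tristimulus(wl, 0.37 * tr, tables, extend_from = max(wl)),
               0.37 * tristimulus(wl, tr, tables, extend_from = max(wl)),
               tolerance = 1e-12)
})

test_that("coverage gaps are rejected by name; red-end extension works", {
  expect_error(tristimulus(400:780, rep(1, 381), tables), "380")
  expect_error(tristimulus(380:600, rep(1, 221), tables), "700")
  # spectrum to 700 nm extends as constant to 780
  v <- tristimulus(380:700, rep(0.5, 321), tables)
  expect_equal(unname(v["Y"]), 50, tolerance = 1e-12)
})

test_that("CIELAB forward and inverse transforms are exact", {
  wp <- white_point(tables)
  expect_equal(unname(lab_from_xyz(wp, wp)), c(100, 0, 0), tolerance = 1e-12)
  # mid-grey: L* = 116 * 0.18^(1/3) - 16
  grey <- lab_from_xyz(0.18 * wp, wp)
  expect_equal(unname(grey["L"]), 116 * 0.18^(1 / 3) - 16, tolerance = 1e-12)
  expect_equal(unname(grey[c("a", "b")]), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(lab_from_xyz(c(0, 0, 0), wp)["L"]), 0)
  expect_error(lab_from_xyz(wp, c(95, -1, 108)), "positive")

  # round trip Lab -> XYZ -> Lab below 1e-8, including the linear segment
  set.seed(8)
  for (i in 1:25) {
    lab <- c(runif(1, 0, 100), runif(2, -60, 60))
    back <- lab_from_xyz(xyz_from_lab(lab, wp), wp)
    expect_equal(unname(back), lab, tolerance = 1e-8)
  }
  dark <- c(2, 1, -1)  # exercises the linear-segment branch
  expect_equal(unname(lab_from_xyz(xyz_from_lab(dark, wp), wp)), dark,
               tolerance = 1e-8)
})

test_that("chroma and hue follow the signed-degree convention", {
  ch <- chroma_hue(25.44, 15.50)
  expect_equal(round(ch$C, 2), 29.79)
  ch2 <- chroma_hue(7.30, 1.97)
  expect_equal(round(ch2$H, 2), 15.10)
  ch3 <- chroma_hue(0, 5)
  expect_equal(ch3$C, 5)
  expect_equal(ch3$H, 90)
  expect_lt(chroma_hue(29.29, -0.57)$H, 0)  # near-neutral red prints negative
  neutral <- chroma_hue(0, 0)
  expect_equal(neutral$C, 0)
  expect_equal(neutral$H, 0)
  expect_false(neutral$hue_defined)
})

test_that("printed colour records satisfy the chroma identity", {
  v <- validate_printed_lab(load_cielab_table())
  expect_equal(nrow(v), 52L)
  expect_true(all(abs(round(v$C_calc, 2) - v$C) <= 0.01 + 1e-9))
  # printed hue is quantised in 0.01 rad steps; deviations stay below 0.4 deg
  expect_true(all(abs(v$dH) < 0.4))
  expect_equal(round(v$H_calc[v$couple == "none" & v$pH == 3.6], 2), 15.10)
})

test_that("sRGB swatches render anchors and round-trip the red primary", {
  expect_equal(as.character(srgb_swatch(100, 0, 0)), "#FFFFFF")
  expect_equal(as.character(srgb_swatch(0, 0, 0)), "#000000")
  # pure sRGB red through the same transforms
  lin <- c(1, 0, 0)
  M <- matrix(c(3.2404542, -1.5371385, -0.4985314,
                -0.9692660, 1.8760108, 0.0415560,
                0.0556434, -0.2040259, 1.0572252), 3, 3, byrow = TRUE)
  xyz <- 100 * solve(M, lin)
  lab <- lab_from_xyz(xyz, c(95.047, 100, 108.883))
  hex <- srgb_swatch(lab["L"], lab["a"], lab["b"])
  rgb_back <- grDevices::col2rgb(as.character(hex))[, 1]
  expect_true(all(abs(rgb_back - c(255, 0, 0)) <= 1))
  expect_false(attr(srgb_swatch(50, 0, 0), "gamut_clipped"))
  expect_true(attr(srgb_swatch(50, 120, -120), "gamut_clipped"))
})

test_that("a perfect transmitter is perfectly white end to end", {
  s0 <- spectrum(300:700, rep(0, 401))
  cr <- spectrum_color(s0, tables)
  expect_equal(cr$L, 100, tolerance = 1e-9)
  expect_lt(abs(cr$a), 1e-6)
  expect_lt(abs(cr$b), 1e-6)
  expect_equal(cr$srgb_hex, "#FFFFFF")
})

test_that("colour tables carry metadata and plausible wine colours", {
  bands <- data.frame(center = c(440, 523), width = c(30, 45),
                      amplitude = c(0.1, 0.5))
  s <- generate_aged_spectrum(bands, meta = sample_meta(
    copigment = "CAF", pH = 3.6, molar_ratio = 5, timepoint = "T12"))
  tab <- color_table(list(x1 = s), tables)
  expect_equal(tab$sample_id, "x1")
  expect_equal(tab$pH, 3.6)
  expect_gt(tab$a, 0)   # red
  expect_gt(tab$C, 5)
  expect_lt(tab$L, 100)
  expect_match(tab$srgb_hex, "^#[0-9A-F]{6}$")
})
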