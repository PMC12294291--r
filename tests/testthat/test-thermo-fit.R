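test_that("hyperchromic shift is plain relative absorbance gain", {
  expect_equal(hyperchromic_shift(0.40, 0.40), 0)
  expect_equal(hyperchromic_shift(0.4974, 0.400), 0.2435)
  expect_equal(hyperchromic_shift(0.38, 0.40), -0.05)  # hypochromic allowed
  expect_error(hyperchromic_shift(0.5, 0), "positive")
})

test_that("titration series validates its observations", {
  expect_error(titration_series(0, std_ladder, rep(1, 4)), "positive")
  expect_error(titration_series(1, c(2e-4, 1e-4), c(1.1, 1.2)), "increasing")
  expect_error(titration_series(1, c(-1e-4, 1e-4), c(1.1, 1.2)), "positive")
  s <- titration_series(0.4, std_ladder, c(0.39, 0.42, 0.45, 0.50))
  expect_s3_class(s, "titration_series")  # hypochromic point storable
})

test_that("log-log fit reproduces published regression summaries", {
  tab <- load_shift_table()
  fit_row <- function(cp, ph) {
    r <- tab[tab$copigment == cp & tab$pH == ph, ]
    sh <- as.numeric(r[, c("shift_1_1", "shift_1_5", "shift_1_10",
                           "shift_1_20")])
    fit_copigmentation(titration_series(1, std_ladder, 1 + sh,
                                        copigment = cp, pH = ph))
  }
  # stoichiometry rounds to the printed value
  expect_equal(round(fit_row("CA", 3.6)$n, 2), 0.64)
  # determination coefficient rounds to the printed value
  expect_equal(round(fit_row("CAF", 2.8)$r2, 3), 0.999)
  # Gibbs energy rounds to the printed value
  expect_equal(round(fit_row("CAF", 3.8)$dG0, 2), -5.31)
  expect_equal(round(fit_row("SI", 3.6)$dG0, 2), -9.56)
})

test_that("fit equals the closed-form least-squares oracle", {
  set.seed(5)
  for (rep in 1:10) {
    cp0 <- sort(10^runif(6, -4.5, -2.5))
    sh <- exp(rnorm(6, -2, 0.5))
    s <- titration_series(1, cp0, 1 + sh)
    fit <- fit_copigmentation(s)
    orc <- ols_oracle(log(cp0), log(sh))
    expect_equal(fit$n, unname(orc["slope"]), tolerance = 1e-10)
    expect_equal(fit$lnKeq, unname(orc["intercept"]), tolerance = 1e-10)
    expect_equal(fit$Keq, exp(fit$lnKeq), tolerance = 1e-12)
  }
})

test_that("noiseless 1:1 isotherm is recovered exactly and is ladder-invariant", {
  gen <- function(cp0) titration_series(0.4, cp0, 0.4 * (1 + 50 * cp0))
  f1 <- fit_copigmentation(gen(std_ladder))
  expect_equal(f1$n, 1, tolerance = 1e-6)
  expect_equal(f1$Keq, 50, tolerance = 50 * 1e-6)
  # a different concentration ladder gives the same constant
  f2 <- fit_copigmentation(gen(c(2e-5, 8e-5, 3e-4, 6e-4, 2e-3)))
  expect_equal(f2$Keq, f1$Keq, tolerance = 1e-8)
})

test_that("scaling concentrations by c shifts lnKeq by -n log(c) only", {
  tab <- load_shift_table()
  sh <- as.numeric(tab[1, c("shift_1_1", "shift_1_5", "shift_1_10",
                            "shift_1_20")])
  f1 <- fit_copigmentation(titration_series(1, std_ladder, 1 + sh))
  f2 <- fit_copigmentation(titration_series(1, 2 * std_ladder, 1 + sh))
  expect_equal(f2$n, f1$n, tolerance = 1e-10)
  expect_equal(f2$r2, f1$r2, tolerance = 1e-10)
  expect_equal(f2$lnKeq, f1$lnKeq - f1$n * log(2), tolerance = 1e-10)
})

test_that("non-positive shifts are dropped loudly; degenerate designs error", {
  s <- titration_series(0.4, c(1e-5, std_ladder),
                        c(0.399, 0.4 * (1 + 50 * std_ladder)))
  expect_warning(fit <- fit_copigmentation(s), "non-positive shift")
  expect_equal(fit$points_used, 4L)
  expect_equal(fit$Keq, 50, tolerance = 1e-6)

  few <- titration_series(0.4, std_ladder[1:3],
                          c(0.399, 0.41, 0.42))
  expect_warning(expect_error(fit_copigmentation(few), "fewer than 3"))

  # zero x-variance is impossible through the constructor (strictly
  # increasing cp0), so exercise the guard on a minimal hand-built object
  degen <- structure(list(A0 = 1, cp0 = rep(1e-4, 3), A = c(1.1, 1.2, 1.3),
                          lambda_ref = 523, pigment = "p", copigment = "CA",
                          pH = 3.6, replicate = 1L),
                     class = "titration_series")
  expect_error(fit_copigmentation(degen), "zero variance")
})

test_that("stoichiometry outside 0.5-2 is flagged", {
  cp0 <- std_ladder
  steep <- titration_series(1, cp0, 1 + 1e5 * cp0^2.5)  # n = 2.5
  fit <- fit_copigmentation(steep)
  expect_match(fit$flags, "outside 0.5-2", all = FALSE)
})

test_that("Gibbs energy follows -RT ln(Keq) in kJ/mol", {
  expect_equal(gibbs_free_energy(0), 0)
  expect_equal(round(gibbs_free_energy(3.859455), 2), -9.56)
  expect_equal(round(gibbs_free_energy(log(65)), 2), -10.34)
  expect_error(gibbs_free_energy(NaN), "finite")
  # round trip to numerical precision over a wide range
  x <- seq(-20, 20, length.out = 41)
  expect_equal(gibbs_free_energy(log(exp(x))),
               -8.314 * 298 * x / 1000, tolerance = 1e-12)
  # sign equivalence: dG0 < 0 iff Keq > 1
  expect_true(all((gibbs_free_energy(x) < 0) == (exp(x) > 1)))
})

test_that("replicate combination supports mean-shift and per-replicate fits", {
  cfg <- generator_config(Keq_true = 40, noise_sd_rel = 0.02, pH = 3.6,
                          seed = 99)
  g <- generate_titration(cfg)
  fm <- fit_condition(g$series, method = "mean_shift")
  fr <- fit_condition(g$series, method = "per_replicate")
  expect_equal(fm$Keq, 40, tolerance = 0.15 * 40)
  expect_equal(fr$Keq, 40, tolerance = 0.15 * 40)
  expect_true(is.finite(fr$lnKeq_sd))
  bad <- c(g$series, generate_titration(generator_config(pH = 2.8))$series)
  expect_error(fit_condition(bad), "more than one condition")
})

test_that("thermo table covers all published conditions with negative dG0", {
  res <- run_short_term()
  expect_equal(nrow(res$table), 12L)
  expect_true(all(res$table$dG0_kJ_mol < 0))
  expect_true(all(res$table$flags == ""))
  # remaining cells agree loosely with print (replicate-averaging ambiguity)
  tab <- load_shift_table()
  key <- paste(tab$copigment, tab$pH)
  ord <- match(paste(res$table$copigment, res$table$pH), key)
  expect_true(all(abs(res$table$n - tab$n_printed[ord]) <= 0.06))
  expect_true(all(abs(res$table$dG0_kJ_mol - tab$dG0_printed[ord]) <= 0.4))
})

test_that("table building degrades gracefully", {
  expect_warning(empty <- build_thermo_table(list()), "empty")
  expect_equal(nrow(empty), 0L)
  two <- titration_series(0.4, std_ladder[1:2], c(0.41, 0.42), pH = 3.0)
  ok <- titration_series(0.4, std_ladder, 0.4 * (1 + 30 * std_ladder),
                         copigment = "CA", pH = 3.6)
  tab <- suppressWarnings(build_thermo_table(list(two, ok)))
  expect_equal(nrow(tab), 2L)
  expect_match(tab$flags[tab$pH == 3.0], "fit failed")
  expect_true(is.na(tab$Keq_M[tab$pH == 3.0]))
  expect_false(is.na(tab$Keq_M[tab$pH == 3.6]))
})

test_that("copigments rank by descending Keq with ties and pH guard", {
  mk <- function(cp, keq, ph = 3.6) {
    structure(list(n = 1, lnKeq = log(keq), Keq = keq,
                   dG0 = gibbs_free_energy(log(keq)), r2 = 1, rmse = 0,
                   residuals = numeric(), points_used = 4L,
                   flags = character(), pigment = "Mv-3-O-glc",
                   copigment = cp, pH = ph), class = "thermo_fit_result")
  }
  rk <- rank_copigments(list(mk("CA", 26.6), mk("CAF", 65), mk("SI", 48.5)))
  expect_equal(rk$copigment, c("CAF", "SI", "CA"))
  expect_equal(rk$rank, 1:3)
  expect_equal(rank_copigments(list(mk("CAF", 65)))$rank, 1L)
  tied <- rank_copigments(list(mk("CA", 30.0), mk("SI", 30.5)))
  expect_equal(tied$rank, c(1L, 1L))
  expect_error(rank_copigments(list(mk("CA", 30, 3.2), mk("SI", 40, 3.6))),
               "mixed pH")
})
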