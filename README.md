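# copigmentr

Thermodynamics and colour of anthocyanin copigmentation in model wine.

Red-wine colour depends on malvidin-3-O-glucoside (Mv-3-O-glc), whose red
flavylium form is mostly lost to hydration at wine pH. Colourless
polyphenols — caffeic acid (CAF), (+)-catechin (CA), syringic acid (SI) —
stack onto the flavylium and pull the equilibrium back toward colour.
`copigmentr` is for researchers in wine/phytochemistry who quantify that
effect from UV-Vis spectra:

* **Association thermodynamics.** The hyperchromic shift at the 523 nm
  maximum is linearised as

  `ln[(A − A₀)/A₀] = ln K_eq + n·ln [Cp]₀`,

  fitted by OLS to give the association constant `K_eq` (M⁻¹), apparent
  stoichiometry `n`, and `ΔG⁰ = −RT·ln K_eq` (kJ mol⁻¹, T = 298 K).
* **Spectral toolbox.** CSV I/O (long/wide), Savitzky–Golay smoothing with
  truncated edge windows, linear interpolation, parabolic sub-nanometre
  peak refinement, 440/510 nm band ratios.
* **Colorimetry.** Transmittance → CIE XYZ (illuminant D65, 1964 10°
  observer) → CIELAB with chroma `C*`, signed hue `H*`, and sRGB swatches;
  plus a validation mode auditing printed Lab tables against the
  `C* = √(a*²+b*²)` and `H* = atan2(b*, a*)` identities.
* **Group statistics.** Levene and Shapiro–Wilk checks, one-way ANOVA,
  Tukey HSD (studentized-range, Tukey–Kramer) with compact-letter display.
* **Synthetic data.** A seeded generator for titrations (flavylium pH
  decay × 1:n binding isotherm × multiplicative shift noise) and aged
  spectra (sum of Gaussians with closed-form band values), so the entire
  pipeline runs and is tested without instrument data.

## Worked example

Refit the packaged table of published mean hyperchromic shifts (three
copigments × four pH values, final copigment concentrations
5×10⁻⁵–10⁻³ M):

```r
library(copigmentr)
res <- run_short_term()
res$table[, c("copigment", "pH", "r2", "n", "Keq_M", "dG0_kJ_mol")]
#>    copigment  pH     r2      n  Keq_M dG0_kJ_mol
#> 1        CAF 2.8 0.9994 0.7514 16.637     -6.966
#> 2        CAF 3.2 0.9858 0.7235 22.986     -7.767
#> 3        CAF 3.6 0.9962 0.8027 58.955    -10.101
#> ...
#> 7         CA 3.6 0.9952 0.6351 24.213     -7.896
#> 11        SI 3.6 0.9904 0.7399 47.439     -9.562
```

Every condition gives `ΔG⁰ < 0`: the association is always spontaneous,
strongest at pH 3.6, and the copigments at that pH rank

```r
rank_copigments(Filter(function(f) f$pH == 3.6, res$fits))
#>    copigment    Keq_M dG0_kJ_mol rank
#>          CAF 58.95542 -10.100520    1
#>           SI 47.43852  -9.562027    2
#>           CA 24.21318  -7.895767    3
```

i.e. CAF > SI > CA, with slopes `n` near unity (≈1:1 complexes).
Colour of an aged, yellow-shifted solution:

```r
bands <- data.frame(center = c(440, 510), width = c(35, 25),
                    amplitude = c(0.50, 0.21))
s <- generate_aged_spectrum(bands)
spectrum_color(s)
#> <color_result> L* 91.46  a* 7.73  b* 42.34  C* 43.04  H* 79.65  #FFDF96
band_ratio(s)   # 440/510 nm yellow-to-red index
#> [1] 1.823...
```

The `analysis/` directory holds the narrative drivers
(`01_simulate_titrations.R` … `04_ratio_anova.R`) that run the full
pipeline — simulation, thermodynamic tables and figures, colour
validation, ratio ANOVA with Tukey letters — writing their tables under
`results/`.

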