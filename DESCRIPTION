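Package: copigmentr
Title: Anthocyanin Copigmentation Thermodynamics and Colour in Model Wine
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to quantify anthocyanin-copigment association in model wine
    solutions from UV-Vis spectra. Implements the hyperchromic-shift log-log
    linearisation of the 1:n binding isotherm to estimate the association
    constant (Keq), apparent stoichiometry (n) and standard Gibbs free energy,
    CIE XYZ/CIELAB colorimetry (illuminant D65, 10 degree observer) of
    transmittance spectra with chroma, hue angle and sRGB swatches, one-way
    ANOVA with Tukey HSD compact-letter grouping of 440/510 nm band ratios,
    and a synthetic spectra generator emulating flavylium pH equilibria and
    aged-pigment bands so the full pipeline is testable without instrument
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    stats,
    tools,
    utils
Suggests:
    car,
    ggplot2,
    jsonlite,
    signal,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
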