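# Independent oracles used across tests.

# Closed-form two-moment least squares (slope = Sxy/Sxx, intercept by the
# means) — independent of the lm-based fitting path.
ols_oracle <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  c(intercept = mean(y) - slope * mean(x), slope = slope)
}

# Gaussian absorbance band sampled on a grid.
gaussian_spectrum <- function(center, width, amplitude = 1, grid = 300:700,
                              meta = sample_meta()) {
  spectrum(grid, amplitude * exp(-0.5 * ((grid - center) / width)^2),
           meta = meta)
}

# Concentration ladder of the standard titration design (final M).
std_ladder <- c(1, 5, 10, 20) * 5e-5
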