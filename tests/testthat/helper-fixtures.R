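# Small fixtures shared across tests: a coarse 10-deg field keeps the unit
# tests fast; acceptance tests use the full-scale defaults.

small_grid <- function() make_grid(fieldExtentDeg = 10, nSamples = 21)

small_stim <- function(...) {
  generate_aperture(bar_sweep_spec(secondsPerSweep = 6, ...), small_grid())
}

quick_config <- function(...) {
  fit_config(gridX = seq(-4, 4, by = 2), gridY = seq(-4, 4, by = 2),
             gridSigma = c(0.5, 1, 2, 4),
             xlim = c(-10, 10), ylim = c(-10, 10), sigmalim = c(0.1, 8),
             nStarts = 2, ...)
}

# independent O(n*k) direct-summation convolution oracle
conv_oracle <- function(x, k) {
  n <- length(x)
  y <- numeric(n)
  for (t in seq_len(n)) {
    acc <- 0
    for (j in seq_len(min(t, length(k)))) acc <- acc + k[j] * x[t - j + 1]
    y[t] <- acc
  }
  y
}
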