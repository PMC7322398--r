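# Independent numerical oracles used to freeze expected values.

# Modified Bessel function of the first kind by direct series summation,
# independent of base R's besselI.
bessel_series <- function(x, nu, terms = 60) {
  k <- 0:(terms - 1)
  sum((x / 2)^(2 * k + nu) / (factorial(k) * factorial(k + nu)))
}

# Uniform-disk fractional recovery from the series oracle.
recovery_series <- function(t, w, D) {
  x <- 2 * (w^2 / (4 * D)) / t
  exp(-x) * (bessel_series(x, 0) + bessel_series(x, 1))
}

# Convenience: noise-free exponential-model trace at given truth.
make_exp_trace <- function(D_true = 1, sigma_noise = 0, seed = NULL, ...) {
  generate_trace(sim_config(D_true = D_true, sigma_noise = sigma_noise,
                            curve_model = "exponential_model", seed = seed,
                            ...))
}

# Convenience: ring image with absolute ring value over a background.
make_ring_fixture <- function(ring_value = 50, background = 5, radius = 20,
                              half_band = 1.5, size = 64) {
  rows <- matrix(seq_len(size), size, size)
  cols <- t(rows)
  ctr <- (size + 1) / 2
  dist <- sqrt((rows - ctr)^2 + (cols - ctr)^2)
  img <- matrix(background, size, size)
  img[abs(dist - radius) <= half_band] <- ring_value
  img
}
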