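# Small fixtures built in code; kept deliberately tiny so the suite stays fast.

# single-class uniform phantom: one lipid band over a constant baseline
uniform_phantom <- function(n = 60, pitch = 20, amplitude = 0.4, baseline = 0.05) {
  prof <- spectral_profile("uniform",
                           spectral_band(2926, 60, amplitude),
                           baseline = baseline)
  tissue_phantom(matrix(1L, n, n), pitch, list("1" = prof))
}

# two-class phantom: left half class 1, right half class 2
split_phantom <- function(n = 40, pitch = 20) {
  labels <- matrix(1L, n, n)
  labels[, (n / 2 + 1):n] <- 2L
  profs <- list(
    "1" = spectral_profile("low", spectral_band(2926, 60, 0.3), baseline = 0.04),
    "2" = spectral_profile("high", spectral_band(2926, 60, 0.8), baseline = 0.05))
  tissue_phantom(labels, pitch, profs)
}

expect_matrix_equal <- function(a, b, tol = 1e-12) {
  expect_true(is.matrix(a) && is.matrix(b))
  expect_equal(dim(a), dim(b))
  expect_lt(max(abs(a - b)), tol)
}
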