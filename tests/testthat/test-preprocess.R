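test_that("absorbance conversion inverts the decade law", {
  ibg <- matrix(2, 10, 10)
  expect_matrix_equal(to_absorbance(ibg, ibg)$values, matrix(0, 10, 10))
  expect_matrix_equal(to_absorbance(ibg / 10, ibg)$values, matrix(1, 10, 10))
  expect_error(to_absorbance(ibg, matrix(c(-1, rep(1, 99)), 10, 10)),
               "row 1, col 1")
})

test_that("noiseless scan output recovers the phantom absorbance exactly", {
  ph <- split_phantom(n = 30)
  scan <- simulate_mir_scan(ph, scanner_config(noise_sd = 0), seed = 1)
  imgs <- mir_absorbance(scan)
  for (k in 1:4) {
    wn <- scan$config$lasers$wavenumber[k]
    truth <- phantom_absorbance_map(ph, wn)
    expect_lt(max(abs(imgs[[as.character(k)]]$values - truth)), 1e-9)
  }
})

test_that("threshold adjustment amplifies weak signals continuously", {
  x <- matrix(c(0.1, 0.8), 10, 10)
  # gain 1 is the identity
  expect_matrix_equal(threshold_adjust(x, gain = 1), x)
  # constant image unchanged
  expect_matrix_equal(threshold_adjust(matrix(0.3, 5, 5), gain = 3),
                      matrix(0.3, 5, 5))
  # two-level oracle: threshold 0.5, gain 2 -> low level doubled, high kept
  y <- threshold_adjust(x, gain = 2, threshold = 0.5)
  expect_equal(unique(y[x == 0.1]), 0.2)
  expect_equal(unique(y[x == 0.8]), 0.8)
  # monotone non-decreasing over a dense grid
  g <- matrix(seq(0, 1, length.out = 100), 10, 10)
  yg <- threshold_adjust(g, gain = 3, threshold = 0.4)
  expect_true(all(diff(yg[order(g)]) >= -1e-12))
})

test_that("adaptive TV denoising suppresses flat-region noise and keeps edges", {
  set.seed(11)
  f <- matrix(0.2, 100, 100); f[, 51:100] <- 0.8
  noisy <- f + matrix(stats::rnorm(1e4, sd = 0.1), 100, 100)
  den <- tv_denoise_adaptive(noisy)
  flat <- cbind(rep(1:100, 30), rep(6:35, each = 100))
  reduction <- 1 - stats::var(den[flat] - f[flat]) / stats::var(noisy[flat] - f[flat])
  expect_gte(reduction, 0.5)
  # 50% crossing of the edge moves by at most one pixel
  crossing <- which(colMeans(den) > 0.5)[1L]
  expect_lte(abs(crossing - 51L), 1L)
  # output range bounded by input range
  expect_gte(min(den), min(noisy))
  expect_lte(max(den), max(noisy))
  # identity cases
  expect_matrix_equal(tv_denoise_adaptive(noisy, strength = 0), noisy)
  expect_matrix_equal(tv_denoise_adaptive(matrix(0.4, 20, 20)), matrix(0.4, 20, 20))
  expect_matrix_equal(tv_denoise_adaptive(f), f)  # noise-free: sigma-hat = 0
})

test_that("robust normalization is affine-invariant and idempotent", {
  set.seed(3)
  x <- matrix(stats::runif(400, 2, 4), 20, 20)
  n1 <- normalize_image(x, 0, 100)
  expect_equal(range(n1), c(0, 1))
  expect_matrix_equal(normalize_image(n1, 0, 100), n1)
  expect_matrix_equal(normalize_image(3 * x - 1, 5, 95), normalize_image(x, 5, 95))
  expect_error(normalize_image(matrix(1, 5, 5)), "degenerate")
})

test_that("cube preprocessing smooths, normalizes and restricts the axis", {
  ph <- split_phantom(n = 10)
  cube <- simulate_ftir(ph, ftir_config(pixel_pitch_um = 20), seed = 1)
  # default ranges on the 407-channel axis: enumeration oracle
  keep_n <- sum((cube$wavenumbers >= 750 & cube$wavenumbers <= 1500) |
                  (cube$wavenumbers >= 2500 & cube$wavenumbers <= 4000))
  proc <- preprocess_cube(cube)
  expect_equal(dim(proc$data)[3L], keep_n)
  # every pixel spectrum has unit norm after window-1 full-range processing
  p1 <- preprocess_cube(cube, smooth_window = 1L, ranges = list(c(750, 4000)))
  norms <- sqrt(apply(p1$data^2, c(1, 2), sum))
  expect_matrix_equal(norms, matrix(1, 10, 10), tol = 1e-9)
  # a constant spectrum is invariant under smoothing
  const <- hyper_cube(array(0.7, c(3, 3, 21)), seq(3000, by = -8, length.out = 21), 20)
  sm <- preprocess_cube(const, smooth_window = 5L, ranges = list(c(0, 5000)),
                        vector_norm = FALSE)
  expect_matrix_equal(sm$data[, , 10L], matrix(0.7, 3, 3))
  expect_error(preprocess_cube(cube, ranges = list(c(100, 200))),
               "removes every channel")
})

test_that("cross-correlation alignment recovers constructed shifts", {
  set.seed(9)
  a <- matrix(stats::runif(2500), 50, 50)
  expect_equal(attr(align_images(list(a, a)), "shifts")[2L, ], c(0, 0))
  b <- a[c(48:50, 1:47), c(3:50, 1:2)]  # content moved by (+3, -2), circular
  al <- align_images(list(a, b))
  expect_equal(attr(al, "shifts")[2L, ], c(3, -2))
  expect_matrix_equal(al[[2L]][5:45, 5:45], a[5:45, 5:45])
  # pure-noise pair: failure signalled, inputs unchanged
  n1 <- matrix(stats::rnorm(2500), 50, 50)
  n2 <- matrix(stats::rnorm(2500), 50, 50)
  expect_warning(r <- align_images(list(n1, n2)), "alignment failure")
  expect_true(isTRUE(attr(r, "alignment_failed")))
  expect_identical(r[[2L]], n2)
})

test_that("affine transforms are applied with bilinear interpolation", {
  ramp <- outer(seq_len(30), seq_len(30), function(i, j) 0.02 * i + 0.01 * j)
  # identity transform
  tr <- rbind(c(1, 0, 0), c(0, 1, 0))
  out <- align_images(list(ramp), transform = tr)
  expect_matrix_equal(out[[1L]], ramp, tol = 1e-9)
  # pure translation by (2, 1): affine fields are interpolated exactly
  tr2 <- rbind(c(1, 0, 2), c(0, 1, 1))
  out2 <- align_images(list(ramp), transform = tr2)[[1L]]
  expect_matrix_equal(out2[1:27, 1:28], ramp[3:29, 2:29], tol = 1e-9)
})

test_that("the MIR chain preserves shape and logs its stage order", {
  ph <- split_phantom(n = 20)
  scan <- simulate_mir_scan(ph, scanner_config(noise_sd = 0.02), seed = 1)
  prep <- preprocess_mir(scan)
  expect_named(prep, c("images", "manifest"))
  expect_equal(prep$manifest$chain,
               c("absorbance", "align", "threshold_adjust", "tv_denoise",
                 "normalize"))
  for (img in prep$images) {
    expect_equal(dim(img$values), c(20L, 20L))
    expect_gte(min(img$values), 0)
    expect_lte(max(img$values), 1)
  }
})
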