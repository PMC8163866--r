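test_that("scan geometry arithmetic is exact", {
  expect_identical(samples_per_line(1, 20, 10), 5000L)
  expect_identical(samples_per_line(1, 20, 1), 500L)
  expect_identical(samples_per_line(2, 25, 2), 1600L)
  expect_error(samples_per_line(1, 30, 10), "integer multiple")

  expect_equal(implied_sample_rate(5.3, 20, 10), 2.65)
  expect_equal(implied_sample_rate(1, 1, 1), 1)
  expect_equal(implied_sample_rate(5.3, 20, 1), 0.265)

  g <- pixel_grid(c(10, 10), 20)
  expect_equal(g$total_pixels, 250000L)
  expect_equal(pixel_grid(c(10, 10), 25)$total_pixels, 160000L)
  expect_equal(pixel_grid(c(1, 1), 20)$total_pixels, 2500L)
  expect_error(pixel_grid(c(10, 10), 30), "integer multiple")
})

test_that("geometry quantities are dimensionally consistent", {
  # samples per line / sample rate = line traversal time = length / velocity
  v <- 5.3; res <- 20; f <- 10; len_cm <- 1
  n <- samples_per_line(len_cm, res, f)
  rate <- implied_sample_rate(v, res, f) * 1e6
  expect_equal(n / rate, (len_cm / 100) / v)
  # halving the resolution quadruples the pixel count
  expect_equal(pixel_grid(c(10, 10), 10)$total_pixels,
               4L * pixel_grid(c(10, 10), 20)$total_pixels)
})

test_that("wavenumber-wavelength conversion matches the laser table", {
  expect_equal(round(wavenumber_to_wavelength(2790), 1), 3.6)
  expect_equal(round(wavenumber_to_wavelength(2926), 1), 3.4)
  expect_equal(round(wavenumber_to_wavelength(3350), 1), 3.0)
  expect_equal(round(wavenumber_to_wavelength(3700), 1), 2.7)
  expect_equal(wavenumber_to_wavelength(10000), 1)
  expect_error(wavenumber_to_wavelength(0), "> 0")
})

test_that("noiseless MIR scan follows the Beer-Lambert closed form", {
  ph <- uniform_phantom(n = 20, amplitude = 0.4, baseline = 0.05)
  cfg <- scanner_config(noise_sd = 0, slide_reflectance = 0.9, i0 = 2)
  scan <- simulate_mir_scan(ph, cfg, seed = 1)
  a <- evaluate_absorbance(ph$profiles[["1"]], cfg$lasers$wavenumber)
  for (k in seq_len(4L)) {
    id <- as.character(cfg$lasers$id[k])
    expect_matrix_equal(scan$images[[id]],
                        matrix(2 * 0.9 * 10^(-a[k]), 20, 20))
    expect_matrix_equal(scan$background[[id]], matrix(2 * 0.9, 20, 20))
  }
  # deterministic given the seed even with noise
  cfgn <- scanner_config(noise_sd = 0.05)
  s1 <- simulate_mir_scan(ph, cfgn, seed = 3)
  s2 <- simulate_mir_scan(ph, cfgn, seed = 3)
  expect_identical(s1$images, s2$images)
})

test_that("oversampling reduces pixel noise by one over root f", {
  ph <- uniform_phantom(n = 120)
  s10 <- simulate_mir_scan(ph, scanner_config(noise_sd = 0.1, oversampling = 10),
                           seed = 2)
  s1 <- simulate_mir_scan(ph, scanner_config(noise_sd = 0.1, oversampling = 1),
                          seed = 3)
  ratio <- stats::sd(s10$images[["2"]]) / stats::sd(s1$images[["2"]])
  expect_lt(abs(ratio - 1 / sqrt(10)) / (1 / sqrt(10)), 0.1)
})

test_that("the lipid target laser is darkest over white matter", {
  ph <- make_brain_phantom(c(4, 4), 20, seed = 1)
  scan <- simulate_mir_scan(ph, scanner_config(noise_sd = 0.02), seed = 1)
  wm <- ph$labels == 2L
  m <- vapply(scan$images, function(img) mean(img[wm]), numeric(1L))
  expect_equal(names(which.min(m)), "2")
})

test_that("FT-IR axis and noiseless cube match the forward model", {
  ph <- uniform_phantom(n = 8, pitch = 25)
  cube <- simulate_ftir(ph, ftir_config(), seed = 1)
  expect_length(cube$wavenumbers, 407L)
  expect_equal(cube$wavenumbers[407L], 752)
  expect_equal(cube$wavenumbers[1L], 4000)
  # noiseless: every channel equals the class absorbance exactly
  a <- evaluate_absorbance(ph$profiles[["1"]], cube$wavenumbers)
  for (ch in c(1L, 135L, 407L))
    expect_matrix_equal(cube$data[, , ch], matrix(a[ch], 8, 8))
})

test_that("accumulations reduce FT-IR noise by one over root n", {
  ph <- uniform_phantom(n = 100, pitch = 20)
  cfg <- function(acc) ftir_config(wavenumber_max = 3000, wavenumber_min = 2950,
                                   spectral_spacing = 8, pixel_pitch_um = 20,
                                   accumulations = acc, noise_sd = 0.1)
  f2 <- simulate_ftir(ph, cfg(2L), seed = 4)
  f1 <- simulate_ftir(ph, cfg(1L), seed = 5)
  ratio <- stats::sd(f2$data[, , 1L]) / stats::sd(f1$data[, , 1L])
  expect_lt(abs(ratio - 1 / sqrt(2)) / (1 / sqrt(2)), 0.1)
})

test_that("scan field must fit the phantom and match its pitch", {
  ph <- uniform_phantom(n = 20, pitch = 20)  # 0.4 x 0.4 mm
  expect_error(simulate_mir_scan(ph, scanner_config(field_mm = c(1, 1)), 1),
               "exceeds the phantom")
  expect_error(simulate_mir_scan(ph, scanner_config(spatial_resolution_um = 25)),
               "must divide")
})
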