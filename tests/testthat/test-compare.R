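test_that("bilinear grid resampling is exact for affine fields", {
  x <- matrix(stats::runif(400), 20, 20)
  expect_identical(resample_to_grid(x, 20, 20), x)
  cst <- resample_to_grid(matrix(0.4, 20, 20), 25, 20)
  expect_matrix_equal(cst, matrix(0.4, nrow(cst), ncol(cst)))
  ramp <- outer(seq(0, 1, length.out = 40), seq(0, 2, length.out = 50), "+")
  out <- resample_to_grid(ramp, 25, 20)
  rr <- ((seq_len(nrow(out)) - 0.5) * 20) / 25 + 0.5
  cc <- ((seq_len(ncol(out)) - 0.5) * 20) / 25 + 0.5
  expect_matrix_equal(out, outer((rr - 1) / 39, (cc - 1) / 49 * 2, "+"),
                      tol = 1e-6)
})

test_that("SSIM satisfies its metric identities", {
  set.seed(4)
  x <- matrix(stats::runif(900), 30, 30)
  y <- matrix(stats::runif(900), 30, 30)
  expect_equal(ssim(x, x), 1)
  expect_equal(ssim(x, y), ssim(y, x))
  expect_gte(ssim(x, y), -1); expect_lte(ssim(x, y), 1)
  expect_equal(mse(x, x), 0)
  expect_equal(mse(x, y), mse(y, x))
  # anti-correlated checkerboard scores negative
  cb <- matrix(rep_len(c(0, 1), 900), 30, 30)
  expect_lt(ssim(cb, 1 - cb), 0)
  # common rescale with matching data_range leaves SSIM unchanged
  expect_equal(ssim(2 * x, 2 * y, data_range = 2), ssim(x, y))
  # intensity-only difference: score drops, structure term stays at 1
  comp <- ssim(x, 0.5 * x, components = TRUE)
  expect_lt(comp$ssim, 0.9)
  expect_gt(comp$structure, 0.999)
  expect_error(ssim(x, y, window = 31L), "exceeds the image")
})

test_that("noiseless same-phantom channels are identical across modalities", {
  ph <- make_brain_phantom(c(2, 2), 20, seed = 1)
  scan <- simulate_mir_scan(ph, scanner_config(noise_sd = 0), seed = 1)
  cube <- simulate_ftir(ph, ftir_config(wavenumber_max = 4000,
                                        wavenumber_min = 2700,
                                        spectral_spacing = 2,
                                        pixel_pitch_um = 20, noise_sd = 0),
                        seed = 1)
  rep <- channel_similarity(mir_absorbance(scan), cube,
                            wavenumbers = c(2790, 2926, 3350))
  expect_lt(abs(rep$mean_ssim - 1), 1e-6)
  expect_true(all(rep$table$mse < 1e-12))
  # a wavenumber farther from the axis than its spacing is a matching error
  narrow <- hyper_cube(cube$data[, , 1:10], cube$wavenumbers[1:10], 20)
  expect_error(channel_similarity(mir_absorbance(scan), narrow,
                                  wavenumbers = 2926), "beyond")
})

test_that("label concordance matches permuted labels and scores disjoint maps", {
  lab <- matrix(c(rep(0L, 40), rep(1L, 30), rep(2L, 30)), 10, 10)
  mk <- function(l) structure(list(labels = l, k = 3L,
                                   centroids = matrix(0, 3, 1), seed = 1L,
                                   rejected = integer(0),
                                   sizes = tabulate(l + 1L), wcss = 0),
                              class = "label_map")
  a <- mk(lab)
  conc <- label_concordance(a, a)
  expect_true(all(conc$matching$dice == 1))
  expect_equal(conc$ari, 1)
  # permuted labels: perfect after matching
  perm <- lab; perm[lab == 0L] <- 2L; perm[lab == 1L] <- 0L; perm[lab == 2L] <- 1L
  conc2 <- label_concordance(a, mk(perm))
  expect_true(all(conc2$matching$dice == 1))
  expect_equal(conc2$ari, 1)
  # spatially disjoint single-cluster maps have zero overlap
  l1 <- matrix(-1L, 10, 10); l1[1:5, ] <- 0L
  l2 <- matrix(-1L, 10, 10); l2[6:10, ] <- 0L
  m1 <- mk(l1); m1$k <- 1L
  m2 <- mk(l2); m2$k <- 1L
  expect_equal(label_concordance(m1, m2)$matching$dice, 0)
})

test_that("throughput accounting reproduces the printed scan comparison", {
  tr <- throughput_report(field_mm = c(10, 10),
                          mir_config = scanner_config(), mir_time_s = 3,
                          ftir_cfg = ftir_config(), ftir_time_s = 675)
  expect_equal(tr$mir$pixels, 250000L)
  expect_equal(tr$mir$values_total, 1000000L)
  expect_equal(tr$ftir$pixels, 160000L)
  expect_equal(tr$time_ratio, 225)
  expect_equal(tr$data_ratio, tr$ftir$values_total / 1e6)
  # with equal pitches the data ratio reduces to the channel ratio
  tr2 <- throughput_report(c(10, 10), scanner_config(), 3,
                           ftir_config(pixel_pitch_um = 20), 675,
                           ftir_channels = 100L)
  expect_equal(tr2$data_ratio, 100 / 4)
  expect_error(throughput_report(c(10, 10), scanner_config(), 0,
                                 ftir_config(), 675), "> 0")
})

test_that("dice and boundary Hausdorff behave on known masks", {
  a <- matrix(FALSE, 20, 20); a[5:15, 5:15] <- TRUE
  expect_equal(dice_coefficient(a, a), 1)
  b <- matrix(FALSE, 20, 20); b[7:17, 5:15] <- TRUE
  expect_equal(boundary_hausdorff(a, b), 2)
  expect_equal(boundary_hausdorff(a, a), 0)
})
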