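test_that("brain phantom has the requested geometry and is seeded", {
  ph <- make_brain_phantom(c(10, 10), 20, seed = 1)
  expect_equal(dim(ph$labels), c(500L, 500L))
  expect_setequal(unique(as.vector(ph$labels)), 0:3)
  # deterministic for a fixed seed
  expect_identical(make_brain_phantom(c(10, 10), 20, seed = 1)$labels, ph$labels)
  # different seed jitters the geometry
  expect_false(identical(make_brain_phantom(c(10, 10), 20, seed = 2)$labels,
                         ph$labels))
  # every pixel carries exactly one class (integer partition of the grid)
  expect_true(all(ph$labels %in% 0:3))
})

test_that("hippocampal pixel fraction matches the frozen regression value", {
  # value computed once by direct pixel counting on the default geometry
  ph <- make_brain_phantom(c(10, 10), 20, seed = 1)
  expect_equal(mean(ph$labels == 3L), 0.017688, tolerance = 1e-9)
})

test_that("liver nodule has the requested equivalent-disc diameter", {
  # irregularity 0: exact disc of 3 mm diameter = 150 px at 20 um
  ph0 <- make_liver_phantom(c(10, 10), 20, nodule_diameter_mm = 3,
                            margin_irregularity = 0, seed = 2)
  d0 <- 2 * sqrt(sum(ph0$labels == 2L) / pi)
  expect_lt(abs(d0 - 150), 1)
  # irregular margin perturbs the boundary but roughly preserves the area
  ph1 <- make_liver_phantom(c(10, 10), 20, nodule_diameter_mm = 3,
                            margin_irregularity = 0.5, seed = 2)
  d1 <- 2 * sqrt(sum(ph1$labels == 2L) / pi)
  expect_lt(abs(d1 - 150) / 150, 0.05)
  expect_false(identical(ph0$labels, ph1$labels))
  # seeded reproducibility
  expect_identical(
    make_liver_phantom(c(10, 10), 20, margin_irregularity = 0.5, seed = 2)$labels,
    ph1$labels)
})

test_that("graded margin adds a transition class between tumour and healthy", {
  ph <- make_liver_phantom(c(8, 8), 20, margin_width_mm = 0.12, seed = 1)
  expect_setequal(unique(as.vector(ph$labels)), 0:3)
  # margin spectra lie between healthy and tumour at the C-H band
  a <- class_absorbance_table(ph, 2926)
  expect_gt(a["3", ], a["1", ])
  expect_lt(a["3", ], a["2", ])
})

test_that("impossible geometries are rejected", {
  expect_error(make_brain_phantom(c(1, 1), 20), "smaller than the structure")
  expect_error(make_liver_phantom(c(4, 4), 20, nodule_diameter_mm = 5),
               "does not fit")
  expect_error(make_brain_phantom(c(10, 10), 200), "outside")
  expect_error(tissue_phantom(matrix(1L, 3, 3), 20, profiles = list()),
               "no spectral profile")
})

test_that("phantom serialization round-trips labels and profiles", {
  ph <- make_brain_phantom(c(3, 3), 25, water_fraction = 0.2, seed = 4)
  dir <- withr::local_tempdir()
  write_phantom(ph, dir)
  expect_true(all(file.exists(file.path(dir,
    c("labels.tif", "profiles.csv", "phantom.yaml")))))
  back <- read_phantom(dir)
  expect_identical(back$labels, ph$labels)
  expect_equal(back$water_fraction, 0.2)
  wn <- c(2790, 2926, 3350, 3700)
  for (id in names(ph$profiles))
    expect_equal(evaluate_absorbance(back$profiles[[id]], wn),
                 evaluate_absorbance(ph$profiles[[id]], wn))
})
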