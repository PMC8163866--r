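# Synthetic tissue phantoms: a 2D class-label raster on a physical grid plus
# one absorbance profile per class. Label 0 is the bare (mirrored) slide.
# Phantoms stand in for the real specimens the scanner was built for: a
# coronal brain section with grey matter, white matter and a curved
# hippocampal band, and a liver section with an infiltrating ~3 mm tumour
# nodule. Geometry is schematic by design: only the class topology and the
# class spectra matter to the measurements.

#' Construct a tissue phantom
#'
#' @param labels Integer matrix; 0 = bare slide background, 1..C = tissue
#'   classes. Row axis is the translation-stage direction, column axis the
#'   mirror-line direction; row-major, 0-based pixel indexing in all
#'   serialized coordinates.
#' @param pixel_pitch_um Grid pitch in micrometres.
#' @param profiles Named list mapping class id (as character) to
#'   [spectral_profile()].
#' @param water_fraction Scalar in \[0, 1\]: residual-water level. Scales a
#'   broad O-H band added to every tissue class; 0 is the dried condition.
#' @return A `tissue_phantom` object.
#' @export
tissue_phantom <- function(labels, pixel_pitch_um, profiles, water_fraction = 0) {
  if (!is.matrix(labels)) stopf("`labels` must be a matrix")
  storage.mode(labels) <- "integer"
  assert_scalar_num(pixel_pitch_um, "pixel_pitch_um", lower = 1e-9)
  assert_scalar_num(water_fraction, "water_fraction", lower = 0, upper = 1)
  ids <- sort(unique(as.vector(labels)))
  ids <- ids[ids != 0L]
  missing <- setdiff(as.character(ids), names(profiles))
  if (length(missing))
    stopf("no spectral profile for class id(s): %s", paste(missing, collapse = ", "))
  structure(list(labels = labels, pixel_pitch_um = pixel_pitch_um,
                 profiles = profiles, water_fraction = water_fraction),
            class = "tissue_phantom")
}

#' @export
print.tissue_phantom <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf(
    "<tissue_phantom> %d x %d px @ %g um (%.2f x %.2f mm), %d classes, water %.2f\n",
    d[1L], d[2L], x$pixel_pitch_um, d[1L] * x$pixel_pitch_um / 1e3,
    d[2L] * x$pixel_pitch_um / 1e3, length(x$profiles), x$water_fraction))
  tab <- table(factor(x$labels, levels = c(0L, as.integer(names(x$profiles)))))
  lbl <- c("background", vapply(x$profiles, `[[`, "", "label"))
  for (i in seq_along(tab))
    cat(sprintf("  %-14s %8d px\n", lbl[i], tab[i]))
  invisible(x)
}

#' Effective per-class profiles with the residual-water band applied
#' @noRd
effective_profiles <- function(phantom) {
  lapply(phantom$profiles, add_water_band, water_fraction = phantom$water_fraction)
}

#' Per-class absorbance table at given wavenumbers
#'
#' Rows: background (class 0, absorbance 0) then each tissue class;
#' columns: wavenumbers. Includes the water band per `water_fraction`.
#'
#' @param phantom A [tissue_phantom()].
#' @param wavenumbers Numeric vector in cm^-1.
#' @return Numeric matrix `(1 + n_classes) x n_wavenumbers` with rownames
#'   `"0"` and the class ids.
#' @export
class_absorbance_table <- function(phantom, wavenumbers) {
  prof <- effective_profiles(phantom)
  tab <- rbind("0" = rep(0, length(wavenumbers)),
               do.call(rbind, lapply(prof, evaluate_absorbance,
                                     wavenumbers = wavenumbers)))
  rownames(tab) <- c("0", names(prof))
  tab
}

#' Ground-truth absorbance map of a phantom at one wavenumber
#'
#' @param phantom A [tissue_phantom()].
#' @param wavenumber Scalar wavenumber in cm^-1.
#' @return Matrix of absorbance (AU), 0 on the bare slide.
#' @export
phantom_absorbance_map <- function(phantom, wavenumber) {
  assert_scalar_num(wavenumber, "wavenumber")
  tab <- class_absorbance_table(phantom, wavenumber)
  lut <- numeric(max(as.integer(rownames(tab))) + 1L)
  lut[as.integer(rownames(tab)) + 1L] <- tab[, 1L]
  m <- matrix(lut[phantom$labels + 1L], nrow(phantom$labels), ncol(phantom$labels))
  m
}

# Coordinate grids in normalized units: u along columns, v along rows, both
# centred on the field and scaled by the field extent.
phantom_grid <- function(field_mm, pixel_pitch_um) {
  n_r <- round(field_mm[1L] * 1e3 / pixel_pitch_um)
  n_c <- round(field_mm[2L] * 1e3 / pixel_pitch_um)
  rr <- ((seq_len(n_r) - 0.5) / n_r) - 0.5
  cc <- ((seq_len(n_c) - 0.5) / n_c) - 0.5
  list(n_r = n_r, n_c = n_c,
       v = matrix(rr, n_r, n_c), u = matrix(cc, n_r, n_c, byrow = TRUE))
}

check_phantom_geometry <- function(field_mm, pixel_pitch_um) {
  if (length(field_mm) != 2L || any(!is.finite(field_mm)))
    stopf("`field_mm` must be two finite numbers (rows mm, cols mm)")
  if (any(field_mm < 2))
    stopf("field %g x %g mm is smaller than the structure scale (min 2 x 2 mm)",
          field_mm[1L], field_mm[2L])
  assert_scalar_num(pixel_pitch_um, "pixel_pitch_um", lower = 5, upper = 100)
}

#' Generate a coronal-brain-like phantom
#'
#' A schematic brain section: an elliptical grey-matter section on a bare
#' slide, an arched white-matter band (corpus-callosum-like) and, nested
#' inside it, a curved hippocampal band embedded in grey matter. Class
#' spectra come from [brain_profiles()]. Geometry is deterministic given
#' `seed` (the seed jitters centre positions and axis lengths by up to 2%).
#'
#' @param field_mm Field size (rows mm, cols mm), each >= 2 mm.
#' @param pixel_pitch_um Pitch in \[5, 100\] um.
#' @param water_fraction Residual water in \[0, 1\]; default 0 (dried).
#' @param seed Integer RNG seed.
#' @return A [tissue_phantom()] with classes 1 grey, 2 white, 3 hippocampus.
#' @examples
#' ph <- make_brain_phantom(c(4, 4), 40, seed = 1)
#' table(ph$labels)
#' @export
make_brain_phantom <- function(field_mm = c(10, 10), pixel_pitch_um = 20,
                               water_fraction = 0, seed = 1) {
  check_phantom_geometry(field_mm, pixel_pitch_um)
  g <- phantom_grid(field_mm, pixel_pitch_um)
  with_seed(seed, {
    j <- stats::runif(6L, -0.02, 0.02)
    labels <- matrix(0L, g$n_r, g$n_c)
    u <- g$u; v <- g$v
    # grey-matter section
    sec <- (u / (0.42 + j[1L]))^2 + (v / (0.42 + j[2L]))^2 <= 1
    labels[sec] <- 1L
    # white-matter arch, open at the bottom
    uc <- u - j[3L]; vc <- v + 0.02 + j[4L]
    rho_w <- sqrt((uc / 0.30)^2 + (vc / 0.22)^2)
    arch_w <- abs(rho_w - 1) <= 0.06 & vc < 0.12 & sec
    labels[arch_w] <- 2L
    # hippocampal band nested inside the arch
    uh <- u - j[5L]; vh <- v + 0.02 + j[6L]
    rho_h <- sqrt((uh / 0.21)^2 + (vh / 0.145)^2)
    band_h <- abs(rho_h - 1) <= 0.07 & vh < 0.07 & sec
    labels[band_h] <- 3L
    tissue_phantom(labels, pixel_pitch_um, brain_profiles(),
                   water_fraction = water_fraction)
  })
}

#' Generate a liver phantom with a tumour nodule
#'
#' Homogeneous healthy liver tissue filling an elliptical section, with a
#' tumour nodule of the requested diameter placed toward the left lobe. The
#' nodule boundary is perturbed by seeded low-frequency radial harmonics
#' scaled by `margin_irregularity` (0 gives an exact disc), emulating the
#' infiltrating character of the tumour margin. With `margin_width_mm > 0` a
#' graded transition class (spectral mean of healthy and tumour) surrounds
#' the nodule.
#'
#' @param field_mm Field size (rows mm, cols mm), each >= 2 mm.
#' @param pixel_pitch_um Pitch in \[5, 100\] um.
#' @param nodule_diameter_mm Nodule equivalent-disc diameter (default 3 mm).
#' @param margin_irregularity Scalar in \[0, 1\]; relative amplitude of the
#'   low-frequency boundary perturbation.
#' @param margin_width_mm Width of the graded margin class (default 0: sharp
#'   healthy/tumour boundary).
#' @param water_fraction Residual water in \[0, 1\].
#' @param seed Integer RNG seed.
#' @return A [tissue_phantom()] with classes 1 healthy, 2 tumour and, when
#'   `margin_width_mm > 0`, 3 margin.
#' @export
make_liver_phantom <- function(field_mm = c(10, 10), pixel_pitch_um = 20,
                               nodule_diameter_mm = 3, margin_irregularity = 0.3,
                               margin_width_mm = 0, water_fraction = 0, seed = 1) {
  check_phantom_geometry(field_mm, pixel_pitch_um)
  assert_scalar_num(margin_irregularity, "margin_irregularity", 0, 1)
  assert_scalar_num(margin_width_mm, "margin_width_mm", lower = 0)
  assert_scalar_num(nodule_diameter_mm, "nodule_diameter_mm", lower = 1e-9)
  g <- phantom_grid(field_mm, pixel_pitch_um)
  # physical coordinates in mm, origin at field centre
  x <- g$u * field_mm[2L]
  y <- g$v * field_mm[1L]
  centre_x <- -0.18 * field_mm[2L]
  r_nodule <- nodule_diameter_mm / 2
  sec_a <- 0.46 * field_mm[2L]; sec_b <- 0.46 * field_mm[1L]
  reach <- abs(centre_x) + r_nodule * (1 + 0.15 * margin_irregularity) + margin_width_mm
  if (reach > min(sec_a, sec_b))
    stopf("nodule (diameter %g mm + margin %g mm) does not fit inside the %g x %g mm section",
          nodule_diameter_mm, margin_width_mm, field_mm[1L], field_mm[2L])
  with_seed(seed, {
    labels <- matrix(0L, g$n_r, g$n_c)
    sec <- (x / sec_a)^2 + (y / sec_b)^2 <= 1
    labels[sec] <- 1L
    # radial low-frequency perturbation of the nodule boundary
    theta <- atan2(y, x - centre_x)
    pert <- 0
    if (margin_irregularity > 0) {
      kk <- 2:5
      amp <- stats::rnorm(length(kk))
      phs <- stats::runif(length(kk), 0, 2 * pi)
      s <- 0
      for (i in seq_along(kk)) s <- s + amp[i] * cos(kk[i] * theta + phs[i])
      s_max <- max(abs(range(s)))
      pert <- margin_irregularity * 0.15 * s / s_max
    }
    rad <- sqrt((x - centre_x)^2 + y^2)
    edge <- r_nodule * (1 + pert)
    nod <- rad <= edge & sec
    labels[nod] <- 2L
    if (margin_width_mm > 0) {
      marg <- rad > edge & rad <= edge + margin_width_mm & sec
      labels[marg] <- 3L
    }
    tissue_phantom(labels, pixel_pitch_um,
                   liver_profiles(with_margin = margin_width_mm > 0),
                   water_fraction = water_fraction)
  })
}

#' Serialize a phantom to disk
#'
#' Writes three plain files under `dir`: `labels.tif` (single-channel TIFF of
#' class ids), `profiles.csv` (class_id, class_label, band_center, band_sigma,
#' band_amplitude, baseline; one row per band), and `phantom.yaml`
#' (pixel pitch, water fraction, raster shape).
#'
#' @param phantom A [tissue_phantom()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_label_tiff(phantom$labels, file.path(dir, "labels.tif"))
  rows <- list()
  for (id in names(phantom$profiles)) {
    p <- phantom$profiles[[id]]
    for (b in p$bands)
      rows[[length(rows) + 1L]] <- data.frame(
        class_id = as.integer(id), class_label = p$label,
        band_center = b$center, band_sigma = b$sigma,
        band_amplitude = b$amplitude, baseline = p$baseline)
  }
  utils::write.csv(do.call(rbind, rows), file.path(dir, "profiles.csv"),
                   row.names = FALSE)
  yaml::write_yaml(list(pixel_pitch_um = phantom$pixel_pitch_um,
                        water_fraction = phantom$water_fraction,
                        n_rows = nrow(phantom$labels),
                        n_cols = ncol(phantom$labels)),
                   file.path(dir, "phantom.yaml"))
  invisible(dir)
}

#' Read a phantom written by [write_phantom()]
#' @param dir Directory containing `labels.tif`, `profiles.csv`, `phantom.yaml`.
#' @return A [tissue_phantom()].
#' @export
read_phantom <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "phantom.yaml"))
  labels <- read_label_tiff(file.path(dir, "labels.tif"))
  tab <- utils::read.csv(file.path(dir, "profiles.csv"))
  profiles <- list()
  for (id in unique(tab$class_id)) {
    sub <- tab[tab$class_id == id, , drop = FALSE]
    bands <- Map(spectral_band, sub$band_center, sub$band_sigma, sub$band_amplitude)
    profiles[[as.character(id)]] <- spectral_profile(
      sub$class_label[1L], unname(bands), baseline = sub$baseline[1L])
  }
  tissue_phantom(labels, meta$pixel_pitch_um, profiles,
                 water_fraction = meta$water_fraction)
}
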