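# Virtual instruments. The flying-spot MIR scanner sweeps a focused beam
# along lines (column axis) while a translation stage advances row by row;
# four distributed-feedback lasers are fired sequentially and the detector is
# time-sampled, giving `oversampling` raw readings per 20 um pixel. The FT-IR
# imager acquires a full absorbance spectrum per pixel. Both instruments see
# the same phantom through a Beer-Lambert forward model relative to the bare
# mirrored slide: I = I0 * R_slide * 10^(-A) * (1 + eps), with eps the
# relative intensity noise per raw sample. Transflection's double pass is
# folded into the effective absorbance A, since only the sample/background
# ratio is observable.

#' Default laser channel table
#'
#' The scanner's four-wavenumber set: a reference/target pair on the lipid
#' C-H band and a reference/target pair on the protein amide-A N-H band.
#'
#' @return data.frame with columns `id` (1..4), `wavenumber` (cm^-1), `role`.
#' @export
laser_channels <- function() {
  data.frame(
    id = 1:4,
    wavenumber = c(2790, 2926, 3350, 3700),
    role = c("reference-lipid", "target-lipid", "target-protein",
             "reference-protein"),
    stringsAsFactors = FALSE)
}

#' Flying-spot scanner configuration
#'
#' @param lasers Laser table as from [laser_channels()].
#' @param mirror_velocity_mps Line-scan mirror velocity in m/s (default 5.3).
#' @param spatial_resolution_um Pixel pitch in um (default 20).
#' @param oversampling Raw detector samples per pixel (integer >= 1,
#'   default 10); pixel values are the arithmetic mean of their samples.
#' @param line_offset_cm Acceleration offset discarded at each line end in cm
#'   (default 0.5); affects timing accounting only.
#' @param field_mm Scan extent (rows mm, cols mm); `NULL` = full phantom.
#' @param noise_sd Relative intensity noise sd per raw sample (default 0).
#' @param slide_reflectance Bare-slide reflectance in (0, 1\] (default 1).
#' @param i0 Source intensity scale (arbitrary units, default 1).
#' @return A `scanner_config` object.
#' @export
scanner_config <- function(lasers = laser_channels(), mirror_velocity_mps = 5.3,
                           spatial_resolution_um = 20, oversampling = 10L,
                           line_offset_cm = 0.5, field_mm = NULL,
                           noise_sd = 0, slide_reflectance = 1, i0 = 1) {
  stopifnot(is.data.frame(lasers),
            all(c("id", "wavenumber") %in% names(lasers)))
  assert_scalar_num(mirror_velocity_mps, "mirror_velocity_mps", lower = 1e-9)
  assert_scalar_num(spatial_resolution_um, "spatial_resolution_um", lower = 1e-9)
  if (oversampling < 1 || oversampling != round(oversampling))
    stopf("`oversampling` must be an integer >= 1")
  assert_scalar_num(line_offset_cm, "line_offset_cm", lower = 0)
  assert_scalar_num(noise_sd, "noise_sd", lower = 0)
  assert_scalar_num(slide_reflectance, "slide_reflectance", lower = 1e-9, upper = 1)
  structure(list(lasers = lasers, mirror_velocity_mps = mirror_velocity_mps,
                 spatial_resolution_um = spatial_resolution_um,
                 oversampling = as.integer(oversampling),
                 line_offset_cm = line_offset_cm, field_mm = field_mm,
                 noise_sd = noise_sd, slide_reflectance = slide_reflectance,
                 i0 = i0),
            class = "scanner_config")
}

#' FT-IR imager configuration
#'
#' @param wavenumber_max,wavenumber_min Spectral range in cm^-1
#'   (defaults 4000 down to 750).
#' @param spectral_spacing Channel spacing in cm^-1 (default 8).
#' @param pixel_pitch_um Pixel pitch in um (default 25).
#' @param accumulations Independent accumulations averaged per measurement
#'   point (default 2).
#' @param field_mm Scan extent (rows mm, cols mm); `NULL` = full phantom.
#' @param noise_sd Relative intensity noise sd per accumulation (default 0).
#' @return An `ftir_config` object.
#' @export
ftir_config <- function(wavenumber_max = 4000, wavenumber_min = 750,
                        spectral_spacing = 8, pixel_pitch_um = 25,
                        accumulations = 2L, field_mm = NULL, noise_sd = 0) {
  assert_scalar_num(wavenumber_max, "wavenumber_max")
  assert_scalar_num(wavenumber_min, "wavenumber_min")
  if (wavenumber_max <= wavenumber_min)
    stopf("`wavenumber_max` must exceed `wavenumber_min`")
  assert_scalar_num(spectral_spacing, "spectral_spacing", lower = 1e-9)
  assert_scalar_num(pixel_pitch_um, "pixel_pitch_um", lower = 1e-9)
  if (accumulations < 1 || accumulations != round(accumulations))
    stopf("`accumulations` must be an integer >= 1")
  assert_scalar_num(noise_sd, "noise_sd", lower = 0)
  structure(list(wavenumber_max = wavenumber_max, wavenumber_min = wavenumber_min,
                 spectral_spacing = spectral_spacing,
                 pixel_pitch_um = pixel_pitch_um,
                 accumulations = as.integer(accumulations),
                 field_mm = field_mm, noise_sd = noise_sd),
            class = "ftir_config")
}

#' Raw samples per scan line
#'
#' `count = line_length / spatial_resolution * oversampling`, required to be
#' an exact integer (no silent rounding of the scan geometry).
#'
#' @param line_length_cm Line length in cm.
#' @param spatial_resolution_um Pixel pitch in um.
#' @param oversampling Samples per pixel.
#' @return Integer sample count.
#' @examples
#' samples_per_line(1, 20, 10)  # 5000
#' @export
samples_per_line <- function(line_length_cm, spatial_resolution_um, oversampling) {
  assert_scalar_num(line_length_cm, "line_length_cm", lower = 1e-9)
  assert_scalar_num(spatial_resolution_um, "spatial_resolution_um", lower = 1e-9)
  assert_scalar_num(oversampling, "oversampling", lower = 1)
  px <- line_length_cm * 1e4 / spatial_resolution_um
  if (abs(px - round(px)) > 1e-9)
    stopf("line length %g cm is not an integer multiple of the %g um resolution",
          line_length_cm, spatial_resolution_um)
  as.integer(round(px) * oversampling)
}

#' Detector sample rate implied by the scan geometry
#'
#' `rate = mirror_velocity / spatial_resolution * oversampling`, in
#' megasamples per second.
#'
#' @param mirror_velocity_mps Mirror velocity in m/s.
#' @param spatial_resolution_um Pixel pitch in um.
#' @param oversampling Samples per pixel.
#' @return Sample rate in MS/s.
#' @examples
#' implied_sample_rate(5.3, 20, 10)  # 2.65 MS/s
#' @export
implied_sample_rate <- function(mirror_velocity_mps, spatial_resolution_um,
                                oversampling) {
  assert_scalar_num(mirror_velocity_mps, "mirror_velocity_mps", lower = 1e-9)
  assert_scalar_num(spatial_resolution_um, "spatial_resolution_um", lower = 1e-9)
  assert_scalar_num(oversampling, "oversampling", lower = 1)
  mirror_velocity_mps / (spatial_resolution_um * 1e-6) * oversampling / 1e6
}

#' Pixel grid of a scan field
#'
#' @param field_mm Extent (rows mm, cols mm); each an integer multiple of the
#'   resolution.
#' @param spatial_resolution_um Pixel pitch in um.
#' @return List `n_rows`, `n_cols`, `total_pixels`.
#' @examples
#' pixel_grid(c(10, 10), 20)$total_pixels  # 250000
#' @export
pixel_grid <- function(field_mm, spatial_resolution_um) {
  if (length(field_mm) != 2L) stopf("`field_mm` must have two elements")
  assert_scalar_num(spatial_resolution_um, "spatial_resolution_um", lower = 1e-9)
  n <- field_mm * 1e3 / spatial_resolution_um
  if (any(abs(n - round(n)) > 1e-9))
    stopf("field %g x %g mm is not an integer multiple of the %g um resolution",
          field_mm[1L], field_mm[2L], spatial_resolution_um)
  n <- as.integer(round(n))
  list(n_rows = n[1L], n_cols = n[2L], total_pixels = n[1L] * n[2L])
}

#' Convert wavenumber to wavelength
#'
#' @param wavenumber Wavenumber(s) in cm^-1 (> 0).
#' @return Wavelength in um (`1e4 / wavenumber`).
#' @examples
#' wavenumber_to_wavelength(c(2790, 2926, 3350, 3700))
#' @export
wavenumber_to_wavelength <- function(wavenumber) {
  if (any(wavenumber <= 0)) stopf("wavenumber must be > 0")
  1e4 / wavenumber
}

#' Line and stage timing implied by a scanner configuration
#'
#' Line traversal time is `(line_length + 2 * line_offset) / mirror_velocity`;
#' the implied stage speed is one resolution step per line time. The real
#' instrument's duty cycle (flyback, bidirectionality) is not modelled, so
#' these are lower bounds on wall-clock scan time.
#'
#' @param config A [scanner_config()] with `field_mm` set, or an explicit
#'   `line_length_cm` via the second argument.
#' @param line_length_cm Optional explicit line length in cm.
#' @return List `line_time_s`, `stage_speed_mmps`, `total_time_s` (per laser).
#' @export
scan_timing <- function(config, line_length_cm = NULL) {
  stopifnot(inherits(config, "scanner_config"))
  if (is.null(line_length_cm)) {
    if (is.null(config$field_mm)) stopf("no field or line length given")
    line_length_cm <- config$field_mm[2L] / 10
  }
  swept_cm <- line_length_cm + 2 * config$line_offset_cm
  line_time <- (swept_cm / 100) / config$mirror_velocity_mps
  n_lines <- if (!is.null(config$field_mm))
    pixel_grid(config$field_mm, config$spatial_resolution_um)$n_rows else NA_integer_
  list(line_time_s = line_time,
       stage_speed_mmps = (config$spatial_resolution_um / 1e3) / line_time,
       total_time_s = if (is.na(n_lines)) NA_real_ else n_lines * line_time)
}

# Map the scan grid onto phantom cells: returns the integer label matrix seen
# at scan resolution. The phantom pitch must divide the scan resolution; the
# scan pixel reads the phantom cell at its centre.
scan_labels <- function(phantom, resolution_um, field_mm) {
  if (is.null(field_mm))
    field_mm <- dim(phantom$labels) * phantom$pixel_pitch_um / 1e3
  fac <- resolution_um / phantom$pixel_pitch_um
  if (abs(fac - round(fac)) > 1e-9 || fac < 1)
    stopf("phantom pitch %g um must divide the scan resolution %g um",
          phantom$pixel_pitch_um, resolution_um)
  fac <- as.integer(round(fac))
  g <- pixel_grid(field_mm, resolution_um)
  need <- c(g$n_rows, g$n_cols) * fac
  if (any(need > dim(phantom$labels)))
    stopf("scan field %g x %g mm exceeds the phantom extent",
          field_mm[1L], field_mm[2L])
  ri <- (seq_len(g$n_rows) - 1L) * fac + (fac + 1L) %/% 2L
  ci <- (seq_len(g$n_cols) - 1L) * fac + (fac + 1L) %/% 2L
  phantom$labels[ri, ci, drop = FALSE]
}

#' Simulate a four-laser flying-spot MIR scan
#'
#' For each laser (sequentially, with independent noise streams), raw samples
#' `I0 * R_slide * 10^(-A) * (1 + eps)` with `eps ~ N(0, noise_sd)` are drawn
#' at `oversampling` positions per pixel and averaged into the pixel value. A
#' bare-slide background raster (`A = 0`) is acquired identically per laser,
#' mirroring the instrument's per-laser reference measurement. All rasters
#' share one perfectly co-registered grid.
#'
#' @param phantom A [tissue_phantom()] whose pitch divides the scan
#'   resolution.
#' @param config A [scanner_config()].
#' @param seed Integer RNG seed; output is deterministic given it.
#' @return A `mir_scan_set`: `images` and `background` (named lists of
#'   matrices keyed by laser id), `config`, `seed`.
#' @export
simulate_mir_scan <- function(phantom, config = scanner_config(), seed = 1) {
  stopifnot(inherits(phantom, "tissue_phantom"),
            inherits(config, "scanner_config"))
  lab <- scan_labels(phantom, config$spatial_resolution_um, config$field_mm)
  tab <- class_absorbance_table(phantom, config$lasers$wavenumber)
  lut_ids <- as.integer(rownames(tab))
  n_px <- length(lab)
  f <- config$oversampling
  scale <- config$i0 * config$slide_reflectance
  images <- background <- list()
  with_seed(seed, {
    for (k in seq_len(nrow(config$lasers))) {
      id <- as.character(config$lasers$id[k])
      lut <- numeric(max(lut_ids) + 1L)
      lut[lut_ids + 1L] <- tab[, k]
      a_map <- matrix(lut[lab + 1L], nrow(lab), ncol(lab))
      for (what in c("sample", "background")) {
        base <- if (what == "sample") scale * 10^(-a_map)
                else matrix(scale, nrow(lab), ncol(lab))
        if (config$noise_sd > 0) {
          eps <- matrix(stats::rnorm(n_px * f, sd = config$noise_sd), n_px, f)
          img <- as.vector(base) * (1 + rowMeans(eps))
          img <- matrix(img, nrow(lab), ncol(lab))
        } else img <- base
        if (what == "sample") images[[id]] <- img else background[[id]] <- img
      }
    }
  })
  structure(list(images = images, background = background, config = config,
                 seed = as.integer(seed)),
            class = "mir_scan_set")
}

#' @export
print.mir_scan_set <- function(x, ...) {
  d <- dim(x$images[[1L]])
  cat(sprintf("<mir_scan_set> %d laser(s), %d x %d px @ %g um, noise sd %g, seed %d\n",
              length(x$images), d[1L], d[2L],
              x$config$spatial_resolution_um, x$config$noise_sd, x$seed))
  invisible(x)
}

#' Construct a hyperspectral cube
#'
#' @param data 3D array rows x cols x channels of absorbance (AU).
#' @param wavenumbers Strictly decreasing channel axis in cm^-1, length equal
#'   to the number of channels.
#' @param pixel_pitch_um Pixel pitch in um.
#' @return A `hyper_cube` object.
#' @export
hyper_cube <- function(data, wavenumbers, pixel_pitch_um) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  if (dim(data)[3L] != length(wavenumbers))
    stopf("channel count %d does not match wavenumber axis length %d",
          dim(data)[3L], length(wavenumbers))
  if (length(wavenumbers) > 1L && any(diff(wavenumbers) >= 0))
    stopf("wavenumber axis must be strictly decreasing")
  assert_scalar_num(pixel_pitch_um, "pixel_pitch_um", lower = 1e-9)
  structure(list(data = data, wavenumbers = as.numeric(wavenumbers),
                 pixel_pitch_um = pixel_pitch_um),
            class = "hyper_cube")
}

#' @export
print.hyper_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<hyper_cube> %d x %d px @ %g um, %d channels (%g..%g cm-1)\n",
              d[1L], d[2L], x$pixel_pitch_um, d[3L],
              x$wavenumbers[1L], x$wavenumbers[d[3L]]))
  invisible(x)
}

#' FT-IR channel axis for a configuration
#' @noRd
ftir_axis <- function(config) {
  n <- floor((config$wavenumber_max - config$wavenumber_min) /
               config$spectral_spacing) + 1L
  config$wavenumber_max - config$spectral_spacing * (seq_len(n) - 1L)
}

#' Simulate an FT-IR hyperspectral image
#'
#' Per pixel and channel, `accumulations` independent intensity draws
#' `10^(-A) * (1 + eps)` are averaged and converted back to absorbance
#' `-log10(mean I)`. With `noise_sd = 0` every channel equals the phantom's
#' class absorbance exactly. The channel axis descends from `wavenumber_max`
#' in `spectral_spacing` steps down to the last value >= `wavenumber_min`.
#'
#' @param phantom A [tissue_phantom()] whose pitch divides the pixel pitch.
#' @param config An [ftir_config()].
#' @param seed Integer RNG seed.
#' @return A [hyper_cube()] of absorbance.
#' @export
simulate_ftir <- function(phantom, config = ftir_config(), seed = 1) {
  stopifnot(inherits(phantom, "tissue_phantom"), inherits(config, "ftir_config"))
  lab <- scan_labels(phantom, config$pixel_pitch_um, config$field_mm)
  wn <- ftir_axis(config)
  tab <- class_absorbance_table(phantom, wn)
  lut_ids <- as.integer(rownames(tab))
  n_px <- length(lab)
  acc <- config$accumulations
  cube <- array(0, c(nrow(lab), ncol(lab), length(wn)))
  with_seed(seed, {
    for (ch in seq_along(wn)) {
      lut <- numeric(max(lut_ids) + 1L)
      lut[lut_ids + 1L] <- tab[, ch]
      a <- lut[as.vector(lab) + 1L]
      if (config$noise_sd > 0) {
        eps <- matrix(stats::rnorm(n_px * acc, sd = config$noise_sd), n_px, acc)
        intens <- 10^(-a) * (1 + rowMeans(eps))
        a <- -log10(pmax(intens, .Machine$double.eps))
      }
      cube[, , ch] <- a
    }
  })
  hyper_cube(cube, wn, config$pixel_pitch_um)
}
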