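# File formats: single-channel TIFF for 2D rasters (float32 with a YAML
# sidecar carrying the affine scale, since TIFF float storage is [0,1]),
# ENVI-style band-sequential binary + text header for hyperspectral cubes
# (bit-exact round trip), CSV for tables, YAML for configuration and
# manifests. Pixel coordinates are 0-based, row-major; ROIs are half-open.

#' Write a numeric raster as float TIFF with a scale sidecar
#'
#' Values are affinely mapped to \[0, 1\] for storage; the offset/scale pair
#' is recorded in `<path>.yaml` so [read_raster_tiff()] restores the
#' original values (to float32 precision).
#'
#' @param m Numeric matrix.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_raster_tiff <- function(m, path) {
  stopifnot(is.matrix(m), all(is.finite(m)))
  off <- min(m)
  sc <- max(m) - off
  if (sc == 0) sc <- 1
  tiff::writeTIFF((m - off) / sc, path, bits.per.sample = 32L)
  yaml::write_yaml(list(offset = off, scale = sc,
                        n_rows = nrow(m), n_cols = ncol(m)),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' Read a raster written by [write_raster_tiff()]
#' @param path TIFF path (expects `<path>.yaml` next to it).
#' @return Numeric matrix.
#' @export
read_raster_tiff <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  m * meta$scale + meta$offset
}

# Integer label rasters as 8-bit TIFF; stored value = (label + 1) / 255 so
# that -1 (rejected) and 0 (background) survive. Labels must lie in [-1, 254].
write_label_tiff <- function(labels, path) {
  stopifnot(is.matrix(labels), all(labels >= -1L), all(labels <= 254L))
  tiff::writeTIFF((labels + 1L) / 255, path, bits.per.sample = 8L)
  invisible(path)
}

read_label_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  storage.mode(m) <- "double"
  out <- matrix(as.integer(round(m * 255)) - 1L, nrow(m), ncol(m))
  out
}

#' Write a hyperspectral cube in ENVI band-sequential layout
#'
#' Produces `<path>` (raw little-endian doubles, band-sequential, each band
#' row-major) and `<path>.hdr` (ENVI-style text header with samples, lines,
#' bands, data type 5, the wavelength axis in cm^-1 and the pixel pitch).
#' The round trip through [read_cube()] is bit-exact.
#'
#' @param cube A [hyper_cube()].
#' @param path Output binary path (header written next to it).
#' @return `path`, invisibly.
#' @export
write_cube <- function(cube, path) {
  stopifnot(inherits(cube, "hyper_cube"))
  d <- dim(cube$data)
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  for (ch in seq_len(d[3L]))
    writeBin(as.vector(t(cube$data[, , ch])), con, size = 8L,
             endian = "little")
  hdr <- c(
    "ENVI",
    "description = { mirscan hyperspectral cube }",
    sprintf("samples = %d", d[2L]),
    sprintf("lines = %d", d[1L]),
    sprintf("bands = %d", d[3L]),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 5",
    "interleave = bsq",
    "byte order = 0",
    "wavelength units = cm-1",
    sprintf("pixel size um = %.10g", cube$pixel_pitch_um),
    sprintf("wavelength = { %s }",
            paste(format(cube$wavenumbers, digits = 15), collapse = ", ")))
  writeLines(hdr, paste0(path, ".hdr"))
  invisible(path)
}

# Parse "key = value" / "key = { ... }" pairs from an ENVI header.
parse_envi_header <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  out <- list()
  # braced values may span lines
  pat <- gregexpr("([a-zA-Z ][a-zA-Z0-9 ]*?)\\s*=\\s*(\\{[^}]*\\}|[^\n]*)", txt)
  for (m in regmatches(txt, pat)[[1L]]) {
    key <- trimws(sub("=.*$", "", m))
    val <- trimws(sub("^[^=]*=", "", m))
    out[[tolower(key)]] <- val
  }
  out
}

#' Read an ENVI-style cube written by [write_cube()]
#'
#' @param path Binary path with `<path>.hdr` next to it.
#' @return A [hyper_cube()].
#' @export
read_cube <- function(path) {
  hdr_path <- paste0(path, ".hdr")
  if (!file.exists(hdr_path)) stopf("missing header %s", hdr_path)
  h <- parse_envi_header(hdr_path)
  need <- c("samples", "lines", "bands", "data type", "interleave")
  miss <- setdiff(need, names(h))
  if (length(miss)) stopf("header lacks: %s", paste(miss, collapse = ", "))
  samples <- as.integer(h$samples); lines <- as.integer(h$lines)
  bands <- as.integer(h$bands)
  if (h[["data type"]] != "5" || tolower(h$interleave) != "bsq")
    stopf("only data type 5 (double) bsq cubes are supported")
  expect_bytes <- as.numeric(samples) * lines * bands * 8
  got <- file.size(path)
  if (is.na(got) || got != expect_bytes)
    stopf("binary size mismatch: header implies %d x %d x %d x 8 = %.0f bytes, file has %.0f",
          lines, samples, bands, expect_bytes, got)
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  raw <- readBin(con, "double", n = samples * lines * bands, size = 8L,
                 endian = "little")
  cube <- array(0, c(lines, samples, bands))
  for (ch in seq_len(bands)) {
    off <- (ch - 1L) * samples * lines
    cube[, , ch] <- matrix(raw[off + seq_len(samples * lines)],
                           lines, samples, byrow = TRUE)
  }
  wl <- if (!is.null(h$wavelength))
    as.numeric(strsplit(gsub("[{}]", "", h$wavelength), ",")[[1L]])
  else rev(seq_len(bands))
  pitch <- if (!is.null(h[["pixel size um"]])) as.numeric(h[["pixel size um"]]) else 1
  hyper_cube(cube, wl, pitch)
}

#' Serialize a MIR scan set
#'
#' One float TIFF per laser image plus one per background raster, and a
#' `scan.yaml` sidecar with the laser table, geometry, noise level and seed.
#'
#' @param scan A `mir_scan_set`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_mir_scan <- function(scan, dir) {
  stopifnot(inherits(scan, "mir_scan_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (id in names(scan$images)) {
    write_raster_tiff(scan$images[[id]],
                      file.path(dir, sprintf("laser_%s.tif", id)))
    write_raster_tiff(scan$background[[id]],
                      file.path(dir, sprintf("background_%s.tif", id)))
  }
  cfg <- scan$config
  yaml::write_yaml(list(
    lasers = lapply(seq_len(nrow(cfg$lasers)), function(i)
      as.list(cfg$lasers[i, ])),
    mirror_velocity_mps = cfg$mirror_velocity_mps,
    spatial_resolution_um = cfg$spatial_resolution_um,
    oversampling = cfg$oversampling,
    line_offset_cm = cfg$line_offset_cm,
    noise_sd = cfg$noise_sd,
    slide_reflectance = cfg$slide_reflectance,
    i0 = cfg$i0,
    seed = scan$seed), file.path(dir, "scan.yaml"))
  invisible(dir)
}

#' Read a MIR scan set written by [write_mir_scan()]
#' @param dir Directory with `laser_*.tif`, `background_*.tif`, `scan.yaml`.
#' @return A `mir_scan_set`.
#' @export
read_mir_scan <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "scan.yaml"))
  lasers <- do.call(rbind, lapply(meta$lasers, as.data.frame))
  cfg <- scanner_config(lasers = lasers,
                        mirror_velocity_mps = meta$mirror_velocity_mps,
                        spatial_resolution_um = meta$spatial_resolution_um,
                        oversampling = meta$oversampling,
                        line_offset_cm = meta$line_offset_cm,
                        noise_sd = meta$noise_sd,
                        slide_reflectance = meta$slide_reflectance,
                        i0 = meta$i0)
  images <- background <- list()
  for (id in as.character(lasers$id)) {
    images[[id]] <- read_raster_tiff(file.path(dir, sprintf("laser_%s.tif", id)))
    background[[id]] <- read_raster_tiff(
      file.path(dir, sprintf("background_%s.tif", id)))
  }
  structure(list(images = images, background = background, config = cfg,
                 seed = meta$seed),
            class = "mir_scan_set")
}

#' Write a label map (indexed TIFF + centroid CSV)
#'
#' @param map A `label_map`.
#' @param dir Output directory; writes `labels.tif`, `centroids.csv`,
#'   `labelmap.yaml`.
#' @return `dir`, invisibly.
#' @export
write_label_map <- function(map, dir) {
  stopifnot(inherits(map, "label_map"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_label_tiff(map$labels, file.path(dir, "labels.tif"))
  utils::write.csv(data.frame(cluster = seq_len(nrow(map$centroids)) - 1L,
                              map$centroids),
                   file.path(dir, "centroids.csv"), row.names = FALSE)
  yaml::write_yaml(list(k = map$k, seed = map$seed,
                        rejected = as.list(map$rejected),
                        sizes = as.list(map$sizes)),
                   file.path(dir, "labelmap.yaml"))
  invisible(dir)
}
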