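# Cross-modality comparison: put MIR laser images and matched FT-IR channels
# on one grid, score their structural similarity (SSIM) and MSE, quantify
# segmentation concordance, and account for the scan-time / data-load
# advantage of the discrete-band scanner.

#' Bilinear resampling onto a new pixel pitch
#'
#' Resamples over the shared physical extent; destination pixel centres are
#' interpolated (and, at the border, linearly extrapolated) from the source
#' cell centres, so affine intensity fields survive a pitch change exactly.
#'
#' @param image Matrix or [absorbance_image()].
#' @param src_pitch_um,dst_pitch_um Source and destination pitch in um.
#' @return Matrix (or [absorbance_image()]) on the destination grid.
#' @export
resample_to_grid <- function(image, src_pitch_um, dst_pitch_um) {
  assert_scalar_num(src_pitch_um, "src_pitch_um", lower = 1e-9)
  assert_scalar_num(dst_pitch_um, "dst_pitch_um", lower = 1e-9)
  out <- map_image(image, function(m) {
    if (src_pitch_um == dst_pitch_um) return(m)
    ext_r <- nrow(m) * src_pitch_um
    ext_c <- ncol(m) * src_pitch_um
    n_r <- max(1L, floor(ext_r / dst_pitch_um + 1e-9))
    n_c <- max(1L, floor(ext_c / dst_pitch_um + 1e-9))
    # destination pixel centres in source matrix coordinates
    rr <- ((seq_len(n_r) - 0.5) * dst_pitch_um) / src_pitch_um + 0.5
    cc <- ((seq_len(n_c) - 0.5) * dst_pitch_um) / src_pitch_um + 0.5
    matrix(bilinear_sample(m, rep(rr, times = n_c), rep(cc, each = n_r)),
           n_r, n_c)
  })
  if (inherits(out, "absorbance_image")) out$pixel_pitch_um <- dst_pitch_um
  out
}

#' Mean squared error between two rasters
#' @param a,b Matrices (or [absorbance_image()]s) of equal shape.
#' @return Scalar MSE.
#' @export
mse <- function(a, b) {
  a <- image_values(a); b <- image_values(b)
  stopifnot(all(dim(a) == dim(b)))
  mean((a - b)^2)
}

#' Structural similarity index
#'
#' Standard windowed SSIM (luminance x contrast x structure with the usual
#' stabilizers C1 = (0.01 L)^2, C2 = (0.03 L)^2, C3 = C2/2) over a uniform
#' `window` x `window` moving window, averaged over the interior (a border
#' of half a window is excluded).
#'
#' @param a,b Matrices (or [absorbance_image()]s) of equal shape.
#' @param window Odd window side (default 7); must fit inside the image.
#' @param data_range Dynamic range L of the data (default 1 for normalized
#'   images).
#' @param components Also return the mean luminance, contrast and structure
#'   terms.
#' @return Scalar mean SSIM in \[-1, 1\], or (with `components = TRUE`) a
#'   list `ssim`, `luminance`, `contrast`, `structure`.
#' @export
ssim <- function(a, b, window = 7L, data_range = 1, components = FALSE) {
  a <- image_values(a); b <- image_values(b)
  stopifnot(all(dim(a) == dim(b)))
  if (window %% 2L != 1L || window < 3L) stopf("`window` must be odd and >= 3")
  if (window > min(dim(a)))
    stopf("window %d exceeds the image extent %d x %d", window, nrow(a), ncol(a))
  assert_scalar_num(data_range, "data_range", lower = 1e-12)
  c1 <- (0.01 * data_range)^2
  c2 <- (0.03 * data_range)^2
  c3 <- c2 / 2
  mu_a <- box_mean(a, window); mu_b <- box_mean(b, window)
  va <- pmax(box_mean(a^2, window) - mu_a^2, 0)
  vb <- pmax(box_mean(b^2, window) - mu_b^2, 0)
  cab <- box_mean(a * b, window) - mu_a * mu_b
  lum <- (2 * mu_a * mu_b + c1) / (mu_a^2 + mu_b^2 + c1)
  con <- (2 * sqrt(va) * sqrt(vb) + c2) / (va + vb + c2)
  str <- (cab + c3) / (sqrt(va) * sqrt(vb) + c3)
  h <- (window - 1L) %/% 2L
  rows <- (h + 1L):(nrow(a) - h); cols <- (h + 1L):(ncol(a) - h)
  s <- lum * con * str
  if (!components) return(mean(s[rows, cols]))
  list(ssim = mean(s[rows, cols]), luminance = mean(lum[rows, cols]),
       contrast = mean(con[rows, cols]), structure = mean(str[rows, cols]))
}

#' Per-wavenumber similarity between MIR images and an FT-IR cube
#'
#' For each requested wavenumber the matching MIR laser image and the
#' nearest FT-IR channel are extracted, the FT-IR channel is resampled to
#' the MIR grid, both are passed through the workflow's image-domain
#' denoiser (noise-scaled, so noise-free inputs are untouched), normalized
#' identically ([normalize_image()]), and scored by SSIM and MSE
#' (optionally inside an ROI).
#'
#' @param mir_images Named list of [absorbance_image()]s (e.g. from
#'   [mir_absorbance()] or [preprocess_mir()]); each must carry its
#'   wavenumber and pitch.
#' @param cube A [hyper_cube()] covering the requested wavenumbers.
#' @param wavenumbers Wavenumbers to compare (default: every MIR image's).
#' @param roi Optional ROI `c(row0, col0, height, width)`, 0-based,
#'   half-open, in destination (MIR) grid pixels.
#' @param window SSIM window (default 7).
#' @param p_low,p_high Normalization percentiles (defaults 1, 99).
#' @param denoise Apply [tv_denoise_adaptive()] to both channel images
#'   before scoring (default TRUE; the identity on noise-free inputs).
#' @return A `similarity_report`: `table` (data.frame wavenumber,
#'   ftir_channel, ssim, mse), `mean_ssim`, `roi`.
#' @export
channel_similarity <- function(mir_images, cube, wavenumbers = NULL, roi = NULL,
                               window = 7L, p_low = 1, p_high = 99,
                               denoise = TRUE) {
  stopifnot(inherits(cube, "hyper_cube"))
  mir_wn <- vapply(mir_images, function(im) im$wavenumber, numeric(1L))
  if (is.null(wavenumbers)) wavenumbers <- mir_wn
  rows <- list()
  for (wn in wavenumbers) {
    mi <- which(abs(mir_wn - wn) < 1e-6)
    if (length(mi) != 1L)
      stopf("no MIR image at %g cm^-1 (have: %s)", wn,
            paste(mir_wn, collapse = ", "))
    ci <- which.min(abs(cube$wavenumbers - wn))
    gap <- abs(cube$wavenumbers[ci] - wn)
    spacing <- if (length(cube$wavenumbers) > 1L)
      abs(cube$wavenumbers[1L] - cube$wavenumbers[2L]) else Inf
    if (gap > spacing)
      stopf("nearest FT-IR channel (%g cm^-1) is %g cm^-1 from %g, beyond the %g cm^-1 spacing",
            cube$wavenumbers[ci], gap, wn, spacing)
    mimg <- mir_images[[mi]]
    fimg <- resample_to_grid(cube$data[, , ci], cube$pixel_pitch_um,
                             mimg$pixel_pitch_um)
    n_r <- min(nrow(fimg), nrow(mimg$values))
    n_c <- min(ncol(fimg), ncol(mimg$values))
    av <- mimg$values[seq_len(n_r), seq_len(n_c)]
    bv <- fimg[seq_len(n_r), seq_len(n_c)]
    if (!is.null(roi)) {
      stopifnot(length(roi) == 4L)
      rr <- (roi[1L] + 1L):(roi[1L] + roi[3L])
      cc <- (roi[2L] + 1L):(roi[2L] + roi[4L])
      av <- av[rr, cc]; bv <- bv[rr, cc]
    }
    if (denoise) {
      av <- tv_denoise_adaptive(av)
      bv <- tv_denoise_adaptive(bv)
    }
    av <- image_values(normalize_image(av, p_low, p_high))
    bv <- image_values(normalize_image(bv, p_low, p_high))
    rows[[length(rows) + 1L]] <- data.frame(
      wavenumber = wn, ftir_channel = cube$wavenumbers[ci],
      ssim = ssim(av, bv, window = window, data_range = 1),
      mse = mse(av, bv))
  }
  tab <- do.call(rbind, rows)
  structure(list(table = tab, mean_ssim = mean(tab$ssim), roi = roi),
            class = "similarity_report")
}

#' @export
print.similarity_report <- function(x, ...) {
  cat("<similarity_report>\n")
  for (i in seq_len(nrow(x$table)))
    cat(sprintf("  %7.0f cm-1 (FT-IR channel %7.0f): SSIM %6.4f  MSE %.3e\n",
                x$table$wavenumber[i], x$table$ftir_channel[i],
                x$table$ssim[i], x$table$mse[i]))
  cat(sprintf("  mean SSIM %.4f\n", x$mean_ssim))
  invisible(x)
}

# All permutations of 1..n (n small).
permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations(n - 1L)
  out <- matrix(0L, 0L, n)
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub), n - 1L)))
  }
  out
}

#' Concordance between two segmentations
#'
#' Matches the kept clusters of two label maps one-to-one by solving the
#' assignment problem on total Dice overlap (exhaustive over permutations;
#' both maps must have <= 8 kept clusters), and reports per-matched-class
#' Dice plus the chance-adjusted Rand index over pixels kept in both maps.
#'
#' @param a,b `label_map`s on the same grid (resample first if needed).
#' @return List: `matching` (data.frame class_a, class_b, dice),
#'   `mean_dice`, `ari`.
#' @export
label_concordance <- function(a, b) {
  stopifnot(inherits(a, "label_map"), inherits(b, "label_map"),
            all(dim(a$labels) == dim(b$labels)))
  ids_a <- sort(unique(as.vector(a$labels))); ids_a <- ids_a[ids_a >= 0L]
  ids_b <- sort(unique(as.vector(b$labels))); ids_b <- ids_b[ids_b >= 0L]
  if (length(ids_a) == 0L || length(ids_b) == 0L) stopf("empty label map")
  if (max(length(ids_a), length(ids_b)) > 8L)
    stopf("exhaustive matching supports at most 8 kept clusters")
  swapped <- length(ids_a) > length(ids_b)
  if (swapped) { tmp <- a; a <- b; b <- tmp; tmp <- ids_a; ids_a <- ids_b; ids_b <- tmp }
  D <- matrix(0, length(ids_a), length(ids_b))
  for (i in seq_along(ids_a)) for (j in seq_along(ids_b))
    D[i, j] <- dice_coefficient(a$labels == ids_a[i], b$labels == ids_b[j])
  perms <- permutations(length(ids_b))
  na <- length(ids_a)
  scores <- apply(perms, 1L, function(p) sum(D[cbind(seq_len(na), p[seq_len(na)])]))
  best <- perms[which.max(scores), seq_len(na)]
  matching <- data.frame(class_a = if (swapped) ids_b[best] else ids_a,
                         class_b = if (swapped) ids_a else ids_b[best],
                         dice = D[cbind(seq_len(na), best)])
  both <- a$labels >= 0L & b$labels >= 0L
  ari <- mclust::adjustedRandIndex(a$labels[both], b$labels[both])
  list(matching = matching, mean_dice = mean(matching$dice), ari = ari)
}

#' Scan-time and data-load accounting for the two modalities
#'
#' Pixel counts come from [pixel_grid()]; channel counts are the laser count
#' (MIR) and the restricted preprocessed channel count (FT-IR). Scan times
#' are supplied measurements, never derived from the configs (the
#' instruments' duty cycles are not modelled).
#'
#' @param field_mm Shared field extent (rows mm, cols mm).
#' @param mir_config A [scanner_config()].
#' @param mir_time_s Measured MIR scan time over the field, in s (all
#'   lasers).
#' @param ftir_cfg An [ftir_config()].
#' @param ftir_time_s Measured FT-IR scan time over the field, in s.
#' @param ftir_channels Channel count actually clustered; default: the
#'   config's axis restricted to the default fingerprint + functional-group
#'   ranges.
#' @return A `throughput_report`: `mir` and `ftir` records (pixels,
#'   channels, values_total, scan_time_s), `data_ratio`, `time_ratio`.
#' @export
throughput_report <- function(field_mm, mir_config, mir_time_s,
                              ftir_cfg, ftir_time_s, ftir_channels = NULL) {
  stopifnot(inherits(mir_config, "scanner_config"),
            inherits(ftir_cfg, "ftir_config"))
  if (mir_time_s <= 0 || ftir_time_s <= 0) stopf("scan times must be > 0")
  if (is.null(ftir_channels)) {
    wn <- ftir_axis(ftir_cfg)
    ftir_channels <- sum((wn >= 750 & wn <= 1500) | (wn >= 2500 & wn <= 4000))
  }
  gm <- pixel_grid(field_mm, mir_config$spatial_resolution_um)
  gf <- pixel_grid(field_mm, ftir_cfg$pixel_pitch_um)
  mir <- list(pixels = gm$total_pixels, channels = nrow(mir_config$lasers),
              values_total = gm$total_pixels * nrow(mir_config$lasers),
              scan_time_s = mir_time_s)
  ftir <- list(pixels = gf$total_pixels, channels = as.integer(ftir_channels),
               values_total = gf$total_pixels * ftir_channels,
               scan_time_s = ftir_time_s)
  structure(list(mir = mir, ftir = ftir,
                 data_ratio = ftir$values_total / mir$values_total,
                 time_ratio = ftir_time_s / mir_time_s),
            class = "throughput_report")
}

#' @export
print.throughput_report <- function(x, ...) {
  fmt <- function(r, name) sprintf(
    "  %-6s %9d px x %3d channels = %10d values, scan time %8.1f s\n",
    name, r$pixels, r$channels, r$values_total, r$scan_time_s)
  cat("<throughput_report>\n", fmt(x$mir, "MIR"), fmt(x$ftir, "FT-IR"),
      sprintf("  data load ratio (FT-IR / MIR): %.1f\n", x$data_ratio),
      sprintf("  scan time ratio (FT-IR / MIR): %.1f\n", x$time_ratio), sep = "")
  invisible(x)
}
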