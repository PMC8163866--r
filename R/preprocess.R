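# Pre-processing for both modalities. MIR chain (fixed order): absorbance ->
# align -> threshold_adjust -> tv_denoise -> normalize. FT-IR chain:
# spectral smoothing -> per-pixel vector normalization -> range restriction.
# Every stage is deterministic and shape-preserving (the cube restriction
# changes only the spectral axis).

#' Construct an absorbance image
#'
#' @param values Matrix of absorbance (AU); finite.
#' @param wavenumber Wavenumber the image was measured at (cm^-1), or `NA`.
#' @param pixel_pitch_um Pixel pitch in um.
#' @return An `absorbance_image` object.
#' @export
absorbance_image <- function(values, wavenumber = NA_real_, pixel_pitch_um = NA_real_) {
  if (!is.matrix(values) || !all(is.finite(values)))
    stopf("`values` must be a finite matrix")
  structure(list(values = values, wavenumber = wavenumber,
                 pixel_pitch_um = pixel_pitch_um),
            class = "absorbance_image")
}

#' @export
print.absorbance_image <- function(x, ...) {
  cat(sprintf("<absorbance_image> %d x %d px @ %s um, %s cm-1, range [%.4f, %.4f]\n",
              nrow(x$values), ncol(x$values),
              format(x$pixel_pitch_um), format(x$wavenumber),
              min(x$values), max(x$values)))
  invisible(x)
}

# Accept a bare matrix or an absorbance_image; run f on the values and
# rewrap, preserving metadata.
map_image <- function(image, f) {
  if (inherits(image, "absorbance_image")) {
    image$values <- f(image$values)
    image
  } else f(image)
}

image_values <- function(image) {
  if (inherits(image, "absorbance_image")) image$values else image
}

#' Background-referenced absorbance
#'
#' `A = -log10(I / I_bg)`, clipped below at `floor`. The floor (default 0)
#' absorbs the negative excursions noise produces when `I > I_bg`, keeping
#' downstream clustering features nonnegative.
#'
#' @param intensity,background Intensity matrices of equal shape;
#'   `background` must be positive everywhere.
#' @param floor Lower clip for absorbance (default 0; use `-Inf` to disable).
#' @param wavenumber,pixel_pitch_um Optional metadata for the result.
#' @return An [absorbance_image()].
#' @export
to_absorbance <- function(intensity, background, floor = 0,
                          wavenumber = NA_real_, pixel_pitch_um = NA_real_) {
  if (!all(dim(intensity) == dim(background)))
    stopf("intensity and background shapes differ")
  bad <- which(background <= 0)
  if (length(bad))
    stopf("nonpositive background at pixel (row %d, col %d)%s",
          (bad[1L] - 1L) %% nrow(background) + 1L,
          (bad[1L] - 1L) %/% nrow(background) + 1L,
          if (length(bad) > 1L) sprintf(" and %d more", length(bad) - 1L) else "")
  a <- pmax(-log10(intensity / background), floor)
  absorbance_image(a, wavenumber = wavenumber, pixel_pitch_um = pixel_pitch_um)
}

#' Absorbance images for every laser of a MIR scan
#'
#' Applies [to_absorbance()] per laser against that laser's bare-slide
#' background raster.
#'
#' @param scan A `mir_scan_set` from [simulate_mir_scan()].
#' @param floor Lower absorbance clip (default 0).
#' @return Named list of [absorbance_image()] keyed by laser id.
#' @export
mir_absorbance <- function(scan, floor = 0) {
  stopifnot(inherits(scan, "mir_scan_set"))
  out <- list()
  for (id in names(scan$images)) {
    wn <- scan$config$lasers$wavenumber[match(as.integer(id), scan$config$lasers$id)]
    out[[id]] <- to_absorbance(scan$images[[id]], scan$background[[id]],
                               floor = floor, wavenumber = wn,
                               pixel_pitch_um = scan$config$spatial_resolution_um)
  }
  out
}

#' Amplify weak signals below a threshold
#'
#' Continuous piecewise-linear transfer: pixels below the threshold level `T`
#' (the `low_percentile` quantile, or an explicit `threshold`) are amplified
#' as `min(gain * x, T)`; pixels at or above `T` pass unchanged. The mapping
#' is monotone non-decreasing; `gain = 1` is the identity.
#'
#' @param image Matrix or [absorbance_image()].
#' @param low_percentile Percentile in \[0, 100) defining `T` (default 10).
#' @param gain Amplification factor >= 1 (default 1).
#' @param threshold Optional explicit threshold overriding the percentile.
#' @return Same type as `image`.
#' @export
threshold_adjust <- function(image, low_percentile = 10, gain = 1,
                             threshold = NULL) {
  assert_scalar_num(low_percentile, "low_percentile", 0, 100 - 1e-12)
  assert_scalar_num(gain, "gain", lower = 1)
  map_image(image, function(x) {
    tt <- if (is.null(threshold))
      stats::quantile(x, low_percentile / 100, names = FALSE) else threshold
    ifelse(x < tt, pmin(gain * x, tt), x)
  })
}

#' Locally adaptive total-variation denoising
#'
#' Minimizes the weighted Rudin-Osher-Fatemi energy `sum w(x) |grad u| +
#' 1/2 sum (u - f)^2` with a first-order primal-dual (Chambolle-Pock)
#' scheme. The base weight is `strength` times the image's noise level
#' (robust median-absolute-difference estimate of the per-pixel noise sd),
#' so denoising automatically matches each channel's noise regardless of
#' its dynamic range and a noise-free image passes through unchanged. The
#' per-pixel weight is additionally scaled down in windows of high local
#' gradient variance (edges are preserved) and up in flat windows. The
#' output is clamped to the input range; `strength = 0` is the identity.
#'
#' @param image Matrix or [absorbance_image()].
#' @param strength Regularization weight in multiples of the estimated
#'   noise sd, >= 0 (default 4).
#' @param adapt_window Odd window (>= 3) for the local gradient-variance
#'   estimate (default 7).
#' @param iterations Primal-dual iterations (default 60).
#' @return Same type as `image`.
#' @export
tv_denoise_adaptive <- function(image, strength = 4, adapt_window = 7L,
                                iterations = 60L) {
  assert_scalar_num(strength, "strength", lower = 0)
  if (adapt_window %% 2L != 1L || adapt_window < 3L)
    stopf("`adapt_window` must be odd and >= 3")
  map_image(image, function(f) {
    if (strength == 0 || stats::sd(f) == 0) return(f)
    # robust noise estimate from horizontal first differences
    sigma <- stats::median(abs(f[, -1L, drop = FALSE] -
                                 f[, -ncol(f), drop = FALSE])) / (0.6745 * sqrt(2))
    if (sigma == 0) return(f)
    rng <- range(f)
    nr <- nrow(f); nc <- ncol(f)
    up <- function(m) m[c(1L, seq_len(nr - 1L)), , drop = FALSE]
    dn <- function(m) m[c(seq_len(nr)[-1L], nr), , drop = FALSE]
    lf <- function(m) m[, c(1L, seq_len(nc - 1L)), drop = FALSE]
    rt <- function(m) m[, c(seq_len(nc)[-1L], nc), drop = FALSE]
    grad <- function(m) list(x = rt(m) - m, y = dn(m) - m)
    divg <- function(p) (p$x - lf(p$x)) + (p$y - up(p$y))
    # adaptive weight from the variance of the gradient magnitude of f
    g0 <- grad(f)
    gmag <- sqrt(g0$x^2 + g0$y^2)
    vloc <- pmax(box_mean(gmag^2, adapt_window) - box_mean(gmag, adapt_window)^2, 0)
    w <- strength * sigma / (1 + vloc / (mean(vloc) + .Machine$double.eps))
    # Chambolle-Pock with ||grad||^2 <= 8: sigma = tau = 1/sqrt(8)
    sig <- tau <- 1 / sqrt(8)
    u <- f; ub <- f
    p <- list(x = matrix(0, nr, nc), y = matrix(0, nr, nc))
    for (it in seq_len(iterations)) {
      g <- grad(ub)
      px <- p$x + sig * g$x
      py <- p$y + sig * g$y
      nrm <- pmax(sqrt(px^2 + py^2), w)
      # project |p| <= w pointwise (nrm >= w by construction above)
      p <- list(x = px * (w / nrm), y = py * (w / nrm))
      u_new <- (u + tau * divg(p) + tau * f) / (1 + tau)
      ub <- 2 * u_new - u
      u <- u_new
    }
    pmin(pmax(u, rng[1L]), rng[2L])
  })
}

#' Robust percentile normalization of an image
#'
#' Linear rescale mapping the `p_low` percentile to 0 and the `p_high`
#' percentile to 1, clipped to \[0, 1\]. Invariant to affine rescaling of the
#' input.
#'
#' @param image Matrix or [absorbance_image()].
#' @param p_low,p_high Percentiles in \[0, 100\] with `p_low < p_high`
#'   (defaults 1 and 99).
#' @return Same type as `image`, values in \[0, 1\].
#' @export
normalize_image <- function(image, p_low = 1, p_high = 99) {
  if (p_low >= p_high) stopf("`p_low` must be below `p_high`")
  map_image(image, function(x) {
    q <- stats::quantile(x, c(p_low, p_high) / 100, names = FALSE)
    if (q[2L] <= q[1L])
      stopf("degenerate image: percentile %g and %g levels coincide (%g)",
            p_low, p_high, q[1L])
    pmin(pmax((x - q[1L]) / (q[2L] - q[1L]), 0), 1)
  })
}

#' Smooth, vector-normalize and range-restrict an FT-IR cube
#'
#' Per pixel: moving-average smoothing along the spectral axis (window
#' truncated at the axis ends), scaling of the spectrum to unit Euclidean
#' norm (all-zero spectra are left at zero), then restriction of the channel
#' axis to the union of the given wavenumber intervals. Defaults keep the
#' fingerprint region (750-1500 cm^-1) and the functional-group region
#' (2500-4000 cm^-1).
#'
#' @param cube A [hyper_cube()].
#' @param smooth_window Odd moving-average window (default 5; 1 = no
#'   smoothing).
#' @param ranges List of `c(lo, hi)` wavenumber intervals in cm^-1.
#' @param vector_norm Scale every pixel spectrum to unit Euclidean norm
#'   (default TRUE, the standard choice before clustering; disable when the
#'   channels are compared as absorbance images).
#' @return A [hyper_cube()] with the restricted axis.
#' @export
preprocess_cube <- function(cube, smooth_window = 5L,
                            ranges = list(c(750, 1500), c(2500, 4000)),
                            vector_norm = TRUE) {
  stopifnot(inherits(cube, "hyper_cube"))
  if (smooth_window %% 2L != 1L || smooth_window < 1L)
    stopf("`smooth_window` must be odd and >= 1")
  d <- dim(cube$data)
  n_px <- d[1L] * d[2L]; n_ch <- d[3L]
  m <- matrix(cube$data, n_px, n_ch)
  if (smooth_window > 1L && n_ch > 1L) {
    h <- (smooth_window - 1L) %/% 2L
    cs <- matrix(0, n_px, n_ch + 1L)
    for (j in seq_len(n_ch)) cs[, j + 1L] <- cs[, j] + m[, j]
    sm <- matrix(0, n_px, n_ch)
    for (j in seq_len(n_ch)) {
      j0 <- max(j - h, 1L); j1 <- min(j + h, n_ch)
      sm[, j] <- (cs[, j1 + 1L] - cs[, j0]) / (j1 - j0 + 1L)
    }
    m <- sm
  }
  if (vector_norm) {
    nrm <- sqrt(rowSums(m^2))
    nrm[nrm == 0] <- 1
    m <- m / nrm
  }
  keep <- rep(FALSE, n_ch)
  for (r in ranges) {
    if (length(r) != 2L || r[1L] > r[2L]) stopf("each range must be c(lo, hi)")
    keep <- keep | (cube$wavenumbers >= r[1L] & cube$wavenumbers <= r[2L])
  }
  if (!any(keep)) stopf("range restriction removes every channel")
  hyper_cube(array(m[, keep, drop = FALSE], c(d[1L], d[2L], sum(keep))),
             cube$wavenumbers[keep], cube$pixel_pitch_um)
}

#' Co-register a collection of rasters
#'
#' With `transform` given (a 2x3 affine matrix mapping output pixel
#' coordinates `(row, col, 1)` to input coordinates), applies it to every
#' image with bilinear interpolation. With `transform = NULL`, estimates an
#' integer-pixel circular shift of each image against the first by
#' cross-correlation and undoes it (zero fill). If any estimated shift
#' exceeds 10% of the image extent, alignment fails: a warning is raised and
#' the inputs are returned unmodified with attribute `alignment_failed`.
#'
#' @param images List of matrices (or [absorbance_image()]s) of equal shape.
#' @param transform Optional 2x3 affine matrix.
#' @return List of the same type; attribute `shifts` holds the per-image
#'   estimated `(row, col)` shifts when estimation was used.
#' @export
align_images <- function(images, transform = NULL) {
  vals <- lapply(images, image_values)
  dims <- vapply(vals, dim, integer(2L))
  if (any(dims != dims[, 1L])) stopf("images must share one shape")
  if (!is.null(transform)) {
    stopifnot(is.matrix(transform), all(dim(transform) == c(2L, 3L)))
    nr <- nrow(vals[[1L]]); nc <- ncol(vals[[1L]])
    grid_r <- matrix(seq_len(nr), nr, nc)
    grid_c <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    src_r <- transform[1L, 1L] * grid_r + transform[1L, 2L] * grid_c + transform[1L, 3L]
    src_c <- transform[2L, 1L] * grid_r + transform[2L, 2L] * grid_c + transform[2L, 3L]
    out <- Map(function(img, v) map_image(img, function(x)
      matrix(bilinear_sample(v, as.vector(src_r), as.vector(src_c)), nr, nc)),
      images, vals)
    return(out)
  }
  ref <- vals[[1L]] - mean(vals[[1L]])
  fr <- stats::fft(ref)
  nr <- nrow(ref); nc <- ncol(ref)
  shifts <- matrix(0L, length(vals), 2L)
  for (i in seq_along(vals)[-1L]) {
    b <- vals[[i]] - mean(vals[[i]])
    cc <- Re(stats::fft(fr * Conj(stats::fft(b)), inverse = TRUE))
    pk <- which.max(cc)
    sr <- (pk - 1L) %% nr; sc <- (pk - 1L) %/% nr
    if (sr > nr / 2) sr <- sr - nr
    if (sc > nc / 2) sc <- sc - nc
    # cc peaks at minus the displacement of image i relative to the reference
    shifts[i, ] <- c(-sr, -sc)
  }
  if (any(abs(shifts[, 1L]) > 0.1 * nr | abs(shifts[, 2L]) > 0.1 * nc)) {
    warning("alignment failure: estimated shift exceeds 10% of the image extent; inputs returned unmodified")
    attr(images, "alignment_failed") <- TRUE
    attr(images, "shifts") <- shifts
    return(images)
  }
  out <- images
  for (i in seq_along(vals)[-1L]) {
    s <- shifts[i, ]
    out[[i]] <- map_image(out[[i]], function(x) shift_matrix(x, -s[1L], -s[2L]))
  }
  attr(out, "shifts") <- shifts
  out
}

# Integer shift with zero fill (positive dr moves content down).
shift_matrix <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  src_r <- seq_len(nr) - dr
  src_c <- seq_len(nc) - dc
  ok_r <- src_r >= 1L & src_r <= nr
  ok_c <- src_c >= 1L & src_c <= nc
  out[which(ok_r), which(ok_c)] <- m[src_r[ok_r], src_c[ok_c]]
  out
}

#' Full MIR pre-processing chain
#'
#' Fixed stage order: background-referenced absorbance, co-registration,
#' threshold adjustment, locally adaptive TV denoising, robust
#' normalization. Returns the processed per-laser images plus a manifest of
#' the stage parameters applied.
#'
#' @param scan A `mir_scan_set`.
#' @param floor Absorbance floor (default 0).
#' @param low_percentile,gain [threshold_adjust()] parameters (defaults: no
#'   amplification, `gain = 1`).
#' @param tv_strength,adapt_window,tv_iterations [tv_denoise_adaptive()]
#'   parameters.
#' @param p_low,p_high [normalize_image()] percentiles.
#' @param align_shifts Estimate and undo inter-laser pixel shifts in the
#'   align stage (default FALSE: the simulated lasers share one grid, so
#'   the stage is the identity; set TRUE for data that may be misaligned).
#' @return List: `images` (named list of [absorbance_image()], values in
#'   \[0, 1\]) and `manifest` (stage parameter list, in execution order).
#' @export
preprocess_mir <- function(scan, floor = 0, low_percentile = 10, gain = 1,
                           tv_strength = 4, adapt_window = 7L,
                           tv_iterations = 60L, p_low = 1, p_high = 99,
                           align_shifts = FALSE) {
  imgs <- mir_absorbance(scan, floor = floor)
  if (align_shifts) imgs <- align_images(imgs)
  imgs <- lapply(imgs, threshold_adjust, low_percentile = low_percentile,
                 gain = gain)
  imgs <- lapply(imgs, tv_denoise_adaptive, strength = tv_strength,
                 adapt_window = adapt_window, iterations = tv_iterations)
  imgs <- lapply(imgs, normalize_image, p_low = p_low, p_high = p_high)
  manifest <- list(
    chain = c("absorbance", "align", "threshold_adjust", "tv_denoise",
              "normalize"),
    floor = floor, low_percentile = low_percentile, gain = gain,
    tv_strength = tv_strength, adapt_window = adapt_window,
    tv_iterations = tv_iterations, p_low = p_low, p_high = p_high,
    align_shifts = align_shifts)
  list(images = imgs, manifest = manifest)
}
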