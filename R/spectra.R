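# Per-class infrared absorbance models: sums of Gaussian bands over a
# scattering baseline. The functional-group region (~2500-4000 cm^-1) carries
# the bands the discrete-laser scanner interrogates: the lipid C-H valence
# vibration peaking at 2926 cm^-1, the protein amide-A N-H band near
# 3350 cm^-1 (the band position ranges over ~3200-3500 cm^-1 depending on the
# protein), and a broad O-H water band near 3400 cm^-1 that superposes both
# when the section is not fully dried. The reference wavenumbers 2790 and
# 3700 cm^-1 sit in low-absorbance wings of these bands.

# Default band shape parameters (centers/sigmas in cm^-1)
LIPID_CH_CENTER <- 2926
LIPID_CH_SIGMA <- 60
AMIDE_A_CENTER <- 3350
AMIDE_A_SIGMA <- 90
WATER_OH_CENTER <- 3400
WATER_OH_SIGMA <- 180
WATER_OH_FULL_AMPLITUDE <- 0.6

WAVENUMBER_RANGE <- c(700, 4100)

#' Construct a Gaussian spectral band
#'
#' A band is a Gaussian absorbance feature `amplitude * exp(-(v - center)^2 /
#' (2 sigma^2))` on the wavenumber axis.
#'
#' @param center Band centre in cm^-1 (> 0).
#' @param sigma Gaussian width in cm^-1 (> 0).
#' @param amplitude Peak absorbance in AU (>= 0).
#' @return A `spectral_band` object.
#' @export
spectral_band <- function(center, sigma, amplitude) {
  assert_scalar_num(center, "center", lower = 1e-9)
  assert_scalar_num(sigma, "sigma", lower = 1e-9)
  assert_scalar_num(amplitude, "amplitude", lower = 0)
  structure(list(center = center, sigma = sigma, amplitude = amplitude),
            class = "spectral_band")
}

#' Construct a tissue-class absorbance profile
#'
#' A profile is a deterministic absorbance model for one tissue class: a
#' constant scattering baseline plus a sum of Gaussian bands.
#'
#' @param label Class name (e.g. `"white_matter"`).
#' @param bands List of [spectral_band()] objects.
#' @param baseline Constant scattering absorbance in AU (>= 0).
#' @return A `spectral_profile` object.
#' @export
spectral_profile <- function(label, bands, baseline = 0.05) {
  stopifnot(is.character(label), length(label) == 1L)
  assert_scalar_num(baseline, "baseline", lower = 0)
  if (inherits(bands, "spectral_band")) bands <- list(bands)
  ok <- vapply(bands, inherits, logical(1L), what = "spectral_band")
  if (!all(ok)) stopf("`bands` must be a list of spectral_band objects")
  structure(list(label = label, bands = bands, baseline = baseline),
            class = "spectral_profile")
}

#' @export
print.spectral_profile <- function(x, ...) {
  cat(sprintf("<spectral_profile> %s: baseline %.3f AU, %d band(s)\n",
              x$label, x$baseline, length(x$bands)))
  for (b in x$bands)
    cat(sprintf("  band %7.1f cm-1  sigma %6.1f  amplitude %.3f\n",
                b$center, b$sigma, b$amplitude))
  invisible(x)
}

#' Evaluate a profile's absorbance at given wavenumbers
#'
#' Computes `A(v) = baseline + sum_b amplitude_b * exp(-(v - center_b)^2 /
#' (2 sigma_b^2))` for each requested wavenumber.
#'
#' @param profile A [spectral_profile()].
#' @param wavenumbers Numeric vector of wavenumbers in cm^-1; must lie in
#'   the supported mid-infrared range \[700, 4100\].
#' @return Absorbance vector (AU), one value per wavenumber.
#' @examples
#' p <- spectral_profile("lipid", spectral_band(2926, 60, 0.8), baseline = 0.05)
#' evaluate_absorbance(p, c(2926, 3700))
#' @export
evaluate_absorbance <- function(profile, wavenumbers) {
  stopifnot(inherits(profile, "spectral_profile"))
  if (!is.numeric(wavenumbers) || length(wavenumbers) == 0L)
    stopf("`wavenumbers` must be a non-empty numeric vector")
  if (any(wavenumbers < WAVENUMBER_RANGE[1L] | wavenumbers > WAVENUMBER_RANGE[2L]))
    stopf("wavenumbers must lie within [%g, %g] cm^-1",
          WAVENUMBER_RANGE[1L], WAVENUMBER_RANGE[2L])
  a <- rep(profile$baseline, length(wavenumbers))
  for (b in profile$bands)
    a <- a + b$amplitude * exp(-(wavenumbers - b$center)^2 / (2 * b$sigma^2))
  a
}

#' Add a water O-H band to a profile
#'
#' Scales a broad O-H valence band (centre 3400 cm^-1, sigma 180 cm^-1) by
#' `water_fraction` and appends it; `water_fraction = 0` returns the profile
#' unchanged (the dried condition).
#' @noRd
add_water_band <- function(profile, water_fraction) {
  if (water_fraction == 0) return(profile)
  profile$bands <- c(profile$bands, list(spectral_band(
    WATER_OH_CENTER, WATER_OH_SIGMA, water_fraction * WATER_OH_FULL_AMPLITUDE)))
  profile
}

#' Default brain tissue-class profiles
#'
#' Three classes on a shared band table (lipid C-H at 2926 cm^-1, amide A at
#' 3350 cm^-1). Amplitudes are free parameters chosen so that, at
#' 2926 cm^-1, white matter (corpus callosum) > hippocampal CA3 band > grey
#' matter (cortex), and so that the hippocampal class has a distinct
#' lipid-to-amide ratio from both matters.
#'
#' @return Named list of [spectral_profile()] objects keyed by class id
#'   ("1" grey matter, "2" white matter, "3" hippocampus).
#' @export
brain_profiles <- function() {
  list(
    "1" = spectral_profile("grey_matter", list(
      spectral_band(LIPID_CH_CENTER, LIPID_CH_SIGMA, 0.30),
      spectral_band(AMIDE_A_CENTER, AMIDE_A_SIGMA, 0.45)), baseline = 0.04),
    "2" = spectral_profile("white_matter", list(
      spectral_band(LIPID_CH_CENTER, LIPID_CH_SIGMA, 0.80),
      spectral_band(AMIDE_A_CENTER, AMIDE_A_SIGMA, 0.40)), baseline = 0.05),
    "3" = spectral_profile("hippocampus", list(
      spectral_band(LIPID_CH_CENTER, LIPID_CH_SIGMA, 0.45),
      spectral_band(AMIDE_A_CENTER, AMIDE_A_SIGMA, 0.70)), baseline = 0.04)
  )
}

#' Default liver tissue-class profiles
#'
#' Healthy liver and tumour (hepatocellular-carcinoma-like) classes; the
#' tumour differs from healthy tissue predominantly in the long-chain C-H
#' band at 2926 cm^-1. An optional margin class is the arithmetic mean of
#' the two, used for graded infiltration zones.
#'
#' @param with_margin Include the class-3 margin profile.
#' @return Named list of [spectral_profile()] objects keyed by class id
#'   ("1" healthy, "2" tumour, optionally "3" margin).
#' @export
liver_profiles <- function(with_margin = FALSE) {
  healthy <- spectral_profile("healthy_liver", list(
    spectral_band(LIPID_CH_CENTER, LIPID_CH_SIGMA, 0.40),
    spectral_band(AMIDE_A_CENTER, AMIDE_A_SIGMA, 0.50)), baseline = 0.05)
  tumour <- spectral_profile("tumour", list(
    spectral_band(LIPID_CH_CENTER, LIPID_CH_SIGMA, 0.75),
    spectral_band(AMIDE_A_CENTER, AMIDE_A_SIGMA, 0.52)), baseline = 0.05)
  out <- list("1" = healthy, "2" = tumour)
  if (with_margin) {
    out[["3"]] <- spectral_profile("tumour_margin", list(
      spectral_band(LIPID_CH_CENTER, LIPID_CH_SIGMA, (0.40 + 0.75) / 2),
      spectral_band(AMIDE_A_CENTER, AMIDE_A_SIGMA, (0.50 + 0.52) / 2)),
      baseline = 0.05)
  }
  out
}
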