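# Hemoglobin optics: extinction coefficients and blood / bulk-tissue
# absorption. Everything is in mm^-1 and g/L so values line up with the
# layered-model scale (bulk tissue mu_a of order 0.01-0.1 mm^-1 in the NIR).

# Compiled molar extinction coefficients for oxy- and deoxy-hemoglobin
# (cm^-1 per mol/L, decadic). Anchor points across the NIR window; values
# between anchors are interpolated linearly.
.hb_extinction_anchors <- tibble::tibble(
  wavelength = c(600, 650, 700, 730, 740, 750, 760, 780, 800, 850, 900, 950, 1000),
  eps_hbo2   = c(3200, 368, 290, 390, 446, 518, 586, 710, 816, 1058, 1198, 1204, 1096),
  eps_hhb    = c(14677.2, 3750.12, 1794.28, 1102.2, 1115.88, 1405.24, 1548.52,
                 1075.44, 761.72, 691.32, 761.84, 602.0, 432.0)
)

# decadic molar extinction -> mm^-1 per (g/L): ln(10) / molar mass / 10 mm/cm
.HB_MOLAR_MASS <- 64500
.EPS_SCALE <- log(10) / .HB_MOLAR_MASS / 10

#' Hemoglobin extinction coefficients
#'
#' Returns the oxy- and deoxy-hemoglobin extinction coefficients at the
#' requested wavelengths, interpolated from an embedded table of compiled
#' hemoglobin spectra and converted to mm^-1 per (g/L) of hemoglobin.
#'
#' @param wavelength Numeric vector of wavelengths in nm. Supported range is
#'   600-1000 nm.
#' @return A tibble with columns `wavelength`, `eps_hbo2`, `eps_hhb`
#'   (mm^-1 per g/L).
#' @examples
#' extinction_coeffs(c(735, 850))
#' @export
extinction_coeffs <- function(wavelength) {
  check_wavelength(wavelength)
  tibble::tibble(
    wavelength = wavelength,
    eps_hbo2 = approx(.hb_extinction_anchors$wavelength,
                      .hb_extinction_anchors$eps_hbo2, wavelength)$y * .EPS_SCALE,
    eps_hhb  = approx(.hb_extinction_anchors$wavelength,
                      .hb_extinction_anchors$eps_hhb, wavelength)$y * .EPS_SCALE
  )
}

check_wavelength <- function(wavelength) {
  if (!is.numeric(wavelength) || any(!is.finite(wavelength))) {
    abort("`wavelength` must be finite numeric (nm).", class = "tfo_error_wavelength")
  }
  if (any(wavelength < 600 | wavelength > 1000)) {
    abort("Unsupported wavelength: extinction data cover 600-1000 nm.",
          class = "tfo_error_wavelength")
  }
  invisible(wavelength)
}

#' Blood state
#'
#' A blood compartment is described by its total hemoglobin concentration and
#' arterial-style oxygen saturation (fraction of oxyhemoglobin).
#'
#' @param hb_conc Total hemoglobin concentration, g/L (>= 0).
#' @param saturation Oxygen saturation as a fraction in \[0, 1\].
#' @return A `blood_state` list.
#' @export
blood_state <- function(hb_conc, saturation) {
  stopifnot(is.numeric(hb_conc), hb_conc >= 0,
            is.numeric(saturation), saturation >= 0, saturation <= 1)
  structure(list(hb_conc = hb_conc, saturation = saturation),
            class = "blood_state")
}

#' Absorption coefficient of whole blood
#'
#' `mu_a = hb_conc * (sat * eps_HbO2 + (1 - sat) * eps_HHb)`, linear in the
#' hemoglobin concentration and monotone in saturation with sign set by the
#' extinction contrast at the wavelength.
#'
#' @param blood A [blood_state()].
#' @param wavelength Wavelength in nm.
#' @return Absorption coefficient in mm^-1.
#' @examples
#' mu_a_blood(blood_state(150, 0.6), 735)
#' @export
mu_a_blood <- function(blood, wavelength) {
  stopifnot(inherits(blood, "blood_state"))
  eps <- extinction_coeffs(wavelength)
  blood$hb_conc * (blood$saturation * eps$eps_hbo2 +
                   (1 - blood$saturation) * eps$eps_hhb)
}

#' Venous blood derived from the arterial state
#'
#' Venous saturation is taken as a fixed fraction of the arterial saturation
#' (default 0.75); hemoglobin concentration is shared.
#'
#' @param arterial A [blood_state()].
#' @param venous_fraction Venous-to-arterial saturation ratio.
#' @return A `blood_state`.
#' @export
venous_from_arterial <- function(arterial, venous_fraction = 0.75) {
  blood_state(arterial$hb_conc, arterial$saturation * venous_fraction)
}

#' Bulk tissue absorption of a perfused layer
#'
#' Combines arterial and venous blood compartments, each occupying a fixed
#' volume fraction (default 5% each, 10% blood total), with a wavelength
#' power-law baseline for the non-blood matrix:
#' `mu_a = vf * (mu_a_arterial + mu_a_venous) + 7.84e7 * lambda^-3.255`
#' with `lambda` in nm and the result in mm^-1. Melanin is not modeled.
#'
#' @param arterial,venous [blood_state()] objects for the two compartments.
#' @param wavelength Wavelength in nm.
#' @param blood_fraction Volume fraction per compartment (default 0.05).
#' @return Absorption coefficient in mm^-1.
#' @examples
#' a <- blood_state(150, 0.97)
#' mu_a_tissue(a, venous_from_arterial(a), 735)
#' @export
mu_a_tissue <- function(arterial, venous, wavelength, blood_fraction = 0.05) {
  baseline <- 7.84e7 * wavelength^-3.255
  blood_fraction * (mu_a_blood(arterial, wavelength) +
                    mu_a_blood(venous, wavelength)) + baseline
}
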