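# Four-layer pregnant-abdomen model: maternal abdominal wall / uterus /
# amniotic fluid / fetal tissue. Hemodynamics only touch mu_a of layers 1
# and 4; scattering, anisotropy and refractive index are static per layer.

.layer_names <- c("maternal_wall", "uterus", "amniotic_fluid", "fetal_tissue")

# Static optical properties per wavelength. mu_a is NA for the two perfused
# layers (computed from the blood model), fixed for uterus and amniotic fluid.
.layer_optics <- list(
  `735` = tibble::tibble(
    layer = 1:4, name = .layer_names,
    mu_a = c(NA, 0.0158, 0.0125, NA),
    mu_s = c(11.816, 10.575, 0.1, 12.5)
  ),
  `850` = tibble::tibble(
    layer = 1:4, name = .layer_names,
    mu_a = c(NA, 0.0991, 0.0042, NA),
    mu_s = c(11.169, 8.125, 0.1, 9.916)
  )
)
.layer_g <- c(0.9, 0.9, 0.9, 0.9)
.layer_n <- c(1.4, 1.4, 1.33, 1.4)
.uterus_thickness <- 5    # mm
.amniotic_thickness <- 1  # mm

#' Static layer optical properties
#'
#' Scattering and static absorption for the four tissue layers at one of the
#' two supported source wavelengths. Maternal-wall and fetal-tissue `mu_a`
#' are `NA` here; they come from the hemodynamic model via [build_state()].
#'
#' @param wavelength 735 or 850 (nm). 740 nm is mapped onto the 735 nm
#'   property set (the scattering difference over 5 nm is negligible).
#' @param dm Maternal abdominal wall thickness in mm.
#' @return A tibble with columns `layer`, `name`, `mu_a`, `mu_s`, `g`, `n`,
#'   `thickness` (mm, `Inf` for the semi-infinite fetal layer).
#' @export
tissue_layers <- function(wavelength, dm = 14) {
  key <- if (abs(wavelength - 735) <= 5) "735" else if (abs(wavelength - 850) <= 5) "850" else
    abort("Layer optical properties are tabulated at 735 and 850 nm.",
          class = "tfo_error_config")
  if (dm < 4 || dm > 34) {
    abort("`dm` outside the configured 4-34 mm range.", class = "tfo_error_config")
  }
  .layer_optics[[key]] |>
    mutate(g = .layer_g, n = .layer_n,
           thickness = c(dm, .uterus_thickness, .amniotic_thickness, Inf))
}

#' Build a tissue state at one instant
#'
#' Assembles the four-layer model for one wavelength and pulsation phase.
#' Layers 2-3 use static absorption; layers 1 (maternal wall) and 4 (fetal
#' tissue) use the perfused-tissue model with the supplied blood states.
#' In systole the fetal hemoglobin concentration is raised by the pulsation
#' fraction (default 2.5%) relative to the diastolic baseline.
#'
#' @param dm Maternal wall thickness, mm (4-34).
#' @param maternal,fetal Arterial [blood_state()]s; venous compartments are
#'   derived via [venous_from_arterial()].
#' @param wavelength Source wavelength, nm.
#' @param phase `"diastole"` (baseline) or `"systole"`.
#' @param pulsation Fractional systolic increase of fetal hemoglobin.
#' @param venous_fraction,blood_fraction See [venous_from_arterial()] and
#'   [mu_a_tissue()].
#' @return A `tfo_state`: list with `layers` tibble (full optical properties),
#'   `dm`, `wavelength`, `phase`, and the blood states.
#' @examples
#' st <- build_state(14, blood_state(120, 0.97), blood_state(160, 0.4), 735)
#' st$layers
#' @export
build_state <- function(dm, maternal, fetal, wavelength,
                        phase = c("diastole", "systole"),
                        pulsation = 0.025,
                        venous_fraction = 0.75, blood_fraction = 0.05) {
  phase <- match.arg(phase)
  stopifnot(inherits(maternal, "blood_state"), inherits(fetal, "blood_state"))
  if (phase == "systole") {
    fetal <- blood_state(fetal$hb_conc * (1 + pulsation), fetal$saturation)
  }
  layers <- tissue_layers(wavelength, dm)
  layers$mu_a[1] <- mu_a_tissue(maternal, venous_from_arterial(maternal, venous_fraction),
                                wavelength, blood_fraction)
  layers$mu_a[4] <- mu_a_tissue(fetal, venous_from_arterial(fetal, venous_fraction),
                                wavelength, blood_fraction)
  structure(list(layers = layers, dm = dm, wavelength = wavelength,
                 phase = phase, maternal = maternal, fetal = fetal,
                 pulsation = pulsation, venous_fraction = venous_fraction,
                 blood_fraction = blood_fraction),
            class = "tfo_state")
}

#' Systole/diastole pair for one hemodynamic configuration
#'
#' Returns the two static states bracketing a fetal cardiac cycle: the
#' diastolic baseline and the systolic state with fetal hemoglobin raised by
#' the pulsation fraction. Only the fetal-layer absorption differs.
#'
#' @param state A diastolic (baseline) `tfo_state` from [build_state()].
#' @return A list with elements `systole` and `diastole`.
#' @export
pulsation_pair <- function(state) {
  stopifnot(inherits(state, "tfo_state"))
  base <- if (state$phase == "diastole") state else
    build_state(state$dm, state$maternal,
                blood_state(state$fetal$hb_conc / (1 + state$pulsation),
                            state$fetal$saturation),
                state$wavelength, "diastole", state$pulsation,
                state$venous_fraction, state$blood_fraction)
  sys <- build_state(base$dm, base$maternal, base$fetal, base$wavelength,
                     "systole", base$pulsation, base$venous_fraction,
                     base$blood_fraction)
  list(systole = sys, diastole = base)
}

#' Absorption assignment of a state
#'
#' @param state A `tfo_state`.
#' @return Numeric length-4 vector of per-layer `mu_a` (mm^-1).
#' @export
mu_assignment <- function(state) {
  stopifnot(inherits(state, "tfo_state"))
  state$layers$mu_a
}

#' Hemodynamic sweep grid
#'
#' Cartesian product of the model parameters, `dm` outermost, wavelength
#' innermost; one row per (geometry, hemodynamics, wavelength) whose systole
#' and diastole states are built on demand. Defaults span a physiologic
#' range: fetal saturation 10-70%, maternal 90-98%, fetal hemoglobin
#' 120-180 g/L, maternal 110-140 g/L.
#'
#' @param dm Maternal wall thicknesses, mm.
#' @param sm,sf Maternal / fetal arterial saturations (fractions).
#' @param hbm,hbf Maternal / fetal hemoglobin concentrations, g/L.
#' @param wavelengths Source wavelengths, nm.
#' @return A tibble with one row per combination.
#' @export
sweep_grid <- function(dm = 14,
                       sm = c(0.90, 0.94, 0.98),
                       sf = seq(0.10, 0.70, by = 0.025),
                       hbm = c(110, 140),
                       hbf = c(120, 150, 180),
                       wavelengths = c(735, 850)) {
  for (v in list(dm, sm, sf, hbm, hbf, wavelengths)) {
    if (length(v) < 1) abort("Empty sweep list.", class = "tfo_error_config")
  }
  tidyr::expand_grid(dm = dm, sm = sm, hbm = hbm, sf = sf, hbf = hbf,
                     wavelength = wavelengths)
}

#' Enumerate systole/diastole state pairs of a sweep
#'
#' @param grid A tibble from [sweep_grid()].
#' @param ... Passed to [build_state()] (pulsation, fractions).
#' @return The grid with a list-column `pair`, each element a
#'   [pulsation_pair()] result.
#' @export
enumerate_sweep <- function(grid, ...) {
  if (nrow(grid) == 0) abort("Empty sweep grid.", class = "tfo_error_config")
  grid |>
    mutate(pair = purrr::pmap(list(.data$dm, .data$sm, .data$hbm, .data$sf,
                                   .data$hbf, .data$wavelength),
      function(dm, sm, hbm, sf, hbf, wl) {
        pulsation_pair(build_state(dm, blood_state(hbm, sm),
                                   blood_state(hbf, sf), wl, ...))
      }))
}

# mu_a matrices for a sweep at one wavelength without building full states;
# rows are grid rows, columns layers. Used by the batch feature path.
sweep_mu_matrix <- function(grid_wl, phase, pulsation = 0.025,
                            venous_fraction = 0.75, blood_fraction = 0.05) {
  wl <- grid_wl$wavelength
  stopifnot(length(unique(wl)) == 1)
  wl <- wl[[1]]
  eps <- extinction_coeffs(wl)
  baseline <- 7.84e7 * wl^-3.255
  mu_perf <- function(hb, s) {
    art <- hb * (s * eps$eps_hbo2 + (1 - s) * eps$eps_hhb)
    ven <- hb * (s * venous_fraction * eps$eps_hbo2 +
                 (1 - s * venous_fraction) * eps$eps_hhb)
    blood_fraction * (art + ven) + baseline
  }
  hbf <- grid_wl$hbf * (if (phase == "systole") 1 + pulsation else 1)
  static <- tissue_layers(wl, dm = grid_wl$dm[[1]])$mu_a
  cbind(mu_perf(grid_wl$hbm, grid_wl$sm),
        rep(static[2], nrow(grid_wl)),
        rep(static[3], nrow(grid_wl)),
        mu_perf(hbf, grid_wl$sf))
}
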