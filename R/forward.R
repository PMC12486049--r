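# Forward engine: turns a pathlength table plus per-layer absorption
# assignments into normalized intensities, sensitivity derivatives, fetal
# sensitivity, EPR / RoR features, smoothed EPR-vs-SDD curves, and
# pathlength-distribution summaries.

check_mu <- function(table, mu) {
  m <- max_layer_index(table$records)
  if (!is.numeric(mu) || length(mu) != m || any(mu < 0) || any(!is.finite(mu))) {
    abort(sprintf("`mu` must be a nonnegative numeric vector of length %d.", m),
          class = "tfo_error_mu")
  }
  invisible(mu)
}

ring_area <- function(sdd, radius) {
  pi * ((sdd + radius)^2 - pmax(sdd - radius, 0)^2)
}

#' Normalized detected intensity at one ring
#'
#' White-MC reweighting of the stored photon paths:
#' `I = (1/n_launched) * sum_i w_i * exp(-sum_j mu[j] * L[i, j])` over the
#' ring's records. Strictly decreasing in every `mu[j]` with positive
#' pathlength mass in the ring.
#'
#' @param table A `tfo_table` from [simulate_paths()].
#' @param mu Per-layer absorption coefficients, mm^-1 (length = n layers).
#' @param sdd Ring center, mm.
#' @param per_area If `TRUE`, divide by the ring's annular area (mm^2),
#'   giving spatially resolved reflectance per unit area.
#' @return Dimensionless normalized intensity (or mm^-2 reflectance).
#' @export
intensity <- function(table, mu, sdd, per_area = FALSE) {
  check_mu(table, mu)
  rec <- ring_collect(table, sdd)
  val <- sum(rec$weight * exp(-drop(layer_matrix(rec) %*% mu))) / table$n_launched
  if (per_area) val / ring_area(sdd, table$detectors$radius) else val
}

#' Derivative of intensity with respect to one layer's absorption
#'
#' `dI/dmu[j] = -(1/n) * sum_i w_i * L[i, j] * exp(-sum mu * L)`; always
#' nonpositive, and zero when no ring photon traverses the layer.
#'
#' @inheritParams intensity
#' @param layer Layer index (1 = maternal wall, 4 = fetal tissue).
#' @return The (nonpositive) derivative, mm.
#' @export
sensitivity_derivative <- function(table, mu, sdd, layer) {
  check_mu(table, mu)
  rec <- ring_collect(table, sdd)
  L <- layer_matrix(rec)
  stopifnot(layer >= 1, layer <= ncol(L))
  -sum(rec$weight * L[, layer] * exp(-drop(L %*% mu))) / table$n_launched
}

#' Fetal sensitivity of one ring
#'
#' Fraction of the absorption-derivative signal attributable to the fetal
#' layer versus fetal plus maternal layers:
#' `|dI/dmu_f| / (|dI/dmu_f| + |dI/dmu_m|)`. Zero when no photon reaches the
#' fetal layer; grows with SDD to a saturation plateau.
#'
#' @inheritParams intensity
#' @param maternal_layer,fetal_layer Layer indices (defaults 1 and the
#'   deepest layer).
#' @return Fraction in \[0, 1\].
#' @export
fetal_sensitivity <- function(table, mu, sdd, maternal_layer = 1,
                              fetal_layer = max_layer_index(table$records)) {
  df <- abs(sensitivity_derivative(table, mu, sdd, fetal_layer))
  dm_ <- abs(sensitivity_derivative(table, mu, sdd, maternal_layer))
  if (df + dm_ == 0) {
    abort("Both derivatives vanish: fetal sensitivity undefined for this ring.",
          class = "tfo_error_undefined")
  }
  df / (df + dm_)
}

#' Fetal-sensitive and total intensity
#'
#' Splits the ring intensity into the contribution of photons that probed
#' the fetal layer (`L_f > 0`) and the total. Their ratio approaches 1 at
#' large SDD, where essentially every detected photon is fetal sensitive.
#'
#' @inheritParams intensity
#' @return Tibble with columns `sensitive`, `total`, `ratio`.
#' @export
fetal_sensitive_intensity <- function(table, mu, sdd) {
  check_mu(table, mu)
  rec <- classify_fetal_sensitive(ring_collect(table, sdd))
  L <- layer_matrix(rec)
  contrib <- rec$weight * exp(-drop(L %*% mu))
  total <- sum(contrib) / table$n_launched
  sens <- sum(contrib[rec$fetal_sensitive]) / table$n_launched
  tibble::tibble(sensitive = sens, total = total,
                 ratio = if (total > 0) sens / total else NA_real_)
}

#' Exponential Pulsation Ratio at one ring
#'
#' `EPR = I2 / I1`, the diastolic-peak over systolic-trough intensity; >= 1
#' whenever the diastolic fetal absorption does not exceed the systolic one.
#'
#' @inheritParams intensity
#' @param mu_systole,mu_diastole Per-layer absorption assignments for the
#'   two pulsation extremes. They should differ only in the fetal layer; if
#'   not, a warning is issued and the plain intensity ratio is returned.
#' @return The EPR (dimensionless).
#' @export
epr <- function(table, mu_systole, mu_diastole, sdd) {
  check_mu(table, mu_systole); check_mu(table, mu_diastole)
  m <- length(mu_systole)
  if (any(mu_systole[-m] != mu_diastole[-m])) {
    warn("Assignments differ outside the fetal layer; returning the raw intensity ratio.")
  }
  i1 <- intensity(table, mu_systole, sdd)
  if (i1 <= 0) {
    abort("Zero systolic intensity (empty ring): EPR undefined.",
          class = "tfo_error_undefined")
  }
  intensity(table, mu_diastole, sdd) / i1
}

#' First-order EPR shift under a non-fetal absorption perturbation
#'
#' How much the EPR at one ring moves when one layer's absorption is scaled
#' by `1 + frac` in both pulsation states. Computed through the derivative
#' identity `d ln(EPR) / d mu_a,j = E_sys[L_j] - E_dia[L_j]` (intensity-
#' weighted means over the ring), which shares every photon path between
#' the two states; the equivalent finite exponential-reweighting estimator
#' has far larger Monte Carlo variance because `exp(delta mu * L_j)` spans
#' orders of magnitude across the ring. A perfectly isolated EPR would
#' return 0; the residual quantifies the coupling induced by within-ring
#' correlation between the layer's pathlength and the fetal pathlength.
#'
#' @inheritParams epr
#' @param layer Perturbed layer index (default 1, the maternal wall).
#' @param frac Fractional absorption perturbation (default 0.2).
#' @return The first-order change in EPR (signed, for `+frac`).
#' @export
epr_layer_shift <- function(table, mu_systole, mu_diastole, sdd,
                            layer = 1, frac = 0.2) {
  delta <- numeric(length(mu_systole))
  delta[layer] <- frac * mu_systole[layer]
  epr_perturbation_shift(table, mu_systole, mu_diastole, sdd, delta, delta)
}

#' @rdname epr_layer_shift
#' @param delta_systole,delta_diastole Per-layer absorption increments
#'   applied to the systolic and diastolic assignments respectively; they
#'   may differ, e.g. when the perturbation changes the pulsation gap
#'   itself.
#' @export
epr_perturbation_shift <- function(table, mu_systole, mu_diastole, sdd,
                                   delta_systole, delta_diastole) {
  check_mu(table, mu_systole); check_mu(table, mu_diastole)
  stopifnot(length(delta_systole) == length(mu_systole),
            length(delta_diastole) == length(mu_diastole))
  rec <- ring_collect(table, sdd)
  L <- layer_matrix(rec)
  w_sys <- rec$weight * exp(-drop(L %*% mu_systole))
  w_dia <- rec$weight * exp(-drop(L %*% mu_diastole))
  if (sum(w_sys) <= 0) {
    abort("Zero systolic intensity (empty ring).", class = "tfo_error_undefined")
  }
  e <- sum(w_dia) / sum(w_sys)
  mean_s <- drop(crossprod(L, w_sys)) / sum(w_sys)
  mean_d <- drop(crossprod(L, w_dia)) / sum(w_dia)
  e * sum(mean_s * delta_systole - mean_d * delta_diastole)
}

#' Ratio-of-Ratios from two per-wavelength EPRs
#'
#' The conventional pulse-oximetry feature: `RoR = ln(EPR_wl1) / ln(EPR_wl2)`.
#' For small fetal pulsation this reduces to the usual AC/DC ratio of ratios.
#'
#' @param epr_wl1,epr_wl2 Per-wavelength EPRs (> 0, `epr_wl2 != 1`).
#' @return The RoR (dimensionless).
#' @export
ror <- function(epr_wl1, epr_wl2) {
  if (any(epr_wl1 <= 0) || any(epr_wl2 <= 0)) {
    abort("EPRs must be positive.", class = "tfo_error_undefined")
  }
  if (any(epr_wl2 == 1)) {
    abort("RoR undefined: denominator EPR equals 1.", class = "tfo_error_undefined")
  }
  log(epr_wl1) / log(epr_wl2)
}

#' Smooth an EPR-vs-SDD curve
#'
#' Monte Carlo noise in raw per-ring EPRs is reduced by (1) taking the
#' divided central difference of the curve (one-sided at the ends), (2) a
#' 2-point moving average over the difference sequence, and (3) regenerating
#' the curve by cumulative summation anchored at the first point. Affine
#' curves are fixed points of the procedure.
#'
#' @param sdd Strictly increasing SDDs, mm.
#' @param values EPR values, same length.
#' @return Smoothed values, same length. With fewer than 3 points the input
#'   is returned with a warning.
#' @export
smooth_epr_curve <- function(sdd, values) {
  n <- length(values)
  stopifnot(length(sdd) == n)
  if (n < 3) {
    warn("Fewer than 3 points: returning the curve unsmoothed.")
    return(values)
  }
  if (is.unsorted(sdd, strictly = TRUE)) {
    abort("SDDs must be strictly increasing.", class = "tfo_error_config")
  }
  d <- numeric(n)
  d[1] <- (values[2] - values[1]) / (sdd[2] - sdd[1])
  d[n] <- (values[n] - values[n - 1]) / (sdd[n] - sdd[n - 1])
  if (n > 2) {
    i <- 2:(n - 1)
    d[i] <- (values[i + 1] - values[i - 1]) / (sdd[i + 1] - sdd[i - 1])
  }
  e <- (d[-n] + d[-1]) / 2
  out <- numeric(n)
  out[1] <- values[1]
  for (i in seq_len(n - 1)) out[i + 1] <- out[i] + e[i] * (sdd[i + 1] - sdd[i])
  out
}

#' Pathlength distribution summary for one ring
#'
#' Empirical quartiles and mean of the total pathlength or of one layer's
#' partial pathlength among the ring's detected photons.
#'
#' @inheritParams intensity
#' @param component `"total"`, `"fetal"`, or a layer index.
#' @return One-row tibble: `min`, `q1`, `median`, `q3`, `max`, `mean`, `n`.
#' @export
pathlength_summary <- function(table, sdd, component = "total") {
  rec <- ring_collect(table, sdd)
  if (nrow(rec) == 0) {
    abort("Empty ring: no pathlength distribution.", class = "tfo_error_undefined")
  }
  L <- layer_matrix(rec)
  x <- if (identical(component, "total")) rowSums(L)
       else if (identical(component, "fetal")) L[, ncol(L)]
       else L[, component]
  q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  tibble::tibble(min = min(x), q1 = q[1], median = q[2], q3 = q[3],
                 max = max(x), mean = mean(x), n = length(x))
}

#' Raw EPR-vs-SDD curve over all rings
#'
#' @inheritParams epr
#' @return Tibble with `sdd` and `epr`; rings with zero systolic intensity
#'   are dropped.
#' @export
epr_curve <- function(table, mu_systole, mu_diastole) {
  purrr::map_dfr(table$detectors$sdd, function(s) {
    i1 <- intensity(table, mu_systole, s)
    if (i1 <= 0) return(tibble::tibble(sdd = s, epr = NA_real_))
    tibble::tibble(sdd = s, epr = intensity(table, mu_diastole, s) / i1)
  }) |> dplyr::filter(!is.na(.data$epr))
}

#' EPR features for a hemodynamic sweep over one pathlength table
#'
#' Batch white-MC reweighting: for every row of a single-wavelength,
#' single-geometry sweep, compute the per-ring EPR curve, smooth it with
#' [smooth_epr_curve()], and (optionally) interpolate it at the feature
#' SDDs. The interpolated values feed all further analysis.
#'
#' @param table A `tfo_table` for the sweep's geometry and wavelength.
#' @param grid_wl Sweep rows (one wavelength, one `dm`), as from
#'   [sweep_grid()] filtered to the table's wavelength.
#' @param sdd_out Feature SDDs, mm (defaults to the five-detector probe
#'   layout 15/33/46/68/94 mm).
#' @param smooth,interpolate Toggles for the smoothing and interpolation
#'   steps; with `interpolate = FALSE` the table's own ring SDDs are used.
#' @param pulsation,venous_fraction,blood_fraction Blood-model constants.
#' @param noise Optional [noise_config()]. When supplied, the systolic and
#'   diastolic ring intensities receive independent photodetector noise
#'   draws (seeds `seed` and `seed + 1`) before the EPR ratio is taken —
#'   the evaluation-side protocol for noisy-data studies, where the
#'   estimator is trained on clean features and evaluated on noisy ones.
#'   Noisy intensities are floored at a tiny positive value so ratios stay
#'   defined.
#' @return Long tibble: the grid columns plus `sdd` and `epr`.
#' @export
epr_sweep <- function(table, grid_wl, sdd_out = c(15, 33, 46, 68, 94),
                      smooth = TRUE, interpolate = TRUE,
                      pulsation = 0.025, venous_fraction = 0.75,
                      blood_fraction = 0.05, noise = NULL) {
  stopifnot(inherits(table, "tfo_table"), nrow(grid_wl) >= 1)
  mu_sys <- sweep_mu_matrix(grid_wl, "systole", pulsation, venous_fraction, blood_fraction)
  mu_dia <- sweep_mu_matrix(grid_wl, "diastole", pulsation, venous_fraction, blood_fraction)
  rec <- table$records
  L <- layer_matrix(rec)
  nd <- length(table$detectors$sdd)
  I_sys <- intensity_batch_cpp(L, rec$weight, rec$detector, nd, mu_sys, table$n_launched)
  I_dia <- intensity_batch_cpp(L, rec$weight, rec$detector, nd, mu_dia, table$n_launched)
  if (!is.null(noise)) {
    stopifnot(inherits(noise, "tfo_noise_config"))
    n2 <- noise; n2$seed <- noise$seed + 1
    floor_pos <- .Machine$double.xmin
    I_sys <- pmax(inject_noise(I_sys, noise), floor_pos)
    I_dia <- pmax(inject_noise(I_dia, n2), floor_pos)
  }
  sdds <- table$detectors$sdd
  out_sdd <- if (interpolate) sdd_out else sdds
  purrr::map_dfr(seq_len(nrow(grid_wl)), function(a) {
    ok <- I_sys[, a] > 0
    ep <- I_dia[ok, a] / I_sys[ok, a]
    s <- sdds[ok]
    if (smooth && length(ep) >= 3) ep <- smooth_epr_curve(s, ep)
    val <- if (interpolate) approx(s, ep, xout = out_sdd, rule = 2)$y else ep
    dplyr::bind_cols(grid_wl[a, ], tibble::tibble(sdd = out_sdd, epr = val))
  })
}

#' Pivot an EPR sweep to estimator feature matrices
#'
#' Builds the wide per-sample feature tibble consumed by the estimator:
#' EPR features are one column per (wavelength, SDD) pair (10 in the default
#' two-wavelength, five-detector setup); RoR features collapse the two
#' wavelengths to one log-ratio per detector (5 columns). The label is the
#' fetal arterial saturation in percent.
#'
#' @param long Output of [epr_sweep()], possibly row-bound across
#'   wavelengths and geometries.
#' @param type `"epr"` or `"ror"`.
#' @return Tibble with id columns (`dm`, `sm`, `hbm`, `sf`, `hbf`), the
#'   feature columns, and `label` (percent).
#' @export
feature_matrix <- function(long, type = c("epr", "ror")) {
  type <- match.arg(type)
  wls <- sort(unique(long$wavelength))
  wide <- long |>
    tidyr::pivot_wider(names_from = c("wavelength", "sdd"),
                       values_from = "epr", names_prefix = "epr_") |>
    mutate(label = .data$sf * 100)
  if (type == "epr") return(wide)
  stopifnot(length(wls) == 2)
  sdds <- sort(unique(long$sdd))
  for (s in sdds) {
    num <- log(wide[[paste0("epr_", wls[1], "_", s)]])
    den <- log(wide[[paste0("epr_", wls[2], "_", s)]])
    # a detector whose EPR is exactly 1 saw no fetal pulsation; its RoR is
    # the 0/0 limit and is encoded as the neutral value 0
    wide[[paste0("ror_", s)]] <- ifelse(den == 0, 0, num / den)
  }
  wide |> select(-dplyr::starts_with("epr_"))
}
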