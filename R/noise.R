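# Photodetector noise model: shot noise of the photocurrent, thermal noise
# of the transimpedance gain resistor, and per-detector opamp gains chosen
# to equalize received optical power. Dark current and physiological noise
# are deliberately excluded.

.Q_ELECTRON <- 1.602176634e-19  # C
.K_BOLTZMANN <- 1.380649e-23    # J/K

#' Noise configuration
#'
#' Physical constants and scenario switches for [inject_noise()]. The
#' bandwidth, temperature and gain resistance defaults (80 Hz, 300 K,
#' 10 MOhm) describe a modest transimpedance front end; the
#' `source_power` scale (W) converts normalized simulated intensity into
#' received optical power and therefore sets the effective SNR — report it
#' alongside any noisy-data result.
#'
#' @param scenario `"shot_only"` or `"shot_plus_measurement"`.
#' @param responsivity Photodiode responsivity, A/W.
#' @param bandwidth Noise bandwidth B, Hz.
#' @param temperature TIA temperature, K.
#' @param resistance Gain resistor, Ohm.
#' @param gains Per-detector gain vector (scenario 2); see [compute_gains()].
#' @param source_power Source optical power scale, W.
#' @param seed RNG seed for the injected draws.
#' @return A `tfo_noise_config` list.
#' @export
noise_config <- function(scenario = c("shot_only", "shot_plus_measurement"),
                         responsivity = 0.60, bandwidth = 80,
                         temperature = 300, resistance = 10e6,
                         gains = NULL, source_power = 10e-3, seed = 1) {
  scenario <- match.arg(scenario)
  stopifnot(responsivity > 0, bandwidth > 0, temperature > 0,
            resistance > 0, source_power > 0)
  structure(list(scenario = scenario, responsivity = responsivity,
                 bandwidth = bandwidth, temperature = temperature,
                 resistance = resistance, gains = gains,
                 source_power = source_power, seed = seed),
            class = "tfo_noise_config")
}

#' Photocurrent generated by received optical power
#'
#' @param power Received optical power, W (>= 0).
#' @param responsivity Photodiode responsivity, A/W (default 0.60).
#' @return Photocurrent, A.
#' @export
photocurrent <- function(power, responsivity = 0.60) {
  if (any(power < 0)) abort("Optical power must be >= 0.", class = "tfo_error_config")
  responsivity * power
}

#' Shot-noise current standard deviation
#'
#' `sigma_shot = sqrt(2 q B i_k)` for photocurrent `i_k` and bandwidth `B`.
#'
#' @param i_k Photocurrent, A (>= 0).
#' @param bandwidth Noise bandwidth, Hz.
#' @return Current standard deviation, A.
#' @export
shot_sigma <- function(i_k, bandwidth) {
  stopifnot(all(i_k >= 0), bandwidth > 0)
  sqrt(2 * .Q_ELECTRON * bandwidth * i_k)
}

#' Thermal (Johnson) noise current standard deviation
#'
#' `sigma_thermal = sqrt(4 k_B T B / R)` for the TIA gain resistor.
#'
#' @param temperature Temperature, K.
#' @param bandwidth Noise bandwidth, Hz.
#' @param resistance Gain resistance, Ohm.
#' @return Current standard deviation, A.
#' @export
thermal_sigma <- function(temperature, bandwidth, resistance) {
  stopifnot(temperature > 0, bandwidth > 0, resistance > 0)
  sqrt(4 * .K_BOLTZMANN * temperature * bandwidth / resistance)
}

#' Per-detector gains normalizing received power
#'
#' `G_d = P_ref / P_d`, so every post-gain power equals the reference
#' detector's.
#'
#' @param powers Baseline per-detector optical powers (> 0).
#' @param reference Index of the reference detector.
#' @return Gain vector.
#' @export
compute_gains <- function(powers, reference = 1) {
  if (any(powers <= 0)) abort("Baseline powers must be > 0.", class = "tfo_error_config")
  powers[reference] / powers
}

#' Inject photodetector noise into simulated intensities
#'
#' Converts normalized intensities to optical power via the source-power
#' scale, then to photocurrent, and adds zero-mean Gaussian noise in current
#' units, converted back to intensity units. Scenario 1 uses shot noise
#' only; scenario 2 applies the per-detector gain first and adds the
#' root-sum-square of shot and thermal noise. Draws are independent per
#' value and reproducible under the config seed.
#'
#' @param intensities Numeric vector (or matrix, detectors in rows) of
#'   normalized intensities (>= 0).
#' @param cfg A [noise_config()].
#' @param detector Integer vector/matrix mapping each intensity to its
#'   detector (needed for gains in scenario 2; defaults to row index for a
#'   matrix, 1 otherwise).
#' @return Noisy intensities, same shape as the input.
#' @export
inject_noise <- function(intensities, cfg, detector = NULL) {
  stopifnot(inherits(cfg, "tfo_noise_config"), all(intensities >= 0))
  dims <- dim(intensities)
  x <- as.numeric(intensities)
  det <- if (!is.null(detector)) as.integer(detector)
         else if (!is.null(dims)) rep(seq_len(dims[1]), times = dims[2])
         else rep(1L, length(x))
  power <- x * cfg$source_power
  i_k <- photocurrent(power, cfg$responsivity)
  sig_shot <- shot_sigma(i_k, cfg$bandwidth)
  set.seed(cfg$seed)
  out <- if (cfg$scenario == "shot_only") {
    x + rnorm(length(x), 0, 1) * sig_shot / cfg$responsivity / cfg$source_power
  } else {
    if (is.null(cfg$gains)) {
      abort("Scenario 2 needs per-detector gains (see compute_gains()).",
            class = "tfo_error_config")
    }
    if (max(det) > length(cfg$gains)) {
      abort("Gain vector shorter than the number of detectors.",
            class = "tfo_error_config")
    }
    g <- cfg$gains[det]
    sig <- sqrt(sig_shot^2 + thermal_sigma(cfg$temperature, cfg$bandwidth,
                                           cfg$resistance)^2)
    g * x + rnorm(length(x), 0, 1) * sig / cfg$responsivity / cfg$source_power
  }
  if (!is.null(dims)) dim(out) <- dims
  out
}
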