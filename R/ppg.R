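# Synthetic frequency-multiplexed dual-wavelength PPG and the extraction
# chain: synchronous demodulation at the LED toggle frequency, two-stage
# anti-alias decimation to 80 Hz, lower-envelope DC (systolic trough),
# lock-in fetal AC at the instantaneous fetal heart rate, and the EPR
# series with moving-average smoothing.

#' Synthetic PPG configuration
#'
#' Describes a frequency-multiplexed acquisition: each LED is toggled
#' (50% duty square wave) at its carrier, so every detector channel carries
#' both wavelengths' basebands. Each baseband is a DC level plus
#' quasi-periodic maternal cardiac, maternal respiratory and fetal cardiac
#' components, frequency-modulated by the supplied rate traces.
#'
#' @param channels Tibble with one row per (detector, wavelength):
#'   columns `detector`, `wavelength`, `dc` (arbitrary intensity units) and
#'   `ac_fetal` (fetal sinusoid amplitude, same units; half the
#'   peak-to-peak). Often taken from forward-engine intensities so the
#'   pipeline-recovered EPR has a physics-grounded target.
#' @param fs Raw sample rate, per second.
#' @param out_rate Demodulated rate, per second.
#' @param carriers Named-by-position carrier frequencies (Hz), one per
#'   wavelength in `sort(unique(channels$wavelength))` order.
#' @param duration Record length, s.
#' @param fhr,mhr,mrr Fetal heart, maternal heart and maternal respiratory
#'   rate traces (Hz): scalars or vectors of length `fs * duration`.
#'   Physiologic bands are 1.5-3.5, 1.1-2 and 0.2-0.33 Hz respectively;
#'   values outside them only trigger a warning.
#' @param maternal_frac,resp_frac Maternal cardiac / respiratory amplitudes
#'   as fractions of each channel's DC.
#' @param noise_sd Additive white Gaussian noise on each baseband, same
#'   units as `dc`.
#' @param seed RNG seed.
#' @return A `tfo_ppg_config`.
#' @export
ppg_config <- function(channels, fs = 8000, out_rate = 80,
                       carriers = c(690, 940), duration = 30,
                       fhr = 2.5, mhr = 1.4, mrr = 0.25,
                       maternal_frac = 0.02, resp_frac = 0.01,
                       noise_sd = 0, seed = 1) {
  stopifnot(is.data.frame(channels),
            all(c("detector", "wavelength", "dc", "ac_fetal") %in% names(channels)),
            all(channels$dc > 0), all(channels$ac_fetal >= 0))
  if (any(carriers >= fs / 2)) {
    abort("Carriers must be below Nyquist.", class = "tfo_error_config")
  }
  wls <- sort(unique(channels$wavelength))
  if (length(carriers) != length(wls)) {
    abort("One carrier per wavelength is required.", class = "tfo_error_config")
  }
  rng_warn <- function(x, lo, hi, what) {
    if (any(x < lo | x > hi, na.rm = TRUE)) {
      warn(sprintf("%s trace outside the physiologic %.2f-%.2f Hz band.", what, lo, hi))
    }
  }
  rng_warn(fhr, 1.5, 3.5, "FHR"); rng_warn(mhr, 1.1, 2, "MHR")
  rng_warn(mrr, 0.2, 0.33, "MRR")
  structure(list(channels = tibble::as_tibble(channels), fs = fs,
                 out_rate = out_rate, carriers = setNames(carriers, wls),
                 duration = duration, fhr = fhr, mhr = mhr, mrr = mrr,
                 maternal_frac = maternal_frac, resp_frac = resp_frac,
                 noise_sd = noise_sd, seed = seed),
            class = "tfo_ppg_config")
}

trace_vec <- function(x, n) if (length(x) == 1) rep(x, n) else {
  stopifnot(length(x) == n); x
}

#' Band-limited LED toggle waveform
#'
#' A 50%-duty 0/1 square wave represented by its Fourier series truncated
#' below the Nyquist frequency — the waveform an acquisition front end with
#' an anti-alias filter actually records. Harmonics above Nyquist would
#' otherwise alias into the demodulated band as spurious discretization
#' lines. The fundamental amplitude is `2/pi`, as for the ideal square.
#'
#' @param fc Toggle (carrier) frequency, Hz.
#' @param t Sample times, s.
#' @param fs Sample rate, per second.
#' @return Waveform values in (approximately) \[0, 1\].
#' @export
square_carrier <- function(fc, t, fs) {
  s <- rep(0.5, length(t))
  k <- 1
  while (k * fc < fs / 2) {
    s <- s + (2 / (k * pi)) * sin(2 * pi * k * fc * t)
    k <- k + 2
  }
  s
}

#' Synthesize a multiplexed PPG record
#'
#' Builds each (detector, wavelength) baseband, multiplies it by its 50%-duty
#' square-wave carrier, and sums per detector. Ground truth per channel —
#' the systolic trough `I1 = DC - AC`, the fetal amplitude, and the implied
#' `EPR = (2 AC + I1) / I1` — is stored alongside.
#'
#' @param cfg A [ppg_config()].
#' @return A `tfo_ppg`: `raw` matrix (samples x detectors), `t`, `fs`,
#'   `traces` tibble (`t`, `fhr`, `mhr`, `mrr`), `truth` tibble, `cfg`.
#' @export
synthesize_ppg <- function(cfg) {
  stopifnot(inherits(cfg, "tfo_ppg_config"))
  n <- round(cfg$fs * cfg$duration)
  t <- (seq_len(n) - 1) / cfg$fs
  fhr <- trace_vec(cfg$fhr, n); mhr <- trace_vec(cfg$mhr, n)
  mrr <- trace_vec(cfg$mrr, n)
  ph_f <- 2 * pi * cumsum(fhr) / cfg$fs
  ph_m <- 2 * pi * cumsum(mhr) / cfg$fs
  ph_r <- 2 * pi * cumsum(mrr) / cfg$fs
  dets <- sort(unique(cfg$channels$detector))
  set.seed(cfg$seed)
  raw <- matrix(0, n, length(dets))
  for (i in seq_len(nrow(cfg$channels))) {
    ch <- cfg$channels[i, ]
    fc <- cfg$carriers[[as.character(ch$wavelength)]]
    base <- ch$dc +
      ch$dc * cfg$maternal_frac * sin(ph_m) +
      ch$dc * cfg$resp_frac * sin(ph_r) +
      ch$ac_fetal * sin(ph_f)
    if (cfg$noise_sd > 0) base <- base + rnorm(n, 0, cfg$noise_sd)
    sq <- square_carrier(fc, t, cfg$fs)
    d <- match(ch$detector, dets)
    raw[, d] <- raw[, d] + base * sq
  }
  truth <- cfg$channels |>
    mutate(i1 = .data$dc - .data$ac_fetal,
           epr_true = (2 * .data$ac_fetal + .data$i1) / .data$i1)
  structure(list(raw = raw, t = t, fs = cfg$fs, detectors = dets,
                 traces = tibble::tibble(t = t, fhr = fhr, mhr = mhr, mrr = mrr),
                 truth = truth, cfg = cfg),
            class = "tfo_ppg")
}

#' @export
print.tfo_ppg <- function(x, ...) {
  cat("<tfo_ppg> ", length(x$t), " samples @ ", x$fs, "/s, ",
      length(x$detectors), " detectors, ",
      nrow(x$truth), " channels\n", sep = "")
  invisible(x)
}

# low-pass + integer decimation, one stage
decimate_stage <- function(x, fs, cutoff, factor, order = 6) {
  bf <- signal::butter(order, cutoff / (fs / 2))
  y <- signal::filtfilt(bf, x)
  y[seq(1, length(y), by = factor)]
}

#' Demodulate one carrier from a raw multiplexed channel
#'
#' Synchronous (complex) demodulation at the carrier fundamental followed by
#' two-stage anti-alias low-pass filtering and decimation to `out_rate`.
#' For a 50%-duty 0/1 square-wave carrier the fundamental complex amplitude
#' is `1/pi` of the baseband, so the recovered magnitude is rescaled by the
#' documented constant `pi`. Cross-talk from the other carrier is attenuated
#' by the 30 Hz final low-pass (the carriers are 250 Hz apart).
#'
#' @param x Raw waveform at `fs`.
#' @param fs Raw sample rate.
#' @param carrier Carrier frequency, Hz (below Nyquist).
#' @param out_rate Output rate (must divide `fs`; default 80).
#' @return Tibble `t`, `ppg` (recovered baseband), `edge` (logical: within
#'   one filter settling length of either end).
#' @export
demodulate <- function(x, fs, carrier, out_rate = 80) {
  if (carrier >= fs / 2) abort("Carrier at or above Nyquist.", class = "tfo_error_config")
  n <- length(x)
  t <- (seq_len(n) - 1) / fs
  z <- x * exp(-2i * pi * carrier * t)
  f1 <- 10
  mid <- out_rate * f1
  re <- decimate_stage(Re(z), fs, mid / 4, round(fs / mid))
  im <- decimate_stage(Im(z), fs, mid / 4, round(fs / mid))
  re <- decimate_stage(re, mid, 30, f1)
  im <- decimate_stage(im, mid, 30, f1)
  ppg <- pi * sqrt(re^2 + im^2)
  tt <- (seq_along(ppg) - 1) / out_rate
  settle <- 0.5  # s; one effective filter length at the 30 Hz stage
  tibble::tibble(t = tt, ppg = ppg,
                 edge = tt < settle | tt > max(tt) - settle)
}

#' Demodulate every (detector, wavelength) channel of a record
#'
#' @param record A `tfo_ppg` from [synthesize_ppg()].
#' @return Long tibble: `detector`, `wavelength`, `t`, `ppg`, `edge`.
#' @export
demodulate_record <- function(record) {
  stopifnot(inherits(record, "tfo_ppg"))
  cfg <- record$cfg
  tidyr::expand_grid(detector = record$detectors,
                     wavelength = as.numeric(names(cfg$carriers))) |>
    purrr::pmap_dfr(function(detector, wavelength) {
      d <- match(detector, record$detectors)
      demodulate(record$raw[, d], record$fs,
                 cfg$carriers[[as.character(wavelength)]], cfg$out_rate) |>
        mutate(detector = detector, wavelength = wavelength,
               .before = 1)
    })
}

#' Lower envelope (systolic trough, I1)
#'
#' Morphological opening: a centered rolling minimum followed by a centered
#' rolling maximum, both over one window. This interpolates the signal's
#' local minima, lies at or below the input away from the edges, and is
#' exactly idempotent on its own output.
#'
#' @param x Demodulated PPG at `fs`.
#' @param fs Sample rate.
#' @param window_s Window length, s; should cover at least one fetal
#'   cardiac period.
#' @return Envelope, same length as `x`.
#' @export
lower_envelope <- function(x, fs, window_s) {
  if (round(window_s * fs) < 1) {
    abort("Window shorter than one sample.", class = "tfo_error_config")
  }
  w <- max(3, round(window_s * fs))
  if (w %% 2 == 0) w <- w + 1  # symmetric structuring element
  pad <- function(z) c(rep(z[1], w), z, rep(z[length(z)], w))
  crop <- function(z) z[(w + 1):(length(z) - w)]
  lo <- zoo::rollapply(pad(x), w, min, partial = TRUE, align = "center")
  crop(zoo::rollapply(lo, w, max, partial = TRUE, align = "center"))
}

#' Lock-in fetal AC amplitude
#'
#' Complex demodulation at the instantaneous fetal heart rate with a sliding
#' Hann-weighted integration window. Returns the sinusoid amplitude `A`
#' (half the peak-to-peak); the EPR formula consumes it as `AC_fetal`.
#'
#' @param x Demodulated PPG at `fs`.
#' @param fs Sample rate.
#' @param fhr FHR trace, Hz: scalar or vector of length `x`; `NA` gaps mask
#'   the output.
#' @param window_s Integration window, s (default 4: resolves FHR from MHR
#'   at their minimum separation while tracking FHR drift).
#' @return AC amplitude series, same length as `x` (`NA` where masked).
#' @export
lockin_fetal_ac <- function(x, fs, fhr, window_s = 4) {
  n <- length(x)
  fhr <- trace_vec(fhr, n)
  mask <- is.na(fhr)
  ph <- 2 * pi * cumsum(ifelse(mask, 0, fhr)) / fs
  z <- x * exp(-1i * ph)
  w <- round(window_s * fs)
  h <- 0.5 - 0.5 * cos(2 * pi * seq(0, 1, length.out = w))
  h <- h / sum(h)
  num <- complex(real = as.numeric(stats::filter(Re(z), h, sides = 2)),
                 imaginary = as.numeric(stats::filter(Im(z), h, sides = 2)))
  ac <- 2 * Mod(num)
  # edges where the window is truncated: recompute with partial windows
  half <- floor(w / 2)
  for (i in c(seq_len(min(half, n)), seq(max(1, n - half + 1), n))) {
    lo <- max(1, i - half); hi <- min(n, i + half)
    hh <- h[seq(lo - i + half + 1, hi - i + half + 1)]
    ac[i] <- 2 * Mod(sum(z[lo:hi] * hh) / sum(hh))
  }
  ac <- as.numeric(ac)
  ac[mask] <- NA_real_
  ac
}

#' EPR series from DC and fetal AC series
#'
#' Elementwise `EPR = (2 AC + DC) / DC` followed by a centered moving
#' average (default window 90 s). Nonpositive DC samples are masked.
#'
#' @param dc,ac Aligned series at `fs` (DC = systolic trough I1).
#' @param fs Sample rate.
#' @param smooth_window_s Moving-average window, s.
#' @return Tibble `t`, `epr_raw`, `epr`.
#' @export
epr_series <- function(dc, ac, fs, smooth_window_s = 90) {
  stopifnot(length(dc) == length(ac))
  raw <- ifelse(dc > 0, (2 * ac + dc) / dc, NA_real_)
  w <- max(1, round(smooth_window_s * fs))
  sm <- zoo::rollapply(raw, w, mean, na.rm = TRUE, partial = TRUE, align = "center")
  tibble::tibble(t = (seq_along(dc) - 1) / fs, epr_raw = raw, epr = sm)
}

#' Full extraction chain on a synthetic record
#'
#' Demodulation, lower envelope, lock-in, and EPR series for every
#' (detector, wavelength) channel; the per-channel EPR estimate is the
#' median of the smoothed series away from the filter edges.
#'
#' @param record A `tfo_ppg`.
#' @param smooth_window_s EPR moving-average window, s.
#' @param envelope_periods Lower-envelope window in fetal cardiac periods.
#' @param lockin_window_s Lock-in integration window, s.
#' @return List: `series` (long tibble with `t`, `dc`, `ac`, `epr_raw`,
#'   `epr`) and `summary` (per channel: `epr_hat`, joined with the stored
#'   truth when present).
#' @export
extract_epr <- function(record, smooth_window_s = 90, envelope_periods = 1,
                        lockin_window_s = 4) {
  dem <- demodulate_record(record)
  fs_out <- record$cfg$out_rate
  idx <- round(seq(1, length(record$t), length.out = sum(dem$detector == dem$detector[1] &
                                                         dem$wavelength == dem$wavelength[1])))
  fhr_out <- trace_vec(record$cfg$fhr, length(record$t))[idx]
  series <- dem |>
    group_by(.data$detector, .data$wavelength) |>
    group_modify(function(df, key) {
      win <- envelope_periods / mean(fhr_out, na.rm = TRUE)
      dc <- lower_envelope(df$ppg, fs_out, win)
      ac <- lockin_fetal_ac(df$ppg, fs_out, fhr_out, lockin_window_s)
      # samples inside the demodulation filter settling region are masked so
      # they cannot leak into the smoothed EPR series
      dc[df$edge] <- NA_real_
      es <- epr_series(dc, ac, fs_out, smooth_window_s)
      tibble::tibble(t = df$t, edge = df$edge, dc = dc, ac = ac,
                     epr_raw = es$epr_raw, epr = es$epr)
    }) |>
    ungroup()
  summary <- series |>
    dplyr::filter(!.data$edge) |>
    group_by(.data$detector, .data$wavelength) |>
    summarise(epr_hat = median(.data$epr, na.rm = TRUE),
              dc_hat = median(.data$dc, na.rm = TRUE),
              ac_hat = median(.data$ac, na.rm = TRUE), .groups = "drop")
  if (!is.null(record$truth)) {
    summary <- left_join(summary, record$truth, by = c("detector", "wavelength"))
  }
  list(series = series, summary = summary)
}
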