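# Shared fixtures: Monte Carlo tables are expensive, so they are simulated
# once per session and cached; everything is generated in code.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# baseline four-layer table: dm = 14 mm, 735 nm
fixture_table <- function(n = 4e5, dm = 14, wl = 735, seed = 101) {
  key <- paste("tab", n, dm, wl, seed, sep = "_")
  cached(key, simulate_paths(tissue_layers(wl, dm), n, seed = seed,
                             wavelength = wl, l_layer_max = tissue_budgets()))
}

fixture_states <- function(sf = 0.4, dm = 14, wl = 735, hbf = 160,
                           sm = 0.94, hbm = 120) {
  pulsation_pair(build_state(dm, blood_state(hbm, sm), blood_state(hbf, sf), wl))
}

# hand-built pathlength table for closed-form checks
make_table <- function(L, weight, detector, sdd_grid, n_launched,
                       radius = 2) {
  L <- as.matrix(L)
  colnames(L) <- paste0("L", seq_len(ncol(L)))
  det <- detector_grid(sdd_grid, radius = radius)
  structure(list(
    records = dplyr::bind_cols(
      tibble::tibble(detector = detector, sdd = sdd_grid[detector],
                     r = sdd_grid[detector]),
      tibble::as_tibble(L),
      tibble::tibble(weight = weight)),
    n_launched = n_launched, n_top_exit = length(weight),
    top_exit_weight = sum(weight), detectors = det, wavelength = NA_real_,
    fingerprint = "hand-built", seed = 0, oracle = FALSE),
    class = "tfo_table")
}

# diffusion-theory oracle: steady-state spatially resolved reflectance of a
# semi-infinite homogeneous medium (extrapolated-boundary dipole), matched
# refractive index (A = 1)
farrell_reflectance <- function(rho, mu_a, mu_s_prime) {
  mu_t <- mu_a + mu_s_prime
  z0 <- 1 / mu_t
  D <- 1 / (3 * mu_t)
  mu_eff <- sqrt(3 * mu_a * mu_t)
  zb <- 2 * D
  r1 <- sqrt(z0^2 + rho^2)
  r2 <- sqrt((z0 + 2 * zb)^2 + rho^2)
  (mu_s_prime / mu_t) / (4 * pi) *
    (z0 * (mu_eff + 1 / r1) * exp(-mu_eff * r1) / r1^2 +
     (z0 + 2 * zb) * (mu_eff + 1 / r2) * exp(-mu_eff * r2) / r2^2)
}

# smoothed EPR curve interpolated at arbitrary SDDs
epr_at <- function(tab, pair, sdd_out) {
  cur <- epr_curve(tab, mu_assignment(pair$systole), mu_assignment(pair$diastole))
  sm <- smooth_epr_curve(cur$sdd, cur$epr)
  approx(cur$sdd, sm, xout = sdd_out, rule = 2)$y
}

# photon-resampling bootstrap standard error of epr_at()
epr_at_se <- function(tab, pair, sdd_out, B = 40, seed = 1) {
  set.seed(seed)
  n <- nrow(tab$records)
  reps <- replicate(B, {
    tb <- tab
    tb$records <- tab$records[sample.int(n, n, replace = TRUE), ]
    epr_at(tb, pair, sdd_out)
  })
  if (is.null(dim(reps))) sd(reps) else apply(reps, 1, sd)
}

ppg_channels <- function(n_det = 2) {
  tidyr::expand_grid(detector = seq_len(n_det), wavelength = c(740, 850)) |>
    dplyr::mutate(dc = seq(1, 0.4, length.out = dplyr::n()),
                  ac_fetal = dc * 0.01)
}
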