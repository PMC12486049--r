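test_that("extinction table is positive with distinct chromophore spectra", {
  eps <- extinction_coeffs(c(650, 735, 740, 800, 850, 950))
  expect_true(all(eps$eps_hbo2 > 0))
  expect_true(all(eps$eps_hhb > 0))
  expect_true(all(eps$eps_hbo2 != eps$eps_hhb))
  # NIR crossover: deoxyhemoglobin dominates below ~800 nm, oxy above
  expect_gt(eps$eps_hhb[eps$wavelength == 735], eps$eps_hbo2[eps$wavelength == 735])
  expect_gt(eps$eps_hbo2[eps$wavelength == 850], eps$eps_hhb[eps$wavelength == 850])
  expect_error(extinction_coeffs(550), class = "tfo_error_wavelength")
  expect_error(extinction_coeffs(1100), class = "tfo_error_wavelength")
})

test_that("blood absorption follows the saturation-weighted extinction mix", {
  eps <- extinction_coeffs(735)
  # pure oxyhemoglobin limit and zero-chromophore limit
  expect_equal(mu_a_blood(blood_state(150, 1), 735), 150 * eps$eps_hbo2)
  expect_equal(mu_a_blood(blood_state(0, 0.5), 735), 0)
  # convexity: mixed saturation is the matching combination of the extremes
  expect_equal(mu_a_blood(blood_state(150, 0.6), 735),
               0.6 * mu_a_blood(blood_state(150, 1), 735) +
               0.4 * mu_a_blood(blood_state(150, 0), 735))
  # linear in concentration
  expect_equal(mu_a_blood(blood_state(300, 0.7), 735),
               2 * mu_a_blood(blood_state(150, 0.7), 735))
})

test_that("bulk tissue absorption = blood fraction + wavelength power law", {
  # bloodless tissue keeps only the power-law baseline
  z <- blood_state(0, 0.5)
  expect_equal(mu_a_tissue(z, z, 735), 7.84e7 * 735^-3.255)
  expect_equal(mu_a_tissue(z, z, 735), 0.0366, tolerance = 2e-2)
  # doubling both concentrations doubles the blood portion only
  a1 <- blood_state(100, 0.9); v1 <- venous_from_arterial(a1)
  a2 <- blood_state(200, 0.9); v2 <- venous_from_arterial(a2)
  base <- mu_a_tissue(z, z, 735)
  expect_equal(mu_a_tissue(a2, v2, 735) - base,
               2 * (mu_a_tissue(a1, v1, 735) - base))
  # venous (lower saturation) ordering tracks the extinction contrast:
  # deoxy dominates at 735 nm, oxy at 850 nm
  art <- blood_state(150, 0.98)
  ven <- venous_from_arterial(art)
  expect_lt(ven$saturation, art$saturation)
  expect_equal(ven$saturation, 0.75 * art$saturation)
  expect_gt(mu_a_blood(ven, 735), mu_a_blood(art, 735))
  expect_lt(mu_a_blood(ven, 850), mu_a_blood(art, 850))
})

test_that("tissue absorption is affine in hemoglobin with the expected slope", {
  wl <- 850
  eps <- extinction_coeffs(wl)
  s <- 0.6
  mus <- sapply(c(50, 100, 200), function(hb) {
    a <- blood_state(hb, s)
    mu_a_tissue(a, venous_from_arterial(a), wl)
  })
  slopes <- diff(mus) / c(50, 100)
  expect_equal(slopes[1], slopes[2])
  sv <- 0.75 * s
  expected_slope <- 0.05 * ((s * eps$eps_hbo2 + (1 - s) * eps$eps_hhb) +
                            (sv * eps$eps_hbo2 + (1 - sv) * eps$eps_hhb))
  expect_equal(unname(slopes[1]), expected_slope)
})

test_that("build_state assembles the four-layer model from static tables", {
  st <- build_state(14, blood_state(120, 0.97), blood_state(160, 0.4), 735)
  expect_equal(nrow(st$layers), 4)
  expect_equal(st$layers$name,
               c("maternal_wall", "uterus", "amniotic_fluid", "fetal_tissue"))
  # uterus and amniotic fluid carry the tabulated static properties
  expect_equal(st$layers$mu_a[2], 0.0158)
  expect_equal(st$layers$mu_s[2], 10.575)
  expect_equal(st$layers$n[3], 1.33)
  expect_equal(st$layers$thickness[3], 1)
  expect_equal(st$layers$thickness[1], 14)
  st850 <- build_state(14, blood_state(120, 0.97), blood_state(160, 0.4), 850)
  expect_equal(st850$layers$mu_a[2], 0.0991)
  expect_equal(st850$layers$mu_s[2], 8.125)
  # maternal saturation only touches layer-1 absorption
  stb <- build_state(14, blood_state(120, 0.90), blood_state(160, 0.4), 735)
  expect_false(st$layers$mu_a[1] == stb$layers$mu_a[1])
  expect_equal(st$layers$mu_a[-1], stb$layers$mu_a[-1])
  expect_equal(st$layers$mu_s, stb$layers$mu_s)
  expect_error(build_state(2, blood_state(120, 0.9), blood_state(160, 0.4), 735),
               class = "tfo_error_config")
})

test_that("the pulsation pair changes only fetal hemoglobin, by 2.5%", {
  st <- build_state(14, blood_state(120, 0.97), blood_state(160, 0.4), 735)
  pp <- pulsation_pair(st)
  expect_equal(pp$systole$fetal$hb_conc / pp$diastole$fetal$hb_conc, 1.025)
  expect_equal(mu_assignment(pp$systole)[1:3], mu_assignment(pp$diastole)[1:3])
  expect_gt(mu_assignment(pp$systole)[4], mu_assignment(pp$diastole)[4])
  # diastolic-over-systolic intensity ratio >= 1 on any table
  tab <- fixture_table(n = 1e5)
  e <- epr(tab, mu_assignment(pp$systole), mu_assignment(pp$diastole),
           tab$detectors$sdd[9])
  expect_gte(e, 1)
  # a systolic input state round-trips to the same pair
  pp2 <- pulsation_pair(pp$systole)
  expect_equal(pp2$diastole$fetal$hb_conc, st$fetal$hb_conc)
})

test_that("sweep enumeration is a deterministic cartesian product", {
  g <- sweep_grid(dm = c(10, 14), sm = c(0.9, 0.95), sf = 0.4, hbm = 120,
                  hbf = 160, wavelengths = c(735, 850))
  expect_equal(nrow(g), 8)
  expect_equal(g, sweep_grid(dm = c(10, 14), sm = c(0.9, 0.95), sf = 0.4,
                             hbm = 120, hbf = 160, wavelengths = c(735, 850)))
  # dm is the outermost axis
  expect_equal(g$dm, rep(c(10, 14), each = 4))
  g1 <- sweep_grid(dm = 14, sm = 0.9, sf = 0.4, hbm = 120, hbf = 160,
                   wavelengths = 735)
  expect_equal(nrow(g1), 1)
  en <- enumerate_sweep(g1)
  expect_s3_class(en$pair[[1]]$systole, "tfo_state")
  expect_error(sweep_grid(dm = numeric(0)), class = "tfo_error_config")
})
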