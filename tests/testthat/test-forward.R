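test_that("intensity reduces to closed forms on hand-built tables", {
  # single photon: 10 mm in layer 1 at mu_a = 0.05 -> w * exp(-0.5)
  tab <- make_table(L = rbind(c(10, 0, 0, 0)), weight = 0.9, detector = 1L,
                    sdd_grid = c(15, 30), n_launched = 4)
  expect_equal(intensity(tab, c(0.05, 0, 0, 0), 15), 0.9 * exp(-0.5) / 4)
  # zero absorption returns the detected weight fraction
  expect_equal(intensity(tab, rep(0, 4), 15), 0.9 / 4)
  expect_equal(intensity(tab, rep(0, 4), 30), 0)
  expect_error(intensity(tab, c(0.1, 0.1), 15), class = "tfo_error_mu")
  expect_error(intensity(tab, c(-1, 0, 0, 0), 15), class = "tfo_error_mu")
})

test_that("intensity is strictly decreasing in each layer's absorption", {
  tab <- fixture_table(n = 1e5)
  s <- tab$detectors$sdd[8]
  mu <- mu_assignment(fixture_states()$diastole)
  for (j in 1:4) {
    up <- mu; up[j] <- mu[j] + 0.005
    expect_lt(intensity(tab, up, s), intensity(tab, mu, s))
  }
})

test_that("white-MC reweighting equals the in-flight absorption oracle", {
  st <- fixture_states(sf = 0.4, dm = 10)$diastole
  tw <- simulate_paths(st, 5e4, seed = 11)
  to <- simulate_paths(st, 5e4, seed = 11, oracle = TRUE)
  expect_equal(nrow(tw$records), nrow(to$records))
  L <- as.matrix(tw$records[paste0("L", 1:4)])
  pred <- tw$records$weight * exp(-drop(L %*% mu_assignment(st)))
  expect_equal(pred, to$records$weight, tolerance = 1e-10)
})

test_that("sensitivity derivatives match finite differences and scale linearly", {
  tab <- fixture_table(n = 1e5)
  s <- tab$detectors$sdd[8]
  mu <- mu_assignment(fixture_states()$diastole)
  for (j in c(1, 4)) {
    d <- sensitivity_derivative(tab, mu, s, j)
    expect_lte(d, 0)
    h <- 1e-6
    up <- mu; up[j] <- mu[j] + h
    dn <- mu; dn[j] <- mu[j] - h
    fd <- (intensity(tab, up, s) - intensity(tab, dn, s)) / (2 * h)
    expect_equal(d, fd, tolerance = 1e-6)
  }
  # layer with no pathlength mass has zero derivative
  hand <- make_table(L = rbind(c(10, 0, 0, 5), c(12, 0, 0, 0)),
                     weight = c(1, 1), detector = c(1L, 1L),
                     sdd_grid = 15, n_launched = 2)
  expect_equal(sensitivity_derivative(hand, rep(0, 4), 15, 2), 0)
  # at mu = 0 the derivative is -mean(w * Lj): doubling Lj doubles it
  expect_equal(sensitivity_derivative(hand, rep(0, 4), 15, 4), -5 / 2)
  hand2 <- make_table(L = rbind(c(10, 0, 0, 10), c(12, 0, 0, 0)),
                      weight = c(1, 1), detector = c(1L, 1L),
                      sdd_grid = 15, n_launched = 2)
  expect_equal(sensitivity_derivative(hand2, rep(0, 4), 15, 4), -10 / 2)
})

test_that("fetal sensitivity spans its limits and grows with SDD", {
  none <- make_table(L = rbind(c(10, 2, 1, 0)), weight = 1, detector = 1L,
                     sdd_grid = 15, n_launched = 1)
  expect_equal(fetal_sensitivity(none, rep(0.01, 4), 15), 0)
  pure <- make_table(L = rbind(c(0, 2, 1, 8)), weight = 1, detector = 1L,
                     sdd_grid = 15, n_launched = 1)
  expect_equal(fetal_sensitivity(pure, rep(0.01, 4), 15), 1)
  degenerate <- make_table(L = rbind(c(0, 2, 1, 0)), weight = 1, detector = 1L,
                           sdd_grid = 15, n_launched = 1)
  expect_error(fetal_sensitivity(degenerate, rep(0.01, 4), 15),
               class = "tfo_error_undefined")
  tab <- fixture_table(n = 4e5)
  mu <- mu_assignment(fixture_states()$diastole)
  expect_gt(fetal_sensitivity(tab, mu, tab$detectors$sdd[14]),   # ~68 mm
            fetal_sensitivity(tab, mu, tab$detectors$sdd[2]))    # ~14.5 mm
})

test_that("fetal-sensitive intensity converges to the total at large SDD", {
  tab <- fixture_table(n = 4e5)
  mu <- mu_assignment(fixture_states()$diastole)
  out <- purrr::map_dfr(tab$detectors$sdd[c(2, 8, 14)],
                        function(s) fetal_sensitive_intensity(tab, mu, s))
  expect_true(all(out$sensitive <= out$total))
  expect_true(all(diff(out$ratio) > -0.02))
  expect_gt(out$ratio[3], out$ratio[1])
  # degenerate hand-built cases
  insens <- make_table(L = rbind(c(10, 0, 0, 0)), weight = 1, detector = 1L,
                       sdd_grid = 15, n_launched = 1)
  expect_equal(fetal_sensitive_intensity(insens, rep(0, 4), 15)$sensitive, 0)
  sens <- make_table(L = rbind(c(10, 0, 0, 3)), weight = 1, detector = 1L,
                     sdd_grid = 15, n_launched = 1)
  fsi <- fetal_sensitive_intensity(sens, rep(0, 4), 15)
  expect_equal(fsi$sensitive, fsi$total)
})

test_that("EPR equals the fetal-layer weighted-expectation identity exactly", {
  tab <- fixture_table(n = 1e5)
  pp <- fixture_states(sf = 0.3)
  ms <- mu_assignment(pp$systole); md <- mu_assignment(pp$diastole)
  s <- tab$detectors$sdd[9]
  e <- epr(tab, ms, md, s)
  expect_gte(e, 1)
  # identical assignments give exactly 1
  expect_equal(epr(tab, md, md, s), 1)
  # expectation form: weights a_i carry all non-fetal attenuation
  rec <- ring_collect(tab, s)
  L <- as.matrix(rec[paste0("L", 1:4)])
  a <- rec$weight * exp(-drop(L[, 1:3] %*% md[1:3]))
  e_expect <- sum(a * exp(-md[4] * L[, 4])) / sum(a * exp(-ms[4] * L[, 4]))
  expect_equal(e, e_expect, tolerance = 1e-12)
  # widening the systole-diastole absorption gap raises EPR monotonically
  gaps <- seq(0, 0.004, by = 0.001)
  eprs <- sapply(gaps, function(g) {
    ms2 <- md; ms2[4] <- md[4] + g
    epr(tab, ms2, md, s)
  })
  expect_true(all(diff(eprs) > 0))
  # cross-layer difference warns but still computes
  ms3 <- ms; ms3[1] <- ms[1] * 1.1
  expect_warning(epr(tab, ms3, md, s), "fetal")
  # empty ring is an error
  empty <- make_table(L = rbind(c(10, 0, 0, 0)), weight = 1, detector = 1L,
                      sdd_grid = c(15, 30), n_launched = 1)
  expect_error(epr(empty, rep(0, 4), rep(0, 4), 30),
               class = "tfo_error_undefined")
})

test_that("first-order EPR layer shift matches a small finite perturbation", {
  hand <- make_table(L = rbind(c(30, 2, 1, 5), c(40, 3, 1, 0),
                               c(35, 2, 1, 10)),
                     weight = c(1, 0.8, 1.2), detector = c(1L, 1L, 1L),
                     sdd_grid = 15, n_launched = 3)
  md <- c(0.05, 0.016, 0.012, 0.08)
  ms <- md; ms[4] <- md[4] + 0.002
  frac <- 1e-3
  scaled <- function(f) {
    ms2 <- ms; md2 <- md
    ms2[1] <- ms[1] * (1 + f); md2[1] <- md[1] * (1 + f)
    suppressWarnings(epr(hand, ms2, md2, 15))
  }
  fd <- scaled(frac) - scaled(0)
  expect_equal(epr_layer_shift(hand, ms, md, 15, layer = 1, frac = frac),
               fd, tolerance = 1e-4)
  # perturbing a layer with no pathlength spread leaves EPR untouched
  expect_equal(epr_layer_shift(hand, ms, md, 15, layer = 3, frac = 0.2), 0,
               tolerance = 1e-12)
})

test_that("RoR is the log-ratio of per-wavelength EPRs", {
  expect_equal(ror(exp(1), exp(2)), 0.5)
  expect_equal(ror(1.05, 1.05), 1)
  expect_error(ror(1.05, 1), class = "tfo_error_undefined")
  expect_error(ror(-1, 1.05), class = "tfo_error_undefined")
  # small-pulsation limit: ln(1 + 2AC/DC) ~ 2AC/DC, so RoR ~ ratio of AC/DC
  acdc1 <- 1e-4; acdc2 <- 3e-4
  expect_equal(ror(1 + 2 * acdc1, 1 + 2 * acdc2), acdc1 / acdc2,
               tolerance = 1e-3)
})

test_that("EPR curve smoothing fixes affine curves and matches hand arithmetic", {
  sdd <- c(10, 20, 30, 40, 50)
  expect_equal(smooth_epr_curve(sdd, rep(1.02, 5)), rep(1.02, 5))
  lin <- 1 + 0.001 * sdd
  expect_equal(smooth_epr_curve(sdd, lin), lin)
  # affine invariance holds on non-uniform grids too (divided differences)
  sdd_nu <- c(10, 14, 30, 31, 55)
  lin_nu <- 2 - 0.003 * sdd_nu
  expect_equal(smooth_epr_curve(sdd_nu, lin_nu), lin_nu)
  # worked 5-point zigzag: differences (1,0,0,0,-1), averaged
  # (.5,0,0,-.5), reintegrated from the first point
  expect_equal(smooth_epr_curve(1:5, c(1, 2, 1, 2, 1)),
               c(1, 1.5, 1.5, 1.5, 1))
  expect_warning(out <- smooth_epr_curve(1:2, c(1, 2)), "3 points")
  expect_equal(out, c(1, 2))
})

test_that("pathlength summaries behave like empirical quartiles", {
  single <- make_table(L = rbind(c(30, 5, 2, 8)), weight = 1, detector = 1L,
                       sdd_grid = 15, n_launched = 1)
  s1 <- pathlength_summary(single, 15, "total")
  expect_equal(s1$min, 45); expect_equal(s1$max, 45)
  expect_equal(s1$mean, 45); expect_equal(s1$median, 45)
  tab <- fixture_table(n = 4e5)
  s <- tab$detectors$sdd[9]
  tot <- pathlength_summary(tab, s, "total")
  fet <- pathlength_summary(tab, s, "fetal")
  expect_gte(tot$mean, fet$mean)
  expect_lte(tot$q1, tot$median); expect_lte(tot$median, tot$q3)
  expect_lte(tot$min, tot$mean);  expect_lte(tot$mean, tot$max)
  # a deeper fetus shifts fetal-pathlength mass toward zero
  deep <- fixture_table(n = 2e5, dm = 24, seed = 103)
  fet_deep <- pathlength_summary(deep, s, "fetal")
  expect_lt(fet_deep$median, fet$median)
  expect_lt(fet_deep$mean, fet$mean)
  expect_error(pathlength_summary(make_table(L = rbind(c(1, 0, 0, 0)),
                                             weight = 1, detector = 1L,
                                             sdd_grid = c(15, 30),
                                             n_launched = 1), 30),
               class = "tfo_error_undefined")
})

test_that("sweep features pivot to the estimator layouts", {
  tab735 <- fixture_table(n = 1e5)
  tab850 <- fixture_table(n = 1e5, wl = 850, seed = 102)
  grid <- sweep_grid(dm = 14, sm = 0.94, sf = c(0.2, 0.4, 0.6), hbm = 120,
                     hbf = 160)
  long <- dplyr::bind_rows(
    epr_sweep(tab735, grid[grid$wavelength == 735, ]),
    epr_sweep(tab850, grid[grid$wavelength == 850, ]))
  expect_equal(nrow(long), 3 * 2 * 5)
  expect_true(all(long$epr > 0))
  wide <- feature_matrix(long, "epr")
  expect_equal(nrow(wide), 3)
  expect_length(grep("^epr_", names(wide)), 10)
  expect_equal(wide$label, c(20, 40, 60))
  ror_wide <- feature_matrix(long, "ror")
  expect_length(grep("^ror_", names(ror_wide)), 5)
  expect_equal(ror_wide$ror_15,
               ror(wide$epr_735_15, wide$epr_850_15))
})
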