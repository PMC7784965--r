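test_that("local flux reproduces Fick's first law on a linear gradient", {
  z <- seq(-0.5, 0, 0.1)
  # slope -100 umol L-1 mm-1 = -1000 nmol cm-4; J = -D * dC/dz
  pr <- depth_profile("O2", z, 100 - 100 * z)
  fl <- local_flux(pr, 1.78e-5)
  expect_equal(fl$J, 1.78e-5 * 1000, tolerance = 1e-12)
  expect_equal(fl$J_mmol_m2_d, flux_mmol_m2_d(fl$J))
  # flat profile -> zero flux
  expect_equal(local_flux(depth_profile("O2", z, rep(50, 6)), 1.78e-5)$J, 0)
  expect_error(local_flux(pr, 1.78e-5, window = c(-0.05, 0)), ">= 3")
  expect_warning(
    local_flux(depth_profile("O2", seq(0, 1, 0.1), (seq(0, 1, 0.1))^2 * 50),
               1.78e-5), "curved")
})

test_that("DBL window detection finds the near-linear surface segment", {
  z <- seq(-0.6, 0.6, 0.06)
  v <- ifelse(z <= 0, 100 + 50 * z, 100 + 50 * z - 400 * z^2)
  pr <- depth_profile("O2", z, pmax(v, 0))
  w <- dbl_window(pr)
  expect_lte(w[2], 0)
  expect_gte(sum(pr$depth_mm >= w[1] & pr$depth_mm <= w[2]), 3)
  fl <- local_flux(pr, 1.78e-5, w)
  expect_equal(fl$J, -1.78e-5 * 500, tolerance = 1e-9)
})

test_that("single-zone inversion recovers parabolic curvature exactly", {
  z <- seq(0, 2, 0.1)
  D <- 1.78e-5
  for (a in c(-10, 4)) {     # dome (production) and bowl (consumption)
    pr <- depth_profile("O2", z, 100 + abs(a) * 4 + a * (z - 1)^2)
    fit <- fit_rate_profile(pr, D, zones = 1)
    # C'' = 2a umol L-1 mm-2 = 200a nmol cm-5; R = -D C''
    expect_equal(unname(fit$rates), -200 * a * D, tolerance = 1e-8)
    expect_lt(max(abs(residuals(fit))), 1e-10)
  }
  # a local minimum (convex-up) must read as consumption
  bowl <- fit_rate_profile(depth_profile("O2", z, 50 + 5 * (z - 1)^2), D, 1)
  expect_lt(bowl$rates, 0)
})

test_that("linear profiles yield zero rates in any zonation", {
  z <- seq(0, 3, 0.15)
  pr <- depth_profile("S_tot", z, 300 + 30 * z)
  for (m in 1:3)
    expect_equal(unname(fit_rate_profile(pr, D_S, m)$rates), rep(0, m),
                 tolerance = 1e-10)
})

test_that("fitted rate models conserve flux exactly", {
  # for every fit: integral of R over the domain = J(bottom) - J(top)
  set.seed(4)
  z <- seq(0, 3, 0.15)
  for (rep in 1:5) {
    v <- 300 + cumsum(rnorm(length(z), 0, 5))
    pr <- depth_profile("S_tot", z, pmax(v, 1))
    fit <- fit_rate_profile(pr, D_S, zones = 3)
    J <- rate_flux(fit, range(z))
    integral <- depth_integrate(fit)
    expect_equal(J[2] - J[1], integral,
                 tolerance = 1e-10 * max(abs(integral), 1e-6))
  }
})

test_that("model predictions interpolate the fit and refuse extrapolation", {
  z <- seq(0, 2, 0.2)
  pr <- depth_profile("O2", z, 100 - 10 * z^2)
  fit <- fit_rate_profile(pr, 1.78e-5, 1)
  expect_equal(predict(fit), fitted(fit))
  expect_equal(predict(fit, 1.3), 100 - 10 * 1.3^2, tolerance = 1e-6)
  expect_error(predict(fit, 2.5), "outside")
  expect_length(coef(fit), 1)
  s <- summary(fit)
  expect_s3_class(s, "summary.rate_profile")
  expect_equal(s$integral, s$flux_bottom - s$flux_top, tolerance = 1e-10)
})

test_that("forward-inverse loop recovers imposed zone rates", {
  st <- steady_three_zone
  sc <- st$scenario
  ps <- sample_profiles(st, 0.18, noise_sd = c(O2 = 0, S_tot = 0))
  sub <- trim_profile(ps$s_tot, 0.3, 3)
  fit <- fit_rate_profile(sub, D_S, zones = three_zone_truth$knots[2:3])
  expect_equal(unname(fit$rates[1]), three_zone_truth$rates[["cyano"]],
               tolerance = 0.05)
  expect_lt(abs(fit$rates[2]), 0.05 * abs(three_zone_truth$rates[["cyano"]]))
  expect_equal(unname(fit$rates[3]), three_zone_truth$rates[["production"]],
               tolerance = 0.05)
})

test_that("zonation selection finds the true structure and resists noise", {
  z <- seq(0, 2, 0.1)
  # single-zone truth
  pr1 <- depth_profile("O2", z, 100 - 10 * z^2)
  expect_length(select_zonation(pr1, 1.78e-5, max_zones = 3)$rates, 1)
  # flat noise-only profile: one zone, rate ~ 0
  pr0 <- depth_profile("O2", z, add_noise(rep(100, length(z)), 1, seed = 1))
  s0 <- select_zonation(pr0, 1.78e-5, max_zones = 3)
  expect_length(s0$rates, 1)
  expect_lt(abs(s0$rates), 0.2)
  # two-zone truth with strong contrast (consumption then inert), sigma = 1
  ps <- sample_profiles(steady_three_zone, 0.18,
                        noise_sd = c(O2 = 0, S_tot = 1), seed = 1)
  sub <- trim_profile(ps$s_tot, 0.3, 2.2)
  s2 <- select_zonation(sub, D_S, max_zones = 3)
  expect_length(s2$rates, 2)
  expect_lt(abs(s2$knots_mm[2] - 1.1), 0.18)  # boundary within one step
})

test_that("layer balances read net rates off boundary fluxes", {
  # linear profile: identical fluxes at both boundaries -> zero balance
  z <- seq(-0.5, 3, 0.1)
  lin <- depth_profile("S_tot", z, 300 + 20 * z)
  lb0 <- layer_balance(lin, D_S, c(0.5, 2))
  expect_equal(lb0$consumption, 0, tolerance = 1e-12)

  # consuming layer: J(top) - J(bottom) = imposed areal consumption
  ps <- sample_profiles(steady_three_zone, 0.18,
                        noise_sd = c(O2 = 0, S_tot = 0))
  lb <- layer_balance(ps$s_tot, D_S, c(0.3, 1.1))
  expect_equal(lb$consumption, three_zone_truth$areal_ap, tolerance = 0.03)

  # interior production zone: fluxes diverge upward and downward, so the
  # within-mat sulfide production is the sum of the outgoing magnitudes
  sc <- mat_scenario(domain_mm = c(0, 3), h_mm = 0.02,
                     boundary = list(O2 = c(100, 100), S_tot = c(100, 100)),
                     layers = list(mat_layer("above", 0, 1.4),
                                   mat_layer("source", 1.4, 2.2,
                                             rate = c(S_tot = 0.5)),
                                   mat_layer("below", 2.2, 3)))
  st <- solve_steady_state(sc)
  pp <- sample_profiles(st, 0.18, noise_sd = c(O2 = 0, S_tot = 0))
  lb2 <- layer_balance(pp$s_tot, D_S, c(1.4, 2.2), window_mm = 0.5)
  expect_lt(lb2$flux_top$J, 0)                  # upward above the source
  expect_gt(lb2$flux_bottom$J, 0)               # downward below it
  expect_equal(lb2$production,
               abs(lb2$flux_top$J) + abs(lb2$flux_bottom$J),
               tolerance = 1e-9)
  expect_equal(lb2$production, 0.5 * 0.08, tolerance = 0.03)
})

test_that("light-dark slope extraction returns the gross rate magnitude", {
  t <- seq(0, 10, 0.5)
  expect_equal(gross_rate_lightdark(t, 100 - 2 * t, "OP"), 2)
  expect_equal(gross_rate_lightdark(t, rep(80, length(t)), "AP"), 0)
  expect_equal(gross_rate_lightdark(t, 50 + 1.5 * t, "AP"), 1.5)
  expect_error(gross_rate_lightdark(t, 100 - 2 * t, "OP", window_s = 20),
               "window")
  expect_warning(gross_rate_lightdark(t, 100 - 5 * t + 0.4 * t^2, "OP",
                                      window_s = 6), "nonlinear")
  expect_warning(gross_rate_lightdark(t, 100 + 2 * t, "OP"), "wrong sign")
})

test_that("depth integration handles tables and fitted models", {
  tab <- data.frame(depth_mm = c(0, 0.5, 1), rate = c(1, 1, 1))
  expect_equal(depth_integrate(tab), 0.1)        # 1 nmol cm-3 s-1 over 1 mm
  expect_equal(depth_integrate(tab, c(0, 0.5)), 0.05)
  expect_equal(depth_integrate(data.frame(depth_mm = 0:1, rate = c(0, 0))), 0)
  expect_error(depth_integrate(tab, c(1, 1)), "empty")
  z <- seq(0, 2, 0.1)
  fit <- fit_rate_profile(depth_profile("O2", z, 100 - 10 * z^2), 1.78e-5, 1)
  J <- rate_flux(fit, c(0, 2))
  expect_equal(depth_integrate(fit), J[2] - J[1], tolerance = 1e-10)
})

test_that("finite differencing agrees with the model fit on clean data", {
  z <- seq(0, 2, 0.1)
  pr <- depth_profile("O2", z, 100 - 10 * z^2)
  fd <- finite_difference_rates(pr, 1.78e-5)
  expect_equal(fd$rate, rep(200 * 10 * 1.78e-5, nrow(fd)), tolerance = 1e-6)
})
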