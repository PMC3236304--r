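test_that("osmolarity sums solutes with counter-ion stoichiometry", {
  p <- mean_params()
  expect_equal(osmolarity(liquid_state(), p), 0.10)
  # 10 g/L glucose alone
  expect_equal(osmolarity(liquid_state(G = 10 / GLUCOSE_G_MOL), p),
               0.1555, tolerance = 1e-3)
  expect_equal(
    osmolarity(liquid_state(G = 0.02, Ac = 0.05, Lac = 0.01, CO2sol = 0.005),
               p),
    0.25)
  expect_error(liquid_state(G = -0.01), "negative")
  expect_error(osmolarity(c(X = 0, G = 1), p), "missing")
})

test_that("H2 inhibition and activation are exact complements below critical", {
  p <- mean_params()
  f0 <- regulation_factors(liquid_state(G = 0.02), p)
  expect_identical(f0$inhib_h2, 1)
  expect_identical(f0$act_h2, 0)
  for (r in seq(0.05, 0.95, by = 0.1)) {
    f <- regulation_factors(liquid_state(G = 0.02, H2aq = r * p$H2aq_crit), p)
    expect_equal(f$inhib_h2 + f$act_h2, 1)
    expect_equal(f$act_h2, r^p$n_H2)
  }
  # clamping at and above the critical concentration
  for (r in c(1, 1.5)) {
    f <- regulation_factors(liquid_state(G = 0.02, H2aq = r * p$H2aq_crit), p)
    expect_identical(f$inhib_h2, 0)
    expect_identical(f$act_h2, 1)
  }
})

test_that("80% of critical H2 with the mean exponent cuts the rate by 37%", {
  p <- mean_params()  # n_H2 = 4.50
  f <- regulation_factors(liquid_state(G = 1, H2aq = 0.8 * p$H2aq_crit), p)
  expect_equal(f$inhib_h2, 1 - 0.8^4.5)
  expect_equal(round(100 * f$act_h2), 37)
})

test_that("osmolarity factor follows the power law", {
  p <- mean_params()  # OSM_crit 0.28, n_mu 4.68
  s <- liquid_state(G = 0.0278)  # OSM = 0.1278
  f <- regulation_factors(s, p)
  expect_equal(f$osm_growth_factor, 1 - (0.1278 / 0.28)^4.68)
  expect_equal(f$osm_growth_factor, 0.9746, tolerance = 1e-4)
  # above critical osmolarity growth shuts off entirely
  f2 <- regulation_factors(liquid_state(G = 0.5), p)
  expect_identical(f2$osm_growth_factor, 0)
})

test_that("specific growth rate hits its Monod and inhibition limits", {
  p <- mean_params(OSM_background = 1e-9)
  # saturating glucose, no inhibitors
  expect_equal(specific_growth_rate(liquid_state(G = 1e-2), p), p$mu_max,
               tolerance = 1e-2)
  p2 <- mean_params(mu_max = 0.28, OSM_background = 1e-9)
  expect_equal(specific_growth_rate(liquid_state(G = 0.0278), p2),
               0.2795, tolerance = 2e-3)
  # 80% of critical dissolved H2
  mu <- specific_growth_rate(
    liquid_state(G = 10, H2aq = 0.8 * p$H2aq_crit), mean_params(
      OSM_background = 1e-9, OSM_crit = 1e3))
  expect_equal(mu / 0.28, 1 - 0.8^4.5, tolerance = 1e-2)
})

test_that("growth rate is monotone in glucose, H2 and osmolarity", {
  p <- mean_params()
  mus_h2 <- vapply(seq(0, 1.2 * p$H2aq_crit, length.out = 30), function(h)
    specific_growth_rate(liquid_state(G = 0.02, H2aq = h), p), numeric(1))
  expect_true(all(diff(mus_h2) <= 1e-12))
  p_free <- params_no_osm()  # glucose also raises osmolarity; isolate Monod
  mus_g <- vapply(seq(1e-6, 0.03, length.out = 30), function(g)
    specific_growth_rate(liquid_state(G = g), p_free), numeric(1))
  expect_true(all(diff(mus_g) >= -1e-12))
  mus_osm <- vapply(seq(0, 0.1, length.out = 30), function(ac)
    specific_growth_rate(liquid_state(G = 0.001, Ac = ac), p), numeric(1))
  expect_true(all(diff(mus_osm) <= 1e-12))
})

test_that("product coefficients follow the yield-linked structure", {
  p <- mean_params(R_AcF = 1.91, Y_GH2 = 4.77)
  f <- list(inhib_h2 = 1, act_h2 = 0, act_osm = 0)
  a <- product_alphas(f, p)
  expect_equal(a$alpha_Ac, 1.91)
  expect_equal(a$alpha_Lac, 0)
  expect_equal(a$alpha_H2, 1.91 * 4.77 / 2)
  expect_equal(a$alpha_H2, 4.556, tolerance = 1e-3)
  # at critical H2 acetate stops, lactate formation saturates
  f2 <- list(inhib_h2 = 0, act_h2 = 1, act_osm = 0.3)
  a2 <- product_alphas(f2, p)
  expect_identical(a2$alpha_Ac, 0)
  expect_equal(a2$alpha_Lac, p$R_LacF_H2 + p$R_LacF_OSM * 0.3)
  # the stoichiometric yields cancel: CO2 always tracks acetate
  for (act in c(0, 0.2, 0.7, 1)) {
    f3 <- list(inhib_h2 = 1 - act, act_h2 = act, act_osm = 0.1)
    a3 <- product_alphas(f3, p)
    expect_equal(a3$alpha_CO2, a3$alpha_Ac)
  }
})

test_that("liquid derivatives respect biomass and balance structure", {
  p <- mean_params()
  # no biomass: only exchange terms remain
  d0 <- liquid_derivatives(liquid_state(G = 0.02), p,
                           transfer_h2 = 1e-3, transfer_co2 = 2e-3,
                           carb_rate = 5e-4)
  expect_equal(unname(d0[c("X", "G", "Ac", "Lac")]), rep(0, 4))
  expect_equal(d0[["H2aq"]], -1e-3)
  expect_equal(d0[["CO2aq"]], -2e-3 - 5e-4)
  expect_equal(d0[["CO2sol"]], 5e-4)
  # stationary biomass when growth balances death
  p_bal <- mean_params(mu_max = 0.014 / (0.02 / (0.02 + 0.048e-3)) /
                         (1 - (0.12 / 0.28)^4.68))
  s <- liquid_state(X = 1e-3, G = 0.02)
  d <- liquid_derivatives(s, p_bal)
  expect_equal(d[["X"]], 0, tolerance = 1e-12)
  # glucose consumption stops at depletion
  dd <- liquid_derivatives(liquid_state(X = 1e-3, G = 0), p)
  expect_identical(dd[["G"]], 0)
})

test_that("uninhibited H2 per glucose stays below the four-mol ceiling", {
  p <- mean_params()
  s <- liquid_state(X = 1e-3, G = 0.02)
  d <- liquid_derivatives(s, p)
  a <- attr(d, "alphas")
  ratio <- a$alpha_H2 / (1 / p$Y_GX + a$alpha_Ac / 2 + a$alpha_Lac / 2)
  expect_equal(-d[["H2aq"]] / d[["G"]], ratio)
  expect_equal(ratio, 3.91, tolerance = 0.02)
  expect_lt(ratio, 4)
  # instantaneous product ratios with all inhibition off
  expect_equal(d[["H2aq"]] / d[["Ac"]], p$Y_GH2 / 2, tolerance = 1e-6)
  expect_equal(a$alpha_CO2 / a$alpha_Ac, 1)
})
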