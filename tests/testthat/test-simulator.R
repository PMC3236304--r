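test_that("an abiotic run leaves the broth untouched", {
  p <- mean_params()
  cfg <- default_cfg()
  tc <- simulate_batch(p, cfg, init = initial_state(5, X0 = 0, cfg),
                       t_end = 20)
  n <- nrow(tc)
  expect_equal(tc$G[n], tc$G[1])
  expect_equal(max(tc$Ac, tc$Lac, tc$H2aq, tc$cum_h2_out), 0)
  expect_equal(tc$q_h2, rep(0, n))
  # pure N2 purge stays at total pressure
  expect_equal(max(abs((tc$N2G * cfg$R_gas * cfg$T_K) - cfg$P_tot)) /
                 cfg$P_tot, 0, tolerance = 1e-7)
  expect_error(yield_summary(tc), "no glucose")
})

test_that("compiled and pure-R derivative routes integrate identically", {
  p <- mean_params()
  cfg <- default_cfg(F_in_N2 = 2)
  tc_c <- simulate_batch(p, cfg, t_end = 30)
  tc_r <- simulate_batch(p, cfg, t_end = 30, use_compiled = FALSE)
  for (col in c("X", "G", "Ac", "Lac", "H2aq", "CO2aq", "CO2sol",
                "H2G", "CO2G", "N2G", "cum_h2_out", "mu", "q_h2")) {
    scale <- max(abs(tc_r[[col]]), 1e-12)
    expect_lt(max(abs(tc_c[[col]] - tc_r[[col]])) / scale, 1e-6)
  }
})

test_that("a standard 5 g/L batch consumes glucose below the Thauer limit", {
  tc <- simulate_batch(mean_params(), default_cfg(), t_end = 40)
  ys <- yield_summary(tc)
  # glucose fully consumed
  expect_lt(tc$G[nrow(tc)] / tc$G[1], 1e-3)
  expect_lte(ys$h2_yield_mol_mol, 4)
  expect_gt(ys$h2_yield_mol_mol, 2)
  # cumulative H2 out never decreases (beyond interpolation jitter)
  expect_true(all(diff(tc$cum_h2_out) >= -1e-10))
  # dissolved H2 stays heavily oversaturated while producing
  peak <- which.max(tc$q_h2)
  ratio <- tc$H2aq[peak] / (default_cfg()$H_H2 * tc$H2G[peak] *
                              default_cfg()$R_gas * default_cfg()$T_K)
  expect_gt(ratio, 5)
})

test_that("mass-balance audit passes healthy runs and flags corrupted ones", {
  tc <- simulate_batch(mean_params(), default_cfg(), t_end = 40)
  a <- mass_balance_audit(tc)
  expect_true(a$ok)
  expect_lt(a$h2_closure_rel_error, 0.005)
  expect_lt(a$glucose_closure_rel_error, 0.005)
  expect_lt(a$pressure_drift_rel, 0.005)
  # corrupting the off-gas accounting breaks the hydrogen closure
  tc_bad <- tc
  tc_bad$cum_h2_out <- tc$cum_h2_out * 1.10
  expect_false(mass_balance_audit(tc_bad)$ok)
  # corrupting the headspace shows up as pressure drift
  tc_bad2 <- tc
  tc_bad2$N2G <- tc$N2G * 1.05
  a2 <- mass_balance_audit(tc_bad2)
  expect_gt(a2$pressure_drift_rel, 0.005)
  expect_false(a2$ok)
})

test_that("tightening solver tolerances barely moves the result", {
  p <- mean_params()
  tc1 <- simulate_batch(p, default_cfg(), t_end = 40,
                        rtol = 1e-8, atol = 1e-10)
  tc2 <- simulate_batch(p, default_cfg(), t_end = 40,
                        rtol = 1e-9, atol = 1e-11)
  n <- nrow(tc1)
  expect_lt(abs(tc1$cum_h2_out[n] - tc2$cum_h2_out[n]) / tc2$cum_h2_out[n],
            1e-3)
})

test_that("without inhibition the model reduces to Monod plus Luedeking-Piret", {
  p <- mean_params(H2aq_crit = 10, OSM_crit = 1e3, R_LacF_H2 = 0,
                   R_LacF_OSM = 0, r_cd = 0)
  cfg <- default_cfg()
  tc <- simulate_batch(p, cfg, t_end = 40)
  n <- nrow(tc)
  dG <- tc$G[1] - tc$G[n]
  dX <- tc$X[n] - tc$X[1]
  dAc <- tc$Ac[n]
  expect_equal(tc$Lac[n], 0)
  # glucose balance: growth demand plus acetate demand
  expect_equal(dAc, 2 * (dG - dX / p$Y_GX), tolerance = 1e-6)
  # product stoichiometry: H2 tracks acetate by the estimated yield ratio
  h2_total <- tc$cum_h2_out[n] + tc$H2aq[n] * cfg$V_l + tc$H2G[n] * cfg$V_g
  expect_equal(h2_total / (dAc * cfg$V_l), p$Y_GH2 / 2, tolerance = 1e-3)
})

test_that("faster stripping lowers the dissolved hydrogen peak", {
  p <- mean_params()
  peaks <- vapply(c(1.2, 3, 6), function(f) {
    max(simulate_batch(p, default_cfg(F_in_N2 = f), t_end = 40)$H2aq)
  }, numeric(1))
  expect_true(all(diff(peaks) < 0))
})

test_that("low stripping with fast growth drives H2aq to an inhibiting plateau", {
  # low-stripping, high-growth-rate conditions
  p <- mean_params(mu_max = 0.33)
  tc <- simulate_batch(p, default_cfg(F_in_N2 = 0.78), t_end = 40)
  peak_ratio <- max(tc$H2aq) / p$H2aq_crit
  expect_gt(peak_ratio, 0.6)
  expect_lt(peak_ratio, 1.0)
  # near the plateau the growth rate is strongly suppressed
  at_peak <- which.max(tc$H2aq)
  expect_lt(tc$inhib_h2[at_peak], 0.6)
  # and dissolved H2 has plateaued over the hours leading up to the peak
  # (it collapses within minutes once glucose runs out and stripping
  # continues, so the window ends at the peak)
  window <- tc$H2aq[tc$time >= tc$time[at_peak] - 8 &
                      tc$time <= tc$time[at_peak]]
  expect_lt(diff(range(window)) / max(window), 0.15)
})

test_that("simulator rejects invalid inputs", {
  p <- mean_params()
  bad <- initial_state()
  bad["X"] <- -1
  expect_error(simulate_batch(p, default_cfg(), init = bad), "non-negative")
  expect_error(simulate_batch(p, default_cfg(), times = c(0, 2, 2)),
               "increasing")
})
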