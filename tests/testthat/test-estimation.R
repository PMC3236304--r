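# The fitting tests run the full pipeline on small synthetic problems; the
# optimizer legitimately probes parameter corners where the solver warns, so
# fits are wrapped in quiet().

test_that("noise-free kinetic data are recovered essentially exactly", {
  p_true <- params_no_osm()
  scn <- list(glucose_g_L = 5, stripping_L_h = 6, mu_max = 0.28,
              horizon_h = 40)
  cfg <- default_cfg(F_in_N2 = 6)
  obs <- generate_batch_observations(scn, p_true, cfg,
                                     nm = noise_model(0, 0, 0), seed = 1)
  fit <- quiet(fit_kinetic_parameters(obs, cfg, fixed = p_true,
                                      n_starts = 2, seed = 0))
  truth <- c(Y_GX = 4.78, Y_GH2 = 4.77, mu_max = 0.28, R_AcF = 1.91,
             R_LacF_H2 = 0.20, H2aq_crit = 2.2e-3, n_H2 = 4.5)
  expect_lt(fit$lsq, 1e-7)
  expect_equal(fit$estimates[names(truth)], truth, tolerance = 0.01)
  expect_true(all(fit$ci_halfwidth >= 0))
})

test_that("noise-free osmolarity data are recovered essentially exactly", {
  p_true <- kinetic_parameters(mu_max = 0.27, OSM_crit = 0.28, n_mu = 4.68,
                               R_LacF_OSM = 0.41)
  scn <- list(glucose_g_L = 10, stripping_L_h = 6, mu_max = 0.27,
              horizon_h = 40)
  cfg <- default_cfg(F_in_N2 = 6)
  obs <- generate_batch_observations(scn, p_true, cfg,
                                     nm = noise_model(0, 0, 0), seed = 2)
  fit <- quiet(fit_osmolarity_parameters(obs, cfg, base = kinetic_parameters(),
                                         mu_max_assumed = 0.27,
                                         n_starts = 2, seed = 0))
  expect_lt(fit$lsq, 1e-7)
  expect_equal(fit$estimates[["OSM_crit"]], 0.28, tolerance = 0.01)
  expect_equal(fit$estimates[["n_mu"]], 4.68, tolerance = 0.05)
  expect_equal(fit$estimates[["R_LacF_OSM"]], 0.41, tolerance = 0.05)
})

test_that("estimation is invariant to observation row order", {
  p_true <- params_no_osm()
  scn <- list(glucose_g_L = 5, stripping_L_h = 6, mu_max = 0.28,
              horizon_h = 40)
  cfg <- default_cfg()
  obs <- generate_batch_observations(scn, p_true, cfg, seed = 4)
  shuffled <- obs[sample.int(nrow(obs)), ]
  attr(shuffled, "scenario") <- attr(obs, "scenario")
  f1 <- quiet(fit_kinetic_parameters(obs, cfg, fixed = p_true,
                                     which = c("Y_GH2", "mu_max"),
                                     guess = kinetic_guess_from_data(obs),
                                     n_starts = 1, seed = 0))
  f2 <- quiet(fit_kinetic_parameters(shuffled, cfg, fixed = p_true,
                                     which = c("Y_GH2", "mu_max"),
                                     guess = kinetic_guess_from_data(obs),
                                     n_starts = 1, seed = 0))
  expect_equal(f1$estimates, f2$estimates, tolerance = 1e-8)
  expect_equal(f1$lsq, f2$lsq, tolerance = 1e-8)
})

test_that("degenerate observations are rejected as unidentifiable", {
  flat <- data.frame(time_h = seq(2, 20, by = 2),
                     biomass_molcell_L = rep(1e-3, 10))
  expect_error(quiet(fit_kinetic_parameters(flat, default_cfg())),
               "unidentifiable|uninformative")
  # too few residuals for the parameter count
  tiny <- data.frame(time_h = c(2, 4), glucose_mol_L = c(0.027, 0.020))
  expect_error(quiet(fit_kinetic_parameters(tiny, default_cfg())),
               "residuals")
})

test_that("parameter averaging follows the protocol of the study", {
  # per-experiment estimates of the five low-substrate fits
  sets <- list(
    c(Y_GH2 = 6.0, Y_GX = 2.8, mu_max = 0.240, R_AcF = 1.4),
    c(Y_GH2 = 5.1, Y_GX = 6.5, mu_max = 0.36, R_AcF = 2.0),
    c(Y_GH2 = 3.6, Y_GX = 5.1, mu_max = 0.33, R_AcF = 2.3),
    c(Y_GH2 = 4.5, Y_GX = 4.3, mu_max = 0.2, R_AcF = 1.8),
    c(Y_GH2 = 4.71, Y_GX = 5.22, mu_max = 0.21, R_AcF = 2.0))
  avg <- average_parameters(sets)
  expect_equal(avg$Y_GH2, 4.78, tolerance = 2e-3)
  expect_equal(avg$Y_GH2, 4.77, tolerance = 3e-3)
  expect_equal(avg$R_AcF, 1.90, tolerance = 1e-6)
  expect_equal(avg$R_AcF, 1.91, tolerance = 6e-3)
  expect_equal(avg$Y_GX, mean(c(2.8, 6.5, 5.1, 4.3, 5.22)))
  # the growth rate is averaged for the record but kept per set
  expect_equal(unname(attr(avg, "mu_max_by_set")),
               c(0.240, 0.36, 0.33, 0.2, 0.21))
  # single result: identity
  one <- average_parameters(sets[1])
  expect_equal(one$Y_GH2, 6.0)
  expect_error(average_parameters(list()), "no estimation results")
})

test_that("cell death rate comes from the post-peak biomass decline", {
  tt <- seq(0, 60, by = 4)
  mk <- function(rate) {
    x <- 1e-3 * exp(pmin(0.3 * tt, 0.3 * 24)) * exp(-rate * pmax(tt - 24, 0))
    data.frame(time_h = tt, biomass_molcell_L = x)
  }
  expect_equal(as.numeric(estimate_cell_death_rate(list(mk(0.014)))), 0.014,
               tolerance = 1e-6)
  two <- estimate_cell_death_rate(list(mk(0.010), mk(0.018)))
  expect_equal(as.numeric(two), 0.014, tolerance = 1e-6)
  expect_length(attr(two, "per_experiment"), 2)
  # pure growth: skipped with a warning, then an error when nothing remains
  growing <- data.frame(time_h = tt,
                        biomass_molcell_L = 1e-3 * exp(0.1 * tt))
  expect_warning(
    out <- estimate_cell_death_rate(list(mk(0.02), growing)), "skipped")
  expect_equal(as.numeric(out), 0.02, tolerance = 1e-6)
  expect_error(suppressWarnings(estimate_cell_death_rate(list(growing))),
               "no experiment")
})

test_that("dynamic gas transients yield kLa and the stripping exponent", {
  tt <- seq(0, 1.5, by = 0.1)
  conc <- 2e-3 + (1e-4 - 2e-3) * exp(-5.0 * tt)
  fit <- fit_kla_from_dynamic_gas(tt, conc)
  expect_equal(fit$kla, 5.0, tolerance = 1e-6)
  expect_equal(fit$C_star, 2e-3, tolerance = 1e-6)
  expect_error(fit_kla_from_dynamic_gas(tt, rep(1e-3, length(tt))),
               "no transient")
  # gamma from a set of flows generated by the power law, with noise
  flows <- c(2.0, 3.5, 6.0, 9.8)
  klas <- kla_at_flow(5.3, flows, 6.0, 0.46)
  g0 <- fit_kla_gamma(klas, flows)
  expect_equal(g0$gamma, 0.46, tolerance = 1e-8)
  expect_equal(g0$kla_ref, 5.3, tolerance = 1e-8)
  gammas <- vapply(1:10, function(s) {
    set.seed(s)
    noisy <- klas * exp(rnorm(length(klas), 0, 0.05))
    fit_kla_gamma(noisy, flows)$gamma
  }, numeric(1))
  expect_equal(mean(gammas), 0.46, tolerance = 0.1)
  expect_true(all(abs(gammas - 0.46) < 0.15))
  # the measured coefficient range end-points bracket the same exponent
  expect_equal(fit_kla_gamma(c(3.4, 7.2), c(2.0, 9.8))$gamma, 0.46,
               tolerance = 0.05)
})

test_that("linearized intervals agree with closed-form linear regression", {
  set.seed(11)
  tt <- 1:20
  y <- 0.7 * tt + rnorm(20, 0, 0.5)
  # residual r(a) = y - a t has Jacobian -t
  J <- matrix(-tt, ncol = 1, dimnames = list(NULL, "a"))
  a_hat <- sum(tt * y) / sum(tt^2)
  ci <- linearized_confidence(J, y - a_hat * tt)
  ref <- summary(lm(y ~ tt - 1))$coefficients
  expect_equal(unname(ci$se), ref[1, 2], tolerance = 1e-10)
  expect_equal(unname(ci$halfwidth),
               qt(0.975, 19) * ref[1, 2], tolerance = 1e-10)
  # duplicated observations shrink the standard error by about sqrt(2)
  ci2 <- linearized_confidence(rbind(J, J), c(y, y) - a_hat * c(tt, tt))
  expect_equal(unname(ci$se / ci2$se), sqrt(2), tolerance = 0.05)
})

test_that("interval coverage is near nominal on a linear test model", {
  tt <- 1:15
  hits <- vapply(1:200, function(s) {
    set.seed(s)
    y <- 2.5 * tt + rnorm(15, 0, 1)
    a_hat <- sum(tt * y) / sum(tt^2)
    ci <- linearized_confidence(matrix(-tt, ncol = 1), y - a_hat * tt)
    abs(a_hat - 2.5) <= ci$halfwidth
  }, logical(1))
  expect_gt(mean(hits), 0.90)
  expect_lt(mean(hits), 0.99)
})

test_that("pooled parallel experiments share one parameter set", {
  p_true <- params_no_osm()
  cfg6 <- default_cfg(F_in_N2 = 1.2)
  cfg7 <- default_cfg(F_in_N2 = 1.56)
  scn6 <- list(glucose_g_L = 5, stripping_L_h = 1.2, mu_max = 0.21,
               horizon_h = 40)
  scn7 <- list(glucose_g_L = 5, stripping_L_h = 1.56, mu_max = 0.21,
               horizon_h = 40)
  o6 <- generate_batch_observations(scn6, p_true, cfg6,
                                    nm = noise_model(0, 0, 0), seed = 1)
  o7 <- generate_batch_observations(scn7, p_true, cfg7,
                                    nm = noise_model(0, 0, 0), seed = 1)
  fit <- quiet(fit_kinetic_parameters(list(o6, o7), list(cfg6, cfg7),
                                      fixed = p_true,
                                      which = c("Y_GH2", "mu_max", "R_AcF"),
                                      guess = kinetic_guess_from_data(o6),
                                      n_starts = 1, seed = 0))
  expect_equal(fit$estimates[["mu_max"]], 0.21, tolerance = 0.01)
  expect_equal(fit$estimates[["Y_GH2"]], 4.77, tolerance = 0.01)
  expect_equal(fit$n_residuals, 10 * nrow(o6))
})
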