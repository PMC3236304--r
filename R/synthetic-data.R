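# Synthetic batch experiments with the structure of the eight laboratory
# runs (glucose 5 or 10 g/L, nitrogen stripping 0.78-6 L/h, ~40 h horizon,
# sparse sampling, multiplicative measurement noise), so that every stage of
# the estimation pipeline can be exercised against a known ground truth.

#' Measurement noise model
#'
#' Relative standard deviations per observable under a multiplicative
#' log-normal noise law (which preserves non-negativity). The defaults mimic
#' the scatter typical of HPLC metabolite assays (5%), optical-density-based
#' biomass (7%) and GC gas measurements (3%).
#'
#' @param rel_sd_conc relative sd for glucose/acetate/lactate.
#' @param rel_sd_biomass relative sd for cell mass.
#' @param rel_sd_gas relative sd for gas fractions and cumulative H2.
#' @return A list of class `noise_model` with one relative sd per
#'   observable column.
#' @export
noise_model <- function(rel_sd_conc = 0.05, rel_sd_biomass = 0.07,
                        rel_sd_gas = 0.03) {
  if (any(c(rel_sd_conc, rel_sd_biomass, rel_sd_gas) < 0))
    stop("relative standard deviations must be non-negative")
  nm <- list(glucose_mol_L = rel_sd_conc,
             acetate_mol_L = rel_sd_conc,
             lactate_mol_L = rel_sd_conc,
             biomass_molcell_L = rel_sd_biomass,
             cum_h2_mol_per_L = rel_sd_gas,
             h2_gas_frac = rel_sd_gas,
             co2_gas_frac = rel_sd_gas)
  class(nm) <- "noise_model"
  nm
}

# Multiplicative log-normal noise with the requested coefficient of
# variation; sdlog = sqrt(log(1 + cv^2)) makes the CV exact.
apply_noise <- function(x, cv) {
  if (cv == 0) return(x)
  sdlog <- sqrt(log(1 + cv^2))
  x * exp(rnorm(length(x), mean = 0, sd = sdlog))
}

#' Preset batch scenarios
#'
#' The eight batch experiments of the study design: glucose load, nitrogen
#' stripping rate, and the per-experiment-set maximum specific growth rate
#' (parallel sets shared inocula and growth rates; the growth rate of the
#' first high-substrate run is the cross-set average, and the second uses
#' the average of its parallel low-substrate set).
#'
#' @return A data frame with columns `experiment`, `glucose_g_L`,
#'   `stripping_L_h`, `mu_max`, `horizon_h`.
#' @export
table1_scenarios <- function() {
  data.frame(
    experiment = 1:8,
    glucose_g_L = c(5, 10, 5, 5, 5, 5, 5, 10),
    stripping_L_h = c(6, 6, 6, 0.78, 6, 1.2, 1.56, 6),
    mu_max = c(0.24, 0.27, 0.36, 0.33, 0.20, 0.21, 0.21, 0.22),
    horizon_h = rep(40, 8)
  )
}

#' Default sparse sampling schedule
#'
#' Denser early sampling (every 2 h up to 20 h, then every 4 h), matching
#' the point density of the laboratory time courses; about 15 points over a
#' 40 h run.
#'
#' @param horizon_h run horizon (h).
#' @return Sampling times (h).
#' @export
default_sampling_schedule <- function(horizon_h = 40) {
  s <- c(seq(2, min(20, horizon_h), by = 2),
         if (horizon_h > 20) seq(24, horizon_h, by = 4))
  unique(s[s <= horizon_h])
}

#' Generate noisy observations from a simulated batch
#'
#' Simulates a scenario with the supplied parameters, samples the
#' trajectory at a sparse schedule and applies multiplicative log-normal
#' measurement noise observable-wise. The noise-free values and the
#' generating parameters are stored alongside (attribute `truth`) for
#' recovery studies; estimation code must not read them.
#'
#' @param scenario one row of [table1_scenarios()] (or any list with
#'   `glucose_g_L`, `stripping_L_h`, `mu_max`, `horizon_h`).
#' @param p generating [kinetic_parameters()]; its `mu_max` is overridden by
#'   the scenario's.
#' @param cfg a [reactor_config()]; its stripping rate is overridden by the
#'   scenario's.
#' @param nm a [noise_model()].
#' @param seed RNG seed (the draw is bit-reproducible given it).
#' @param schedule sampling times (h); default [default_sampling_schedule()].
#' @param X0 inoculum (mol cells/L).
#' @return An `observation_set`: a data frame with `time_h`,
#'   `glucose_mol_L`, `acetate_mol_L`, `lactate_mol_L`,
#'   `biomass_molcell_L`, `cum_h2_mol_per_L`, `h2_gas_frac`,
#'   `co2_gas_frac`; attributes `truth` (noise-free data frame, generating
#'   parameters, configuration), `seed` and `scenario`.
#' @export
generate_batch_observations <- function(scenario, p = kinetic_parameters(),
                                        cfg = reactor_config(),
                                        nm = noise_model(), seed = 0,
                                        schedule = NULL, X0 = 1e-4) {
  scn <- as.list(scenario)
  req <- c("glucose_g_L", "stripping_L_h", "mu_max", "horizon_h")
  if (!all(req %in% names(scn)))
    stop("scenario must provide: ", paste(req, collapse = ", "))
  if (is.null(schedule)) schedule <- default_sampling_schedule(scn$horizon_h)
  p_run <- update_params(p, mu_max = scn$mu_max)
  cfg_run <- update_params(cfg, F_in_N2 = scn$stripping_L_h)
  tc <- simulate_batch(p_run, cfg_run,
                       init = initial_state(scn$glucose_g_L, X0, cfg_run),
                       times = sort(unique(c(0, schedule))))
  idx <- match(schedule, tc$time)
  clean <- data.frame(time_h = schedule,
                      glucose_mol_L = tc$G[idx],
                      acetate_mol_L = tc$Ac[idx],
                      lactate_mol_L = tc$Lac[idx],
                      biomass_molcell_L = tc$X[idx],
                      cum_h2_mol_per_L = tc$cum_h2_out[idx] / cfg_run$V_l,
                      h2_gas_frac = tc$h2_gas_frac[idx],
                      co2_gas_frac = tc$co2_gas_frac[idx])
  noisy <- clean
  with_seed(seed, {
    for (col in setdiff(names(clean), "time_h"))
      noisy[[col]] <- apply_noise(clean[[col]], nm[[col]])
  })
  structure(noisy,
            class = c("observation_set", class(noisy)),
            truth = list(clean = clean, parameters = p_run, config = cfg_run,
                         X0 = X0),
            seed = seed, scenario = scn)
}

#' Serum-flask dissolved-hydrogen measurement emulator
#'
#' Models the flask assay used to measure dissolved H2: a broth sample is
#' drawn into an evacuated flask and equilibrated at 20 degrees C, the H2
#' partitions almost completely into the flask headspace, the headspace is
#' assayed (with relative measurement noise), and the original dissolved
#' concentration is back-calculated from the headspace moles plus the
#' Henry's-law residual still dissolved at 20 degrees C. With zero noise the
#' estimator inverts the partitioning exactly.
#'
#' @param true_H2aq dissolved H2 in the broth sample (mol/L).
#' @param V_liq sample volume (L).
#' @param V_flask total flask volume (L).
#' @param rel_sd relative sd of the headspace assay.
#' @param henry_20C Henry constant of H2 at the 20 degree C water-bath
#'   temperature (mol/L/Pa).
#' @param T_K water-bath temperature (K).
#' @param R_gas gas constant (Pa L/(mol K)).
#' @return Estimated dissolved H2 (mol/L).
#' @export
emulate_flask_h2aq_measurement <- function(true_H2aq, V_liq = 0.035,
                                           V_flask = 0.25, rel_sd = 0,
                                           henry_20C = 7.8e-9,
                                           T_K = 293.15,
                                           R_gas = 8314.462618) {
  if (any(true_H2aq < 0)) stop("true_H2aq must be non-negative")
  if (V_liq <= 0 || V_liq >= V_flask)
    stop("sample volume must be positive and smaller than the flask volume")
  V_head <- V_flask - V_liq
  # equilibrium partition of the sample's H2 between headspace and liquid
  n_total <- true_H2aq * V_liq
  n_head <- n_total / (1 + henry_20C * R_gas * T_K * V_liq / V_head)
  n_head_meas <- apply_noise(n_head, rel_sd)
  # back-calculation: headspace moles plus the Henry's-law residual
  P_H2 <- n_head_meas * R_gas * T_K / V_head
  (n_head_meas + henry_20C * P_H2 * V_liq) / V_liq
}
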