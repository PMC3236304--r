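# Gas-liquid mass transfer and headspace balances. Gas-phase states are
# molar concentrations of the headspace (mol/L of gas volume); partial
# pressures follow from the ideal gas law at reactor temperature.

GAS_FIELDS <- c("H2G", "CO2G", "N2G")

#' Construct a headspace gas state
#'
#' @param H2G,CO2G,N2G headspace concentrations (mol per L of gas volume).
#' @return Named numeric vector of class `gas_state`.
#' @export
gas_state <- function(H2G = 0, CO2G = 0, N2G = 0) {
  g <- c(H2G = H2G, CO2G = CO2G, N2G = N2G)
  if (any(!is.finite(g)) || any(g < 0))
    stop("gas state components must be finite and non-negative")
  class(g) <- c("gas_state", class(g))
  g
}

#' Henry's-law saturation concentration
#'
#' @param partial_pressure gas partial pressure (Pa).
#' @param henry Henry's-law solubility constant (mol/L/Pa).
#' @return Equilibrium dissolved concentration (mol/L).
#' @examples
#' # 3% H2 in the headspace at 1 atm
#' saturation_conc(0.03 * 101325, 7.40e-9) * 1e3   # ~0.022 mmol/L
#' @export
saturation_conc <- function(partial_pressure, henry) {
  if (any(partial_pressure < 0)) stop("partial pressure must be non-negative")
  if (any(henry < 0)) stop("Henry constant must be non-negative")
  henry * partial_pressure
}

#' Mass-transfer coefficient at a given stripping rate
#'
#' Power-law scaling of the volumetric mass-transfer coefficient with the
#' nitrogen sparging rate, `kla = kla_ref (F/F_ref)^gamma`. The correlation
#' has no meaning without sparging, so non-positive flows are rejected.
#'
#' @param kla_ref reference coefficient (1/h) at flow `F_ref`.
#' @param F stripping rate to scale to (L/h).
#' @param F_ref reference stripping rate (L/h).
#' @param gamma power-law exponent.
#' @return Scaled coefficient (1/h).
#' @examples
#' kla_at_flow(9.0, 0.78, 6.0, 0.46)   # ~3.52/h
#' @export
kla_at_flow <- function(kla_ref, F, F_ref = 6.0, gamma = 0.46) {
  if (any(F <= 0) || F_ref <= 0)
    stop("stripping rate must be positive: the correlation cannot describe ",
         "an unsparged system")
  if (kla_ref <= 0) stop("kla_ref must be positive")
  kla_ref * (F / F_ref)^gamma
}

#' Convert a CO2 mass-transfer coefficient to the H2 coefficient
#'
#' Uses the square-root dependence of kLa on aqueous diffusivity:
#' `kla_CO2 / kla_H2 = sqrt(D_CO2 / D_H2)`.
#'
#' @param kla_co2 CO2 coefficient (1/h).
#' @param cfg a [reactor_config()] supplying the diffusivities.
#' @return H2 coefficient (1/h).
#' @export
kla_h2_from_co2 <- function(kla_co2, cfg = reactor_config()) {
  if (any(kla_co2 <= 0)) stop("kla_co2 must be positive")
  kla_co2 / sqrt(cfg$D_CO2 / cfg$D_H2)
}

#' Carbonate pool at speciation equilibrium
#'
#' Equilibrium bicarbonate-plus-carbonate concentration corresponding to a
#' dissolved CO2 concentration at the controlled pH:
#' `CO2aq (10^(pH - K1) + 10^(2 pH - K1 - K2))`. The speciation dynamics
#' relax toward this target at rate `k_carb`.
#'
#' @param CO2aq dissolved CO2 (mol/L).
#' @param cfg a [reactor_config()].
#' @return Equilibrium carbonate pool (mol/L).
#' @export
carbonate_equilibrium_target <- function(CO2aq, cfg = reactor_config()) {
  if (any(CO2aq < 0)) stop("CO2aq must be non-negative")
  CO2aq * carbonate_ratio(cfg)
}

# Equilibrium CO2sol/CO2aq ratio at the configured pH (~1.996 at pH 6.6).
carbonate_ratio <- function(cfg) {
  10^(cfg$pH - cfg$K1) + 10^(2 * cfg$pH - cfg$K1 - cfg$K2)
}

#' Carbonate interconversion rate
#'
#' @param CO2aq dissolved CO2 (mol/L).
#' @param CO2sol current carbonate pool (mol/L).
#' @param cfg a [reactor_config()].
#' @return Net CO2(aq) -> carbonates rate (mol/L/h).
#' @export
carbonate_rate <- function(CO2aq, CO2sol, cfg = reactor_config()) {
  cfg$k_carb * (carbonate_equilibrium_target(CO2aq, cfg) - CO2sol)
}

#' Liquid-to-gas transfer rate
#'
#' Two-film driving-force rate `kla (C - C_star)`; positive when the liquid
#' is supersaturated (net transfer into the gas phase).
#'
#' @param kla volumetric mass-transfer coefficient (1/h).
#' @param C dissolved concentration (mol/L).
#' @param C_star saturation concentration (mol/L).
#' @return Transfer rate (mol per L of liquid per h).
#' @export
transfer_rate <- function(kla, C, C_star) {
  if (any(kla < 0)) stop("kla must be non-negative")
  kla * (C - C_star)
}

#' Headspace balances and outflow partitioning
#'
#' Accumulation of H2, CO2 and N2 in the headspace under constant total
#' pressure. Each species gains transferred gas scaled by the liquid-to-gas
#' volume ratio and leaves with the off-gas. The off-gas molar flow is
#' closed against constant pressure: total moles out = nitrogen moles in +
#' total moles transferred from the liquid, and the outflow is split among
#' species by instantaneous headspace mole fractions. A net gas uptake
#' larger than the inflow would demand a negative outflow; the flow is then
#' floored at zero and flagged.
#'
#' @param gas a [gas_state()].
#' @param transfer_h2,transfer_co2 liquid-to-gas transfer rates
#'   (mol per L liquid per h).
#' @param cfg a [reactor_config()].
#' @return A list with `derivatives` (named vector, mol/L gas/h), `flows`
#'   (volumetric outflows `F_out_H2`, `F_out_CO2`, `F_out_N2` in L/h at
#'   reactor T and P), `n_out_H2` (molar H2 outflow, mol/h) and `flagged`
#'   (logical, outflow floored).
#' @export
gas_derivatives <- function(gas, transfer_h2, transfer_co2,
                            cfg = reactor_config()) {
  g <- unclass(gas)[GAS_FIELDS]
  if (any(!is.finite(unlist(g))))
    stop("gas state must be finite")
  RT <- cfg$R_gas * cfg$T_K
  n_in <- cfg$F_in_N2 * cfg$P_tot / RT                     # mol N2/h
  n_out <- n_in + cfg$V_l * (transfer_h2 + transfer_co2)   # mol/h total
  flagged <- n_out < 0
  if (flagged) n_out <- 0
  ctot <- g[["H2G"]] + g[["CO2G"]] + g[["N2G"]]
  y <- if (ctot > 0) unlist(g) / ctot else c(H2G = 0, CO2G = 0, N2G = 0)
  out_mol <- n_out * y                                     # mol/h per species
  d <- c(H2G = (cfg$V_l * transfer_h2 - out_mol[["H2G"]]) / cfg$V_g,
         CO2G = (cfg$V_l * transfer_co2 - out_mol[["CO2G"]]) / cfg$V_g,
         N2G = (n_in - out_mol[["N2G"]]) / cfg$V_g)
  flows <- c(F_out_H2 = out_mol[["H2G"]],
             F_out_CO2 = out_mol[["CO2G"]],
             F_out_N2 = out_mol[["N2G"]]) * RT / cfg$P_tot
  list(derivatives = d, flows = flows, n_out_H2 = out_mol[["H2G"]],
       flagged = flagged)
}
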