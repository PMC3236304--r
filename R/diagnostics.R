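# Operating-condition diagnostics: oversaturation of dissolved hydrogen,
# closed-form steady-state dissolved H2, the mass-transfer coefficient
# needed to stay out of severe inhibition, response surfaces over stripping
# rate and productivity, and per-run yield summaries.

#' Steady-state dissolved hydrogen
#'
#' When production balances liquid-to-gas transfer,
#' `H2aq = Q/kla + H_H2 P_H2`: the supersaturation excess over the
#' Henry's-law value is the productivity divided by the transfer
#' coefficient.
#'
#' @param Q volumetric H2 productivity (mol/L/h).
#' @param kla H2 mass-transfer coefficient (1/h).
#' @param P_H2 H2 partial pressure in the headspace (Pa).
#' @param cfg a [reactor_config()].
#' @return Steady-state dissolved H2 (mol/L).
#' @export
steady_state_h2aq <- function(Q, kla, P_H2, cfg = reactor_config()) {
  if (any(kla <= 0)) stop("kla must be positive (otherwise H2aq is unbounded)")
  if (any(Q < 0) || any(P_H2 < 0)) stop("Q and P_H2 must be non-negative")
  Q / kla + saturation_conc(P_H2, cfg$H_H2)
}

#' Minimum kLa to avoid severe hydrogen inhibition
#'
#' Severe inhibition is taken to set in when the steady-state dissolved H2
#' reaches a threshold fraction (default 80%) of the critical
#' concentration. Inverting the steady-state relation gives the minimum
#' transfer coefficient `kla = Q / (threshold * H2aq_crit - H_H2 * P_H2)`.
#'
#' @param Q volumetric H2 productivity (mol/L/h).
#' @param P_H2 H2 partial pressure (Pa).
#' @param p a [kinetic_parameters()] (supplies `H2aq_crit`).
#' @param cfg a [reactor_config()].
#' @param threshold fraction of the critical concentration defining severe
#'   inhibition.
#' @return Minimum kLa (1/h).
#' @examples
#' # 10 mmol/L/h into 60% H2 at 1 atm without stripping
#' critical_kla(10e-3, 0.60 * 101325)   # ~7.6/h
#' @export
critical_kla <- function(Q, P_H2, p = kinetic_parameters(),
                         cfg = reactor_config(), threshold = 0.8) {
  if (any(Q < 0)) stop("Q must be non-negative")
  headroom <- threshold * p$H2aq_crit - saturation_conc(P_H2, cfg$H_H2)
  if (any(headroom <= 0))
    stop("saturation exceeds the inhibition threshold: at this partial ",
         "pressure severe inhibition is unavoidable at any kla")
  Q / headroom
}

#' Degree of oversaturation of dissolved hydrogen
#'
#' Ratio of the dissolved concentration to its Henry's-law equilibrium at
#' the prevailing partial pressure; values well above 1 indicate transfer
#' limitation.
#'
#' @param H2aq measured or modeled dissolved H2 (mol/L).
#' @param P_H2 H2 partial pressure (Pa).
#' @param cfg a [reactor_config()].
#' @return Dimensionless oversaturation ratio.
#' @export
oversaturation_ratio <- function(H2aq, P_H2, cfg = reactor_config()) {
  if (any(P_H2 <= 0))
    stop("oversaturation is undefined at zero H2 partial pressure")
  H2aq / saturation_conc(P_H2, cfg$H_H2)
}

#' Steady-state dissolved-H2 response surface
#'
#' Dissolved H2 as a function of stripping rate and volumetric H2
#' productivity. At each grid point the transfer coefficient follows the
#' power-law stripping correlation, the headspace H2 partial pressure is
#' closed self-consistently from the steady gas balance (H2 mole fraction =
#' H2 molar outflow over total molar outflow, with CO2 transfer equimolar to
#' H2 production scaled by the stoichiometric CO2/H2 yield ratio), and the
#' dissolved concentration follows the closed-form steady state. Cells
#' whose dissolved H2 exceeds the critical concentration are flagged.
#'
#' @param p a [kinetic_parameters()].
#' @param cfg a [reactor_config()].
#' @param Q_grid productivities (mol/L/h).
#' @param F_grid stripping rates (L/h).
#' @return A data frame with `Q`, `F`, `kla`, `P_H2`, `H2aq` and
#'   `exceeds_critical`.
#' @export
h2aq_response_surface <- function(p = kinetic_parameters(),
                                  cfg = reactor_config(),
                                  Q_grid = seq(1e-3, 15e-3, length.out = 15),
                                  F_grid = seq(0.5, 10, length.out = 15)) {
  if (any(Q_grid <= 0) || any(F_grid <= 0))
    stop("grids must be positive")
  grid <- expand.grid(Q = Q_grid, F = F_grid)
  kla <- kla_at_flow(cfg$kla_ref_H2, grid$F, cfg$F_ref, cfg$gamma)
  n_h2 <- grid$Q * cfg$V_l                                # mol/h H2 to gas
  n_co2 <- n_h2 * p$Y_GCO2 / p$Y_GH2                      # mol/h CO2 to gas
  n_n2 <- grid$F * cfg$P_tot / (cfg$R_gas * cfg$T_K)      # mol/h N2 purge
  y_h2 <- n_h2 / (n_h2 + n_co2 + n_n2)
  P_H2 <- y_h2 * cfg$P_tot
  H2aq <- steady_state_h2aq(grid$Q, kla, P_H2, cfg)
  data.frame(grid, kla = kla, P_H2 = P_H2, H2aq = H2aq,
             exceeds_critical = H2aq > p$H2aq_crit)
}

#' Yield summary of a batch run
#'
#' Accounts every mole of H2 produced (cumulative off-gas plus the change
#' in the dissolved and headspace pools) against the glucose consumed, and
#' reports the product yields, the H2:acetate ratio and the peak
#' volumetric H2 productivity.
#'
#' @param tc a [simulate_batch()] result.
#' @return A list of class `yield_summary`.
#' @export
yield_summary <- function(tc) {
  cfg <- attr(tc, "config")
  n <- nrow(tc)
  glc <- (tc$G[1] - tc$G[n]) * cfg$V_l
  if (glc <= 0) stop("no glucose was consumed; yields are undefined")
  h2 <- tc$cum_h2_out[n] + (tc$H2aq[n] - tc$H2aq[1]) * cfg$V_l +
    (tc$H2G[n] - tc$H2G[1]) * cfg$V_g
  ac <- (tc$Ac[n] - tc$Ac[1]) * cfg$V_l
  lac <- (tc$Lac[n] - tc$Lac[1]) * cfg$V_l
  out <- list(glucose_consumed_mol = glc,
              h2_total_mol = h2,
              h2_yield_mol_mol = h2 / glc,
              acetate_yield_mol_mol = ac / glc,
              lactate_yield_mol_mol = lac / glc,
              h2_to_acetate = if (ac > 0) h2 / ac else NA_real_,
              peak_productivity_mol_L_h = max(tc$q_h2))
  class(out) <- "yield_summary"
  out
}

#' @export
print.yield_summary <- function(x, ...) {
  cat("Batch yield summary\n")
  cat(sprintf("  glucose consumed   %.4f mol\n", x$glucose_consumed_mol))
  cat(sprintf("  H2 yield           %.3f mol/mol glucose\n", x$h2_yield_mol_mol))
  cat(sprintf("  acetate yield      %.3f mol/mol glucose\n",
              x$acetate_yield_mol_mol))
  cat(sprintf("  lactate yield      %.3f mol/mol glucose\n",
              x$lactate_yield_mol_mol))
  cat(sprintf("  H2 : acetate       %.3f\n", x$h2_to_acetate))
  cat(sprintf("  peak productivity  %.3f mmol/L/h\n",
              1e3 * x$peak_productivity_mol_L_h))
  invisible(x)
}
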