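# Molar masses used only for I/O against mass-based data (g/mol).
# Cell mass from the elemental formula CH1.62O0.46N0.23S0.0052P0.0071.
#' @export
GLUCOSE_G_MOL <- 180.16
#' @export
BIOMASS_G_MOL <- 24.7

#' Organism-specific kinetic parameters
#'
#' Constructs the full parameter set of the growth/product-formation model.
#' Defaults are the averaged batch-fermentation estimates for
#' *C. saccharolyticus* at 70 degrees C, pH 6.6, together with the fixed
#' stoichiometric and literature constants.
#'
#' @param mu_max maximum specific growth rate (1/h).
#' @param K_G glucose affinity constant of the Monod term (mol/L).
#' @param Y_GX cell mass yield on glucose (mol cells/mol glucose); the
#'   stoichiometric coefficient of the anabolic reaction.
#' @param Y_GH2 H2 yield coefficient (mol H2/mol glucose, estimated; may
#'   exceed 4 even though realized yields never do).
#' @param Y_GAc,Y_GLac,Y_GCO2 stoichiometric yields of acetate, lactate and
#'   CO2 on glucose (mol/mol); fixed at 2 by the catabolic reactions
#'   glucose -> 2 acetate + 2 CO2 + 4 H2 and glucose -> 2 lactate.
#' @param R_AcF maximum growth-associated acetate formation factor
#'   (mol Ac/mol cells).
#' @param R_LacF_H2 maximum lactate formation factor activated by dissolved
#'   H2 (mol Lac/mol cells).
#' @param R_LacF_OSM maximum lactate formation factor activated by
#'   osmolarity (mol Lac/mol cells).
#' @param H2aq_crit critical dissolved H2 concentration at which growth and
#'   H2/acetate formation stop (mol/L).
#' @param n_H2 exponent of the H2 inhibition/activation power law.
#' @param OSM_crit critical osmolarity (mol/L).
#' @param n_mu exponent of the osmolarity inhibition/activation power law.
#' @param r_cd first-order cell death rate (1/h).
#' @param OSM_background background osmolarity of the medium (mol/L).
#' @param beta non-growth-associated production term (mol/(L h)); all
#'   products are treated as purely growth-associated, so this is fixed at 0.
#'
#' @return An object of class `kinetic_parameters` (a validated named list).
#' @examples
#' p <- kinetic_parameters()
#' p$H2aq_crit    # 2.2e-3 mol/L
#' @export
kinetic_parameters <- function(mu_max = 0.28,
                               K_G = 0.048e-3,
                               Y_GX = 4.78,
                               Y_GH2 = 4.77,
                               Y_GAc = 2,
                               Y_GLac = 2,
                               Y_GCO2 = 2,
                               R_AcF = 1.91,
                               R_LacF_H2 = 0.20,
                               R_LacF_OSM = 0.41,
                               H2aq_crit = 2.2e-3,
                               n_H2 = 4.50,
                               OSM_crit = 0.28,
                               n_mu = 4.68,
                               r_cd = 0.014,
                               OSM_background = 0.10,
                               beta = 0) {
  p <- list(mu_max = mu_max, K_G = K_G, Y_GX = Y_GX, Y_GH2 = Y_GH2,
            Y_GAc = Y_GAc, Y_GLac = Y_GLac, Y_GCO2 = Y_GCO2,
            R_AcF = R_AcF, R_LacF_H2 = R_LacF_H2, R_LacF_OSM = R_LacF_OSM,
            H2aq_crit = H2aq_crit, n_H2 = n_H2,
            OSM_crit = OSM_crit, n_mu = n_mu,
            r_cd = r_cd, OSM_background = OSM_background, beta = beta)
  class(p) <- "kinetic_parameters"
  validate_kinetic_parameters(p)
  p
}

validate_kinetic_parameters <- function(p) {
  num <- vapply(p, function(x) is.numeric(x) && length(x) == 1 && is.finite(x),
                logical(1))
  if (!all(num))
    stop("kinetic parameters must be finite numeric scalars: ",
         paste(names(p)[!num], collapse = ", "))
  strict_pos <- c("mu_max", "K_G", "Y_GX", "Y_GH2", "Y_GAc", "Y_GLac",
                  "Y_GCO2", "H2aq_crit", "n_H2", "OSM_crit", "n_mu")
  bad <- strict_pos[vapply(strict_pos, function(nm) p[[nm]] <= 0, logical(1))]
  if (length(bad))
    stop("kinetic parameters must be strictly positive: ",
         paste(bad, collapse = ", "))
  nonneg <- c("R_AcF", "R_LacF_H2", "R_LacF_OSM", "r_cd", "OSM_background")
  bad <- nonneg[vapply(nonneg, function(nm) p[[nm]] < 0, logical(1))]
  if (length(bad))
    stop("kinetic parameters must be non-negative: ", paste(bad, collapse = ", "))
  if (p$Y_GAc != 2 || p$Y_GLac != 2 || p$Y_GCO2 != 2)
    stop("Y_GAc, Y_GLac and Y_GCO2 are fixed at 2 by the catabolic stoichiometry")
  if (p$beta != 0)
    stop("beta is fixed at 0: all products are growth-associated")
  invisible(p)
}

#' @export
print.kinetic_parameters <- function(x, ...) {
  cat("Kinetic parameter set (h2ferm)\n")
  v <- unlist(x)
  for (nm in names(v)) cat(sprintf("  %-14s %g\n", nm, v[[nm]]))
  invisible(x)
}

#' Update a parameter or configuration object
#'
#' Returns a copy of `object` with the named fields replaced and the result
#' re-validated.
#'
#' @param object a `kinetic_parameters` or `reactor_config` object.
#' @param ... named replacement values.
#' @return An object of the same class.
#' @export
update_params <- function(object, ...) {
  repl <- list(...)
  if (length(repl) == 0) return(object)
  if (is.null(names(repl)) || any(names(repl) == ""))
    stop("all replacement values must be named")
  unknown <- setdiff(names(repl), names(object))
  if (length(unknown))
    stop("unknown field(s): ", paste(unknown, collapse = ", "))
  out <- modifyList(unclass(object), repl)
  class(out) <- class(object)
  if (inherits(object, "kinetic_parameters")) validate_kinetic_parameters(out)
  if (inherits(object, "reactor_config")) validate_reactor_config(out)
  out
}

#' Reactor and gas-phase configuration
#'
#' Physical constants of the sparged laboratory fermentor: volumes, pressure,
#' temperature, Henry constants, carbonate dissociation constants, nitrogen
#' stripping rate and the mass-transfer correlation. Internal units are an
#' SI-consistent (mol, L, h, Pa, K) set; the gas constant is carried in
#' Pa L/(mol K).
#'
#' @param V_l liquid working volume (L).
#' @param V_g headspace gas volume (L).
#' @param P_tot total pressure (Pa); default one standard atmosphere.
#' @param T_K broth and headspace temperature (K); default 70 degrees C.
#' @param pH broth pH, held constant by titration.
#' @param R_gas gas constant in Pa L/(mol K).
#' @param H_H2,H_CO2 Henry's-law solubility constants (mol/L/Pa).
#' @param K1 pK of CO2(aq) -> bicarbonate.
#' @param K2 pK of bicarbonate -> carbonate.
#' @param k_carb first-order relaxation rate toward carbonate equilibrium
#'   (1/h); the unit rate makes the relaxation term match the equilibrium speciation balance.
#' @param F_in_N2 nitrogen stripping (sparging) rate (L/h at reactor T, P).
#' @param kla_ref_H2 reference volumetric H2 mass-transfer coefficient (1/h)
#'   measured at stripping rate `F_ref`.
#' @param F_ref reference stripping rate for `kla_ref_H2` (L/h).
#' @param gamma exponent of the kLa-vs-stripping-rate power law.
#' @param D_CO2,D_H2 aqueous diffusion coefficients (cm^2/s) used to convert
#'   between CO2 and H2 mass-transfer coefficients.
#'
#' @return An object of class `reactor_config`. The effective `kla_H2` and
#'   `kla_CO2` at the configured stripping rate are available through
#'   [effective_kla()].
#' @examples
#' cfg <- reactor_config(F_in_N2 = 6)
#' effective_kla(cfg)   # kla_H2 = 9/h at the 6 L/h reference
#' @export
reactor_config <- function(V_l = 1.00,
                           V_g = 0.05,
                           P_tot = 101325,
                           T_K = 343.15,
                           pH = 6.6,
                           R_gas = 8314.462618,
                           H_H2 = 7.40e-9,
                           H_CO2 = 2.70e-7,
                           K1 = 6.3,
                           K2 = 10.3,
                           k_carb = 1,
                           F_in_N2 = 6,
                           kla_ref_H2 = 9.0,
                           F_ref = 6.0,
                           gamma = 0.46,
                           D_CO2 = 1.98e-5,
                           D_H2 = 4.65e-5) {
  cfg <- list(V_l = V_l, V_g = V_g, P_tot = P_tot, T_K = T_K, pH = pH,
              R_gas = R_gas, H_H2 = H_H2, H_CO2 = H_CO2, K1 = K1, K2 = K2,
              k_carb = k_carb, F_in_N2 = F_in_N2, kla_ref_H2 = kla_ref_H2,
              F_ref = F_ref, gamma = gamma, D_CO2 = D_CO2, D_H2 = D_H2)
  class(cfg) <- "reactor_config"
  validate_reactor_config(cfg)
  cfg
}

validate_reactor_config <- function(cfg) {
  num <- vapply(cfg, function(x) is.numeric(x) && length(x) == 1 && is.finite(x),
                logical(1))
  if (!all(num))
    stop("reactor configuration fields must be finite numeric scalars: ",
         paste(names(cfg)[!num], collapse = ", "))
  pos <- setdiff(names(cfg), "gamma")
  bad <- pos[vapply(pos, function(nm) cfg[[nm]] <= 0, logical(1))]
  if (length(bad))
    stop("reactor configuration fields must be positive: ",
         paste(bad, collapse = ", "))
  if (cfg$gamma <= 0 || cfg$gamma >= 1)
    stop("gamma must lie strictly between 0 and 1")
  invisible(cfg)
}

#' @export
print.reactor_config <- function(x, ...) {
  cat("Reactor configuration (h2ferm)\n")
  v <- unlist(x)
  for (nm in names(v)) cat(sprintf("  %-11s %g\n", nm, v[[nm]]))
  kla <- effective_kla(x)
  cat(sprintf("  effective kla_H2 %.3f /h, kla_CO2 %.3f /h at F_in_N2 = %g L/h\n",
              kla$kla_H2, kla$kla_CO2, x$F_in_N2))
  invisible(x)
}

#' Effective mass-transfer coefficients at the configured stripping rate
#'
#' Scales the reference H2 coefficient to the configured nitrogen flow with
#' the power-law correlation and converts it to the CO2 coefficient through
#' the square root of the diffusivity ratio.
#'
#' @param cfg a [reactor_config()] object.
#' @return A list with `kla_H2` and `kla_CO2` (1/h).
#' @export
effective_kla <- function(cfg) {
  kla_h2 <- kla_at_flow(cfg$kla_ref_H2, cfg$F_in_N2, cfg$F_ref, cfg$gamma)
  list(kla_H2 = kla_h2, kla_CO2 = kla_h2 * sqrt(cfg$D_CO2 / cfg$D_H2))
}
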