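# Core reaction-kinetic quantities. A liquid state is a named numeric vector
# (or list) with components X, G, Ac, Lac, H2aq, CO2aq, CO2sol, all mol/L;
# X is on a carbon-mole cell basis (24.7 g/mol for conversions).

LIQUID_FIELDS <- c("X", "G", "Ac", "Lac", "H2aq", "CO2aq", "CO2sol")

#' Construct a liquid-phase state
#'
#' @param X cell concentration (mol cells/L).
#' @param G glucose (mol/L).
#' @param Ac acetate (mol/L).
#' @param Lac lactate (mol/L).
#' @param H2aq dissolved hydrogen (mol/L).
#' @param CO2aq dissolved carbon dioxide (mol/L).
#' @param CO2sol bicarbonate plus carbonate (mol/L).
#' @return A named numeric vector of class `liquid_state`.
#' @export
liquid_state <- function(X = 0, G = 0, Ac = 0, Lac = 0,
                         H2aq = 0, CO2aq = 0, CO2sol = 0) {
  s <- c(X = X, G = G, Ac = Ac, Lac = Lac,
         H2aq = H2aq, CO2aq = CO2aq, CO2sol = CO2sol)
  validate_liquid_state(s)
  class(s) <- c("liquid_state", class(s))
  s
}

validate_liquid_state <- function(state) {
  state <- unclass(state)
  missing <- setdiff(LIQUID_FIELDS, names(state))
  if (length(missing))
    stop("liquid state is missing component(s): ", paste(missing, collapse = ", "))
  vals <- unlist(state[LIQUID_FIELDS])
  if (any(!is.finite(vals)))
    stop("liquid state contains non-finite concentrations")
  if (any(vals < 0))
    stop("invalid liquid state: negative concentration in ",
         paste(LIQUID_FIELDS[vals < 0], collapse = ", "))
  invisible(state)
}

#' Medium osmolarity
#'
#' Total osmotically active solute concentration: glucose plus twice the
#' acetate, lactate and carbonate pools (each acid mole is titrated with one
#' mole of NaOH, and carbonates carry sodium counter-ions likewise), plus the
#' background contribution of yeast extract and salts.
#'
#' @param state a [liquid_state()] (or any named vector with the same fields).
#' @param p a [kinetic_parameters()] object (supplies `OSM_background`).
#' @return Osmolarity in mol/L.
#' @examples
#' osmolarity(liquid_state(G = 10 / GLUCOSE_G_MOL), kinetic_parameters())
#' @export
osmolarity <- function(state, p) {
  s <- validate_liquid_state(state)
  s[["G"]] + 2 * s[["Ac"]] + 2 * s[["CO2sol"]] + 2 * s[["Lac"]] +
    p$OSM_background
}

#' Growth-regulation factors
#'
#' Evaluates the Monod glucose limitation together with the critical-
#' concentration (Han-Levenspiel) inhibition/activation power laws for
#' dissolved hydrogen and osmolarity. The H2 inhibition factor
#' `1 - (H2aq/H2aq_crit)^n_H2` and activation factor `(H2aq/H2aq_crit)^n_H2`
#' are exact complements below the critical concentration; at and above it
#' the inhibition factor is clamped to 0 (the power law is only valid below
#' the critical value) and activation to 1. The osmolarity factor behaves
#' the same way, except that the activation term `act_osm` is left unclamped
#' because it drives lactate formation, which does not shut off above the
#' critical osmolarity.
#'
#' @inheritParams osmolarity
#' @return A list of class `regulation_factors` with components `monod`,
#'   `inhib_h2`, `act_h2`, `act_osm`, `osm_growth_factor`.
#' @export
regulation_factors <- function(state, p) {
  s <- validate_liquid_state(state)
  G <- s[["G"]]
  monod <- if (G <= 0) 0 else G / (G + p$K_G)
  ratio_h2 <- s[["H2aq"]] / p$H2aq_crit
  act_h2 <- if (ratio_h2 >= 1) 1 else ratio_h2^p$n_H2
  inhib_h2 <- 1 - act_h2
  act_osm <- (osmolarity(s, p) / p$OSM_crit)^p$n_mu
  osm_growth_factor <- max(0, 1 - act_osm)
  out <- list(monod = monod, inhib_h2 = inhib_h2, act_h2 = act_h2,
              act_osm = act_osm, osm_growth_factor = osm_growth_factor)
  class(out) <- "regulation_factors"
  out
}

#' Specific growth rate
#'
#' Monod kinetics on glucose multiplied by the osmolarity and dissolved-H2
#' inhibition factors; never negative.
#'
#' @inheritParams osmolarity
#' @return Specific growth rate mu (1/h).
#' @export
specific_growth_rate <- function(state, p) {
  f <- regulation_factors(state, p)
  max(0, p$mu_max * f$monod * f$osm_growth_factor * f$inhib_h2)
}

#' Growth-associated product formation coefficients
#'
#' Luedeking-Piret alpha coefficients (mol product per mol cells formed).
#' Acetate formation is proportional to the H2 inhibition factor; lactate is
#' activated both by dissolved H2 (hydrogenase back-pressure raising the
#' NADH/NAD ratio) and by osmolarity. H2 follows acetate scaled by the
#' estimated H2 yield, and CO2 follows H2 scaled back by the stoichiometric
#' CO2 yield, so that alpha_CO2 always equals alpha_Ac.
#'
#' @param f a [regulation_factors()] object.
#' @param p a [kinetic_parameters()] object.
#' @return A list of class `alpha_set` with `alpha_Ac`, `alpha_Lac`,
#'   `alpha_H2`, `alpha_CO2`.
#' @export
product_alphas <- function(f, p) {
  alpha_Ac <- p$R_AcF * f$inhib_h2
  alpha_Lac <- p$R_LacF_H2 * f$act_h2 + p$R_LacF_OSM * f$act_osm
  alpha_H2 <- alpha_Ac * (p$Y_GH2 / p$Y_GAc)
  alpha_CO2 <- alpha_H2 * (p$Y_GCO2 / p$Y_GH2)
  out <- list(alpha_Ac = alpha_Ac, alpha_Lac = alpha_Lac,
              alpha_H2 = alpha_H2, alpha_CO2 = alpha_CO2)
  class(out) <- "alpha_set"
  out
}

#' Liquid-phase derivative assembly
#'
#' Assembles the liquid mass balances: net cell growth `(mu - r_cd) X`,
#' growth-associated product formation `alpha_i mu X`, glucose consumption
#' by growth and by acetate/lactate formation, dissolved-gas depletion by
#' liquid-to-gas transfer, and carbonate interconversion. Transfer terms are
#' positive for liquid-to-gas flux and are supplied by the mass-transfer
#' layer; `carb_rate` is the CO2(aq) -> carbonates conversion rate.
#'
#' @inheritParams osmolarity
#' @param transfer_h2,transfer_co2 liquid-to-gas transfer rates (mol/L/h).
#' @param carb_rate carbonate formation rate (mol/L/h).
#' @return A named numeric vector of derivatives (mol/L/h) over the liquid
#'   state fields, with attributes `mu` and `alphas`.
#' @export
liquid_derivatives <- function(state, p, transfer_h2 = 0, transfer_co2 = 0,
                               carb_rate = 0) {
  s <- validate_liquid_state(state)
  f <- regulation_factors(s, p)
  mu <- max(0, p$mu_max * f$monod * f$osm_growth_factor * f$inhib_h2)
  a <- product_alphas(f, p)
  X <- s[["X"]]
  growth_flux <- mu * X
  dG <- -(1 / p$Y_GX + a$alpha_Ac / p$Y_GAc + a$alpha_Lac / p$Y_GLac) *
    growth_flux
  if (s[["G"]] <= 0) dG <- 0
  d <- c(X = (mu - p$r_cd) * X,
         G = dG,
         Ac = a$alpha_Ac * growth_flux,
         Lac = a$alpha_Lac * growth_flux,
         H2aq = a$alpha_H2 * growth_flux - transfer_h2,
         CO2aq = a$alpha_CO2 * growth_flux - transfer_co2 - carb_rate,
         CO2sol = carb_rate)
  attr(d, "mu") <- mu
  attr(d, "alphas") <- a
  d
}
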