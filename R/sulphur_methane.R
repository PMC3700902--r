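# Sulphide speciation, oxidation and FeS precipitation/dissolution; methane
# oxidation by oxygen or sulphate, pressure-dependent saturation and
# ebullition.

#' Diprotic sulphide speciation
#'
#' Partitions total dissolved sulphide over H2S, HS- and S2- at chemical
#' equilibrium for a given pH, using the two acidity constants. Species
#' fractions depend on pH only.
#'
#' @param SUD total dissolved sulphide, g S m-3 (pore water).
#' @param pH acidity.
#' @param co coefficients.
#' @return list with molar concentrations `H2S`, `HS`, `S2` (mol/L) and the
#'   dimensionless fractions `f_h2s`, `f_hs`, `f_s2`.
#' @export
sulphide_speciation <- function(SUD, pH, co = eco_coefficients()) {
  stopifnot(all(SUD >= 0), all(pH > 0), all(pH < 14))
  H <- 10^(-pH)
  den <- H^2 + co$Ks_1 * H + co$Ks_1 * co$Ks_2
  f_h2s <- H^2 / den
  f_hs <- co$Ks_1 * H / den
  f_s2 <- co$Ks_1 * co$Ks_2 / den
  tot <- SUD / (1000 * co$mw_s)  # mol/L
  list(H2S = f_h2s * tot, HS = f_hs * tot, S2 = f_s2 * tot,
       f_h2s = f_h2s, f_hs = f_hs, f_s2 = f_s2)
}

#' Sulphide oxidation rate
#'
#' First-order in both total dissolved sulphide and dissolved oxygen;
#' produces sulphate and consumes 2 g O2 per g S.
#'
#' @param SUD,DO pore-water concentrations, g m-3.
#' @param k_so rate at 20 degC, (g O2 m-3)-1 d-1.
#' @param T_deg temperature, degC.
#' @param co coefficients.
#' @return rate, g S m-3 d-1.
#' @export
sulphide_oxidation <- function(SUD, DO, k_so = NULL, T_deg = 20,
                               co = eco_coefficients()) {
  if (is.null(k_so)) k_so <- co$k_so
  temperature_adjust(k_so, co$kt_mic, T_deg, ts = co$ts) * SUD * DO
}

#' Quasi-equilibrium sulphide precipitation/dissolution over a time step
#'
#' Iron monosulphide precipitates when the free sulphide ion exceeds its
#' saturation concentration and dissolves when pore water is undersaturated
#' and particulate sulphide is present. Because the first-order rates are
#' very large (1e6 d-1 scale) the exchange is integrated analytically within
#' the step: the transfer relaxes exponentially towards the total dissolved
#' sulphide concentration at which the free ion equals saturation, so
#' dissolved sulphide effectively tracks the equilibrium. Dissolution is
#' limited by the available mineral.
#'
#' @param SUD total dissolved sulphide, g S m-3 pore water.
#' @param SUP particulate sulphide, g S m-3 pore-water basis (i.e. bulk/phi).
#' @param pH acidity.
#' @param dt time step, d.
#' @param co coefficients.
#' @return net transfer SUD -> SUP over the step, g S m-3 (pore-water
#'   basis); negative values are dissolution.
#' @export
sulphide_equilibration <- function(SUD, SUP, pH, dt, co = eco_coefficients()) {
  f_s2 <- sulphide_speciation(1, pH, co)$f_s2  # fraction is SUD-independent
  SUD_e <- co$Cs_e / f_s2 * 1000 * co$mw_s     # g S m-3 at saturation
  over <- pmax(0, SUD - SUD_e) * (1 - exp(-co$ks_p * dt))
  under <- pmin(pmax(0, SUD_e - SUD) * (1 - exp(-co$k_sd * dt)), pmax(0, SUP))
  over - under
}

#' Methane oxidation rates
#'
#' Michaelis-Menten in methane and in the oxidizing agent. Oxidation with
#' oxygen excludes oxidation with sulphate; the exclusion is implemented as
#' a smooth oxygen inhibition factor on the sulphate pathway.
#'
#' @param CH4,DO,SO4 pore-water concentrations, g m-3.
#' @param T_deg temperature, degC.
#' @param co coefficients.
#' @return list `rate_O2`, `rate_SO4`, g C m-3 d-1. The oxygen pathway
#'   consumes 5.33 g O2 per g C; the sulphate pathway consumes 2.67 g SO4-S
#'   per g C and releases the same mass as sulphide.
#' @export
methane_oxidation <- function(CH4, DO, SO4, T_deg = 20,
                              co = eco_coefficients()) {
  fm <- CH4 / (co$Ks_me + CH4)
  r_o2 <- temperature_adjust(co$k_moo, co$kt_mic, T_deg, ts = co$ts) *
    fm * DO / (co$Ks_moo + DO)
  r_so4 <- temperature_adjust(co$k_mos, co$kt_mic, T_deg, ts = co$ts) *
    fm * SO4 / (co$Ks_mos + SO4) * co$Ks_moo / (co$Ks_moo + DO)
  list(rate_O2 = r_o2, rate_SO4 = r_so4)
}

#' Methane saturation concentration
#'
#' Hydrostatic-pressure and temperature dependent solubility,
#' `CH4_s = base * (1 + Z/10) * kt^(20 - T)` with the base expressed in
#' g C m-3 at surface pressure and 20 degC.
#'
#' @param Z depth below the water surface, m.
#' @param T_deg temperature, degC.
#' @param co coefficients.
#' @return saturation concentration, g C m-3.
#' @export
methane_saturation <- function(Z, T_deg = 20, co = eco_coefficients()) {
  stopifnot(all(Z >= 0))
  co$ch4_sat_base * (1 + Z / 10) * co$ch4_sat_kt^(20 - T_deg)
}

#' Ebullition of supersaturated methane
#'
#' All methane in excess of the local saturation concentration is removed
#' instantly (gas bubbles escaping to the atmosphere).
#'
#' @param CH4 dissolved methane, g C m-3 (pore water).
#' @param CH4_s saturation concentration, g C m-3.
#' @return removed excess, g C m-3 (>= 0).
#' @export
ebullition_excess <- function(CH4, CH4_s) pmax(0, CH4 - CH4_s)
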