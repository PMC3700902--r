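# Nitrification, phosphate speciation (adsorption on redox-corrected
# reactive iron, vivianite-like and apatite-like minerals) and opal
# dissolution. Dissolved concentrations are pore-water based.

#' Nitrification rate
#'
#' Michaelis-Menten in both ammonium and dissolved oxygen with a maximum
#' volumetric rate that differs between water column and sediment.
#'
#' @param NH4,DO pore-water concentrations, g m-3.
#' @param k_ni maximum rate at 20 degC, g N m-3 d-1 (water 0.2, sediment 25).
#' @param T_deg temperature, degC.
#' @param co coefficients.
#' @return rate, g N m-3 d-1 (pore-water basis). Oxygen demand is
#'   `st_o2_n` = 4.57 g O2 per g N.
#' @export
nitrification_rate <- function(NH4, DO, k_ni, T_deg = 20,
                               co = eco_coefficients()) {
  temperature_adjust(k_ni, co$kt_mic, T_deg, ts = co$ts) *
    NH4 / (co$Ks_an + NH4) * DO / (co$Ks_do + DO)
}

#' Phosphate adsorption capacity
#'
#' Total molar adsorbent derived from the reactive iron content of the
#' inorganic sediment (or suspended sediment in the water column), expressed
#' per litre of pore water, and corrected for the oxidized iron(III)
#' fraction: the correction is 1 above a critical oxygen concentration and
#' ramps linearly down to `f_ox` at zero oxygen.
#'
#' @param IM1,IM3 bulk inorganic matter, g m-3 (IM1 bed silt, IM3 suspended).
#' @param fe,fe_i reactive iron mass fractions of IM1 and IM3.
#' @param f_ox residual oxidized iron fraction at anoxia.
#' @param DO pore-water oxygen, g O2 m-3.
#' @param phi porosity.
#' @param co coefficients.
#' @return total adsorbent `Cads_t`, mol sites per L pore water (vectorized).
#' @export
adsorption_capacity <- function(IM1, IM3 = 0, fe, fe_i = 0, f_ox, DO,
                                phi = 1, co = eco_coefficients()) {
  stopifnot(all(fe >= 0 & fe <= 1), all(fe_i >= 0 & fe_i <= 1))
  mol <- (fe * IM1 + fe_i * IM3) / (1000 * phi) / co$mw_fe
  corr <- f_ox + (1 - f_ox) * pmin(1, DO / co$do_crit)
  mol * corr
}

#' Langmuir equilibrium of adsorbed phosphate
#'
#' pH-dependent Langmuir isotherm: the effective affinity
#' `K_ads * (OH-)^(-a)` decreases as pH rises, reproducing desorption in
#' alkaline water. One mol P is allowed per mol of reactive iron site.
#'
#' @param Cads_t total adsorbent, mol/L (from [adsorption_capacity()]).
#' @param Cdp dissolved phosphate, mol/L.
#' @param pH acidity of the (pore) water.
#' @param co coefficients.
#' @return equilibrium adsorbed phosphate, mol/L; bounded by `Cads_t`,
#'   increasing in `Cdp`, decreasing in pH.
#' @export
phosphate_adsorption_equilibrium <- function(Cads_t, Cdp, pH,
                                             co = eco_coefficients()) {
  stopifnot(all(Cdp >= 0), all(pH > 0), all(pH < 14))
  OH <- 10^(pH - 14)
  Kl <- co$K_ads * OH^(-co$a_ads)
  Cads_t * Kl * Cdp / (1 + Kl * Cdp)
}

#' Sorption flux towards the Langmuir equilibrium
#'
#' First-order relaxation of adsorbed phosphate towards its equilibrium,
#' positive for adsorption (PO4 -> AAP).
#'
#' @param AAP,AAP_e actual and equilibrium adsorbed phosphate, g P m-3
#'   (bulk).
#' @param k_s sorption rate at 20 degC, d-1.
#' @param T_deg temperature, degC.
#' @param co coefficients.
#' @return flux, g P m-3 d-1.
#' @export
sorption_flux <- function(AAP, AAP_e, k_s = NULL, T_deg = 20,
                          co = eco_coefficients()) {
  if (is.null(k_s)) k_s <- co$k_s
  temperature_adjust(k_s, co$kt_mic, T_deg) * (AAP_e - AAP)
}

#' Vivianite-like mineral kinetics
#'
#' Precipitation is first-order in the supersaturation of dissolved
#' phosphate over the vivianite equilibrium and gated to anoxic conditions
#' (mean oxygen below the critical value); dissolution is proportional to
#' the mineral and dissolved oxygen.
#'
#' @param PO4 dissolved phosphate, g P m-3 (pore water).
#' @param VIVP vivianite-like phosphate, g P m-3 (bulk or pore basis, the
#'   rate follows the basis of the input).
#' @param DO pore-water oxygen, g O2 m-3.
#' @param co coefficients.
#' @return list `precipitation`, `dissolution`, both >= 0, g P m-3 d-1.
#' @export
vivianite_kinetics <- function(PO4, VIVP, DO, co = eco_coefficients()) {
  pre <- co$kv_p * pmax(0, PO4 - co$PO4_ve) * (DO < co$do_crit)
  dis <- co$kv_d * VIVP * DO
  list(precipitation = pre, dissolution = dis)
}

#' Apatite-like mineral kinetics
#'
#' Precipitation shares the phosphate supersaturation with vivianite through
#' the apatite:vivianite ratio `r_av` and is not redox-gated (calcium
#' phosphate stability does not depend on redox potential); dissolution
#' depends on both the undersaturation and the mineral concentration.
#'
#' @param PO4 dissolved phosphate, g P m-3 (pore water).
#' @param APATP apatite-like phosphate, g P m-3.
#' @param co coefficients.
#' @return list `precipitation`, `dissolution`, g P m-3 d-1.
#' @export
apatite_kinetics <- function(PO4, APATP, co = eco_coefficients()) {
  pre <- co$r_av * co$kv_p * pmax(0, PO4 - co$PO4_ae)
  dis <- co$k_ad * APATP * pmax(0, co$PO4_ae - PO4)
  list(precipitation = pre, dissolution = dis)
}

#' Opal silicate dissolution
#'
#' Proportional to the opal concentration and the undersaturation of
#' dissolved silicate relative to the equilibrium concentration.
#'
#' @param OPAL opal concentration, g Si m-3.
#' @param Si dissolved silicate, g Si m-3 (pore water).
#' @param k_od dissolution rate at 20 degC, (g Si m-3)-1 d-1.
#' @param Si_e equilibrium dissolved silicate, g Si m-3.
#' @param T_deg temperature, degC.
#' @param co coefficients.
#' @return rate, g Si m-3 d-1.
#' @export
opal_dissolution <- function(OPAL, Si, k_od = NULL, Si_e = NULL, T_deg = 20,
                             co = eco_coefficients()) {
  if (is.null(k_od)) k_od <- co$k_od
  if (is.null(Si_e)) Si_e <- co$Si_e
  temperature_adjust(k_od, co$kt_opal, T_deg) * OPAL * pmax(0, Si_e - Si)
}

#' Equilibrium partition of total phosphate over the Langmuir isotherm
#'
#' Splits a total (dissolved + adsorbed) phosphate pool into its
#' equilibrium dissolved and adsorbed parts for a given adsorption capacity
#' and pH-dependent affinity. Solving the partition for the closed total --
#' rather than evaluating the isotherm at the current dissolved
#' concentration -- keeps the sorption step unconditionally mass-limited:
#' the equilibrium adsorbed phase can never exceed the pool.
#'
#' @param Cads_t total adsorbent, mol/L.
#' @param Ptot total phosphate (dissolved + adsorbed), mol/L.
#' @param pH acidity.
#' @param co coefficients.
#' @return list with equilibrium `Cdp` and `Cap`, mol/L.
#' @export
phosphate_partition_equilibrium <- function(Cads_t, Ptot, pH,
                                            co = eco_coefficients()) {
  OH <- 10^(pH - 14)
  Kl <- co$K_ads * OH^(-co$a_ads)
  b <- 1 + Kl * (Cads_t - Ptot)
  Cdp <- (-b + sqrt(b^2 + 4 * Kl * Ptot)) / (2 * Kl)
  Cdp <- pmin(pmax(Cdp, 0), Ptot)
  list(Cdp = Cdp, Cap = Ptot - Cdp)
}

# unit bridge mol P per litre pore water <-> g P per m3 (pore water)
po4_gm3_to_molL <- function(x, co = eco_coefficients()) x / (1000 * co$mw_p)
po4_molL_to_gm3 <- function(x, co = eco_coefficients()) x * 1000 * co$mw_p
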