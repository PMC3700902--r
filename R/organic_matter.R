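# Multi-G decomposition of detrital organic matter: five fractions (POX1-4
# particulate, DOX dissolved) of C, N, P and S, mineralized with first-order
# kinetics and partially converted into the next, more refractory fraction.
# Mineralized carbon is allocated over the electron-acceptor cascade.

#' Nutrient availability modifier of the decomposition rate
#'
#' Detritus-decomposing bacteria mineralize nutrient-rich substrate faster.
#' The first-order rate of fractions with distinct minimum and maximum rates
#' is interpolated by this factor: 0 at or below the minimum N and P content
#' of the fraction, 1 at or above the maximum, linear in between, combined
#' Liebig-style as the minimum of the N- and P-based weights.
#'
#' @param NC,PC actual nitrogen and phosphorus content of the fraction,
#'   g N (P) per g C.
#' @param an_min,an_max,ap_min,ap_max content band bounds, g per g C.
#' @return interpolation weight in \[0, 1\] (vectorized).
#' @export
nutrient_rate_modifier <- function(NC, PC, an_min, an_max, ap_min, ap_max) {
  stopifnot(an_min < an_max, ap_min < ap_max)
  wn <- pmin(1, pmax(0, (NC - an_min) / (an_max - an_min)))
  wp <- pmin(1, pmax(0, (PC - ap_min) / (ap_max - ap_min)))
  pmin(wn, wp)
}

#' First-order mineralization rate of a detritus fraction
#'
#' `rate = T-adjusted(k_min + fnut * (k_max - k_min)) * fel * C`. The
#' electron-acceptor dependency `fel` is an interface hook fixed at 1 by
#' default. The dissolved fraction (j = 5) has a single rate and no nutrient
#' dependency.
#'
#' @param j fraction index 1..5.
#' @param C_j carbon concentration of the fraction, g C m-3.
#' @param fnut nutrient availability weight from [nutrient_rate_modifier()].
#' @param T_deg temperature, degC.
#' @param fel electron-acceptor factor (default 1).
#' @param co coefficients, see [eco_coefficients()].
#' @return mineralization rate, g C m-3 d-1.
#' @export
mineralization_rate <- function(j, C_j, fnut = 1, T_deg = 20, fel = NULL,
                                co = eco_coefficients()) {
  stopifnot(j %in% 1:5, all(C_j >= 0))
  if (is.null(fel)) fel <- co$fel
  k20 <- co$k_d_min[j] + fnut * (co$k_d_max[j] - co$k_d_min[j])
  temperature_adjust(k20, co$kt_dec, T_deg, ts = co$ts) * fel * C_j
}

#' Preferential nutrient stripping factor
#'
#' Organic N and P are mineralized faster than C when the fraction is richer
#' than the low "objective" content of the refractory residue:
#' `fac = max(1, content / target)`, so nutrient mineralization is never
#' slower than carbon mineralization and shows no acceleration at or below
#' the target content.
#'
#' @param content actual nutrient content, g X per g C.
#' @param target objective residual content `ar_x`, g X per g C.
#' @return acceleration factor >= 1 (vectorized).
#' @export
stripping_factor <- function(content, target) {
  stopifnot(all(content >= 0), target > 0)
  pmax(1, content / target)
}

#' Conversion fluxes between detritus fractions
#'
#' Conversion accompanies mineralization in fixed proportion: POX1 converts
#' to POX2, POX2 to POX3 and DOX, POX3 to POX4 and DOX; POX4 and DOX are
#' terminal. The same ratios apply to each element's own mineralization flux.
#'
#' @param mineralization numeric vector (or matrix, fractions in columns) of
#'   mineralization fluxes for fractions 1..4.
#' @param co coefficients.
#' @return list with `to_next` (fraction j -> j+1, j = 1..3) and `to_dox`
#'   (fractions 2 and 3 -> DOX).
#' @export
conversion_fluxes <- function(mineralization, co = eco_coefficients()) {
  m <- mineralization
  if (is.null(dim(m))) m <- matrix(m, nrow = 1)
  stopifnot(ncol(m) >= 4)
  list(to_next = sweep(m[, 1:3, drop = FALSE], 2, co$fc_p, "*"),
       to_dox  = m[, 2:3, drop = FALSE] * co$fc_d)
}

#' Electron-acceptor allocation of mineralization
#'
#' Scaled Michaelis-Menten limitation and inhibition factors partition
#' mineralized carbon over aerobic oxidation, denitrification, sulphate
#' reduction and methanogenesis. Denitrification is inhibited by oxygen,
#' sulphate reduction by nitrate and oxygen, methanogenesis by sulphate,
#' nitrate and oxygen. The four raw factors are rescaled to sum to exactly 1;
#' the methanogenesis factor is strictly positive whenever all acceptors
#' vanish, so the sum can never be zero.
#'
#' @param DO,NO3,SO4 pore-water concentrations, g m-3 (vectorized).
#' @param co coefficients.
#' @return matrix with columns `f_oc`, `f_de`, `f_sr`, `f_me`, rows summing
#'   to 1.
#' @export
electron_acceptor_fractions <- function(DO, NO3, SO4, co = eco_coefficients()) {
  stopifnot(all(DO >= 0), all(NO3 >= 0), all(SO4 >= 0))
  inh_do <- co$Ks_doi / (co$Ks_doi + DO)
  inh_no3 <- co$Ks_nii / (co$Ks_nii + NO3)
  l_oc <- DO / (co$Ks_oc + DO)
  l_de <- NO3 / (co$Ks_de + NO3) * inh_do
  l_sr <- SO4 / (co$Ks_sr + SO4) * inh_no3 * inh_do
  l_me <- co$Ks_sui / (co$Ks_sui + SO4) * inh_no3 * inh_do
  tot <- l_oc + l_de + l_sr + l_me
  cbind(f_oc = l_oc / tot, f_de = l_de / tot,
        f_sr = l_sr / tot, f_me = l_me / tot)
}

#' Electron-acceptor consumption and mineral products
#'
#' Converts a carbon mineralization flux, its acceptor allocation and the
#' mineralized organic N, P, S into substance rates-of-change: oxygen,
#' nitrate and sulphate consumption, methane production (methanogenic
#' carbon splits equally into methane and carbon dioxide), ammonium,
#' phosphate and sulphide release, and the carbon and nitrogen leaving the
#' modelled pools as CO2 and N2.
#'
#' @param minC carbon mineralization flux, g C m-3 d-1 (vectorized).
#' @param fractions matrix from [electron_acceptor_fractions()].
#' @param minN,minP,minS mineralized organic nutrient fluxes, g m-3 d-1.
#' @param co coefficients.
#' @return list of rate vectors: `dDO`, `dNO3`, `dSO4`, `dCH4`, `dNH4`,
#'   `dPO4`, `dSUD`, `co2` (C to CO2), `n2` (N to N2); consumption negative.
#' @export
acceptor_consumption <- function(minC, fractions, minN = 0, minP = 0,
                                 minS = 0, co = eco_coefficients()) {
  f <- fractions
  deni <- f[, "f_de"] * minC
  ch4 <- co$st_ch4_c * f[, "f_me"] * minC
  list(dDO = -co$st_o2_c * f[, "f_oc"] * minC,
       dNO3 = -co$st_no3_c * deni,
       dSO4 = -co$st_so4_c * f[, "f_sr"] * minC,
       dCH4 = ch4,
       dNH4 = minN, dPO4 = minP,
       dSUD = minS + co$st_so4_c * f[, "f_sr"] * minC,
       co2 = minC - ch4,
       n2 = co$st_no3_c * deni)
}
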