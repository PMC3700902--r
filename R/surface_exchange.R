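# Double-film gas exchange across the water surface: oxygen reaeration and
# methane volatilization.

#' Oxygen saturation concentration (solubility)
#'
#' Temperature- and chlorinity-dependent oxygen solubility following the
#' classical thermodynamic fit (exponential in inverse absolute temperature
#' with a salinity correction). Chlorinity is converted to salinity with
#' S = 1.80655 * Cl.
#'
#' @param T_deg water temperature, degC; values outside (-2, 40) are clamped
#'   with a warning.
#' @param chlorinity g Cl per kg (per mille); 0 for fresh water.
#' @return saturation concentration, g O2 m-3.
#' @export
oxygen_saturation <- function(T_deg, chlorinity = 0) {
  if (any(T_deg <= -2 | T_deg >= 40)) {
    warning("temperature outside (-2, 40) degC; clamped for solubility")
    T_deg <- pmin(pmax(T_deg, -2), 40)
  }
  TK <- T_deg + 273.15
  S <- 1.80655 * chlorinity
  lnC <- -173.4292 + 249.6339 * (100 / TK) + 143.3483 * log(TK / 100) -
    21.8492 * (TK / 100) +
    S * (-0.033096 + 0.014259 * (TK / 100) - 0.0017 * (TK / 100)^2)
  exp(lnC) * 1.42905  # mL/L -> g O2 m-3
}

#' Wind-dependent gas transfer coefficient
#'
#' Polynomial transfer velocity `a*sqrt(W) + b*W + c*W^2` (m d-1) with an
#' exponential temperature correction, clamped at a small positive floor so
#' calm conditions retain a minimal film exchange.
#'
#' @param W wind speed at 10 m, m s-1.
#' @param T_deg water temperature, degC.
#' @param co coefficients (polynomial constants `kl_a`, `kl_b`, `kl_c` and
#'   temperature coefficient `kl_kt`).
#' @return transfer coefficient, m d-1 (>= 0).
#' @export
transfer_coefficient <- function(W, T_deg = 20, co = eco_coefficients()) {
  stopifnot(all(W >= 0))
  kl <- co$kl_a * sqrt(W) + co$kl_b * W + co$kl_c * W^2
  pmax(kl, 0.05) * co$kl_kt^(T_deg - 20)
}

#' Surface gas flux as a volumetric rate
#'
#' Double-film flux `k_l * (C_s - C)` distributed over the depth of the
#' surface-mixed water cell: positive values replenish an undersaturated
#' water column.
#'
#' @param C actual concentration, g m-3.
#' @param C_s saturation concentration, g m-3.
#' @param k_l transfer coefficient, m d-1.
#' @param Z depth of the mixed water cell, m.
#' @return rate of change, g m-3 d-1.
#' @export
gas_flux <- function(C, C_s, k_l, Z) {
  stopifnot(all(Z > 0))
  k_l * (C_s - C) / Z
}
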